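# Published tallies of the New World snake mimicry system. These counts
# summarize the empirical phenotype classification and range-construction
# effort for coral snakes and their presumed mimics; the derived
# percentages are recomputed from the raw counts, never stored.

#' Species and population tallies of the coral-snake mimicry system
#'
#' Raw counts from the published phenotypic classification of red-black
#' banded (RBB) coloration across snakes and the accompanying range
#' compilation: species assigned to RBB colour categories in the New and
#' Old World, the approximate number of described snake species, range
#' construction coverage for continental New World species, and
#' polymorphism tallies in the Sonorini focal clade.
#'
#' @return tibble with columns `quantity` and `count`.
#' @export
mimicry_census <- function() {
  tibble::tribble(
    ~quantity, ~count,
    "rbb_species_new_world", 231,
    "rbb_species_old_world", 24,
    "described_snake_species", 3500,
    "continental_new_world_species", 1328,
    "ranges_constructed", 1107,
    "coral_snake_species_with_ranges", 78,
    "coral_snake_species_identified", 80,
    "mimetic_species_with_ranges", 133,
    "mimetic_species_identified", 151,
    "polymorphic_populations", 35,
    "populations_assessed", 41
  )
}

#' Derived summary statistics of the mimicry census
#'
#' Recomputes, from the raw counts in [mimicry_census()], the headline
#' descriptive figures of the system: the total number of RBB-classified
#' species, the global prevalence of the RBB phenotype, the fraction of
#' continental New World species with constructed ranges, and the
#' fraction of assessed populations that are colour-polymorphic.
#'
#' @return tibble with columns `statistic` and `value` (percentages on a
#'   0-100 scale).
#' @export
census_summary <- function() {
  cs <- mimicry_census()
  g <- function(q) cs$count[cs$quantity == q]
  classified <- g("rbb_species_new_world") + g("rbb_species_old_world")
  tibble::tibble(
    statistic = c("rbb_species_classified",
                  "rbb_prevalence_pct",
                  "range_coverage_pct",
                  "polymorphic_population_pct"),
    value = c(classified,
              100 * classified / g("described_snake_species"),
              100 * g("ranges_constructed") /
                g("continental_new_world_species"),
              100 * g("polymorphic_populations") /
                g("populations_assessed")))
}
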