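# Structure-preserving permutation null for the co-occurrence test: the
# species identity tags of all non-model range polygons are shuffled
# (without replacement) before richness rasters are rebuilt. Because the
# polygons themselves never move, every null iteration preserves exactly
# (a) the range distributions, (b) the per-cell total richness and (c) the
# model-species raster.

#' Permutation test of the model->mimic richness association
#'
#' The observed statistic is the OLS slope of mimic richness on model
#' richness (controlling for total richness); the null distribution
#' shuffles the mimic/other identity tags across all non-model polygons
#' and recomputes the slope from the re-assembled rasters. The one-tailed
#' p value is the fraction of null slopes greater than or equal to the
#' observed slope; since a zero count is conventionally reported as an
#' inequality, the `(b + 1)/(n + 1)` upper bound is returned alongside.
#'
#' @param presence per-species presence raster from
#'   [rasterize_presence()].
#' @param tags data frame with columns `species`, `tag` (`"model"`,
#'   `"mimic"`, `"other"`).
#' @param n_iter number of permutations (the motivating analysis used
#'   1000).
#' @param subset cells entering the regression: containing at least one
#'   model (`"model"`, default) or at least one mimic in the *observed*
#'   data (`"mimic"`); the subset stays fixed across iterations.
#' @param include_interaction add a model x total interaction term
#'   (default FALSE: additive model).
#' @param seed RNG seed.
#' @return object of class `permutation_result`: `observed_slope`,
#'   `null_slopes`, `p`, `p_upper_bound`, `n_iter`, and `cells` (the cell
#'   table with observed mimic counts, null means and the standardized
#'   residual z from [residual_z()]).
#' @export
permutation_test <- function(presence, tags, n_iter = 1000,
                             subset = c("model", "mimic"),
                             include_interaction = FALSE, seed = NULL) {
  subset <- match.arg(subset)
  sp <- species_columns(presence)
  tags <- tags[match(sp, tags$species), ]
  if (!any(tags$tag == "mimic") || !any(tags$tag == "model"))
    mim_abort("need at least one mimic and one model species",
              "invalid_argument")
  mat <- as.matrix(presence[sp])
  onland <- presence$onland
  model_rich <- rowSums(mat[, tags$tag == "model", drop = FALSE])
  total_rich <- rowSums(mat)
  nonmodel <- which(tags$tag != "model")
  nm_tags <- tags$tag[nonmodel]
  mimic_of <- function(tag_perm) {
    cols <- nonmodel[tag_perm == "mimic"]
    rowSums(mat[, cols, drop = FALSE])
  }
  mimic_rich <- mimic_of(nm_tags)
  keep <- onland & (if (subset == "model") model_rich else mimic_rich) >= 1
  slope_of <- function(mimic) {
    df <- data.frame(mimic = mimic[keep], model = model_rich[keep],
                     total = total_rich[keep])
    f <- if (include_interaction) mimic ~ model * total
         else mimic ~ model + total
    stats::coef(stats::lm(f, data = df))[["model"]]
  }
  observed <- slope_of(mimic_rich)
  null_mean <- numeric(nrow(mat))
  null_sq <- numeric(nrow(mat))
  null_slopes <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    perm <- sample(nm_tags)
    mim <- mimic_of(perm)
    null_mean <<- null_mean + mim
    null_sq <<- null_sq + mim^2
    slope_of(mim)
  }, numeric(1)))
  null_mean <- null_mean / n_iter
  null_sd <- sqrt(pmax(0, null_sq / n_iter - null_mean^2))
  cells <- tibble::tibble(
    x = presence$x, y = presence$y, onland = onland,
    mimic = mimic_rich, model = model_rich, total = total_rich,
    null_mean = null_mean, null_sd = null_sd,
    z = residual_z(mimic_rich, null_mean))
  cells$mimic[!onland] <- NA_real_
  structure(list(observed_slope = observed, null_slopes = null_slopes,
                 p = sum(null_slopes >= observed) / n_iter,
                 p_upper_bound = (sum(null_slopes >= observed) + 1) /
                   (n_iter + 1),
                 n_iter = n_iter, subset = subset, seed = seed,
                 cells = cells),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test (", x$n_iter, " iterations, subset = ",
      x$subset, " cells)\n", sep = "")
  cat("observed model-richness slope:", signif(x$observed_slope, 4), "\n")
  cat("one-tailed p =", x$p, if (x$p == 0)
    paste0("(p < ", signif(x$p_upper_bound, 3), ")"), "\n")
  invisible(x)
}
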