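# Placing trait gains and losses in latitude and time: Brownian-motion
# ancestral latitudes, linear interpolation of event positions along
# branches, kernel density and time x latitude summaries, zone ratios,
# and a contrasts-based test of latitudinal conservatism.

#' Brownian-motion ancestral latitudes
#'
#' Maximum-likelihood (generalized least squares) ancestral estimates of a
#' continuous character under single-rate Brownian motion: internal node
#' values minimize the sum over branches of squared changes divided by
#' branch length, a sparse harmonic system solved directly. The REML rate
#' estimate (mean squared standardized contrast) is attached.
#'
#' @param tree a `phylo` (need not be ultrametric).
#' @param tip_latitudes named numeric vector over tips (degrees), or data
#'   frame with columns `species`, `latitude`.
#' @return list with `node_latitudes` (internal nodes, ape numbering),
#'   `all` (tips then internal nodes) and `sigma2` (REML, degrees^2/Myr).
#' @export
bm_ancestral_latitudes <- function(tree, tip_latitudes) {
  if (is.data.frame(tip_latitudes))
    tip_latitudes <- stats::setNames(tip_latitudes$latitude,
                                     tip_latitudes$species)
  miss <- setdiff(tree$tip.label, names(tip_latitudes))
  if (length(miss) > 0)
    mim_abort(paste("missing latitudes for:",
                    paste(utils::head(miss, 5), collapse = ", ")),
              "invalid_argument")
  y <- as.numeric(tip_latitudes[tree$tip.label])
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  len <- pmax(tree$edge.length, 1e-8) # guard zero-length branches
  wts <- 1 / len
  A <- matrix(0, nint, nint)
  b <- numeric(nint)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1] - ntip
    ch <- tree$edge[e, 2]
    w <- wts[e]
    A[par, par] <- A[par, par] + w
    if (ch > ntip) {
      ci <- ch - ntip
      A[ci, ci] <- A[ci, ci] + w
      A[par, ci] <- A[par, ci] - w
      A[ci, par] <- A[ci, par] - w
    } else {
      b[par] <- b[par] + w * y[ch]
    }
  }
  anc <- solve(A, b)
  bt <- tree
  bt$edge.length <- len
  if (!ape::is.binary(bt)) bt <- ape::multi2di(bt)
  bt$edge.length <- pmax(bt$edge.length, 1e-8)
  contrasts <- ape::pic(stats::setNames(y, tree$tip.label), bt)
  list(node_latitudes = anc, all = c(y, anc),
       sigma2 = mean(contrasts^2))
}

#' Interpolated latitude of a change event on a branch
#'
#' An event at fractional position `delta` along a branch (0 = parent
#' node, 1 = descendant node) gets the linearly interpolated latitude
#' `delta * child_lat + (1 - delta) * parent_lat`, so `delta = 0.5` gives
#' the branch midpoint and `delta = 0.1` a point 10% of the way from the
#' parent toward the descendant.
#'
#' @param parent_lat,child_lat node latitudes (degrees).
#' @param delta fractional time along the branch, in `[0, 1]`.
#' @return interpolated latitude (degrees).
#' @export
interpolate_event_latitude <- function(parent_lat, child_lat, delta) {
  if (any(delta < 0 | delta > 1))
    mim_abort("delta must be in [0, 1]", "invalid_argument")
  delta * child_lat + (1 - delta) * parent_lat
}

#' Locate every mapped change event in latitude and time
#'
#' @param ensemble a [sample_map_ensemble()] result (or a list of
#'   [character_map()]s plus a `tree`).
#' @param latitudes per-node latitudes: the `all` element of
#'   [bm_ancestral_latitudes()] (tips then internal nodes) or any numeric
#'   vector indexed by ape node number.
#' @return tibble with one row per change event per map: `map`, `edge`,
#'   `type` (`"gain"`/`"loss"`), `delta`, `parent_lat`, `child_lat`,
#'   `latitude`, `age_mya`.
#' @export
locate_events <- function(ensemble, latitudes) {
  tree <- ensemble$tree
  depth <- node_depths(tree)
  Tmax <- max(depth)
  rows <- lapply(seq_along(ensemble$maps), function(i) {
    ev <- ensemble$maps[[i]]$events
    if (nrow(ev) == 0) return(NULL)
    par <- tree$edge[ev$edge, 1]
    ch <- tree$edge[ev$edge, 2]
    len <- tree$edge.length[ev$edge]
    delta <- ev$time / len
    tibble::tibble(
      map = i, edge = ev$edge,
      type = ifelse(ev$to_state == 1L, "gain", "loss"),
      delta = delta,
      parent_lat = latitudes[par], child_lat = latitudes[ch],
      latitude = interpolate_event_latitude(latitudes[par],
                                            latitudes[ch], delta),
      age_mya = Tmax - (depth[par] + ev$time))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(map = integer(0), edge = integer(0),
                          type = character(0), delta = numeric(0),
                          parent_lat = numeric(0), child_lat = numeric(0),
                          latitude = numeric(0), age_mya = numeric(0))
  out
}

#' Kernel density of event latitudes
#'
#' Gaussian KDE (Silverman's rule by default) of the latitudes of gains or
#' losses across the map ensemble.
#'
#' @param events tibble from [locate_events()].
#' @param type `"gain"` or `"loss"`.
#' @param bandwidth numeric bandwidth in degrees, or `"nrd0"`.
#' @return tibble with `latitude` and `density` (integrates to ~1).
#' @export
event_latitude_density <- function(events, type = c("loss", "gain"),
                                   bandwidth = "nrd0") {
  type <- match.arg(type)
  x <- events$latitude[events$type == type]
  if (length(x) == 0)
    mim_abort(paste("no", type, "events"), "empty_density")
  d <- stats::density(x, bw = bandwidth)
  tibble::tibble(latitude = d$x, density = d$y)
}

#' Time x latitude grid of mean event counts
#'
#' Bins events into a time x latitude grid; each cell holds the mean
#' number of events of each type per map, and both grids are then divided
#' by their joint maximum so gains and losses are directly comparable.
#'
#' @param events tibble from [locate_events()].
#' @param n_maps ensemble size the means are taken over.
#' @param time_breaks,lat_breaks bin edges (Mya and degrees).
#' @return tibble with bin midpoints `age_mya`, `latitude` and scaled
#'   `gain`/`loss` columns; unscaled per-map means in attribute
#'   `"unscaled"`.
#' @export
time_latitude_grid <- function(events, n_maps,
                               time_breaks = NULL, lat_breaks = NULL) {
  time_breaks <- time_breaks %||%
    pretty(range(events$age_mya, finite = TRUE), 10)
  lat_breaks <- lat_breaks %||%
    pretty(range(events$latitude, finite = TRUE), 10)
  tb <- cut(events$age_mya, time_breaks, include.lowest = TRUE)
  lb <- cut(events$latitude, lat_breaks, include.lowest = TRUE)
  grid <- expand.grid(time_bin = levels(tb), lat_bin = levels(lb),
                      stringsAsFactors = FALSE)
  # table() keeps all factor levels; as.vector is column-major (time
  # fastest), matching the expand.grid order
  cnt <- function(tp) {
    sel <- events$type == tp
    as.vector(table(tb[sel], lb[sel])) / n_maps
  }
  gain <- cnt("gain")
  loss <- cnt("loss")
  mx <- max(c(gain, loss), 0)
  tmid <- (time_breaks[-1] + time_breaks[-length(time_breaks)]) / 2
  lmid <- (lat_breaks[-1] + lat_breaks[-length(lat_breaks)]) / 2
  out <- tibble::tibble(
    age_mya = rep(tmid, times = length(lmid)),
    latitude = rep(lmid, each = length(tmid)),
    gain = if (mx > 0) gain / mx else gain,
    loss = if (mx > 0) loss / mx else loss)
  attr(out, "unscaled") <- tibble::tibble(age_mya = out$age_mya,
                                          latitude = out$latitude,
                                          gain = gain, loss = loss)
  attr(out, "max_mean_events") <- mx
  out
}

#' Tropical vs north-temperate loss ratio
#'
#' Ratio of mean per-map loss counts in the tropics (latitude in
#' `[-23, 23]`, closed) to the northern temperate zone (`(23, 35]`,
#' half-open). Undefined (flagged, not an error) when the temperate count
#' is zero.
#'
#' @param events tibble from [locate_events()].
#' @param n_maps ensemble size.
#' @return list with `ratio`, `tropical_mean`, `temperate_mean`,
#'   `undefined`.
#' @export
zone_loss_ratio <- function(events, n_maps) {
  losses <- events[events$type == "loss", ]
  trop <- sum(losses$latitude >= -23 & losses$latitude <= 23) / n_maps
  temp <- sum(losses$latitude > 23 & losses$latitude <= 35) / n_maps
  list(ratio = if (temp > 0) trop / temp else NA_real_,
       tropical_mean = trop, temperate_mean = temp,
       undefined = temp == 0)
}

#' Phylogenetic conservatism of latitudinal midpoints
#'
#' Compares the variance of phylogenetic independent contrasts of tip
#' latitudes with its null distribution under random permutation of the
#' tip values. Strongly clustered (conserved) latitudes give an observed
#' variance far below the null, i.e. a large negative z.
#'
#' @inheritParams bm_ancestral_latitudes
#' @param n_perm number of tip-label permutations (>= 100).
#' @param seed RNG seed.
#' @return object of class `conservatism_result`: `observed_variance`,
#'   `null_mean`, `null_sd`, `z`, `p` (one-tailed, lower), `n_perm`,
#'   `degenerate`.
#' @export
pic_conservatism <- function(tree, tip_latitudes, n_perm = 999,
                             seed = NULL) {
  if (is.data.frame(tip_latitudes))
    tip_latitudes <- stats::setNames(tip_latitudes$latitude,
                                     tip_latitudes$species)
  y <- as.numeric(tip_latitudes[tree$tip.label])
  if (stats::sd(y) == 0)
    mim_abort("tip latitudes are constant", "zero_variance")
  bt <- tree
  if (!ape::is.binary(bt)) {
    warn("polytomies resolved arbitrarily with zero-length branches")
    bt <- ape::multi2di(bt)
  }
  bt$edge.length <- pmax(bt$edge.length, 1e-8)
  vpic <- function(v) stats::var(ape::pic(
    stats::setNames(v, bt$tip.label), bt))
  obs <- vpic(y)
  null <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) vpic(sample(y)), numeric(1)))
  nm <- mean(null)
  ns <- stats::sd(null)
  degenerate <- !is.finite(ns) || ns == 0
  structure(list(observed_variance = obs, null_mean = nm, null_sd = ns,
                 z = if (degenerate) NA_real_ else (obs - nm) / ns,
                 p = (1 + sum(null <= obs)) / (n_perm + 1),
                 n_perm = n_perm, degenerate = degenerate, seed = seed),
            class = "conservatism_result")
}

#' @export
print.conservatism_result <- function(x, ...) {
  cat("PIC conservatism test (", x$n_perm, " permutations)\n", sep = "")
  cat("observed contrast variance:", signif(x$observed_variance, 4),
      " null mean:", signif(x$null_mean, 4), "\n")
  cat("z =", signif(x$z, 4), ", one-tailed p =", signif(x$p, 4), "\n")
  invisible(x)
}
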