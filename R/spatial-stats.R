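# Spatial regression machinery for the model-mimic co-occurrence test:
# great-circle neighbour weights, maximum-likelihood SAR error models with
# stepwise neighbourhood selection, and Moran's I of residuals.

EARTH_RADIUS_KM <- 6371

haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

cell_distances_km <- function(cells) {
  n <- nrow(cells)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- haversine_km(cells$x[i], cells$y[i],
                                       cells$x[j], cells$y[j])
  }
  d
}

#' Smallest neighbourhood radius leaving no cell isolated
#'
#' @param cells data frame with midpoint columns `x`, `y` (degrees).
#' @return distance in km such that every cell has at least one neighbour.
#' @export
min_feasible_threshold <- function(cells) {
  d <- cell_distances_km(cells)
  diag(d) <- Inf
  max(apply(d, 1, min))
}

#' Build a spatial neighbour-weight matrix
#'
#' Neighbours are cell pairs whose great-circle midpoint distance
#' (haversine, spherical Earth R = 6371 km) is within `threshold_km`.
#' Weight styles: `binary` (1), `distance` (d_ij) and `inverse` (1/d_ij);
#' rows are standardized to sum to one.
#'
#' @param cells data frame with columns `x`, `y` (degree midpoints).
#' @param threshold_km neighbourhood radius in km.
#' @param style one of `"binary"`, `"distance"`, `"inverse"`.
#' @param row_standardize divide each row by its sum (default TRUE).
#' @return object of class `neighbor_weights`: list with matrix `W`, the
#'   raw symmetric weights `S`, `threshold_km`, `style`.
#' @export
build_neighbor_weights <- function(cells, threshold_km,
                                   style = c("binary", "distance",
                                             "inverse"),
                                   row_standardize = TRUE) {
  style <- match.arg(style)
  d <- cell_distances_km(cells)
  diag(d) <- Inf
  nb <- d <= threshold_km
  isolated <- which(rowSums(nb) == 0)
  if (length(isolated) > 0)
    mim_abort(paste0("threshold ", threshold_km, " km leaves cell(s) ",
                     paste(utils::head(isolated, 5), collapse = ", "),
                     " without neighbours"),
              "infeasible_threshold", cells = isolated)
  S <- matrix(0, nrow(d), ncol(d))
  S[nb] <- switch(style,
                  binary = 1,
                  distance = d[nb],
                  inverse = 1 / d[nb])
  W <- if (row_standardize) S / rowSums(S) else S
  structure(list(W = W, S = S, threshold_km = threshold_km, style = style,
                 row_standardized = row_standardize, n = nrow(d)),
            class = "neighbor_weights")
}

# Real eigenvalues of W: a row-standardized symmetric-similarity matrix
# D^-1 S is similar to the symmetric D^-1/2 S D^-1/2.
weights_eigenvalues <- function(w) {
  if (w$row_standardized) {
    r <- rowSums(w$S)
    B <- w$S / sqrt(outer(r, r))
    eigen(B, symmetric = TRUE, only.values = TRUE)$values
  } else {
    Re(eigen(w$W, only.values = TRUE)$values)
  }
}

#' Fit a spatial autoregressive (SAR) error model by maximum likelihood
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma2 I)`,
#' profiling beta and sigma2 out of the likelihood and optimizing the
#' spatial error coefficient lambda over its stable interval.
#'
#' @param y numeric response (e.g. mimic richness per cell).
#' @param X numeric matrix or data frame of predictors (an intercept is
#'   added automatically).
#' @param w a [build_neighbor_weights()] object.
#' @return object of class `sar_fit` with coefficients, z statistics,
#'   lambda, logLik, AIC, residuals and Moran's I of the residuals.
#' @export
fit_sar_error <- function(y, X, w) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- cbind(`(Intercept)` = 1, X)
  n <- length(y)
  if (qr(X)$rank < ncol(X))
    mim_abort("predictors are collinear", "invalid_argument")
  ev <- weights_eigenvalues(w)
  lo <- 1 / min(ev) + 1e-6
  hi <- 1 / max(ev) - 1e-6
  W <- w$W
  prof <- function(lambda) {
    A <- diag(n) - lambda * W
    ys <- A %*% y
    Xs <- A %*% X
    fit <- stats::lm.fit(Xs, ys)
    s2 <- sum(fit$residuals^2) / n
    ldet <- sum(log(1 - lambda * ev))
    ll <- -n / 2 * (log(2 * pi) + log(s2) + 1) + ldet
    list(ll = ll, beta = fit$coefficients, s2 = s2, Xs = Xs,
         resid_sp = fit$residuals)
  }
  opt <- stats::optimize(function(l) -prof(l)$ll, c(lo, hi), tol = 1e-8)
  lambda <- opt$minimum
  at <- prof(lambda)
  # beta covariance from the GLS information; lambda SE from the curvature
  # of the profile likelihood.
  vc <- at$s2 * solve(crossprod(at$Xs))
  se <- sqrt(diag(vc))
  zval <- at$beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  h <- 1e-4 * max(1, abs(lambda))
  d2 <- (prof(lambda + h)$ll - 2 * at$ll + prof(lambda - h)$ll) / h^2
  lambda_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  resid <- as.vector(y - X %*% at$beta) # response-scale residuals
  k <- ncol(X) + 2 # betas + lambda + sigma2
  structure(list(
    coefficients = stats::setNames(as.vector(at$beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(as.vector(zval), colnames(X)),
    p = stats::setNames(as.vector(pval), colnames(X)),
    lambda = lambda, lambda_se = lambda_se, sigma2 = at$s2,
    logLik = at$ll, k = k, AIC = 2 * k - 2 * at$ll,
    residuals = resid, residuals_spatial = as.vector(at$resid_sp),
    moran_residuals = morans_i(as.vector(at$resid_sp), w, n_perm = 0),
    n = n, weights = w
  ), class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("SAR error model (ML), n =", x$n, "\n")
  cat("lambda =", signif(x$lambda, 4), " logLik =", signif(x$logLik, 6),
      " AIC =", signif(x$AIC, 6), "\n")
  print(tibble::tibble(term = names(x$coefficients),
                       estimate = x$coefficients, std.error = x$se,
                       statistic = x$z, p.value = x$p))
  invisible(x)
}

#' Select the best neighbourhood size and weighting by AIC
#'
#' Grid search over neighbourhood radii in `step_km` increments starting at
#' the smallest feasible radius, crossed with the three weight styles; the
#' SAR error fit with minimum AIC wins.
#'
#' @inheritParams fit_sar_error
#' @param cells cell table with `x`, `y` midpoints.
#' @param step_km radius increment (default 50 km).
#' @param n_steps number of radii to try.
#' @return list with `fit` (best [fit_sar_error()]), `threshold_km`,
#'   `style`, and `aic_table` (tibble of all candidates).
#' @export
select_neighborhood <- function(y, X, cells, step_km = 50, n_steps = 8) {
  t0 <- ceiling(min_feasible_threshold(cells))
  thresholds <- t0 + step_km * (seq_len(n_steps) - 1)
  styles <- c("binary", "distance", "inverse")
  rows <- list()
  best <- NULL
  for (th in thresholds) {
    for (st in styles) {
      res <- tryCatch({
        w <- build_neighbor_weights(cells, th, st)
        fit_sar_error(y, X, w)
      }, error = function(e) e)
      ok <- inherits(res, "sar_fit")
      rows[[length(rows) + 1]] <- tibble::tibble(
        threshold_km = th, style = st,
        AIC = if (ok) res$AIC else NA_real_,
        logLik = if (ok) res$logLik else NA_real_,
        lambda = if (ok) res$lambda else NA_real_,
        error = if (ok) NA_character_ else conditionMessage(res))
      if (ok && (is.null(best) || res$AIC < best$fit$AIC))
        best <- list(fit = res, threshold_km = th, style = st)
    }
  }
  if (is.null(best))
    mim_abort("no feasible neighbourhood candidate", "infeasible_threshold")
  best$aic_table <- dplyr::bind_rows(rows)
  best
}

#' Moran's I with permutation test
#'
#' `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' variable and `S0` the total weight. The p value is from random
#' permutations of the values across cells.
#'
#' @param x numeric vector over cells (non-constant).
#' @param w a [build_neighbor_weights()] object.
#' @param n_perm number of permutations (0 skips the test).
#' @param alternative `"greater"` (positive autocorrelation), `"less"` or
#'   `"two.sided"`.
#' @param seed RNG seed for the permutations.
#' @return list with `I`, `expectation` (-1/(n-1)), `p`, `n_perm`.
#' @export
morans_i <- function(x, w, n_perm = 999, alternative = "greater",
                     seed = NULL) {
  if (stats::sd(x) == 0)
    mim_abort("Moran's I is undefined for a constant variable",
              "undefined_statistic")
  W <- w$W
  n <- length(x)
  stat <- function(v) {
    z <- v - mean(v)
    (n / sum(W)) * as.vector(z %*% W %*% z) / sum(z^2)
  }
  I <- stat(x)
  p <- NA_real_
  if (n_perm > 0) {
    null <- with_seed(seed, vapply(seq_len(n_perm),
                                   function(i) stat(sample(x)), numeric(1)))
    p <- switch(alternative,
      greater = (1 + sum(null >= I)) / (n_perm + 1),
      less = (1 + sum(null <= I)) / (n_perm + 1),
      two.sided = (1 + sum(abs(null - mean(null)) >=
                             abs(I - mean(null)))) / (n_perm + 1))
  }
  list(I = I, expectation = -1 / (n - 1), p = p, n_perm = n_perm)
}

#' Standardized residual of observed vs null-mean counts
#'
#' The chi-squared-framework z residual `z = (f - fbar) / sqrt(fbar)`
#' comparing an observed per-cell count with its mean over null
#' randomizations; undefined (NA) where the null mean is zero. Set
#' `denominator = "sd"` to standardize by the null standard deviation
#' instead.
#'
#' @param f observed counts (>= 0).
#' @param fbar null mean counts (>= 0).
#' @param null_sd null standard deviations (required for
#'   `denominator = "sd"`).
#' @param denominator `"sqrt_mean"` (default) or `"sd"`.
#' @return numeric vector of z scores with NA where undefined.
#' @export
residual_z <- function(f, fbar, null_sd = NULL,
                       denominator = c("sqrt_mean", "sd")) {
  denominator <- match.arg(denominator)
  if (any(f < 0, na.rm = TRUE) || any(fbar < 0, na.rm = TRUE))
    mim_abort("counts must be non-negative", "invalid_argument")
  den <- if (denominator == "sqrt_mean") sqrt(fbar) else null_sd
  if (is.null(den))
    mim_abort("null_sd required for denominator = 'sd'", "invalid_argument")
  out <- (f - fbar) / den
  out[den == 0] <- NA_real_
  out
}
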