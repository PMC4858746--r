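# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fit_sar_error coefficient table.
#' @param x a fitted object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.sar_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(x$z),
                 p.value = unname(x$p))
}

#' @describeIn fit_sar_error one-row model summary.
#' @exportS3Method generics::glance
glance.sar_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, lambda.se = x$lambda_se,
                 sigma2 = x$sigma2, logLik = x$logLik, AIC = x$AIC,
                 moran.I = x$moran_residuals$I, nobs = x$n)
}

#' @describeIn permutation_test one-row summary.
#' @exportS3Method generics::glance
glance.permutation_result <- function(x, ...) {
  tibble::tibble(observed_slope = x$observed_slope, p.value = x$p,
                 p.upper.bound = x$p_upper_bound, n_iter = x$n_iter,
                 null_mean = mean(x$null_slopes),
                 null_sd = stats::sd(x$null_slopes))
}

#' @describeIn stepwise_partition_search per-step AIC trace.
#' @exportS3Method generics::tidy
tidy.partition_search <- function(x, ...) x$trace

#' @describeIn stepwise_partition_search one-row summary of the final
#'   model.
#' @exportS3Method generics::glance
glance.partition_search <- function(x, ...) {
  tibble::tibble(n_matrices = x$model$n_matrices,
                 k = partition_k(x$model$n_matrices),
                 logLik = x$loglik, AIC = x$AIC,
                 n_shifts = length(x$model$shift_nodes))
}

#' @describeIn mcmc_rates per-parameter posterior summary with 95%
#'   credible intervals and effective sample sizes.
#' @exportS3Method generics::tidy
tidy.rate_posterior <- function(x, ...) {
  s <- x$samples
  tibble::tibble(
    term = names(s),
    estimate = vapply(s, mean, numeric(1)),
    std.error = vapply(s, stats::sd, numeric(1)),
    conf.low = vapply(s, stats::quantile, numeric(1), probs = 0.025),
    conf.high = vapply(s, stats::quantile, numeric(1), probs = 0.975),
    ess = x$ess)
}

#' @describeIn pic_conservatism one-row summary.
#' @exportS3Method generics::glance
glance.conservatism_result <- function(x, ...) {
  tibble::tibble(observed_variance = x$observed_variance,
                 null_mean = x$null_mean, null_sd = x$null_sd,
                 z = x$z, p.value = x$p, n_perm = x$n_perm)
}
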