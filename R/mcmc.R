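# Bayesian estimation of partition rates: Metropolis-Hastings on log
# rates with independent exponential priors whose mean is a multiple
# (default 10) of the whole-tree symmetric ML rate. Partition locations
# stay fixed (hybrid ML-location / Bayesian-rates design).

#' Prior specification for Bayesian rate estimation
#'
#' @param tree,states data used to compute the whole-tree symmetric rate.
#' @param multiplier exponential prior mean = `multiplier` x whole-tree
#'   symmetric ML rate (default 10).
#' @param root_p1 prior probability of the derived (RBB) state at the root
#'   in fixed-root mode (default 0.05).
#' @return list of class `prior_spec` with `prior_mean`, `multiplier`,
#'   `whole_tree_rate`, `root_p1`.
#' @export
prior_spec <- function(tree, states, multiplier = 10, root_p1 = 0.05) {
  r <- whole_tree_symmetric_rate(tree, states)
  structure(list(prior_mean = multiplier * r, multiplier = multiplier,
                 whole_tree_rate = r, root_p1 = root_p1),
            class = "prior_spec")
}

# Effective sample size by the initial-positive-sequence autocorrelation
# method.
ess_acf <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE,
                   demean = TRUE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] <= 0) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

#' MCMC posterior for partition transition rates
#'
#' Metropolis-Hastings sampler over the log rates of a fixed partition
#' model. Per-parameter Gaussian proposals are adapted during burn-in
#' toward a 20-40% acceptance rate; the first `burnin` fraction is
#' discarded and the remainder thinned to at most `max_stored` samples.
#'
#' @inheritParams tree_loglik
#' @param prior a [prior_spec()] (or a list with `prior_mean`); a scalar
#'   prior mean may also be given.
#' @param n_steps total MCMC iterations.
#' @param seed RNG seed (chains are reproducible given the seed).
#' @param use_likelihood set `FALSE` to sample from the prior alone
#'   (validation mode).
#' @param burnin fraction of iterations discarded.
#' @param max_stored cap on stored (thinned) samples.
#' @param ess_floor warn if any parameter's effective sample size falls
#'   below this.
#' @return object of class `rate_posterior`: tibble `samples` (columns
#'   `q01_k`, `q10_k` per matrix), `ess`, `acceptance`, `prior_mean`.
#' @export
mcmc_rates <- function(tree, states, model, prior, n_steps = 20000,
                       seed = NULL, root = c("stationary", "fixed"),
                       root_p1 = 0.05, use_likelihood = TRUE,
                       burnin = 0.25, max_stored = 5000, ess_floor = 100) {
  root <- match.arg(root)
  cache <- if (use_likelihood) mk_cache(tree, states)
  prior_mean <- if (is.numeric(prior)) prior else prior$prior_mean
  m <- model$n_matrices
  npar <- 2L * m
  rate_of <- function(theta) matrix(exp(theta), m, 2)
  logpost <- function(theta) {
    r <- exp(theta)
    lp <- sum(stats::dexp(r, rate = 1 / prior_mean, log = TRUE)) +
      sum(theta) # Jacobian of the log transform
    if (use_likelihood) {
      mod <- model
      mod$rates <- rate_of(theta)
      ll <- loglik_cached(cache, mod, root, root_p1)
      if (!is.finite(ll)) return(-Inf)
      lp <- lp + ll
    }
    lp
  }
  nburn <- floor(burnin * n_steps)
  thin <- max(1L, ceiling((n_steps - nburn) / max_stored))
  with_seed(seed, {
    theta <- rep(log(prior_mean), npar)
    lp <- logpost(theta)
    scales <- rep(0.5, npar)
    acc <- integer(npar)
    tries <- integer(npar)
    acc_win <- integer(npar)
    try_win <- integer(npar)
    kept <- matrix(NA_real_, ceiling((n_steps - nburn) / thin), npar)
    ki <- 0L
    for (it in seq_len(n_steps)) {
      j <- 1L + (it - 1L) %% npar
      prop <- theta
      prop[j] <- prop[j] + stats::rnorm(1, 0, scales[j])
      lp_prop <- logpost(prop)
      tries[j] <- tries[j] + 1L
      try_win[j] <- try_win[j] + 1L
      if (is.finite(lp_prop) &&
          log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
        acc[j] <- acc[j] + 1L
        acc_win[j] <- acc_win[j] + 1L
      }
      if (it <= nburn && it %% (50L * npar) == 0L) {
        rate <- acc_win / pmax(try_win, 1L)
        scales[rate > 0.40] <- scales[rate > 0.40] * 1.5
        scales[rate < 0.20] <- scales[rate < 0.20] / 1.5
        acc_win[] <- 0L
        try_win[] <- 0L
      }
      if (it > nburn && (it - nburn) %% thin == 0L) {
        ki <- ki + 1L
        kept[ki, ] <- exp(theta)
      }
    }
    kept <- kept[seq_len(ki), , drop = FALSE]
    # theta layout is column-major over (m x 2): q01 block then q10 block
    colnames(kept) <- c(paste0("q01_", seq_len(m)),
                        paste0("q10_", seq_len(m)))
    samples <- tibble::as_tibble(kept)
    ess <- vapply(samples, ess_acf, numeric(1))
    if (any(ess < ess_floor))
      warn(paste0("ESS below ", ess_floor, " for: ",
                  paste(names(ess)[ess < ess_floor], collapse = ", ")))
    structure(list(samples = samples, ess = ess,
                   acceptance = acc / pmax(tries, 1L),
                   prior_mean = prior_mean, n_steps = n_steps,
                   burnin = burnin, thin = thin, seed = seed,
                   model = model, root = root, root_p1 = root_p1),
              class = "rate_posterior")
  })
}

#' @export
print.rate_posterior <- function(x, ...) {
  cat("Posterior rate samples:", nrow(x$samples), "stored draws,",
      "acceptance", paste(signif(x$acceptance, 2), collapse = "/"), "\n")
  print(tidy(x))
  invisible(x)
}
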