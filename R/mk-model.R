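# Two-state Mk model of colour-pattern evolution with clade-specific rate
# partitions. States: 0 = cryptic, 1 = RBB (red-black banded) coloration.
# Rates are instantaneous gains (q01) and losses (q10) per Myr. A partition
# model attaches one rate matrix to every branch: shifts declared at
# internal nodes govern the node's stem branch and entire subtree, with
# nested shifts overriding outer ones.

#' Construct a clade-partitioned rate model
#'
#' @param tree a `phylo` tree.
#' @param shift_nodes integer vector of internal node numbers (ape
#'   numbering) where a new rate matrix takes over; the shift applies to
#'   the node's stem branch and all its descendants unless overridden by a
#'   nested shift. Empty for a homogeneous one-matrix model.
#' @param rates m x 2 matrix of `(q01, q10)` per matrix, row 1 the
#'   background matrix, row k+1 the matrix of `shift_nodes[k]`. May be `NA`
#'   before fitting.
#' @return object of class `partition_model` with the per-edge matrix
#'   assignment.
#' @export
partition_model <- function(tree, shift_nodes = integer(0), rates = NULL) {
  ntip <- ape::Ntip(tree)
  shift_nodes <- as.integer(shift_nodes)
  if (any(shift_nodes <= ntip))
    mim_abort("shift nodes must be internal nodes", "invalid_argument")
  m <- length(shift_nodes) + 1L
  if (is.null(rates)) rates <- matrix(NA_real_, m, 2)
  rates <- matrix(as.numeric(rates), m, 2)
  colnames(rates) <- c("q01", "q10")
  if (any(rates < 0, na.rm = TRUE))
    mim_abort("rates must be non-negative", "invalid_argument")
  structure(list(shift_nodes = shift_nodes, rates = rates,
                 assignment = edge_partition(tree, shift_nodes),
                 n_matrices = m),
            class = "partition_model")
}

node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

descendant_tips_count <- function(tree) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  cnt <- c(rep(1L, ntip), rep(0L, tree$Nnode))
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge)))
    cnt[po$edge[e, 1]] <- cnt[po$edge[e, 1]] + cnt[po$edge[e, 2]]
  cnt
}

# Per-edge matrix index: nearest shift node on the path root -> edge child
# (inclusive of the child) wins; unshifted edges use matrix 1.
edge_partition <- function(tree, shift_nodes) {
  ne <- nrow(tree$edge)
  assign_node <- rep(1L, ape::Ntip(tree) + tree$Nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")
  root <- ape::Ntip(tree) + 1L
  shift_of <- integer(0)
  if (length(shift_nodes) > 0)
    shift_of[shift_nodes] <- seq_along(shift_nodes) + 1L
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]
    ch <- pre$edge[e, 2]
    part <- if (ch <= length(shift_of) && !is.na(shift_of[ch]) &&
                shift_of[ch] > 0) shift_of[ch] else assign_node[par]
    assign_node[ch] <- part
  }
  # each edge is identified by its child node
  assign_node[tree$edge[, 2]]
}

#' Two-state transition probability matrix
#'
#' Closed form `P(t) = Pi + (I - Pi) exp(-(q01+q10) t)` where `Pi` has
#' identical rows `(pi0, pi1)` and `pi1 = q01/(q01+q10)`. With both rates
#' zero the identity matrix is returned.
#'
#' @param q01,q10 non-negative gain and loss rates (per Myr).
#' @param t elapsed time (Myr, >= 0).
#' @return 2 x 2 row-stochastic matrix, rows/cols in state order (0, 1).
#' @export
mk_transition_matrix <- function(q01, q10, t) {
  if (q01 < 0 || q10 < 0 || t < 0)
    mim_abort("rates and time must be non-negative", "invalid_argument")
  s <- q01 + q10
  if (s == 0 || t == 0) return(diag(2))
  e <- exp(-s * t)
  pi1 <- q01 / s
  pi0 <- q10 / s
  matrix(c(pi0 + pi1 * e, pi0 - pi0 * e,
           pi1 - pi1 * e, pi1 + pi0 * e), 2, 2)
}

stationary_freq1 <- function(q01, q10) {
  s <- q01 + q10
  if (s <= 0) return(0.5)
  q01 / s
}

as_trait_vector <- function(states, tree) {
  if (is.data.frame(states)) {
    v <- stats::setNames(states$state, states$species)
  } else v <- states
  miss <- setdiff(tree$tip.label, names(v))
  if (length(miss) > 0)
    mim_abort(paste("missing tip state(s):",
                    paste(utils::head(miss, 5), collapse = ", ")),
              "invalid_argument")
  out <- as.integer(v[tree$tip.label])
  if (any(!out %in% c(0L, 1L)))
    mim_abort("states must be 0 or 1", "invalid_argument")
  out
}

root_prior_vec <- function(model, root, root_p1) {
  if (root == "fixed") return(c(1 - root_p1, root_p1))
  q <- model$rates[1, ]
  p1 <- stationary_freq1(q[1], q[2])
  c(1 - p1, p1)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Conditional likelihoods are computed up the tree in postorder and
#' combined at the root with either the stationary frequencies of the
#' root's rate matrix (default) or a fixed prior on state 1.
#'
#' @param tree `phylo` tree with branch lengths in Myr.
#' @param states named 0/1 vector over tips, or a data frame with columns
#'   `species` and `state`.
#' @param model a [partition_model()] with rates filled in.
#' @param root `"stationary"` or `"fixed"`.
#' @param root_p1 prior probability of state 1 at the root when
#'   `root = "fixed"` (the motivating analysis used 0.05).
#' @return log-likelihood (scalar).
#' @export
tree_loglik <- function(tree, states, model, root = c("stationary",
                                                      "fixed"),
                        root_p1 = 0.05) {
  root <- match.arg(root)
  loglik_cached(mk_cache(tree, states), model, root, root_p1)
}

# Precompute the postorder traversal once; optimizer and MCMC inner loops
# then evaluate the likelihood without touching the tree again.
mk_cache <- function(tree, states) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(po = po, map = match(po$edge[, 2], tree$edge[, 2]),
       tips = as_trait_vector(states, tree), n_node = tree$Nnode)
}

loglik_cached <- function(cache, model, root = "stationary",
                          root_p1 = 0.05) {
  a <- model$assignment[cache$map]
  mk_pruning_cpp(cache$po$edge, cache$po$edge.length,
                 model$rates[a, 1], model$rates[a, 2],
                 cache$tips, cache$n_node,
                 root_prior_vec(model, root, root_p1), FALSE)$loglik
}

# Pruning with normalized per-node downpass conditionals (for stochastic
# mapping).
tree_partials <- function(tree, states, model, root = "stationary",
                          root_p1 = 0.05) {
  tips <- as_trait_vector(states, tree)
  po <- ape::reorder.phylo(tree, "postorder")
  a <- model$assignment[match(po$edge[, 2], tree$edge[, 2])]
  res <- mk_pruning_cpp(po$edge, po$edge.length,
                        model$rates[a, 1], model$rates[a, 2],
                        tips, tree$Nnode,
                        root_prior_vec(model, root, root_p1), TRUE)
  res
}

RATE_BOUNDS <- c(1e-8, 1e3)

#' Maximum-likelihood transition rates for a fixed partition
#'
#' Bounded quasi-Newton optimization over log rates with three fixed
#' starting points (scaled to tree height) to dodge local optima.
#' Individual matrices can be held fixed (used by the stepwise search when
#' screening candidate shifts).
#'
#' @inheritParams tree_loglik
#' @param fixed optional m x 2 matrix; non-NA entries are held at the given
#'   value.
#' @param init optional m x 2 matrix of starting rates.
#' @param n_starts number of optimizer starts (default 3).
#' @return a [partition_model()] with `rates` at the MLE, plus `loglik`
#'   attribute.
#' @export
fit_rates_ml <- function(tree, states, model, root = c("stationary",
                                                       "fixed"),
                         root_p1 = 0.05, fixed = NULL, init = NULL,
                         n_starts = 3) {
  root <- match.arg(root)
  m <- model$n_matrices
  free <- if (is.null(fixed)) matrix(TRUE, m, 2) else is.na(fixed)
  base <- matrix(0, m, 2)
  if (!is.null(fixed)) base[!free] <- fixed[!free]
  H <- max(node_depths(tree))
  nfree <- sum(free)
  if (nfree == 0) {
    model$rates <- base
    attr(model, "loglik") <- tree_loglik(tree, states, model, root,
                                         root_p1)
    return(model)
  }
  cache <- mk_cache(tree, states)
  obj <- function(logr) {
    r <- base
    r[free] <- exp(logr)
    mod <- model
    mod$rates <- r
    -loglik_cached(cache, mod, root, root_p1)
  }
  starts <- lapply(c(0.5, 5, 0.05)[seq_len(n_starts)],
                   function(s) rep(log(s / H), nfree))
  best <- NULL
  for (st in seq_along(starts)) {
    s0 <- starts[[st]]
    if (!is.null(init) && st == 1) {
      ini <- pmin(pmax(init, RATE_BOUNDS[1]), RATE_BOUNDS[2])
      s0 <- log(ini)[free]
    }
    o <- tryCatch(
      stats::optim(s0, obj, method = "L-BFGS-B",
                   lower = log(RATE_BOUNDS[1]), upper = log(RATE_BOUNDS[2]),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    mim_abort("rate optimization failed from all starts",
              "optimizer_failure")
  r <- base
  r[free] <- exp(best$par)
  model$rates <- r
  attr(model, "loglik") <- -best$value
  model
}

#' Whole-tree symmetric transition rate
#'
#' ML estimate of the single rate `r` under the symmetric model
#' `q01 = q10 = r` on the full tree; used (times a multiplier, by default
#' 10) as the exponential prior mean for Bayesian rate estimation.
#'
#' @inheritParams tree_loglik
#' @return the MLE rate (per Myr).
#' @export
whole_tree_symmetric_rate <- function(tree, states,
                                      root = c("stationary", "fixed"),
                                      root_p1 = 0.05) {
  root <- match.arg(root)
  tips <- as_trait_vector(states, tree)
  if (length(unique(tips)) < 2)
    warn("all tips share one state; symmetric rate is at the lower bound")
  mod <- partition_model(tree)
  cache <- mk_cache(tree, states)
  obj <- function(logr) {
    mod$rates <- matrix(exp(logr), 1, 2)
    -loglik_cached(cache, mod, root, root_p1)
  }
  o <- stats::optimize(obj, log(RATE_BOUNDS), tol = 1e-10)
  max(exp(o$minimum), RATE_BOUNDS[1])
}

# Parameter count of an m-matrix partition model: 2m rates plus m - 1
# shift-location parameters.
partition_k <- function(m) 2L * m + (m - 1L)

#' Number of free rate parameters of an m-matrix model
#' @param m number of rate matrices.
#' @return integer `2 m`.
#' @export
n_rate_parameters <- function(m) 2L * as.integer(m)
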