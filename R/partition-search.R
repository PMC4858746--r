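# Stepwise-AIC search for clade-specific rate partitions, in the spirit of
# MEDUSA but for a discrete binary character. At each step every internal
# node with enough descendant tips is screened as a candidate shift (new
# matrix free, existing rates held fixed); the best candidate is then
# jointly re-optimized and accepted only if AIC improves by more than
# `delta_aic`. Parameter count of an m-matrix model is 2m rates plus m - 1
# shift locations.

#' Stepwise-AIC search for transition-rate partitions
#'
#' @inheritParams tree_loglik
#' @param min_descendants minimum number of descendant tips for a node to
#'   be a candidate shift (inclusive).
#' @param delta_aic AIC improvement required to accept a more complex
#'   model.
#' @param max_matrices cap on the number of rate matrices.
#' @return object of class `partition_search` with elements `model` (the
#'   final fitted [partition_model()]), `loglik`, `AIC`, `trace` (tibble of
#'   per-step bookkeeping) and `stopped_because`.
#' @export
stepwise_partition_search <- function(tree, states, min_descendants = 5,
                                      delta_aic = 2,
                                      root = c("stationary", "fixed"),
                                      root_p1 = 0.05, max_matrices = 10) {
  root <- match.arg(root)
  ntip <- ape::Ntip(tree)
  cnt <- descendant_tips_count(tree)
  rootnode <- ntip + 1L
  candidates_all <- setdiff(which(cnt >= min_descendants), seq_len(ntip))
  candidates_all <- setdiff(candidates_all, rootnode)

  cur <- fit_rates_ml(tree, states, partition_model(tree), root, root_p1)
  cur_ll <- attr(cur, "loglik")
  cur_aic <- 2 * partition_k(1) - 2 * cur_ll
  trace <- list(tibble::tibble(step = 0L, n_matrices = 1L,
                               k = partition_k(1), loglik = cur_ll,
                               AIC = cur_aic, delta_aic = NA_real_,
                               shift_node = NA_integer_, accepted = TRUE))
  stopped <- "no candidate improved AIC by more than delta_aic"
  step <- 0L
  while (cur$n_matrices < max_matrices) {
    step <- step + 1L
    cand <- setdiff(candidates_all, cur$shift_nodes)
    if (length(cand) == 0) { stopped <- "no remaining candidates"; break }
    m_new <- cur$n_matrices + 1L
    # screen: existing matrices frozen, only the new one free
    screen <- vapply(cand, function(nd) {
      mod <- partition_model(tree, c(cur$shift_nodes, nd))
      fx <- rbind(cur$rates, c(NA, NA))
      fit <- tryCatch(
        fit_rates_ml(tree, states, mod, root, root_p1, fixed = fx,
                     init = rbind(cur$rates,
                                  cur$rates[1, , drop = FALSE]),
                     n_starts = 1),
        error = function(e) NULL)
      if (is.null(fit)) NA_real_ else attr(fit, "loglik")
    }, numeric(1))
    if (all(is.na(screen))) { stopped <- "all candidate fits failed"; break }
    best_nd <- cand[which.max(screen)]
    # joint refit of all rates at the chosen shift configuration
    mod <- partition_model(tree, c(cur$shift_nodes, best_nd))
    joint <- fit_rates_ml(tree, states, mod, root, root_p1,
                          init = rbind(cur$rates,
                                       cur$rates[1, , drop = FALSE]))
    ll <- attr(joint, "loglik")
    aic <- 2 * partition_k(m_new) - 2 * ll
    accepted <- (cur_aic - aic) > delta_aic
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = step, n_matrices = m_new, k = partition_k(m_new),
      loglik = ll, AIC = aic, delta_aic = cur_aic - aic,
      shift_node = best_nd, accepted = accepted)
    if (!accepted) break
    cur <- joint
    cur_ll <- ll
    cur_aic <- aic
    if (cur$n_matrices >= max_matrices)
      stopped <- "reached max_matrices"
  }
  structure(list(model = cur, loglik = cur_ll, AIC = cur_aic,
                 trace = dplyr::bind_rows(trace),
                 stopped_because = stopped),
            class = "partition_search")
}

#' @export
print.partition_search <- function(x, ...) {
  cat("Stepwise-AIC partition search:", x$model$n_matrices,
      "rate matrices, AIC =", signif(x$AIC, 6), "\n")
  if (length(x$model$shift_nodes))
    cat("shift nodes:", paste(x$model$shift_nodes, collapse = ", "), "\n")
  print(x$trace)
  invisible(x)
}

#' Fitch parsimony count and ancestral labelling
#'
#' Minimal number of unweighted state changes for a binary character,
#' computed by the unit-cost parsimony dynamic program (equivalent to
#' Fitch on binary trees and exact on multifurcations). Returns the
#' change count, per-node optimal-state sets, and one deterministic
#' most-parsimonious resolution (ties resolved toward state 0 at the
#' root and toward the parental state below it).
#'
#' @inheritParams tree_loglik
#' @return list with `changes`, `node_sets` (list of sets per node) and
#'   `node_states` (one resolution, tips included).
#' @export
fitch_parsimony <- function(tree, states) {
  tips <- as_trait_vector(states, tree)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  # unit-cost dynamic program (exact on polytomies): cost[s+1, node] is
  # the minimal change count in the subtree given the node is in state s
  cost <- matrix(Inf, 2, ntot)
  cost[cbind(tips + 1L, seq_len(ntip))] <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  cost[, unique(po$edge[, 1])] <- 0
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    cost[1, par] <- cost[1, par] + min(cost[1, ch], cost[2, ch] + 1)
    cost[2, par] <- cost[2, par] + min(cost[2, ch], cost[1, ch] + 1)
  }
  rootnode <- ntip + 1L
  changes <- as.integer(min(cost[, rootnode]))
  # deterministic backtrack: ties resolved toward state 0 at the root and
  # toward the parental state below it
  res <- integer(ntot)
  res[rootnode] <- if (cost[1, rootnode] <= cost[2, rootnode]) 0L else 1L
  res[seq_len(ntip)] <- tips
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]
    ch <- pre$edge[e, 2]
    if (ch <= ntip) next
    sp <- res[par]
    stay <- cost[sp + 1, ch]
    move <- cost[2 - sp, ch] + 1
    res[ch] <- if (stay <= move) sp else 1L - sp
  }
  sets <- lapply(seq_len(ntot), function(nd) {
    m <- min(cost[, nd])
    c(if (cost[1, nd] == m) 0L, if (cost[2, nd] == m) 1L)
  })
  list(changes = changes, node_sets = sets, node_states = res)
}
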