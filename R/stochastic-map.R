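# Stochastic character mapping: sample full trait histories consistent
# with the tip data and a set of (possibly posterior-drawn) rates. Node
# states are drawn top-down from pruning conditionals; branch histories
# are drawn by uniformization, which samples continuous-time Markov paths
# exactly conditional on both endpoint states.

#' Character map container
#'
#' A complete trait history on a tree: the state at every node plus timed
#' change events along branches (times measured from the parent node).
#'
#' @param tree the `phylo` tree the map lives on.
#' @param node_states integer state (0/1) per node (tips then internals,
#'   ape numbering).
#' @param events tibble with columns `edge` (row of `tree$edge`), `time`
#'   (Myr from the parent end), `to_state`.
#' @return object of class `character_map`.
#' @export
character_map <- function(tree, node_states, events) {
  events <- tibble::as_tibble(events)
  structure(list(node_states = as.integer(node_states),
                 events = events, ntip = ape::Ntip(tree)),
            class = "character_map")
}

#' Validate a character map against its tree
#'
#' Checks the invariants: event times strictly increasing within a branch
#' and at most the branch length, consecutive states alternate, and branch
#' endpoint states agree with the recorded node states.
#'
#' @param map a [character_map()].
#' @param tree the companion `phylo` tree.
#' @return `TRUE` invisibly; errors with a message otherwise.
#' @export
validate_character_map <- function(map, tree) {
  ns <- map$node_states
  ev <- map$events
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    ee <- ev[ev$edge == e, , drop = FALSE]
    ee <- ee[order(ee$time), , drop = FALSE]
    state <- ns[par]
    if (nrow(ee) > 0) {
      if (any(diff(ee$time) <= 0))
        mim_abort("event times not strictly increasing", "invalid_map")
      if (any(ee$time > tree$edge.length[e] + 1e-9) || any(ee$time < 0))
        mim_abort("event time outside branch", "invalid_map")
      for (i in seq_len(nrow(ee))) {
        if (ee$to_state[i] == state)
          mim_abort("consecutive states do not alternate", "invalid_map")
        state <- ee$to_state[i]
      }
    }
    if (state != ns[ch])
      mim_abort("branch end state disagrees with child node state",
                "invalid_map")
  }
  invisible(TRUE)
}

#' Tip states of a character map
#' @param map a [character_map()].
#' @return integer vector of tip states.
#' @export
map_tip_states <- function(map) map$node_states[seq_len(map$ntip)]

# Count gains (0->1) and losses (1->0) per edge of one map.
map_event_counts <- function(map, n_edge) {
  gains <- tabulate(map$events$edge[map$events$to_state == 1L], n_edge)
  losses <- tabulate(map$events$edge[map$events$to_state == 0L], n_edge)
  list(gains = gains, losses = losses)
}

# Exact endpoint-conditioned CTMC path on one branch by uniformization.
# Returns event times (from the branch start) and new states; assumes the
# ambient RNG is already seeded by the caller.
sample_ctmc_path <- function(q01, q10, t, a, b) {
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  omega <- max(q01, q10, 1e-12) * 1.05
  R <- diag(2) + Q / omega
  P <- mk_transition_matrix(q01, q10, t)
  pab <- P[a + 1, b + 1]
  if (pab <= 0)
    mim_abort("impossible endpoint combination", "invalid_argument")
  # sample the number of uniformized jumps
  u <- stats::runif(1) * pab
  n <- 0
  Rn <- diag(2)
  cum <- 0
  lam <- omega * t
  repeat {
    cum <- cum + stats::dpois(n, lam) * Rn[a + 1, b + 1]
    if (cum >= u || n > 10000) break
    n <- n + 1
    Rn <- Rn %*% R
  }
  if (n == 0) {
    if (a != b)
      mim_abort("zero jumps with differing endpoints", "internal_error")
    return(list(time = numeric(0), to_state = integer(0)))
  }
  # jump times are iid uniform given n; states by backward sampling
  times <- sort(stats::runif(n, 0, t))
  Rpow <- vector("list", n + 1)
  Rpow[[1]] <- diag(2)
  for (k in seq_len(n)) Rpow[[k + 1]] <- Rpow[[k]] %*% R
  states <- integer(n)
  prev <- a
  for (k in seq_len(n)) {
    w <- R[prev + 1, ] * Rpow[[n - k + 1]][, b + 1]
    states[k] <- sample.int(2, 1, prob = w) - 1L
    prev <- states[k]
  }
  keep <- c(states[1] != a, diff(states) != 0)
  list(time = times[keep], to_state = states[keep])
}

#' Draw one stochastic character map
#'
#' Samples the root state from the root prior combined with the root
#' conditional likelihoods, node states top-down in proportion to their
#' conditional probabilities, and branch histories conditional on both
#' endpoint states by uniformization. Tip states always equal the data.
#'
#' @inheritParams tree_loglik
#' @param seed RNG seed.
#' @return a [character_map()].
#' @export
sample_stochastic_map <- function(tree, states, model,
                                  root = c("stationary", "fixed"),
                                  root_p1 = 0.05, seed = NULL) {
  root <- match.arg(root)
  pr <- tree_partials(tree, states, model, root, root_p1)
  part <- pr$partials
  ntip <- ape::Ntip(tree)
  rootnode <- ntip + 1L
  rprior <- root_prior_vec(model, root, root_p1)
  with_seed(seed, {
    ns <- integer(ntip + tree$Nnode)
    w <- rprior * part[rootnode, ]
    ns[rootnode] <- sample.int(2, 1, prob = w) - 1L
    pre <- ape::reorder.phylo(tree, "cladewise")
    amap <- model$assignment[match(pre$edge[, 2], tree$edge[, 2])]
    for (e in seq_len(nrow(pre$edge))) {
      par <- pre$edge[e, 1]
      ch <- pre$edge[e, 2]
      q <- model$rates[amap[e], ]
      P <- mk_transition_matrix(q[1], q[2], pre$edge.length[e])
      w <- P[ns[par] + 1, ] * part[ch, ]
      ns[ch] <- sample.int(2, 1, prob = w) - 1L
    }
    ev <- list()
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      q <- model$rates[model$assignment[e], ]
      path <- sample_ctmc_path(q[1], q[2], tree$edge.length[e],
                               ns[par], ns[ch])
      if (length(path$time) > 0)
        ev[[length(ev) + 1]] <- tibble::tibble(
          edge = e, time = path$time, to_state = path$to_state)
    }
    events <- if (length(ev)) dplyr::bind_rows(ev)
              else tibble::tibble(edge = integer(0), time = numeric(0),
                                  to_state = integer(0))
    character_map(tree, ns, events)
  })
}

#' Draw an ensemble of stochastic maps
#'
#' Each map uses a fresh rate draw from the posterior (rows of
#' `posterior$samples` sampled uniformly) or, if `posterior` is omitted,
#' the fixed rates in `model`.
#'
#' @inheritParams sample_stochastic_map
#' @param posterior optional [mcmc_rates()] result.
#' @param n_maps number of maps (the motivating analysis used 500).
#' @return object of class `map_ensemble`: list of maps plus the tree.
#' @export
sample_map_ensemble <- function(tree, states, model, posterior = NULL,
                                n_maps = 500,
                                root = c("stationary", "fixed"),
                                root_p1 = 0.05, seed = NULL) {
  root <- match.arg(root)
  m <- model$n_matrices
  with_seed(seed, {
    maps <- vector("list", n_maps)
    for (i in seq_len(n_maps)) {
      mod <- model
      if (!is.null(posterior)) {
        row <- posterior$samples[
          sample.int(nrow(posterior$samples), 1), ]
        mod$rates <- cbind(as.numeric(row[paste0("q01_", seq_len(m))]),
                           as.numeric(row[paste0("q10_", seq_len(m))]))
      }
      maps[[i]] <- sample_stochastic_map(tree, states, mod, root, root_p1,
                                         seed = NULL)
    }
    structure(list(maps = maps, tree = tree, n_maps = n_maps),
              class = "map_ensemble")
  })
}

#' Summarize a stochastic-map ensemble
#'
#' Computes the frequency of the derived state through time on an
#' `n_time`-point grid (fraction of lineages extant at each time in state
#' 1), mean per-branch gain and loss counts, total gains/losses per map,
#' and the maximum-credibility map: the sampled history maximizing the sum
#' over branches of the log marginal frequency of its per-branch
#' (gain, loss) count pair.
#'
#' @param ensemble a [sample_map_ensemble()] result.
#' @param n_time number of equally spaced time points (default 1000).
#' @return list of class `map_ensemble_summary` with `freq_through_time`
#'   (tibble `time`, `age`, `freq1`, `n_lineages`), `branch_events`
#'   (tibble per edge), `per_map` (tibble of totals), `credible_index`,
#'   `credible_map`.
#' @export
summarize_ensemble <- function(ensemble, n_time = 1000) {
  tree <- ensemble$tree
  maps <- ensemble$maps
  ne <- nrow(tree$edge)
  depth <- node_depths(tree)
  pdepth <- depth[tree$edge[, 1]]
  cdepth <- depth[tree$edge[, 2]]
  Tmax <- max(depth)
  times <- seq(0, Tmax, length.out = n_time)
  eps <- 1e-12

  # Pool, over all maps, the absolute-time intervals during which any
  # lineage sits in state 1. A branch occupies the half-open interval
  # (parent_depth, child_depth]; the fraction of extant lineages in state
  # 1 at time t is then a coverage count over pooled interval endpoints.
  starts <- numeric(0)
  ends <- numeric(0)
  for (map in maps) {
    ev <- map$events
    ev_edges <- unique(ev$edge)
    quiet <- which(map$node_states[tree$edge[, 1]] == 1L)
    quiet <- setdiff(quiet, ev_edges)
    starts <- c(starts, pdepth[quiet])
    ends <- c(ends, cdepth[quiet])
    for (e in ev_edges) {
      s <- map$node_states[tree$edge[e, 1]]
      idx <- which(ev$edge == e)
      o <- order(ev$time[idx])
      bt <- c(pdepth[e], pdepth[e] + ev$time[idx][o], cdepth[e])
      bs <- c(s, ev$to_state[idx][o])
      one <- which(bs == 1L)
      if (length(one) > 0) {
        starts <- c(starts, bt[one])
        ends <- c(ends, bt[one + 1])
      }
    }
  }
  starts <- sort(starts)
  ends <- sort(ends)
  # vectorized coverage count: state-1 segments are (start, end] like the
  # branches themselves, so count starts <= t minus ends strictly below t
  n1 <- findInterval(times + eps, starts) - findInterval(times - eps, ends)
  alive <- findInterval(times + eps, sort(pdepth)) -
    findInterval(times - eps, sort(cdepth))
  root_states <- vapply(maps, function(m)
    m$node_states[ape::Ntip(tree) + 1L], integer(1))
  freq1 <- n1 / (length(maps) * pmax(alive, 1L))
  freq1[times <= eps] <- mean(root_states == 1L)
  alive[times <= eps] <- 1L
  ftt <- tibble::tibble(time = times, age = Tmax - times, freq1 = freq1,
                        n_lineages = alive)

  counts <- lapply(maps, map_event_counts, n_edge = ne)
  gains <- do.call(rbind, lapply(counts, `[[`, "gains"))
  losses <- do.call(rbind, lapply(counts, `[[`, "losses"))
  branch_events <- tibble::tibble(
    edge = seq_len(ne),
    mean_gains = colMeans(gains), mean_losses = colMeans(losses))
  per_map <- tibble::tibble(map = seq_along(maps),
                            gains = rowSums(gains),
                            losses = rowSums(losses))
  # maximum-credibility configuration: per-edge marginal frequency of each
  # map's (gain, loss) pair, summed as log frequencies over edges
  score <- numeric(length(maps))
  for (e in seq_len(ne)) {
    code <- paste(gains[, e], losses[, e])
    tab <- table(code) / length(maps)
    score <- score + log(as.numeric(tab[code]))
  }
  ci <- which.max(score)
  structure(list(freq_through_time = ftt, branch_events = branch_events,
                 per_map = per_map, credible_index = ci,
                 credible_map = maps[[ci]], n_time = n_time),
            class = "map_ensemble_summary")
}
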