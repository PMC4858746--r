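# Synthetic data with known ground truth: Yule trees, forward-simulated
# binary trait histories under a partitioned Mk process, Brownian-motion
# latitudinal midpoints, and a virtual-continent biogeography whose
# mimic richness is coupled to model richness by a planted coefficient.
# Every generator takes an explicit seed and is bit-reproducible.

#' Simulate a Yule (pure-birth) time-scaled tree
#'
#' Minimal time-scaled tree source for validation: lineages split at rate
#' `birth_rate` per lineage per Myr; simulation runs until `n_tips`
#' lineages exist plus one further waiting time so pendant branches have
#' positive length.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per Myr (> 0).
#' @param seed RNG seed.
#' @return a binary rooted `phylo` with branch lengths in Myr.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 0.1, seed = NULL) {
  if (n_tips < 2) mim_abort("n_tips must be >= 2", "invalid_argument")
  if (birth_rate <= 0) mim_abort("birth_rate must be > 0",
                                 "invalid_argument")
  with_seed(seed, {
    # lineage records: birth time, split time (NA = extant tip), children
    birth <- c(0, 0)
    split <- c(NA_real_, NA_real_)
    child <- list(NULL, NULL)
    active <- c(1L, 2L)
    t <- 0
    while (length(active) < n_tips) {
      k <- length(active)
      t <- t + stats::rexp(1, k * birth_rate)
      j <- active[sample.int(k, 1)]
      split[j] <- t
      id1 <- length(birth) + 1L
      id2 <- id1 + 1L
      birth <- c(birth, t, t)
      split <- c(split, NA_real_, NA_real_)
      child[[j]] <- c(id1, id2)
      child[[id1]] <- NULL
      child[[id2]] <- NULL
      active <- c(setdiff(active, j), id1, id2)
    }
    t_end <- t + stats::rexp(1, n_tips * birth_rate)

    n_int <- n_tips - 1L
    edge <- matrix(0L, 2L * n_tips - 2L, 2)
    elen <- numeric(nrow(edge))
    tipc <- 0L
    intc <- n_tips + 1L # root gets ntip+1
    ei <- 0L
    node_of <- function(lin) {
      if (is.na(split[lin])) {
        tipc <<- tipc + 1L
        list(id = tipc, end = t_end)
      } else {
        intc <<- intc + 1L
        my <- intc
        for (ch in child[[lin]]) {
          r <- node_of(ch)
          ei <<- ei + 1L
          edge[ei, ] <<- c(my, r$id)
          elen[ei] <<- (if (is.na(split[ch])) t_end else split[ch]) -
            birth[ch]
        }
        list(id = my, end = split[lin])
      }
    }
    root_id <- n_tips + 1L
    for (lin in 1:2) {
      r <- node_of(lin)
      ei <- ei + 1L
      edge[ei, ] <- c(root_id, r$id)
      elen[ei] <- (if (is.na(split[lin])) t_end else split[lin])
    }
    tr <- structure(list(edge = edge, edge.length = elen,
                         tip.label = paste0("t", seq_len(n_tips)),
                         Nnode = n_int), class = "phylo")
    ape::reorder.phylo(tr, "cladewise")
  })
}

#' Forward-simulate a binary trait history on a tree
#'
#' Exact continuous-time simulation: along each branch, waiting times to
#' the next state flip are exponential with the current state's exit rate
#' under that branch's rate matrix.
#'
#' @inheritParams tree_loglik
#' @param root_state_prob probability that the root is in state 1.
#' @param seed RNG seed.
#' @return list with `states` (named 0/1 vector over tips) and `map` (a
#'   [character_map()] holding the full true history).
#' @export
simulate_discrete_history <- function(tree, model, root_state_prob = 0,
                                      seed = NULL) {
  if (any(is.na(model$rates)))
    mim_abort("model rates must be set", "invalid_argument")
  with_seed(seed, {
    ntot <- ape::Ntip(tree) + tree$Nnode
    ns <- integer(ntot)
    rootnode <- ape::Ntip(tree) + 1L
    ns[rootnode] <- stats::rbinom(1, 1, root_state_prob)
    pre <- ape::reorder.phylo(tree, "cladewise")
    amap <- model$assignment[match(pre$edge[, 2], tree$edge[, 2])]
    eidx <- match(pre$edge[, 2], tree$edge[, 2])
    ev <- list()
    for (e in seq_len(nrow(pre$edge))) {
      par <- pre$edge[e, 1]
      ch <- pre$edge[e, 2]
      q <- model$rates[amap[e], ]
      len <- pre$edge.length[e]
      s <- ns[par]
      t <- 0
      repeat {
        rate <- if (s == 0L) q[1] else q[2]
        if (rate <= 0) break
        t <- t + stats::rexp(1, rate)
        if (t >= len) break
        s <- 1L - s
        ev[[length(ev) + 1]] <- tibble::tibble(edge = eidx[e], time = t,
                                               to_state = s)
      }
      ns[ch] <- s
    }
    events <- if (length(ev)) dplyr::bind_rows(ev)
              else tibble::tibble(edge = integer(0), time = numeric(0),
                                  to_state = integer(0))
    map <- character_map(tree, ns, events)
    states <- stats::setNames(ns[seq_len(ape::Ntip(tree))],
                              tree$tip.label)
    list(states = states, map = map)
  })
}

#' Simulate latitudinal midpoints under Brownian motion
#'
#' Each branch increment is Normal(0, sigma2 x branch length); internal
#' node values are retained so reconstruction can be checked against the
#' truth. An optional per-clade sigma2 map (shift nodes, as in
#' [partition_model()]) makes the process multi-rate.
#'
#' @param tree a `phylo`.
#' @param root_value latitude at the root (degrees).
#' @param sigma2 BM rate (degrees^2 per Myr, >= 0).
#' @param seed RNG seed.
#' @param shift_nodes,clade_sigma2 optional parallel vectors: subtrees of
#'   `shift_nodes[k]` evolve with rate `clade_sigma2[k]`.
#' @return list with `tip_latitudes` (named), `node_latitudes` (internal
#'   nodes, ape numbering) and `all` (per-node vector).
#' @export
simulate_bm_latitude <- function(tree, root_value = 0, sigma2 = 1,
                                 seed = NULL, shift_nodes = NULL,
                                 clade_sigma2 = NULL) {
  if (sigma2 < 0 || any(clade_sigma2 < 0))
    mim_abort("sigma2 must be non-negative", "invalid_argument")
  s2_edge <- rep(sigma2, nrow(tree$edge))
  if (!is.null(shift_nodes) && length(shift_nodes) > 0) {
    part <- edge_partition(tree, as.integer(shift_nodes))
    s2 <- c(sigma2, clade_sigma2)
    s2_edge <- s2[part]
  }
  with_seed(seed, {
    ntip <- ape::Ntip(tree)
    val <- numeric(ntip + tree$Nnode)
    val[ntip + 1L] <- root_value
    pre <- ape::reorder.phylo(tree, "cladewise")
    s2p <- s2_edge[match(pre$edge[, 2], tree$edge[, 2])]
    for (e in seq_len(nrow(pre$edge))) {
      par <- pre$edge[e, 1]
      ch <- pre$edge[e, 2]
      val[ch] <- val[par] +
        stats::rnorm(1, 0, sqrt(s2p[e] * pre$edge.length[e]))
    }
    list(tip_latitudes = stats::setNames(val[seq_len(ntip)],
                                         tree$tip.label),
         node_latitudes = val[(ntip + 1L):(ntip + tree$Nnode)],
         all = val)
  })
}
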