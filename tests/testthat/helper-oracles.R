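# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: transition probabilities come from a numerical
# matrix exponential, tree likelihoods from exhaustive enumeration over
# internal-node states, and endpoint-conditioned event counts from direct
# numerical integration of the CTMC flux.

expm_P <- function(q01, q10, t) {
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  as.matrix(Matrix::expm(Q * t))
}

# Brute-force Mk likelihood: sum over all internal-node state assignments.
enum_loglik <- function(tree, states, q01, q10, root_prior) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  tips <- as.integer(states[tree$tip.label])
  total <- 0
  for (code in 0:(2^nint - 1)) {
    assign <- as.integer(intToBits(code))[seq_len(nint)]
    node_state <- c(tips, assign)
    lik <- root_prior[node_state[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      P <- expm_P(q01, q10, tree$edge.length[e])
      lik <- lik * P[node_state[tree$edge[e, 1]] + 1,
                     node_state[tree$edge[e, 2]] + 1]
    }
    total <- total + lik
  }
  log(total)
}

# E[number of transitions | X(0) = a, X(t) = b] by numerical integration:
# sum over ordered pairs i != j of q_ij * int_0^t P_ai(s) P_jb(t-s) ds,
# divided by P_ab(t).
cond_expected_events <- function(q01, q10, t, a, b) {
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  Pab <- expm_P(q01, q10, t)[a + 1, b + 1]
  total <- 0
  for (i in 0:1) for (j in 0:1) {
    if (i == j || Q[i + 1, j + 1] <= 0) next
    f <- function(s) {
      vapply(s, function(si)
        expm_P(q01, q10, si)[a + 1, i + 1] *
          expm_P(q01, q10, t - si)[j + 1, b + 1], numeric(1))
    }
    total <- total + Q[i + 1, j + 1] * stats::integrate(f, 0, t)$value
  }
  total / Pab
}

# Exhaustive minimum-change count over all internal labelings.
enum_parsimony <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  tips <- as.integer(states[tree$tip.label])
  best <- Inf
  for (code in 0:(2^nint - 1)) {
    assign <- as.integer(intToBits(code))[seq_len(nint)]
    node_state <- c(tips, assign)
    ch <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# A star tree: one root polytomy with equal branch lengths.
star_tree <- function(n_tips, branch_length) {
  tr <- structure(list(
    edge = cbind(rep(n_tips + 1L, n_tips), seq_len(n_tips)),
    edge.length = rep(branch_length, n_tips),
    tip.label = paste0("t", seq_len(n_tips)),
    Nnode = 1L), class = "phylo")
  tr
}

random_binary_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
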