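# Independent oracles used across tests. These never call the code paths
# they check.

# Exhaustive minimum-parsimony change count for binary presence states:
# enumerate every labeling of the internal nodes and count state flips
# over all edges. Feasible for trees up to ~12 leaves.
brute_force_parsimony <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  states <- integer(ntip + nint)
  states[seq_len(ntip)] <- as.integer(tip_states[tree$tip.label])
  best <- Inf
  for (code in 0:(2^nint - 1L)) {
    lab <- as.integer(intToBits(code))[seq_len(nint)]
    states[ntip + seq_len(nint)] <- lab
    changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Closed-form SASA of one of two equal spheres of expanded radius R at
# center distance d < 2R: full sphere minus the buried spherical cap.
two_sphere_cap_sasa <- function(R, d) {
  4 * pi * R^2 - 2 * pi * R * (R - d / 2)
}

# Probability that a Bernoulli pattern of n covering spots (each positive
# with prob p) contains a run of >= k consecutive positives, by exhaustive
# enumeration over the 2^n patterns.
run_probability <- function(n, k, p) {
  total <- 0
  for (code in 0:(2^n - 1L)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    r <- rle(bits)
    if (any(r$values == 1L & r$lengths >= k)) {
      npos <- sum(bits)
      total <- total + p^npos * (1 - p)^(n - npos)
    }
  }
  total
}

# Random bifurcating tree with unit-ish branch lengths and random binary
# tip states, for parsimony property tests.
random_presence_case <- function(n_leaves) {
  tree <- ape::rtree(n_leaves)
  states <- sample(c("present", "absent"), n_leaves, replace = TRUE)
  names(states) <- tree$tip.label
  list(tree = tree, states = states)
}

# A small gapped toy alignment used by several conservation tests.
toy_alignment <- function() {
  recs <- list(
    HUMAN = "DEELQWVFVNAG",
    MOUSE = "DEELQWIFVNAG",
    CHICK = "DEELQHAGVNAG",
    FISH  = "DEELQ-VFVNAG")
  tmp <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(recs), function(id) {
    c(paste0(">", id), recs[[id]])
  })), tmp)
  lirtriage::read_alignment(tmp)
}
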