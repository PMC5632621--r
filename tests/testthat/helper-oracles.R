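# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately naive (enumeration, closed forms) and
# shares no code with the implementation paths it checks.

# Brute-force Mk1 log-likelihood: sum over all internal-node state
# assignments of prior * product of per-edge transition probabilities.
brute_mk_loglik <- function(tree, states, alpha, k) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  tip_idx <- states[tree$tip.label]
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    asgn <- integer(n_node)
    asgn[internal] <- combos[r, ]
    pr <- 1 / k
    ok <- TRUE
    for (i in seq_len(nrow(tree$edge))) {
      par <- tree$edge[i, 1]; child <- tree$edge[i, 2]
      P <- mk1_transition(alpha, tree$edge.length[i], k)
      if (child <= n_tip) {
        s <- tip_idx[child]
        pr <- pr * if (is.na(s)) 1 else P[asgn[par], s]
      } else {
        pr <- pr * P[asgn[par], asgn[child]]
      }
      if (pr == 0) { ok <- FALSE; break }
    }
    if (ok) total <- total + pr
  }
  log(total)
}

# Brute-force marginal probabilities at every internal node: enumerate all
# assignments, accumulate each assignment's probability on its node states,
# normalise per node.
brute_mk_marginals <- function(tree, states, alpha, k) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  tip_idx <- states[tree$tip.label]
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  post <- matrix(0, length(internal), k)
  for (r in seq_len(nrow(combos))) {
    asgn <- integer(n_node)
    asgn[internal] <- combos[r, ]
    pr <- 1 / k
    for (i in seq_len(nrow(tree$edge))) {
      par <- tree$edge[i, 1]; child <- tree$edge[i, 2]
      P <- mk1_transition(alpha, tree$edge.length[i], k)
      pr <- pr * if (child <= n_tip) {
        s <- tip_idx[child]
        if (is.na(s)) 1 else P[asgn[par], s]
      } else P[asgn[par], asgn[child]]
    }
    for (m in seq_along(internal))
      post[m, combos[r, m]] <- post[m, combos[r, m]] + pr
  }
  sweep(post, 1L, rowSums(post), `/`)
}

# Random rooted tree with exponential branch lengths and random tip states.
random_tree_states <- function(n_tip, k, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tip)
  st <- setNames(sample.int(k, n_tip, replace = TRUE), tr$tip.label)
  list(tree = tr, states = st)
}

# Two well-separated Gaussian score clouds plus a broad background cloud.
separated_clouds <- function(n, gap, seed) {
  set.seed(seed)
  bg <- cbind(rnorm(2000, 0, 3), rnorm(2000, 0, 3))
  a <- cbind(rnorm(n, -gap / 2, 0.3), rnorm(n, 0, 0.3))
  b <- cbind(rnorm(n, gap / 2, 0.3), rnorm(n, 0, 0.3))
  list(a = a, b = b, bg = bg)
}

# Write a small occurrence CSV and return its path.
write_occ_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# A 2-layer raster stack with hand-set values for lookup tests:
# 4 x 4 cells over lon [0,4], lat [0,4], cellsize 1; layer "a" holds
# row*10 + col (rows counted from the north), layer "b" is its negative;
# the north-west cell (row 1, col 1) is nodata.
tiny_stack <- function() {
  a <- outer(1:4, 1:4, function(r, c) r * 10 + c)
  b <- -a
  a[1, 1] <- NA
  env_raster_stack(list(a = a, b = b), xmin = 0, xmax = 4, ymin = 0, ymax = 4)
}
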