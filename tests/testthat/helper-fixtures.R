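# Small fixtures built in code.

# Straight 10x1x1 field, all FA fa0, all directions +x.
straight_field <- function(fa0 = 0.5, n = 10, labels = NULL) {
  fa <- array(fa0, c(n, 1, 1))
  dir <- array(0, c(n, 1, 1, 3))
  dir[, , , 1] <- 1
  lab <- array(0L, c(n, 1, 1))
  if (!is.null(labels)) lab[] <- labels
  orientation_field(fa, dir, lab)
}

# L-shaped 2-D field: horizontal arm y = 1 (directions +x), corner at
# (xlen, 1), vertical arm x = xlen (directions +y).
l_field <- function(xlen = 5, ylen = 5, fa0 = 0.5) {
  fa <- array(0, c(xlen, ylen, 1))
  dir <- array(0, c(xlen, ylen, 1, 3))
  lab <- array(0L, c(xlen, ylen, 1))
  fa[, 1, 1] <- fa0
  dir[, 1, 1, 1] <- 1
  fa[xlen, , 1] <- fa0
  dir[xlen, 2:ylen, 1, 2] <- 1
  dir[xlen, 1, 1, ] <- c(0, 1, 0)  # corner voxel turns 90 degrees
  orientation_field(fa, dir, lab)
}

# Small cohort for fast end-to-end tests.
small_cohort_config <- function(...) {
  cohort_config(n_per_group = 4, n_regions = 30, n_planted_edges = 3, ...)
}

# Build a connectivity matrix from an upper-triangle edge list.
mat_from_edges <- function(n, edges, weights = 1) {
  w <- matrix(0, n, n)
  weights <- rep_len(weights, nrow(edges))
  for (k in seq_len(nrow(edges))) {
    w[edges[k, 1], edges[k, 2]] <- weights[k]
    w[edges[k, 2], edges[k, 1]] <- weights[k]
  }
  w
}
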