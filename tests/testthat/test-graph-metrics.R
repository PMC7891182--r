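# Global/nodal metrics, sparsity thresholding, random-network normalization,
# AUC and hub identification.

test_that("global metrics match hand-computed values on canonical graphs", {
  k4 <- mat_from_edges(4, edge_index(4))
  gm <- global_metrics(k4)
  expect_equal(gm$Cp, 1)
  expect_equal(gm$Lp, 1)
  expect_equal(gm$Eglob, 1)
  expect_equal(gm$Eloc, 1)

  # 3-node path: pair distances 1, 1, 2
  p3 <- mat_from_edges(3, rbind(c(1, 2), c(2, 3)))
  gm <- global_metrics(p3)
  expect_equal(gm$Eglob, (1 + 1 + 1 / 2) / 3)
  expect_equal(gm$Lp, 4 / 3)

  # triangle with constant weight 0.5: max-normalized weights are all 1
  tri <- mat_from_edges(3, rbind(c(1, 2), c(2, 3), c(1, 3)), 0.5)
  expect_equal(global_metrics(tri)$Cp, 1)
})

test_that("all-zero matrix yields zero efficiencies and undefined Lp", {
  z <- matrix(0, 4, 4)
  expect_warning(gm <- global_metrics(z), "no connected pair")
  expect_equal(gm$Eglob, 0)
  expect_equal(gm$Cp, 0)
  expect_equal(gm$Eloc, 0)
  expect_true(is.na(gm$Lp))
})

test_that("nodal metrics match hand values on a 5-node star", {
  star <- mat_from_edges(5, cbind(1, 2:5))
  nm <- nodal_metrics(star)
  expect_equal(nm$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(nm$efficiency[1], 1)
  # leaf: distances 1, 2, 2, 2 -> mean(1, 1/2, 1/2, 1/2)
  expect_equal(nm$efficiency[2], 0.625)
})

test_that("isolated nodes get zero efficiency and betweenness", {
  w <- mat_from_edges(4, rbind(c(1, 2), c(2, 3)))
  nm <- nodal_metrics(w)
  expect_equal(nm$efficiency[4], 0)
  expect_equal(nm$betweenness[4], 0)
})

test_that("metrics agree with the brute-force oracle on random graphs", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    w <- random_weighted_graph(n, density = stats::runif(1, 0.2, 0.7))
    if (sum(w) == 0) next
    gm <- global_metrics(w)
    or <- oracle_global_metrics(w)
    expect_equal(gm$Cp, or$Cp, tolerance = 1e-9)
    expect_equal(gm$Eglob, or$Eglob, tolerance = 1e-9)
    expect_equal(gm$Eloc, or$Eloc, tolerance = 1e-9)
    if (!is.na(or$Lp)) expect_equal(gm$Lp, or$Lp, tolerance = 1e-9)
    nm <- nodal_metrics(w)
    expect_equal(nm$efficiency, oracle_nodal_efficiency(w), tolerance = 1e-9)
    expect_equal(nm$betweenness, oracle_betweenness(w), tolerance = 1e-9)
  }
})

test_that("weight scaling transforms metrics as expected", {
  set.seed(7)
  w <- random_weighted_graph(10, 0.4)
  w <- w / max(w)  # keep c * w inside [0, 1]
  cc <- 0.5
  gm1 <- global_metrics(w)
  gm2 <- global_metrics(cc * w)
  expect_equal(gm2$Eglob, cc * gm1$Eglob)
  expect_equal(gm2$Lp, gm1$Lp / cc)
  expect_equal(gm2$Cp, gm1$Cp)  # max-normalized: scale invariant
  nm1 <- nodal_metrics(w)
  nm2 <- nodal_metrics(cc * w)
  expect_equal(nm2$efficiency, cc * nm1$efficiency)
  expect_equal(identify_hubs(setNames(nm1$betweenness, nm1$region))$hubs,
               identify_hubs(setNames(nm2$betweenness, nm2$region))$hubs)
})

test_that("removing an edge never increases efficiency", {
  set.seed(11)
  for (rep in 1:10) {
    w <- random_weighted_graph(8, 0.5)
    nz <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) next
    k <- sample(nrow(nz), 1)
    w2 <- w
    w2[nz[k, 1], nz[k, 2]] <- w2[nz[k, 2], nz[k, 1]] <- 0
    expect_lte(global_metrics(w2)$Eglob, global_metrics(w)$Eglob + 1e-12)
    expect_true(all(nodal_metrics(w2)$efficiency <=
                      nodal_metrics(w)$efficiency + 1e-12))
  }
})

test_that("sparsity thresholding keeps round(s * Npairs) strongest edges", {
  k5 <- mat_from_edges(5, edge_index(5))
  thr <- threshold_by_sparsity(k5, 0.3)
  expect_equal(sum(thr > 0) / 2, 3)  # round(0.3 * 10) = 3

  set.seed(3)
  w <- random_weighted_graph(12, 0.5)
  expect_identical(threshold_by_sparsity(w, 1.0), as_connectivity_matrix(w))
  expect_error(threshold_by_sparsity(w, 0), "positive")
  expect_error(threshold_by_sparsity(w, -0.1), "positive")
})

test_that("thresholding breaks weight ties by lexicographic edge order", {
  # 4-node graph: edges (1,2), (1,3), (2,3) tie at 0.5; (3,4) weaker.
  w <- mat_from_edges(4, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4)),
                      c(0.5, 0.5, 0.5, 0.2))
  # K = round(0.34 * 6) = 2 -> the two lexicographically first tied edges
  thr <- threshold_by_sparsity(w, 0.34)
  expect_equal(sum(thr > 0) / 2, 2)
  expect_true(thr[1, 2] > 0 && thr[1, 3] > 0)
  expect_equal(thr[2, 3], 0)
})

test_that("thresholded networks stay symmetric with zero diagonal", {
  set.seed(5)
  w <- random_weighted_graph(15, 0.6)
  for (s in c(0.1, 0.3, 0.8)) {
    thr <- threshold_by_sparsity(w, s)
    expect_identical(thr, t(thr))
    expect_true(all(diag(thr) == 0))
    expect_true(all(thr[thr > 0] %in% w))
  }
})

test_that("random reference on a complete graph is exactly 1", {
  k4 <- mat_from_edges(4, edge_index(4))
  expect_message(rr <- random_reference(k4, n_random = 10, seed = 1),
                 "unchanged")
  expect_equal(rr$gamma, 1)
  expect_equal(rr$lambda, 1)
  expect_equal(rr$sigma, 1)
})

test_that("ER graphs are close to their own degree-preserving null", {
  # an ER graph is its own degree-matched null up to finite-size
  # degree-sequence effects, so gamma scatters mildly around 1
  set.seed(19)
  gammas <- replicate(10, {
    w <- (matrix(stats::runif(60 * 60), 60) < 0.15) * 1
    w[lower.tri(w)] <- 0
    diag(w) <- 0
    w <- w + t(w)
    random_reference(w, n_random = 20, seed = sample.int(1e6, 1))$gamma
  })
  expect_lt(abs(mean(gammas) - 1), 0.15)
  expect_true(all(abs(gammas - 1) < 0.25))
})

test_that("rewired surrogates preserve the binary degree sequence", {
  set.seed(23)
  w <- random_weighted_graph(20, 0.3)
  g0 <- igraph::graph_from_adjacency_matrix((w > 0) * 1, mode = "undirected",
                                            diag = FALSE)
  deg0 <- igraph::degree(g0)
  for (rep in 1:5) {
    gr <- igraph::rewire(g0, igraph::keeping_degseq(niter = 10 * sum(w > 0) / 2))
    expect_identical(igraph::degree(gr), deg0)
  }
})

test_that("random reference is deterministic given a seed", {
  set.seed(31)
  w <- random_weighted_graph(20, 0.4)
  r1 <- random_reference(w, n_random = 20, seed = 99)
  r2 <- random_reference(w, n_random = 20, seed = 99)
  expect_identical(r1, r2)
})

test_that("AUC integrates trapezoidally and is linear", {
  s <- sparsity_grid()
  expect_equal(length(s), 6)
  expect_equal(auc_trapezoid(s, rep(2, 6)), 0.1)
  expect_equal(auc_trapezoid(s, 0:5), 0.125)
  set.seed(1)
  y <- stats::runif(6)
  expect_equal(auc_trapezoid(s, 3 * y), 3 * auc_trapezoid(s, y))
  expect_warning(a <- auc_trapezoid(s, c(y[-6], NA)), "missing")
  expect_true(is.na(a))
  expect_error(auc_trapezoid(0.1, 1), "two grid points")
})

test_that("metric curves cover the grid and Eglob is non-decreasing in s", {
  set.seed(8)
  w <- random_weighted_graph(30, 0.5)
  cur <- metric_curves(w, n_random = 0, nodal = TRUE)
  expect_equal(nrow(cur$global), 6)
  expect_true(all(diff(cur$global$Eglob) >= -1e-12))
  expect_equal(dim(cur$nodal_efficiency), c(30, 6))
  # single point s = 1: whole-matrix metrics
  cur1 <- metric_curves(w, grid = 0.999999, n_random = 0, nodal = FALSE)
  gm <- global_metrics(w)
  expect_equal(cur1$global$Eglob, gm$Eglob)
  expect_equal(cur1$global$Cp, gm$Cp)
})

test_that("hub rule flags nodes at mean + SD of betweenness", {
  h <- identify_hubs(c(n1 = 10, n2 = 2, n3 = 2, n4 = 2))
  expect_equal(h$threshold, 8)  # mean 4, sample SD 4
  expect_equal(h$hubs, "n1")
  # degenerate: equal values -> SD 0 -> all flagged
  expect_equal(length(identify_hubs(rep(3, 5))$hubs), 5)
  expect_equal(length(identify_hubs(rep(0, 4))$hubs), 4)
  expect_error(identify_hubs(5), "two nodes")
})
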