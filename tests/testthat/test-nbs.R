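# Edge-wise statistics, suprathreshold components and the NBS permutation
# test.

# small stack where a chosen edge takes prescribed per-subject values
stack_with_edge <- function(values, n = 4, base = 0.5) {
  lapply(values, function(v) {
    w <- matrix(base, n, n)
    diag(w) <- 0
    w[1, 2] <- w[2, 1] <- v
    w
  })
}

test_that("pairwise edge t matches the pooled-variance formula", {
  mats <- stack_with_edge(c(1, 2, 3, 4, 5, 6) / 10)
  groups <- rep(c("A", "B"), each = 3)
  # constant background edges are flagged as untestable, hence the warning
  es <- suppressWarnings(edge_statistics(mats, groups, contrast = c("A", "B")))
  # oracle: t.test(c(1,2,3), c(4,5,6), var.equal = TRUE)
  expect_equal(es$stat[1, 2], -3.674235, tolerance = 1e-6)
  expect_equal(es$p[1, 2], 0.02131164, tolerance = 1e-6)
  expect_equal(es$df, 4)
  expect_identical(es$stat, t(es$stat))
})

test_that("symmetric group values give t = 0 and balanced equal means F = 0", {
  mats <- stack_with_edge(c(0.4, 0.6, 0.3, 0.7))
  es <- suppressWarnings(edge_statistics(mats, rep(c("A", "B"), each = 2),
                                         contrast = c("A", "B")))
  expect_equal(es$stat[1, 2], 0)
  mats3 <- stack_with_edge(c(0.4, 0.6, 0.3, 0.7, 0.2, 0.8))
  es3 <- suppressWarnings(edge_statistics(mats3, rep(c("A", "B", "C"), each = 2)))
  expect_equal(es3$stat[1, 2], 0)
  expect_equal(es3$method, "anova")
})

test_that("zero within-group variance marks the edge missing with a warning", {
  mats <- stack_with_edge(c(0.5, 0.5, 0.5, 0.5))
  expect_warning(
    es <- edge_statistics(mats, rep(c("A", "B"), each = 2),
                          contrast = c("A", "B")),
    "zero within-group variance"
  )
  expect_true(is.na(es$stat[1, 2]))
})

test_that("component finding matches the union-find oracle", {
  # worked example: edges (1,2), (2,3), (4,5) -> components of sizes 2 and 1
  p <- matrix(0.5, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(4, 5))) {
    p[e[1], e[2]] <- p[e[2], e[1]] <- 0.001
  }
  comps <- suprathreshold_components(p, primary_p = 0.01)
  expect_equal(vapply(comps, `[[`, integer(1), "size"), c(2L, 1L))
  expect_equal(comps[[1]]$nodes, c(1L, 2L, 3L))

  # all p above threshold -> empty
  expect_length(suprathreshold_components(matrix(0.5, 4, 4), 0.01), 0)

  # 5-node ring -> one component of size 5
  ring <- matrix(0.5, 5, 5)
  for (k in 1:5) {
    a <- k
    b <- k %% 5 + 1
    ring[a, b] <- ring[b, a] <- 0.001
  }
  comps <- suprathreshold_components(ring, 0.01)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$size, 5L)

  # random sparse p-matrices vs the oracle
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    p <- matrix(1, n, n)
    ei <- edge_index(n)
    on <- stats::runif(nrow(ei)) < 0.1
    p[ei[on, , drop = FALSE]] <- 0.001
    p[ei[on, c(2, 1), drop = FALSE]] <- 0.001
    comps <- suprathreshold_components(p, 0.01)
    sizes <- sort(vapply(comps, `[[`, integer(1), "size"))
    oracle <- sort(oracle_component_sizes(ei[on, , drop = FALSE], n))
    expect_equal(sizes, oracle)
  }
})

test_that("corrected p follows the smoothed proportion formula", {
  set.seed(101)
  co <- suppressWarnings(generate_cohort(
    cohort_config(n_per_group = 8, n_regions = 30, eglob_effect = 1,
                  planted_delta = 0.25, n_planted_edges = 4, seed = 41)
  ))
  keep <- co$phenotypes$group %in% c("HC", "MCI")
  res <- nbs_test(co$matrices[keep], droplevels(co$phenotypes$group[keep]),
                  nbs_params(n_perm = 199, seed = 5), contrast = c("HC", "MCI"))
  for (cc in res$components) {
    expect_equal(cc$p_corrected,
                 (1 + sum(res$null_max >= cc$size)) / (199 + 1))
    expect_gte(cc$p_corrected, 1 / 200)
    expect_lte(cc$p_corrected, 1)
  }
  # monotone: larger components never have larger corrected p
  sizes <- vapply(res$components, `[[`, integer(1), "size")
  ps <- vapply(res$components, `[[`, numeric(1), "p_corrected")
  expect_true(all(diff(ps[order(sizes)]) <= 0 + 1e-15))
})

test_that("n_perm = 1 with observed M above the single null gives p = 0.5", {
  # formula check on the smoothing: (1 + 0) / (1 + 1)
  set.seed(55)
  co <- suppressWarnings(generate_cohort(
    cohort_config(n_per_group = 6, n_regions = 20, eglob_effect = 1,
                  planted_delta = 0.4, n_planted_edges = 5, seed = 43)
  ))
  keep <- co$phenotypes$group %in% c("HC", "MCI")
  expect_warning(
    res <- nbs_test(co$matrices[keep], droplevels(co$phenotypes$group[keep]),
                    nbs_params(n_perm = 1, seed = 3), contrast = c("HC", "MCI")),
    "coarse"
  )
  big <- res$components[[1]]
  if (big$size > max(res$null_max)) {
    expect_equal(big$p_corrected, 0.5)
  }
  # strict exceedance rule available
  expect_warning(
    res2 <- nbs_test(co$matrices[keep], droplevels(co$phenotypes$group[keep]),
                     nbs_params(n_perm = 1, seed = 3,
                                exceed_rule = "greater"),
                    contrast = c("HC", "MCI")),
    "coarse"
  )
  expect_equal(res2$components[[1]]$p_corrected,
               sum(res2$null_max > res2$components[[1]]$size) / 1)
})

test_that("the permutation engine is reproducible under a seed", {
  co <- suppressWarnings(generate_cohort(
    cohort_config(n_per_group = 6, n_regions = 25, seed = 47)
  ))
  keep <- co$phenotypes$group %in% c("HC", "MCI")
  args <- list(co$matrices[keep], droplevels(co$phenotypes$group[keep]))
  r1 <- nbs_test(args[[1]], args[[2]], nbs_params(n_perm = 150, seed = 9),
                 contrast = c("HC", "MCI"))
  r2 <- nbs_test(args[[1]], args[[2]], nbs_params(n_perm = 150, seed = 9),
                 contrast = c("HC", "MCI"))
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(
    lapply(r1$components, `[[`, "p_corrected"),
    lapply(r2$components, `[[`, "p_corrected")
  )
})

test_that("edges absent in most subjects are masked out", {
  set.seed(61)
  mats <- replicate(10, {
    w <- random_weighted_graph(8, 0.9)
    w
  }, simplify = FALSE)
  # edge (1,2) present in only 2 of 10 subjects
  for (k in 3:10) mats[[k]][1, 2] <- mats[[k]][2, 1] <- 0
  es <- suppressWarnings(
    edge_statistics(mats, rep(c("A", "B"), 5), contrast = c("A", "B"))
  )
  expect_false(es$mask[1, 2])
  expect_true(is.na(es$stat[1, 2]))
})
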