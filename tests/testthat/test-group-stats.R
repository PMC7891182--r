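# Covariate-adjusted group tests, post-hoc contrasts, FDR, Spearman, hubs.

test_that("ANCOVA F reduces to plain one-way ANOVA with constant covariates", {
  values <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  groups <- rep(c("A", "B", "C"), each = 3)
  cov <- data.frame(age = rep(50, 9), sex = rep(0, 9))
  res <- ancova_group_effect(values, groups, cov)
  # explicit sum-of-squares oracle: SSB = 6 (df 2), SSW = 6 (df 6)
  oracle <- summary(stats::aov(values ~ factor(groups)))[[1]]
  expect_equal(res$F, oracle$`F value`[1])
  expect_equal(res$F, 3.0)
  expect_equal(res$p, oracle$`Pr(>F)`[1])
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
})

test_that("ANCOVA adjusts for informative covariates", {
  set.seed(15)
  n <- 60
  groups <- rep(c("A", "B", "C"), each = n / 3)
  age <- stats::rnorm(n, 55, 6)
  # response depends on age only; group effect should be null
  values <- 0.1 * age + stats::rnorm(n, 0, 0.5)
  res <- ancova_group_effect(values, groups, data.frame(age = age))
  plain <- summary(stats::aov(values ~ factor(groups)))[[1]]$`F value`[1]
  # adjusted F computed against the covariate model, not the grand mean
  expect_false(isTRUE(all.equal(res$F, plain)))
  expect_gt(res$p, 0.001)
})

test_that("ANCOVA p-values are calibrated under label permutation", {
  set.seed(29)
  n <- 30
  values <- stats::rnorm(n)
  age <- stats::rnorm(n, 55, 5)
  sex <- stats::rbinom(n, 1, 0.5)
  ps <- replicate(200, {
    g <- sample(rep(c("A", "B", "C"), each = 10))
    ancova_group_effect(values, g, data.frame(age = age, sex = sex))$p
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.12)
})

test_that("rank-deficient designs and tiny groups are rejected", {
  expect_error(ancova_group_effect(1:4, c("A", "A", "B", "B")), "three subjects")
  expect_error(ancova_group_effect(1:6, rep("A", 6)), "two groups")
})

test_that("post-hoc contrasts come from the adjusted model and are gatekept", {
  set.seed(33)
  n <- 45
  groups <- factor(rep(c("HC", "NC", "MCI"), each = 15),
                   levels = c("HC", "NC", "MCI"))
  values <- c(stats::rnorm(15, 3), stats::rnorm(15, 2), stats::rnorm(15, 1))
  cov <- data.frame(age = stats::rnorm(n, 55, 5),
                    sex = stats::rbinom(n, 1, 0.5))
  ph <- posthoc_pairwise(values, groups, cov, correction = "bonferroni")
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_corrected >= ph$p))
  # Bonferroni multiplies by the number of contrasts, capped at 1
  expect_equal(ph$p_corrected, pmin(ph$p * 3, 1))
  expect_true(all(grepl(">", ph$direction)))
  hcmci <- ph[ph$group1 == "HC" & ph$group2 == "MCI", ]
  expect_gt(hcmci$estimate, 0)

  # identical groups: gate closes
  null_vals <- rep(c(1.05, 0.95, 1.0), 15)
  ph0 <- posthoc_pairwise(null_vals, groups, cov)
  expect_equal(nrow(ph0), 0)
  expect_gte(attr(ph0, "omnibus_p"), 0.05)
  # non-gatekept mode evaluates contrasts anyway, all near 1 after correction
  ph1 <- posthoc_pairwise(null_vals, groups, cov, gatekeep = FALSE)
  expect_equal(nrow(ph1), 3)
  expect_true(all(ph1$p_corrected > 0.5))
})

test_that("FDR adjustment reproduces the hand step-up computation", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  # order invariance and dominance over raw p
  set.seed(2)
  p <- stats::runif(20)
  perm <- sample(20)
  expect_equal(fdr_adjust(p)[perm], fdr_adjust(p[perm]))
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "lie in")
})

test_that("Spearman correlation handles monotone pairs and ties", {
  x <- 1:10
  expect_equal(spearman_corr(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  # ties: brute-force oracle = Pearson on average ranks
  a <- c(1, 2, 2, 3, 5, 5, 7)
  b <- c(10, 20, 25, 30, 22, 29, 31)
  oracle <- stats::cor(rank(a), rank(b))
  expect_equal(spearman_corr(a, b)$rho, oracle)
  # zero variance -> missing with warning
  expect_warning(res <- spearman_corr(rep(1, 6), 1:6), "zero variance")
  expect_true(is.na(res$rho))
  expect_error(spearman_corr(1:3, 1:3), "at least 5")
})

test_that("hub set comparison reports shared, gained and lost nodes", {
  same <- compare_hubs(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(same$shared, c("x", "y"))
  expect_length(same$pairs[["a to b"]]$lost, 0)

  cmp <- compare_hubs(list(g1 = c("a", "b", "c"), g2 = c("b", "c", "d")))
  expect_equal(cmp$pairs[["g1 to g2"]]$lost, "a")
  expect_equal(cmp$pairs[["g1 to g2"]]$gained, "d")

  three <- compare_hubs(list(
    h = c("a", "b", "c"), n = c("b", "c", "d"), m = c("c", "d", "e")
  ))
  expect_equal(three$shared, "c")
})

test_that("nodal group table applies FDR across regions per contrast", {
  set.seed(91)
  co <- suppressWarnings(generate_cohort(
    cohort_config(n_per_group = 12, n_regions = 30, seed = 53)
  ))
  nv <- vapply(co$matrices, function(w) {
    nodal_metrics(threshold_by_sparsity(w, 0.15))$efficiency
  }, numeric(30))
  rownames(nv) <- region_labels(30)
  tab <- nodal_group_table(nv, co$phenotypes, gatekeep = FALSE)
  expect_equal(nrow(tab), 30)
  expect_equal(tab$p_corrected, fdr_adjust(tab$p))
  expect_equal(tab$p_HC_vs_MCI_corrected, fdr_adjust(tab$p_HC_vs_MCI))
  # regions with constant values across subjects stay NA
  expect_true(all(tab$p_corrected >= tab$p - 1e-15, na.rm = TRUE))
})

test_that("demographics table runs ANOVA for numerics and chi-square for sex", {
  co <- generate_cohort(small_cohort_config(seed = 57))
  tab <- demographics_table(co$phenotypes, columns = c("age", "education"))
  expect_setequal(tab$variable, c("age", "education", "sex"))
  expect_equal(tab$test[tab$variable == "sex"], "chisq")
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
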