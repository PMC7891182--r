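# Covariate-adjusted group comparisons of network metrics, gatekept post-hoc
# contrasts with Bonferroni/FDR correction, Spearman brain-behaviour
# correlations, and hub-set comparison.

# Build the covariate design data frame (sex recoded to a 0/1 indicator).
prepare_covariates <- function(covariates, n) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    return(NULL)
  }
  cv <- as.data.frame(covariates)
  if (nrow(cv) != n) stop("covariate rows must match values", call. = FALSE)
  for (j in seq_along(cv)) {
    if (is.character(cv[[j]]) || is.factor(cv[[j]])) {
      lev <- sort(unique(as.character(cv[[j]])))
      if (length(lev) > 2) {
        stop("only two-level factor covariates are supported", call. = FALSE)
      }
      cv[[j]] <- as.numeric(as.character(cv[[j]]) == lev[length(lev)])
    }
  }
  cv
}

#' Covariate-adjusted one-way group effect (ANCOVA F)
#'
#' Fits a linear model with group indicators plus covariates and tests the
#' group indicators jointly via the extra-sum-of-squares F against the
#' covariate-only model. With uninformative covariates (constant columns)
#' this reduces exactly to the plain one-way ANOVA F.
#'
#' @param values Numeric response (e.g. AUC of a network metric, one value
#'   per subject).
#' @param groups Group label per subject.
#' @param covariates Optional data frame of confounders (e.g. age and sex;
#'   factors are recoded 0/1).
#' @return A list with `F`, `p`, `df1`, `df2`, and the fitted full model.
#' @export
ancova_group_effect <- function(values, groups, covariates = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 3)) {
    stop("need at least three subjects per group", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    warning("constant response; group effect undefined", call. = FALSE)
    return(list(F = NA_real_, p = NA_real_, df1 = NA_integer_,
                df2 = NA_integer_, fit = NULL))
  }
  cv <- prepare_covariates(covariates, length(values))
  if (is.null(cv)) {
    dat0 <- data.frame(values = values)
    fit0 <- stats::lm(values ~ 1, data = dat0)
    fit1 <- stats::lm(values ~ groups, data = cbind(dat0, groups = groups))
  } else {
    dat0 <- cbind(data.frame(values = values), cv)
    fit0 <- stats::lm(values ~ ., data = dat0)
    fit1 <- stats::lm(values ~ ., data = cbind(dat0, groups = groups))
  }
  if (fit1$df.residual < 1) stop("rank-deficient design", call. = FALSE)
  aov_tab <- stats::anova(fit0, fit1)
  fstat <- aov_tab$F[2]
  if (is.na(fstat)) stop("rank-deficient design", call. = FALSE)
  list(
    F = fstat, p = aov_tab$`Pr(>F)`[2],
    df1 = aov_tab$Df[2], df2 = fit1$df.residual, fit = fit1
  )
}

#' Gatekept post-hoc pairwise contrasts from the adjusted model
#'
#' All pairwise group contrasts estimated from the same covariate-adjusted
#' linear model used for the omnibus test, with the chosen multiplicity
#' correction. Mirroring the usual workflow, post-hoc contrasts are only
#' evaluated when the omnibus test is significant (`gatekeep = TRUE`); a
#' non-gatekept mode exists for power studies.
#'
#' @param values,groups,covariates As in [ancova_group_effect()].
#' @param correction `"bonferroni"`, `"fdr"`, or `"none"`.
#' @param gatekeep Only run when the omnibus p is below `alpha`.
#' @param alpha Gate level for the omnibus test.
#' @return A data frame with one row per contrast: `group1`, `group2`,
#'   `estimate` (adjusted mean difference, group1 minus group2), `t`, `p`,
#'   `p_corrected`, `direction`. Attributes `omnibus_F` and `omnibus_p` carry
#'   the gate; when gated out the frame has zero rows.
#' @export
posthoc_pairwise <- function(values, groups, covariates = NULL,
                             correction = c("bonferroni", "fdr", "none"),
                             gatekeep = TRUE, alpha = 0.05) {
  correction <- match.arg(correction)
  groups <- droplevels(as.factor(groups))
  omni <- ancova_group_effect(values, groups, covariates)
  empty <- data.frame(
    group1 = character(0), group2 = character(0), estimate = numeric(0),
    t = numeric(0), p = numeric(0), p_corrected = numeric(0),
    direction = character(0), stringsAsFactors = FALSE
  )
  if (is.na(omni$p) || (gatekeep && omni$p >= alpha)) {
    return(structure(empty, omnibus_F = omni$F, omnibus_p = omni$p))
  }
  fit <- omni$fit
  beta <- stats::coef(fit)
  vc <- stats::vcov(fit)
  lev <- levels(groups)
  coef_names <- paste0("groups", lev)
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    # contrast a - b in treatment coding (reference level has no coefficient)
    cv <- stats::setNames(numeric(length(beta)), names(beta))
    na_ok <- function(nm, sgn) {
      if (nm %in% names(cv)) cv[nm] <<- cv[nm] + sgn
    }
    na_ok(paste0("groups", a), +1)
    na_ok(paste0("groups", b), -1)
    usable <- !is.na(beta)
    est <- sum(cv[usable] * beta[usable])
    keep <- names(beta)[usable]
    se <- sqrt(drop(t(cv[keep]) %*% vc[keep, keep] %*% cv[keep]))
    tt <- est / se
    pp <- 2 * stats::pt(abs(tt), fit$df.residual, lower.tail = FALSE)
    data.frame(
      group1 = a, group2 = b, estimate = est, t = tt, p = pp,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- stats::p.adjust(out$p, method = switch(
    correction, bonferroni = "bonferroni", fdr = "BH", none = "none"
  ))
  out$direction <- ifelse(out$estimate > 0,
                          paste(out$group1, ">", out$group2),
                          paste(out$group2, ">", out$group1))
  structure(out, omnibus_F = omni$F, omnibus_p = omni$p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1; a thin named
#' wrapper over `stats::p.adjust(method = "BH")` so the correction applied
#' across regions is explicit in pipeline code.
#'
#' @param p Vector of p-values (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average-rank tie handling; two-sided p via the
#' asymptotic t approximation (uncorrected). Zero variance in either vector
#' yields a missing result with a warning.
#'
#' @param x,y Paired numeric vectors (at least 5 complete pairs).
#' @return A list with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; Spearman rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Compare hub sets across groups
#'
#' @param hub_sets Named list of character vectors (hub labels per group).
#' @return A list with `shared` (intersection across all groups) and
#'   `pairs`, one entry per ordered group pair with `lost` (hubs of the first
#'   absent in the second) and `gained`.
#' @export
compare_hubs <- function(hub_sets) {
  stopifnot(is.list(hub_sets), length(hub_sets) >= 2)
  if (is.null(names(hub_sets))) {
    names(hub_sets) <- paste0("G", seq_along(hub_sets))
  }
  shared <- Reduce(intersect, hub_sets)
  nm <- names(hub_sets)
  pairs <- list()
  for (a in nm) {
    for (b in nm) {
      if (a == b) next
      pairs[[paste(a, "to", b)]] <- list(
        lost = setdiff(hub_sets[[a]], hub_sets[[b]]),
        gained = setdiff(hub_sets[[b]], hub_sets[[a]])
      )
    }
  }
  list(shared = shared, pairs = pairs)
}

#' Group comparison table for global metrics
#'
#' One row per metric: group means and SDs, covariate-adjusted omnibus F and
#' p, and gatekept post-hoc contrast summaries — the usual "global network
#' properties by group" results table.
#'
#' @param metric_table Data frame of per-subject metric values (columns =
#'   metrics) aligned with `phenotypes` rows.
#' @param phenotypes Data frame with `group`, `age`, `sex`.
#' @param metrics Character vector of metric column names to test.
#' @param correction Post-hoc correction passed to [posthoc_pairwise()].
#' @param gatekeep Gate post-hoc tests on the omnibus p.
#' @return Data frame with one row per metric.
#' @export
group_global_table <- function(metric_table, phenotypes,
                               metrics = c("Cp", "Lp", "Eglob", "Eloc"),
                               correction = "fdr", gatekeep = TRUE) {
  groups <- droplevels(as.factor(phenotypes$group))
  cov <- phenotypes[, intersect(c("age", "sex"), names(phenotypes)),
                    drop = FALSE]
  lev <- levels(groups)
  rows <- lapply(metrics, function(m) {
    v <- metric_table[[m]]
    omni <- ancova_group_effect(v, groups, cov)
    ph <- posthoc_pairwise(v, groups, cov, correction = correction,
                           gatekeep = gatekeep)
    row <- data.frame(metric = m, stringsAsFactors = FALSE)
    for (g in lev) {
      row[[paste0("mean_", g)]] <- mean(v[groups == g])
      row[[paste0("sd_", g)]] <- stats::sd(v[groups == g])
    }
    row$F <- omni$F
    row$p <- omni$p
    row$posthoc <- if (nrow(ph) == 0) {
      "ns"
    } else {
      paste(sprintf("%s-%s p=%.4g", ph$group1, ph$group2, ph$p_corrected),
            collapse = "; ")
    }
    row
  })
  do.call(rbind, rows)
}

#' Nodal metric group tests with FDR across regions
#'
#' Covariate-adjusted omnibus test per region plus gatekept post-hoc
#' contrasts; FDR correction is applied across the regions within the metric
#' family, separately for the omnibus column and for each pairwise contrast.
#'
#' @param nodal_values Region x subject matrix (or data frame) of per-subject
#'   nodal AUC values.
#' @param phenotypes Data frame with `group`, `age`, `sex` aligned with the
#'   columns of `nodal_values`.
#' @param correction Correction across regions (`"fdr"` or `"bonferroni"`).
#' @param gatekeep Gate post-hoc contrasts on the (uncorrected) omnibus p.
#' @return Data frame with one row per region: omnibus F/p/p_corrected and
#'   raw + corrected p per pairwise contrast.
#' @export
nodal_group_table <- function(nodal_values, phenotypes, correction = "fdr",
                              gatekeep = TRUE) {
  nodal_values <- as.matrix(nodal_values)
  groups <- droplevels(as.factor(phenotypes$group))
  cov <- phenotypes[, intersect(c("age", "sex"), names(phenotypes)),
                    drop = FALSE]
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  pair_names <- paste(pairs[1, ], pairs[2, ], sep = "_vs_")
  nreg <- nrow(nodal_values)
  out <- data.frame(
    region = rownames(nodal_values) %||% region_labels(nreg),
    F = NA_real_, p = NA_real_, stringsAsFactors = FALSE
  )
  praw <- matrix(NA_real_, nreg, length(pair_names),
                 dimnames = list(NULL, pair_names))
  for (r in seq_len(nreg)) {
    v <- nodal_values[r, ]
    omni <- suppressWarnings(ancova_group_effect(v, groups, cov))
    out$F[r] <- omni$F
    out$p[r] <- omni$p
    ph <- suppressWarnings(
      posthoc_pairwise(v, groups, cov, correction = "none",
                       gatekeep = gatekeep)
    )
    if (nrow(ph) > 0) {
      praw[r, paste(ph$group1, ph$group2, sep = "_vs_")] <- ph$p
    }
  }
  meth <- if (correction == "fdr") fdr_adjust else {
    function(p) stats::p.adjust(p, "bonferroni")
  }
  out$p_corrected <- meth(out$p)
  for (pn in pair_names) {
    out[[paste0("p_", pn)]] <- praw[, pn]
    out[[paste0("p_", pn, "_corrected")]] <- meth(praw[, pn])
  }
  out
}

#' Demographic balance tests
#'
#' One-way ANOVA for numeric phenotype columns (age, education, cognitive
#' scores) and a chi-square test for sex composition across groups — the
#' usual demographics table checks.
#'
#' @param phenotypes Data frame with `group`, `sex` and numeric columns.
#' @param columns Numeric columns to test (default: all numeric).
#' @return Data frame with `variable`, `statistic` (F or X-squared), `p`,
#'   `test`.
#' @export
demographics_table <- function(phenotypes, columns = NULL) {
  groups <- droplevels(as.factor(phenotypes$group))
  if (is.null(columns)) {
    columns <- names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))]
  }
  rows <- lapply(columns, function(cn) {
    a <- stats::anova(stats::lm(phenotypes[[cn]] ~ groups))
    data.frame(variable = cn, statistic = a$`F value`[1], p = a$`Pr(>F)`[1],
               test = "anova", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("sex" %in% names(phenotypes)) {
    ct <- suppressWarnings(
      stats::chisq.test(table(phenotypes$sex, groups))
    )
    out <- rbind(out, data.frame(
      variable = "sex", statistic = unname(ct$statistic), p = ct$p.value,
      test = "chisq", stringsAsFactors = FALSE
    ))
  }
  out
}
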