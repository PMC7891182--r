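# Network-based statistic: edge-wise group statistics, component-forming
# threshold, and a max-component permutation null with component-level
# corrected p-values.

#' NBS parameters
#'
#' @param primary_p Component-forming threshold on uncorrected edge p-values
#'   (edges with `p < primary_p` enter components); default 0.01.
#' @param n_perm Number of label permutations (the reference analysis uses
#'   5000); values below 100 trigger a warning because the null resolution
#'   becomes too coarse for `alpha = 0.05`.
#' @param alpha Component-level corrected significance threshold.
#' @param mask_prop Edges are only tested when nonzero in at least this
#'   fraction of subjects (degenerate statistics on rarely-present edges are
#'   excluded).
#' @param exceed_rule How permuted max-component sizes are compared with the
#'   observed size M when computing the corrected p: `"geq"` counts
#'   permutations with max size `>= M` and applies +1 smoothing (guarantees
#'   valid, nonzero p-values); `"greater"` is the strict `> M` reading.
#' @param seed RNG seed for the permutation engine.
#' @return An `nbs_params` list.
#' @export
nbs_params <- function(primary_p = 0.01, n_perm = 5000, alpha = 0.05,
                       mask_prop = 0.5, exceed_rule = c("geq", "greater"),
                       seed = NULL) {
  if (!is_scalar(primary_p) || primary_p <= 0 || primary_p >= 1) {
    stop("primary_p must lie in (0, 1)", call. = FALSE)
  }
  if (!is_count(n_perm)) stop("n_perm must be a positive count", call. = FALSE)
  list(primary_p = primary_p, n_perm = n_perm, alpha = alpha,
       mask_prop = mask_prop, exceed_rule = match.arg(exceed_rule),
       seed = seed)
}

# Stack the upper-triangle edges of a list of matrices into a subjects x
# edges matrix, plus the edge endpoint index.
stack_edges <- function(matrices) {
  n <- nrow(matrices[[1]])
  ei <- edge_index(n)
  x <- t(vapply(matrices, function(w) w[ei], numeric(nrow(ei))))
  list(x = x, ei = ei, n = n)
}

# Vectorized one-way ANOVA F across the columns of X for integer group
# index gi (1..g), via the sum-of-squares identity SSW = colSums(x^2) -
# sum_g n_g m_g^2; css is precomputable when X is fixed across
# permutations. Columns with (numerically) zero within-group variance get
# NA.
edge_f <- function(x, gi, g, css = colSums(x^2)) {
  ns <- tabulate(gi, g)
  m_g <- rowsum(x, gi, reorder = TRUE) / ns
  grand <- colMeans(x)
  n <- nrow(x)
  fit <- colSums(ns * m_g^2)
  ssb <- fit - n * grand^2
  ssw <- css - fit
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[ssw <= 1e-10 * pmax(css, 1)] <- NA_real_
  f
}

# Vectorized pooled-variance two-sample t (group 1 minus group 2) across
# columns of X, using the same identity. Columns with zero pooled variance
# get NA.
edge_t <- function(x, gi, css = colSums(x^2)) {
  i1 <- gi == 1L
  n1 <- sum(i1)
  n2 <- nrow(x) - n1
  s1 <- colSums(x[i1, , drop = FALSE])
  m1 <- s1 / n1
  m2 <- (colSums(x) - s1) / n2
  ss <- css - n1 * m1^2 - n2 * m2^2
  sp2 <- ss / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tt[ss <= 1e-10 * pmax(css, 1)] <- NA_real_
  tt
}

#' Edge-wise group statistics over a matrix stack
#'
#' For every edge present in at least `mask_prop` of subjects, computes a
#' one-way ANOVA F (omnibus contrast across all groups) or a pooled-variance
#' two-sample two-tailed t (pairwise contrast), together with uncorrected
#' p-values. Untested edges are `NA`.
#'
#' @param matrices List of same-sized connectivity matrices (one per
#'   subject).
#' @param groups Group label per subject (factor or character).
#' @param contrast `"omnibus"`, or a length-2 character vector naming the two
#'   groups to compare (t is first minus second).
#' @param mask_prop Minimum fraction of subjects (within the contrast) with a
#'   nonzero weight for an edge to be tested.
#' @return A list with symmetric matrices `stat` and `p` (NA off-mask), the
#'   logical `mask` matrix, `df`, and `method`.
#' @export
edge_statistics <- function(matrices, groups, contrast = "omnibus",
                            mask_prop = 0.5) {
  groups <- as.factor(groups)
  if (length(groups) != length(matrices)) {
    stop("groups must match matrices in length", call. = FALSE)
  }
  if (!identical(contrast, "omnibus")) {
    if (length(contrast) != 2 || !all(contrast %in% levels(groups))) {
      stop("contrast must be 'omnibus' or two group labels", call. = FALSE)
    }
    keep <- groups %in% contrast
    matrices <- matrices[keep]
    groups <- factor(as.character(groups[keep]), levels = contrast)
  }
  groups <- droplevels(groups)
  g <- nlevels(groups)
  if (g < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("need at least two subjects per group", call. = FALSE)
  }
  st <- stack_edges(matrices)
  mask_e <- colMeans(st$x > 0) >= mask_prop
  gi <- as.integer(groups)
  ns <- nrow(st$x)
  if (identical(contrast, "omnibus") && g > 2) {
    stat_e <- edge_f(st$x, gi, g)
    df <- c(g - 1, ns - g)
    p_e <- stats::pf(stat_e, df[1], df[2], lower.tail = FALSE)
    method <- "anova"
  } else {
    stat_e <- edge_t(st$x, gi)
    df <- ns - 2
    p_e <- 2 * stats::pt(abs(stat_e), df, lower.tail = FALSE)
    method <- "t"
  }
  if (any(is.na(stat_e[mask_e]))) {
    warning("edges with zero within-group variance marked missing",
            call. = FALSE)
  }
  stat_e[!mask_e] <- NA_real_
  p_e[!mask_e] <- NA_real_
  labs <- rownames(matrices[[1]]) %||% region_labels(st$n)
  unpack <- function(v, fill = NA_real_) {
    m <- matrix(fill, st$n, st$n, dimnames = list(labs, labs))
    m[st$ei] <- v
    m[st$ei[, c(2, 1)]] <- v
    m
  }
  list(
    stat = unpack(stat_e), p = unpack(p_e),
    mask = unpack(as.numeric(mask_e), fill = 0) > 0,
    df = df, method = method, groups = levels(groups)
  )
}

# Largest-component machinery on an edge subset (indices into ei rows).
# Returns edge count of each connected component (edges connected when they
# share a node).
component_edge_sizes <- function(ei_sub, n) {
  if (nrow(ei_sub) == 0) return(integer(0))
  g <- igraph::graph_from_edgelist(ei_sub, directed = FALSE)
  comp <- igraph::components(g)$membership
  as.integer(table(comp[ei_sub[, 1]]))
}

#' Suprathreshold connected components of an edge p-value matrix
#'
#' Keeps edges with `p < primary_p` (strict) and partitions them into
#' connected components, two edges being connected when they share a node.
#' Component size is the edge count.
#'
#' @param p_matrix Symmetric matrix of uncorrected edge p-values (`NA` =
#'   untested edge).
#' @param primary_p Component-forming threshold.
#' @param mask Optional logical matrix restricting which edges are eligible.
#' @return List of components, each a list with `edges` (2-column index
#'   matrix), `nodes`, and `size` (edge count); ordered by decreasing size.
#' @export
suprathreshold_components <- function(p_matrix, primary_p = 0.01,
                                      mask = NULL) {
  stopifnot(is.matrix(p_matrix), nrow(p_matrix) == ncol(p_matrix))
  n <- nrow(p_matrix)
  ei <- edge_index(n)
  pv <- p_matrix[ei]
  ok <- !is.na(pv) & pv < primary_p
  if (!is.null(mask)) ok <- ok & mask[ei]
  sel <- ei[ok, , drop = FALSE]
  if (nrow(sel) == 0) return(list())
  g <- igraph::graph_from_edgelist(sel, directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[sel[, 1]]
  comps <- lapply(split(seq_len(nrow(sel)), comp_of_edge), function(idx) {
    edges <- sel[idx, , drop = FALSE]
    list(edges = edges, nodes = sort(unique(as.vector(edges))),
         size = nrow(edges))
  })
  comps <- unname(comps)
  comps[order(vapply(comps, `[[`, integer(1), "size"), decreasing = TRUE)]
}

#' Network-based statistic permutation test
#'
#' Runs the NBS procedure: edge-wise statistics under the true labelling, a
#' primary component-forming threshold (`p < primary_p`, uncorrected),
#' connected-component extraction, and an empirical null distribution of the
#' maximal component size obtained by randomly permuting the group labels.
#' The corrected p-value of an observed component of size M is
#' `(1 + #permutations with max size >= M) / (n_perm + 1)` (or the strict
#' `> M` count without smoothing under `exceed_rule = "greater"`).
#'
#' Permutations recompute only the edge statistic and compare it against the
#' critical value equivalent to `primary_p`, which is algebraically identical
#' to thresholding permuted p-values.
#'
#' @param matrices List of connectivity matrices (one per subject).
#' @param groups Group label per subject.
#' @param params An [nbs_params()].
#' @param contrast `"omnibus"` or two group labels (see
#'   [edge_statistics()]).
#' @param covariates Optional data frame of numeric covariates to
#'   residualize edge weights on before testing (off by default).
#' @return An object of class `nbs_result`: list with `components` (each
#'   with `edges`, `labels`, `nodes`, `size`, `p_corrected`, `significant`),
#'   `max_observed`, `null_max` (the permutation distribution), `edge_stats`,
#'   and `params`.
#' @export
nbs_test <- function(matrices, groups, params = nbs_params(),
                     contrast = "omnibus", covariates = NULL) {
  groups <- as.factor(groups)
  if (params$n_perm < 100) {
    warning("n_perm < 100: permutation resolution too coarse for alpha 0.05",
            call. = FALSE)
  }
  if (!identical(contrast, "omnibus")) {
    keep <- groups %in% contrast
    matrices <- matrices[keep]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
    groups <- factor(as.character(groups[keep]), levels = contrast)
  }
  groups <- droplevels(groups)
  g <- nlevels(groups)
  if (g < 2) stop("need at least two groups", call. = FALSE)
  st <- stack_edges(matrices)
  x <- st$x
  ns <- nrow(x)
  mask_e <- colMeans(x > 0) >= params$mask_prop
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    x <- stats::lm.fit(mm, x)$residuals +
      matrix(colMeans(x), ns, ncol(x), byrow = TRUE)
  }
  gi <- as.integer(groups)
  use_f <- g > 2
  css <- colSums(x^2)
  if (use_f) {
    crit <- stats::qf(1 - params$primary_p, g - 1, ns - g)
    stat_fun <- function(idx) edge_f(x, idx, g, css)
    exceeds <- function(s) !is.na(s) & s > crit
  } else {
    crit <- stats::qt(1 - params$primary_p / 2, ns - 2)
    stat_fun <- function(idx) edge_t(x, idx, css)
    exceeds <- function(s) !is.na(s) & abs(s) > crit
  }
  obs_stat <- stat_fun(gi)
  obs_sel <- exceeds(obs_stat) & mask_e
  sel_edges <- st$ei[obs_sel, , drop = FALSE]
  obs_sizes <- component_edge_sizes(sel_edges, st$n)
  max_obs <- if (length(obs_sizes)) max(obs_sizes) else 0L

  null_max <- with_seed(params$seed, {
    vapply(seq_len(params$n_perm), function(b) {
      s <- stat_fun(sample(gi))
      sz <- component_edge_sizes(st$ei[exceeds(s) & mask_e, , drop = FALSE],
                                 st$n)
      if (length(sz)) max(sz) else 0L
    }, integer(1))
  })

  corrected_p <- function(m) {
    if (params$exceed_rule == "geq") {
      (1 + sum(null_max >= m)) / (params$n_perm + 1)
    } else {
      sum(null_max > m) / params$n_perm
    }
  }
  labs <- rownames(matrices[[1]]) %||% region_labels(st$n)
  p_obs <- if (use_f) {
    stats::pf(obs_stat, g - 1, ns - g, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(obs_stat), ns - 2, lower.tail = FALSE)
  }
  pmat <- matrix(NA_real_, st$n, st$n, dimnames = list(labs, labs))
  pmat[st$ei[obs_sel, , drop = FALSE]] <- p_obs[obs_sel]
  pmat[st$ei[obs_sel, c(2, 1), drop = FALSE]] <- p_obs[obs_sel]
  comps <- suprathreshold_components(pmat, primary_p = 1)  # edges preselected
  comps <- lapply(comps, function(cc) {
    cc$labels <- cbind(labs[cc$edges[, 1]], labs[cc$edges[, 2]])
    cc$p_corrected <- corrected_p(cc$size)
    cc$significant <- cc$p_corrected < params$alpha
    cc
  })
  structure(
    list(
      components = comps, max_observed = max_obs, null_max = null_max,
      edge_stat = obs_stat, edge_index = st$ei, mask = mask_e,
      groups = levels(groups), params = params
    ),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("Network-based statistic (", paste(x$groups, collapse = " vs "),
      ")\n", sep = "")
  cat(sprintf("  %d permutations, primary p < %g, alpha %g\n",
              x$params$n_perm, x$params$primary_p, x$params$alpha))
  if (length(x$components) == 0) {
    cat("  no suprathreshold component\n")
  } else {
    for (k in seq_along(x$components)) {
      cc <- x$components[[k]]
      cat(sprintf(
        "  component %d: %d edges / %d nodes, corrected p = %.4f%s\n",
        k, cc$size, length(cc$nodes), cc$p_corrected,
        if (cc$significant) " *" else ""
      ))
    }
  }
  invisible(x)
}
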