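# Global and nodal graph-theory measures on FA-weighted connectomes.
#
# Conventions (fixed once, documented in the methods vignette):
#   * edge distance d_ij = 1 / w_ij, the usual mapping for FA-weighted
#     structural networks (stronger tracts = shorter routes);
#   * Lp averages shortest-path distances over *connected* ordered pairs;
#   * Eglob averages 1/d over all ordered pairs, disconnected pairs
#     contributing 0 (Latora-Marchiori);
#   * Cp is the Onnela geometric-mean weighted clustering coefficient with
#     weights normalized by the matrix maximum;
#   * Eloc is the mean over nodes of the global efficiency of the
#     neighbour-induced weighted subgraph.

as_weighted_graph <- function(w) {
  igraph::graph_from_adjacency_matrix(
    w, mode = "undirected", weighted = TRUE, diag = FALSE
  )
}

# All-pairs shortest-path distances under d = 1/w. Inf for disconnected pairs.
shortest_distances <- function(w) {
  g <- as_weighted_graph(w)
  ew <- igraph::E(g)$weight
  igraph::distances(g, weights = if (length(ew)) 1 / ew else numeric(0))
}

# Per-node Onnela clustering coefficient; weights normalized by max(w).
# Nodes with binary degree < 2 have coefficient 0.
clustering_onnela <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(stats::setNames(rep(0, n), rownames(w)))
  cw <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  paths <- diag(cw %*% cw %*% cw)
  ci <- ifelse(k >= 2, paths / (k * (k - 1)), 0)
  stats::setNames(ci, rownames(w))
}

# Mean inverse shortest-path distance over unordered pairs (== ordered pairs
# by symmetry); disconnected pairs contribute 0. 0 for < 2 nodes.
efficiency_mean <- function(w) {
  if (nrow(w) < 2) return(0)
  d <- shortest_distances(w)[upper.tri(w)]
  mean(ifelse(is.finite(d) & d > 0, 1 / d, 0))
}

local_efficiency_by_node <- function(w) {
  n <- nrow(w)
  eloc <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    efficiency_mean(w[nb, nb, drop = FALSE])
  }, numeric(1))
  stats::setNames(eloc, rownames(w))
}

#' Global network metrics of an FA-weighted connectome
#'
#' Computes the clustering coefficient `Cp`, characteristic path length `Lp`,
#' global efficiency `Eglob` and local efficiency `Eloc` of a weighted
#' undirected network, using edge distances `1/w`. `Lp` is the mean
#' shortest-path distance over connected ordered pairs; `Eglob` is the mean of
#' `1/d` over all ordered pairs with disconnected pairs contributing 0; `Cp`
#' is the mean Onnela (geometric-mean) weighted clustering coefficient after
#' normalizing weights by the matrix maximum; `Eloc` is the mean over nodes of
#' the global efficiency of each node's neighbour-induced subgraph.
#'
#' @param w Connectivity matrix (see [as_connectivity_matrix()]).
#' @return A list with elements `Cp`, `Lp`, `Eglob`, `Eloc`. For a network
#'   with no finite path `Lp` is `NA` (with a warning).
#' @export
global_metrics <- function(w) {
  w <- as_connectivity_matrix(w)
  if (nrow(w) < 2) stop("need at least two nodes", call. = FALSE)
  d <- shortest_distances(w)[upper.tri(w)]
  finite <- is.finite(d)
  eglob <- mean(ifelse(finite, 1 / d, 0))
  if (any(finite)) {
    lp <- mean(d[finite])
  } else {
    warning("network has no connected pair; Lp undefined", call. = FALSE)
    lp <- NA_real_
  }
  list(
    Cp = mean(clustering_onnela(w)),
    Lp = lp,
    Eglob = eglob,
    Eloc = mean(local_efficiency_by_node(w))
  )
}

#' Nodal efficiency and betweenness centrality
#'
#' Nodal efficiency of node i is the mean of `1/d_ij` over all other nodes j
#' (0 for unreachable nodes). Betweenness centrality is the fraction-weighted
#' count of shortest paths (under distances `1/w`) passing through the node,
#' counting each unordered pair of endpoints once.
#'
#' @param w Connectivity matrix.
#' @return A data frame with columns `region`, `efficiency`, `betweenness`.
#' @export
nodal_metrics <- function(w) {
  w <- as_connectivity_matrix(w)
  n <- nrow(w)
  if (n < 2) stop("need at least two nodes", call. = FALSE)
  d <- shortest_distances(w)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(inv) <- 0
  eff <- rowSums(inv) / (n - 1)
  g <- as_weighted_graph(w)
  ew <- igraph::E(g)$weight
  bc <- igraph::betweenness(
    g, directed = FALSE,
    weights = if (length(ew)) 1 / ew else numeric(0)
  )
  data.frame(
    region = rownames(w),
    efficiency = unname(eff),
    betweenness = unname(bc),
    stringsAsFactors = FALSE
  )
}

#' Threshold a connectivity matrix at a target sparsity
#'
#' Retains the `K = round(s * N(N-1)/2)` strongest edges (half-up rounding)
#' and zeroes the rest, keeping the surviving weights so the network stays
#' weighted. If the matrix has fewer than `K` nonzero edges they are all
#' kept. Ties at the cut are broken by ascending `(i, j)` lexicographic edge
#' order, so the output is deterministic.
#'
#' @param w Connectivity matrix.
#' @param s Sparsity fraction in `(0, 1]`: the target proportion of retained
#'   edges among all `N(N-1)/2` possible edges.
#' @return Thresholded connectivity matrix.
#' @export
threshold_by_sparsity <- function(w, s) {
  w <- as_connectivity_matrix(w)
  if (!is_scalar(s) || s <= 0) {
    stop("sparsity must be a positive fraction", call. = FALSE)
  }
  if (s > 1) stop("sparsity cannot exceed 1", call. = FALSE)
  n <- nrow(w)
  k_target <- round_half_up(s * n * (n - 1) / 2)
  ei <- edge_index(n)
  wt <- w[ei]
  nz <- which(wt > 0)
  ord <- nz[order(-wt[nz], nz)]
  keep <- ord[seq_len(min(k_target, length(ord)))]
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[ei[keep, , drop = FALSE]] <- wt[keep]
  out[ei[keep, c(2, 1), drop = FALSE]] <- wt[keep]
  out
}

#' Random-network normalization (small-world indices)
#'
#' Builds `n_random` surrogate networks by degree-preserving double-edge
#' swaps of the binarized topology (`swaps_per_edge * E` attempted swaps)
#' followed by a random permutation of the original weight multiset onto the
#' rewired edges, then returns the normalized clustering coefficient
#' `gamma = Cp / mean(Cp_rand)`, normalized path length
#' `lambda = Lp / mean(Lp_rand)`, and small-worldness `sigma = gamma /
#' lambda`. `sigma > 1` indicates small-world organization.
#'
#' For topologies that double-edge swaps cannot alter (e.g. a star or a
#' complete graph) the surrogates equal the original topology up to weight
#' permutation; a message is emitted.
#'
#' @param w Connectivity matrix with at least one edge.
#' @param n_random Number of surrogate networks (the reference analysis uses
#'   1000; 100 is adequate for screening).
#' @param swaps_per_edge Attempted swaps per edge during rewiring.
#' @param seed Optional RNG seed; the result is deterministic given the seed
#'   and the caller's RNG state is untouched.
#' @return A list with `gamma`, `lambda`, `sigma`, and the surrogate means
#'   `Cp_rand`, `Lp_rand`.
#' @export
random_reference <- function(w, n_random = 1000, swaps_per_edge = 10,
                             seed = NULL) {
  w <- as_connectivity_matrix(w)
  if (!is_count(n_random)) stop("n_random must be a positive count", call. = FALSE)
  ei <- edge_index(nrow(w))
  wt <- w[ei]
  nz <- wt > 0
  ne <- sum(nz)
  if (ne < 1) stop("matrix has no edges", call. = FALSE)
  wts <- wt[nz]
  g0 <- igraph::graph_from_adjacency_matrix(
    (w > 0) * 1, mode = "undirected", diag = FALSE
  )
  d <- shortest_distances(w)[upper.tri(w)]
  finite <- is.finite(d)
  cp_obs <- mean(clustering_onnela(w))
  lp_obs <- if (any(finite)) mean(d[finite]) else NA_real_
  n <- nrow(w)
  ut <- upper.tri(w)
  res <- with_seed(seed, {
    cps <- numeric(n_random)
    lps <- numeric(n_random)
    changed <- FALSE
    for (b in seq_len(n_random)) {
      gr <- igraph::rewire(
        g0, igraph::keeping_degseq(niter = swaps_per_edge * ne)
      )
      el <- igraph::as_edgelist(gr, names = FALSE)
      pw <- wts[sample.int(ne)]
      # distances computed on the rewired graph itself; pw aligns with the
      # graph's edge order, of which as_edgelist is a view
      dd <- igraph::distances(gr, weights = 1 / pw)[ut]
      ww <- matrix(0, n, n)
      ww[el] <- pw
      ww[el[, c(2, 1), drop = FALSE]] <- pw
      if (!changed && !identical_topology(el, ei[nz, , drop = FALSE], n)) {
        changed <- TRUE
      }
      ff <- is.finite(dd)
      cps[b] <- mean(clustering_onnela(ww))
      lps[b] <- if (any(ff)) mean(dd[ff]) else NA_real_
    }
    list(cps = cps, lps = lps, changed = changed)
  })
  if (!res$changed) {
    message("degree-preserving rewiring left the topology unchanged; ",
            "surrogates equal the original topology")
  }
  cp_rand <- mean(res$cps)
  lp_rand <- mean(res$lps, na.rm = TRUE)
  gamma <- cp_obs / cp_rand
  lambda <- lp_obs / lp_rand
  list(
    gamma = gamma, lambda = lambda, sigma = gamma / lambda,
    Cp_rand = cp_rand, Lp_rand = lp_rand
  )
}

# TRUE when the surrogate edge list equals the original edge set.
identical_topology <- function(el, ei, n) {
  a <- pmin(el[, 1], el[, 2]) * (n + 1) + pmax(el[, 1], el[, 2])
  b <- ei[, 1] * (n + 1) + ei[, 2]
  length(a) == length(b) && setequal(a, b)
}

#' Sparsity grid
#'
#' The sequence of sparsity thresholds over which metric curves are computed.
#' The default 0.10-0.15 in steps of 0.01 is the range over which weighted
#' structural connectomes show stable small-world organization; the wider
#' screening range 0.10-0.30 is available by changing `s_max`.
#'
#' @param s_min,s_max Range of sparsity fractions.
#' @param step Grid step.
#' @return Numeric vector of sparsity values.
#' @export
sparsity_grid <- function(s_min = 0.10, s_max = 0.15, step = 0.01) {
  if (!(is_scalar(s_min) && is_scalar(s_max) && is_scalar(step))) {
    stop("grid parameters must be numeric scalars", call. = FALSE)
  }
  if (s_min <= 0 || s_max >= 1 || s_min > s_max || step <= 0) {
    stop("require 0 < s_min <= s_max < 1 and step > 0", call. = FALSE)
  }
  seq(s_min, s_max, by = step)
}

#' Metric curves across sparsity thresholds
#'
#' Applies [threshold_by_sparsity()] at every grid point and evaluates the
#' global metrics, small-world indices and (optionally) nodal metrics on each
#' thresholded network.
#'
#' @param w Connectivity matrix.
#' @param grid Sparsity grid from [sparsity_grid()].
#' @param n_random Surrogates per grid point for the small-world indices;
#'   `0` skips random-network normalization (gamma/lambda/sigma are `NA`).
#' @param swaps_per_edge Attempted swaps per edge during rewiring.
#' @param seed Optional seed; each grid point uses a derived substream.
#' @param nodal Whether to also compute nodal metrics per grid point.
#' @return An object of class `metric_curves`: a list with `global` (data
#'   frame of Cp/Lp/Eglob/Eloc/gamma/lambda/sigma by sparsity),
#'   `nodal_efficiency` and `betweenness` (region x sparsity matrices, or
#'   `NULL`), and `labels`.
#' @export
metric_curves <- function(w, grid = sparsity_grid(), n_random = 100,
                          swaps_per_edge = 10, seed = NULL, nodal = TRUE) {
  w <- as_connectivity_matrix(w)
  ns <- length(grid)
  glob <- data.frame(
    sparsity = grid, Cp = NA_real_, Lp = NA_real_, Eglob = NA_real_,
    Eloc = NA_real_, gamma = NA_real_, lambda = NA_real_, sigma = NA_real_
  )
  n <- nrow(w)
  ne <- if (nodal) matrix(NA_real_, n, ns, dimnames = list(rownames(w), NULL))
  bc <- if (nodal) matrix(NA_real_, n, ns, dimnames = list(rownames(w), NULL))
  for (k in seq_len(ns)) {
    wk <- threshold_by_sparsity(w, grid[k])
    gm <- global_metrics(wk)
    glob$Cp[k] <- gm$Cp
    glob$Lp[k] <- gm$Lp
    glob$Eglob[k] <- gm$Eglob
    glob$Eloc[k] <- gm$Eloc
    if (n_random > 0) {
      rr <- random_reference(
        w = wk, n_random = n_random, swaps_per_edge = swaps_per_edge,
        seed = if (is.null(seed)) NULL else substream_seed(seed, k)
      )
      glob$gamma[k] <- rr$gamma
      glob$lambda[k] <- rr$lambda
      glob$sigma[k] <- rr$sigma
    }
    if (nodal) {
      nm <- nodal_metrics(wk)
      ne[, k] <- nm$efficiency
      bc[, k] <- nm$betweenness
    }
  }
  structure(
    list(global = glob, nodal_efficiency = ne, betweenness = bc,
         labels = rownames(w)),
    class = "metric_curves"
  )
}

#' Trapezoidal area under a metric-by-sparsity curve
#'
#' Summarizes a threshold-dependent metric curve in one number by trapezoidal
#' integration over the sparsity axis. A constant curve `c` over a range of
#' width `h` has AUC `c * h`.
#'
#' @param x Sparsity values (ascending, at least two).
#' @param y Metric values at `x`.
#' @return The AUC; `NA` (with a warning) if any value is missing.
#' @export
auc_trapezoid <- function(x, y) {
  if (length(x) < 2) stop("need at least two grid points", call. = FALSE)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (anyNA(y)) {
    warning("missing metric values; AUC undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' AUC summary of metric curves
#'
#' @param curves A `metric_curves` object.
#' @return A list with `global` (named vector of AUCs for Cp, Lp, Eglob,
#'   Eloc, gamma, lambda, sigma) and, when nodal curves are present,
#'   `nodal_efficiency` and `betweenness` (named per-region AUC vectors).
#' @export
auc_summary <- function(curves) {
  stopifnot(inherits(curves, "metric_curves"))
  s <- curves$global$sparsity
  metrics <- c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda", "sigma")
  glob <- vapply(metrics, function(m) {
    y <- curves$global[[m]]
    if (anyNA(y)) NA_real_ else auc_trapezoid(s, y)
  }, numeric(1))
  out <- list(global = glob)
  if (!is.null(curves$nodal_efficiency)) {
    out$nodal_efficiency <- apply(curves$nodal_efficiency, 1, auc_trapezoid, x = s)
    out$betweenness <- apply(curves$betweenness, 1, auc_trapezoid, x = s)
  }
  out
}

#' Identify hub nodes from betweenness centrality
#'
#' A node is a hub when its betweenness centrality is greater than or equal
#' to the network mean plus one standard deviation (sample SD, n-1
#' denominator). When all values are equal the SD is 0 and every node meets
#' the threshold — a degenerate but well-defined outcome.
#'
#' @param bc Named numeric vector of per-node betweenness values (names are
#'   region labels; unnamed input gets default labels).
#' @return A list with `hubs` (labels), `threshold`, and `betweenness`.
#' @export
identify_hubs <- function(bc) {
  if (length(bc) < 2) stop("need at least two nodes to define hubs", call. = FALSE)
  if (is.null(names(bc))) names(bc) <- region_labels(length(bc))
  thr <- mean(bc) + stats::sd(bc)
  list(hubs = names(bc)[bc >= thr], threshold = thr, betweenness = bc)
}

#' Group-mean connectivity matrix
#'
#' Element-wise mean of a list of same-sized connectivity matrices; the
#' conventional substrate for group-level hub identification.
#'
#' @param matrices List of connectivity matrices.
#' @return A connectivity matrix.
#' @export
group_mean_matrix <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  acc <- Reduce(`+`, matrices) / length(matrices)
  as_connectivity_matrix(acc)
}
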