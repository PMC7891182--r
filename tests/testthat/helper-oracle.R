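# Independent brute-force oracles used to validate the graph-metric and
# component machinery. Deliberately naive: Floyd-Warshall shortest paths,
# explicit shortest-path enumeration for betweenness, and a hand union-find
# for components. No igraph anywhere in here.

oracle_floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_metrics <- function(w) {
  n <- nrow(w)
  d <- oracle_floyd_warshall(w)
  invsum <- 0
  dsum <- 0
  nconn <- 0
  npairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      npairs <- npairs + 1
      if (is.finite(d[i, j])) {
        invsum <- invsum + 1 / d[i, j]
        dsum <- dsum + d[i, j]
        nconn <- nconn + 1
      }
    }
  }
  eglob <- invsum / npairs
  lp <- if (nconn > 0) dsum / nconn else NA_real_
  # Onnela clustering, max-normalized
  mx <- max(w)
  cp_i <- numeric(n)
  if (mx > 0) {
    for (i in seq_len(n)) {
      nb <- which(w[i, ] > 0)
      k <- length(nb)
      if (k < 2) next
      acc <- 0
      for (a in nb) {
        for (b in nb) {
          if (a != b) {
            acc <- acc + ((w[i, a] / mx) * (w[i, b] / mx) *
                            (w[a, b] / mx))^(1 / 3)
          }
        }
      }
      cp_i[i] <- acc / (k * (k - 1))
    }
  }
  # local efficiency: global efficiency of each neighbour-induced subgraph
  eloc_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    sub <- w[nb, nb, drop = FALSE]
    ds <- oracle_floyd_warshall(sub)
    m <- length(nb)
    acc <- 0
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        if (is.finite(ds[a, b])) acc <- acc + 1 / ds[a, b]
      }
    }
    eloc_i[i] <- acc / (m * (m - 1) / 2)
  }
  list(Cp = mean(cp_i), Lp = lp, Eglob = eglob, Eloc = mean(eloc_i),
       d = d)
}

oracle_nodal_efficiency <- function(w) {
  n <- nrow(w)
  d <- oracle_floyd_warshall(w)
  vapply(seq_len(n), function(i) {
    vals <- d[i, -i]
    mean(ifelse(is.finite(vals), 1 / vals, 0))
  }, numeric(1))
}

# Betweenness by shortest-path counting: sigma[s, t] = number of shortest
# s-t paths, computed by dynamic programming over nodes ordered by distance
# from s; BC(v) = sum over unordered pairs (s, t), s != v != t, of
# sigma_sv * sigma_vt / sigma_st when d_sv + d_vt == d_st.
oracle_betweenness <- function(w, tol = 1e-10) {
  n <- nrow(w)
  d <- oracle_floyd_warshall(w)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    sigma[s, s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      acc <- 0
      for (u in seq_len(n)) {
        if (u != v && w[u, v] > 0 &&
            abs(d[s, u] + 1 / w[u, v] - d[s, v]) < tol) {
          acc <- acc + sigma[s, u]
        }
      }
      sigma[s, v] <- acc
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (abs(d[s, v] + d[v, t] - d[s, t]) < tol && sigma[s, t] > 0) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bc
}

# Union-find with path compression; returns edge count of each component.
oracle_component_sizes <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges) == 0) return(integer(0))
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1])
    b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(edges[, 1], find, integer(1))
  as.integer(table(roots))
}

# Random weighted graph for oracle-equivalence checks.
random_weighted_graph <- function(n, density = 0.4) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < density) {
        w[i, j] <- w[j, i] <- stats::runif(1, 0.1, 1)
      }
    }
  }
  w
}
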