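# Independent brute-force oracles for the graph-metric engine. These stay
# deliberately naive (triple-loop Floyd-Warshall, exhaustive triangle
# enumeration) and never call the package's own distance/metric code.

# All-pairs shortest paths by Floyd-Warshall over an edge-length matrix
# (0 = no edge). Returns Inf for unreachable pairs.
oracle_floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- matrix(Inf, n, n)
  d[len > 0] <- len[len > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_lengths <- function(w, binary) {
  if (binary) (w > 0) * 1 else ifelse(w > 0, 1 / w, 0)
}

# Global efficiency, Lp, nodal efficiency and degree from first principles.
oracle_metrics <- function(w, binary) {
  n <- nrow(w)
  d <- oracle_floyd_warshall(oracle_lengths(w, binary))
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  enodal <- rowSums(inv) / (n - 1)
  reach <- is.finite(d) & d > 0
  list(
    d = d,
    Eg = sum(inv) / (n * (n - 1)),
    Lp = if (any(reach)) mean(d[reach]) else NA_real_,
    Enodal = enodal,
    degree = rowSums(w > 0)
  )
}

# Binary clustering: exhaustive triangle count per node.
oracle_clustering_binary <- function(w) {
  a <- w > 0
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ])
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (x in seq_len(k - 1)) {
      for (y in seq((x + 1), k)) {
        if (a[nb[x], nb[y]]) t_i <- t_i + 1
      }
    }
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  ci
}

# Onnela weighted clustering: geometric mean of max-normalised triangle
# weights, exhaustive triple enumeration.
oracle_clustering_onnela <- function(w) {
  n <- nrow(w)
  wn <- w / max(w)
  a <- w > 0
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ])
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (x in seq_len(k - 1)) {
      for (y in seq((x + 1), k)) {
        j <- nb[x]; h <- nb[y]
        if (a[j, h]) s <- s + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
      }
    }
    ci[i] <- 2 * s / (k * (k - 1))
  }
  ci
}

# Random symmetric zero-diagonal test graph; weighted draws lie in (0.2, 1].
random_test_graph <- function(n, p_edge = 0.4, binary = TRUE) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  edge <- runif(sum(ut)) < p_edge
  vals <- if (binary) as.numeric(edge) else edge * runif(sum(ut), 0.201, 1)
  w[ut] <- vals
  w + t(w)
}

# Embed a small adjacency matrix into a padded 90x90 connectivity matrix is
# not needed: the metric engine accepts any square matrix. This helper just
# tags a plain matrix with a kind attribute.
as_conn <- function(w, kind) {
  structure(w, class = "connectivity_matrix", kind = kind,
            subject_id = "test")
}

# Small default cohort settings used to keep generator tests fast.
small_params <- function(...) {
  cohort_params(n_patients = 6L, n_controls = 6L,
                male_count = c(patient = 3L, control = 3L), ...)
}
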