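# Graph-theoretic property engine. Conventions:
#  * weighted shortest paths run over edge lengths 1/w ("reciprocal", the
#    usual choice for FA-weighted networks) or 1 - w ("one_minus");
#  * efficiency-type metrics give unreachable pairs zero contribution
#    (harmonic convention); Lp averages reachable pairs only and reports the
#    unreachable count;
#  * weighted clustering is the Onnela geometric-mean generalisation with
#    weights normalised by the maximum weight; binary matrices use the
#    2 t_i / (k_i (k_i - 1)) triangle formula.

edge_lengths <- function(mat, weight_conversion) {
  w <- unclass(mat)
  len <- matrix(0, nrow(w), ncol(w))
  nz <- w > 0
  len[nz] <- switch(weight_conversion,
                    reciprocal = 1 / w[nz],
                    one_minus = 1 - w[nz])
  len
}

#' All-pairs shortest path lengths
#'
#' Binary matrices give hop counts; weighted matrices give shortest paths
#' over converted edge lengths (`1/w` by default). Unreachable pairs carry
#' the sentinel `Inf` and are counted; every consumer in this package
#' handles them explicitly (zero contribution to efficiencies, exclusion
#' from path-length averages).
#'
#' @param matrix a `connectivity_matrix` (or plain nonnegative symmetric
#'   matrix; the kind attribute selects binary vs weighted mode).
#' @param weight_conversion `"reciprocal"` (length = 1/weight) or
#'   `"one_minus"` (length = 1 - weight).
#' @return A matrix of class `distance_matrix` with attributes `mode`
#'   (`"binary"`/`"weighted"`) and `n_unreachable_pairs` (ordered pairs).
#' @export
#' @examples
#' chain <- matrix(0, 90, 90); chain[1, 2] <- chain[2, 1] <- 1
#' chain[2, 3] <- chain[3, 2] <- 1
#' d <- distance_matrix(connectivity_matrix(chain, "FA_bin"))
#' d[1, 3]  # two hops
distance_matrix <- function(matrix,
                            weight_conversion = c("reciprocal", "one_minus")) {
  weight_conversion <- match.arg(weight_conversion)
  w <- unclass(matrix)
  if (any(w < 0)) stop("negative weights are not allowed", call. = FALSE)
  kind <- attr(matrix, "kind")
  binary <- identical(kind, "FA_bin") || all(w %in% c(0, 1))
  mode <- if (binary) "binary" else "weighted"
  len <- if (binary) (w > 0) * 1 else edge_lengths(matrix, weight_conversion)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE)
  d <- if (binary) {
    igraph::distances(g, weights = NA, algorithm = "unweighted")
  } else {
    igraph::distances(g, algorithm = "dijkstra")
  }
  dimnames(d) <- NULL
  diag(d) <- 0
  structure(d, class = "distance_matrix", mode = mode,
            weight_conversion = weight_conversion,
            n_unreachable_pairs = sum(is.infinite(d)))
}

# mean inverse distance over ordered pairs (Inf -> 0), the efficiency of a
# distance matrix
efficiency_from_distances <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

clustering_per_node <- function(mat, binary) {
  w <- unclass(mat)
  a <- (w > 0) * 1
  k <- rowSums(a)
  if (binary) {
    t_i <- diag(a %*% a %*% a) / 2
  } else {
    wn <- (w / max(w))^(1 / 3)
    t_i <- diag(wn %*% wn %*% wn) / 2
  }
  ci <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  list(ci = ci, k = k)
}

local_efficiency_per_node <- function(mat, binary, weight_conversion) {
  w <- unclass(mat)
  a <- w > 0
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ])
    if (length(nb) < 2L) return(0)
    sub <- w[nb, nb, drop = FALSE]
    len <- if (binary) (sub > 0) * 1 else {
      l <- matrix(0, nrow(sub), ncol(sub))
      nz <- sub > 0
      l[nz] <- switch(weight_conversion, reciprocal = 1 / sub[nz],
                      one_minus = 1 - sub[nz])
      l
    }
    g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                             weighted = TRUE)
    d <- if (binary) {
      igraph::distances(g, weights = NA, algorithm = "unweighted")
    } else {
      igraph::distances(g, algorithm = "dijkstra")
    }
    efficiency_from_distances(d)
  }, numeric(1))
}

#' Global topological properties
#'
#' Computes global efficiency (mean inverse shortest-path length over all
#' ordered node pairs), clustering coefficient (mean over nodes of
#' `2 t_i / (k_i (k_i - 1))`, Onnela-generalised for weighted matrices),
#' local efficiency (mean efficiency of each node's neighbour-induced
#' subgraph) and characteristic path length (mean shortest-path length over
#' reachable ordered pairs). An edgeless matrix yields zero efficiencies and
#' `Lp = NA` rather than an error.
#'
#' @param matrix a `connectivity_matrix`.
#' @param distances the matching [distance_matrix()]; computed when omitted.
#' @param weight_conversion see [distance_matrix()].
#' @return A list of class `global_metrics`: `Eg`, `Cp`, `Eloc`, `Lp`,
#'   `n_unreachable_pairs`.
#' @export
global_metrics <- function(matrix, distances = NULL,
                           weight_conversion = c("reciprocal", "one_minus")) {
  weight_conversion <- match.arg(weight_conversion)
  if (is.null(distances)) {
    distances <- distance_matrix(matrix, weight_conversion)
  }
  binary <- attr(distances, "mode") == "binary"
  d <- unclass(distances)
  n <- nrow(d)
  off <- !diag(TRUE, n)
  reach <- off & is.finite(d)
  eg <- efficiency_from_distances(d)
  cl <- clustering_per_node(matrix, binary)
  eloc <- mean(local_efficiency_per_node(matrix, binary, weight_conversion))
  lp <- if (any(reach)) mean(d[reach]) else NA_real_
  structure(
    list(Eg = eg, Cp = mean(cl$ci), Eloc = eloc, Lp = lp,
         n_unreachable_pairs = sum(off & is.infinite(d))),
    class = "global_metrics"
  )
}

#' Nodal topological properties
#'
#' Nodal efficiency of region i is the mean inverse shortest-path length
#' from i to every other node (unreachable nodes contribute zero); its mean
#' over nodes equals the global efficiency by construction. Degree is the
#' number of edges incident to the node.
#'
#' @inheritParams global_metrics
#' @return A data.frame with columns `region`, `Enodal`, `degree`.
#' @export
nodal_metrics <- function(matrix, distances = NULL,
                          weight_conversion = c("reciprocal", "one_minus")) {
  weight_conversion <- match.arg(weight_conversion)
  if (is.null(distances)) {
    distances <- distance_matrix(matrix, weight_conversion)
  }
  d <- unclass(distances)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  data.frame(
    region = seq_len(n),
    Enodal = rowSums(inv) / (n - 1),
    degree = as.integer(rowSums(unclass(matrix) > 0))
  )
}

#' Small-world coefficients against a null ensemble
#'
#' `gamma = Cp / C_rand`, `lambda = Lp / L_rand`, `sigma = gamma / lambda`;
#' a network is small-world when `sigma > 1` (high clustering at near-random
#' path length).
#'
#' @param metrics a [global_metrics()] result.
#' @param ensemble a [null_ensemble()] result for the same network.
#' @return A list of class `small_world`: `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(metrics, ensemble) {
  stopifnot(inherits(metrics, "global_metrics"),
            inherits(ensemble, "null_ensemble"))
  if (!is.finite(ensemble$C_rand) || ensemble$C_rand <= 0) {
    stop("C_rand must be positive to form gamma", call. = FALSE)
  }
  if (!is.finite(ensemble$L_rand) || ensemble$L_rand <= 0) {
    stop("L_rand must be positive to form lambda", call. = FALSE)
  }
  gamma <- metrics$Cp / ensemble$C_rand
  lambda <- metrics$Lp / ensemble$L_rand
  structure(list(gamma = gamma, lambda = lambda, sigma = gamma / lambda),
            class = "small_world")
}

#' Hub detection from group nodal metrics
#'
#' Computes the group-mean degree of every region and flags a region as a
#' hub when its group-mean degree exceeds the grand mean over regions plus
#' `sd_multiplier` times the SD over regions. All audit quantities are
#' stored as attributes so the flags are reproducible from the table.
#'
#' @param nodal long data.frame with columns `subject_id`, `region`,
#'   `degree` (one row per subject x region) for one group.
#' @param sd_multiplier hub criterion multiplier on the across-region SD.
#' @param atlas optional atlas for region labels.
#' @return A data.frame of class `hub_table`: `region`, `abbreviation`,
#'   `mean_degree`, `hub`; attributes `grand_mean`, `sd`, `threshold`,
#'   `sd_multiplier`, `n_subjects`.
#' @export
hub_detection <- function(nodal, sd_multiplier = 1.0, atlas = aal_atlas()) {
  req <- c("subject_id", "region", "degree")
  if (!all(req %in% names(nodal))) {
    stop("`nodal` needs columns subject_id, region, degree", call. = FALSE)
  }
  n_subj <- length(unique(nodal$subject_id))
  if (n_subj < 2L) stop("hub detection needs at least 2 subjects",
                        call. = FALSE)
  mean_deg <- tapply(nodal$degree, nodal$region, mean)
  regions <- as.integer(names(mean_deg))
  grand <- mean(mean_deg)
  spread <- sd(mean_deg)
  threshold <- grand + sd_multiplier * spread
  out <- data.frame(
    region = regions,
    abbreviation = atlas$abbreviation[match(regions, atlas$index)],
    mean_degree = as.numeric(mean_deg),
    hub = as.numeric(mean_deg) > threshold
  )
  structure(out, class = c("hub_table", "data.frame"), grand_mean = grand,
            sd = spread, threshold = threshold,
            sd_multiplier = sd_multiplier, n_subjects = n_subj)
}
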