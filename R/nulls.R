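#' Degree-preserving random null ensemble
#'
#' Generates `n_null` rewired versions of a network by Maslov-Sneppen
#' double-edge swaps. Each swap replaces edges (x1, y1), (x2, y2) with
#' (x1, y2), (x2, y1) when neither new edge exists, so the degree sequence
#' is preserved exactly; weights travel with their edges, preserving the
#' weight multiset. Each null targets `swaps_per_edge * edge count` accepted
#' swaps. The ensemble summarises the mean clustering coefficient `C_rand`
#' and mean characteristic path length `L_rand` under the same conventions
#' as [global_metrics()].
#'
#' @param matrix a `connectivity_matrix`.
#' @param n_null number of null networks (>= 1).
#' @param swaps_per_edge accepted swaps per edge per null.
#' @param seed integer seed.
#' @param weight_conversion see [distance_matrix()].
#' @param on_degenerate what to do when no swap is possible (e.g. a complete
#'   graph): `"error"` (default) or `"identity"` (use unrewired copies).
#' @return A list of class `null_ensemble`: `n_null`, `seed`, `Cp` and `Lp`
#'   per null, `C_rand`, `L_rand`.
#' @export
#' @examples
#' ring <- matrix(0, 90, 90)
#' for (i in 1:90) ring[i, i %% 90 + 1] <- ring[i %% 90 + 1, i] <- 1
#' ens <- null_ensemble(connectivity_matrix(ring, "FA_bin"),
#'                      n_null = 5, seed = 1)
#' ens$L_rand
null_ensemble <- function(matrix, n_null = 100L, swaps_per_edge = 10L,
                          seed = 1L,
                          weight_conversion = c("reciprocal", "one_minus"),
                          on_degenerate = c("error", "identity")) {
  weight_conversion <- match.arg(weight_conversion)
  on_degenerate <- match.arg(on_degenerate)
  if (n_null < 1L) stop("n_null must be >= 1", call. = FALSE)
  w <- unclass(matrix)
  kind <- attr(matrix, "kind")
  if (is.null(kind)) kind <- if (all(w %in% c(0, 1))) "FA_bin" else "FA_wei"
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2L) {
    stop("graph has fewer than 2 edges; no degree-preserving swaps exist",
         call. = FALSE)
  }
  weights <- w[ut]
  n <- nrow(w)
  target <- as.integer(swaps_per_edge * m)
  max_tries <- max(100L * target, 10000L)
  deg_in <- rowSums(w > 0)
  cps <- numeric(n_null)
  lps <- numeric(n_null)
  with_seed(seed, {
    for (k in seq_len(n_null)) {
      rw <- ms_rewire(ut[, 1], ut[, 2], n, target, max_tries)
      if (rw$accepted == 0L) {
        if (on_degenerate == "error") {
          stop("network could not be rewired (no eligible swap pair found, ",
               "e.g. complete or near-complete graph)", call. = FALSE)
        }
        rw <- list(i = ut[, 1], j = ut[, 2])
      }
      nm <- base::matrix(0, n, n)
      nm[cbind(rw$i, rw$j)] <- weights
      nm[cbind(rw$j, rw$i)] <- weights
      stopifnot(all(rowSums(nm > 0) == deg_in))
      null_mat <- structure(nm, class = "connectivity_matrix", kind = kind,
                            subject_id = "null")
      d <- distance_matrix(null_mat, weight_conversion)
      gm_cl <- clustering_per_node(null_mat, attr(d, "mode") == "binary")
      off <- !diag(TRUE, n)
      reach <- off & is.finite(unclass(d))
      cps[k] <- mean(gm_cl$ci)
      lps[k] <- if (any(reach)) mean(unclass(d)[reach]) else NA_real_
    }
  })
  structure(list(n_null = as.integer(n_null), seed = as.integer(seed),
                 Cp = cps, Lp = lps,
                 C_rand = mean(cps), L_rand = mean(lps, na.rm = TRUE)),
            class = "null_ensemble")
}

#' Per-subject small-world summary
#'
#' Convenience wrapper chaining [distance_matrix()], [global_metrics()],
#' [null_ensemble()] and [small_world()].
#'
#' @inheritParams null_ensemble
#' @return A `small_world` list (`gamma`, `lambda`, `sigma`).
#' @export
subject_small_world <- function(matrix, n_null = 100L, swaps_per_edge = 10L,
                                seed = 1L,
                                weight_conversion = c("reciprocal",
                                                      "one_minus")) {
  weight_conversion <- match.arg(weight_conversion)
  d <- distance_matrix(matrix, weight_conversion)
  gm <- global_metrics(matrix, d, weight_conversion)
  ens <- null_ensemble(matrix, n_null, swaps_per_edge, seed,
                       weight_conversion)
  small_world(gm, ens)
}
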