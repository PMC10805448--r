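#' Connectivity matrix constructor
#'
#' Validated container for a per-subject 90x90 structural network. `FA_wei`
#' matrices carry mean-FA edge weights in (0.2, 1]; `FA_bin` matrices carry
#' 0/1 entries. Both are symmetric with zero diagonal.
#'
#' @param values 90x90 numeric matrix.
#' @param kind `"FA_wei"` or `"FA_bin"`.
#' @param subject_id subject identifier string.
#' @return A matrix of class `connectivity_matrix` with attributes `kind`
#'   and `subject_id`.
#' @export
connectivity_matrix <- function(values, kind = c("FA_wei", "FA_bin"),
                                subject_id = "unknown") {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values) ||
      nrow(values) != 90L || ncol(values) != 90L) {
    stop("`values` must be a 90x90 numeric matrix", call. = FALSE)
  }
  report <- matrix_violations(values, kind)
  if (length(report)) {
    stop("invalid connectivity matrix: ", paste(report, collapse = "; "),
         call. = FALSE)
  }
  structure(values, class = "connectivity_matrix", kind = kind,
            subject_id = subject_id)
}

matrix_violations <- function(values, kind, tol = 1e-9) {
  report <- character(0)
  if (max(abs(values - t(values))) > tol) {
    report <- c(report, "matrix is asymmetric beyond tolerance")
  }
  if (any(diag(values) != 0)) {
    report <- c(report, "diagonal has nonzero entries")
  }
  nz <- values[values != 0]
  if (kind == "FA_bin") {
    if (!all(nz == 1)) report <- c(report, "binary entries must be 0 or 1")
  } else {
    if (length(nz) && (any(nz <= 0.2) || any(nz > 1))) {
      report <- c(report, "weighted entries must lie in (0.2, 1]")
    }
  }
  report
}

#' Validate a connectivity matrix without mutating it
#'
#' Checks the container invariants (symmetry to 1e-9, zero diagonal,
#' in-range weights for the matrix kind) and returns the list of violations;
#' an empty character vector means the matrix is valid.
#'
#' @param matrix a `connectivity_matrix`, or a plain 90x90 matrix plus
#'   `kind`.
#' @param kind matrix kind, inferred from the object when present.
#' @return Character vector of violation descriptions (possibly empty).
#' @export
validate_matrix <- function(matrix, kind = NULL) {
  if (is.null(kind)) kind <- attr(matrix, "kind")
  if (is.null(kind)) kind <- "FA_wei"
  if (!is.matrix(matrix) || !is.numeric(matrix) ||
      nrow(matrix) != 90L || ncol(matrix) != 90L) {
    stop("expected a 90x90 numeric matrix", call. = FALSE)
  }
  matrix_violations(unclass(matrix), kind)
}

#' Build FA-weighted and binary networks from streamline summaries
#'
#' Applies the edge rule of the emulated pipeline: a region pair (i, j) is
#' connected iff its streamline count reaches `min_count` and its mean FA is
#' strictly greater than `fa_threshold` (default 0.2). The weighted network
#' carries the mean FA as edge weight; the binary network carries 1. The two
#' matrices share their nonzero pattern by construction.
#'
#' @param streamlines data.frame with columns `region_i`, `region_j`,
#'   `streamline_count`, `mean_fa` (1-based atlas indices, i < j; duplicates
#'   are an error).
#' @param atlas atlas table (used for index validation).
#' @param fa_threshold FA edge threshold, strict inequality (default 0.2).
#' @param min_count minimum streamline count for an edge (default 1).
#' @param subject_id subject identifier attached to both matrices.
#' @return A list with `FA_wei` and `FA_bin` `connectivity_matrix` objects.
#' @export
#' @examples
#' sl <- data.frame(region_i = 1L, region_j = 2L,
#'                  streamline_count = 10L, mean_fa = 0.25)
#' nets <- build_networks(sl)
#' nets$FA_wei[1, 2]
build_networks <- function(streamlines, atlas = aal_atlas(),
                           fa_threshold = 0.2, min_count = 1L,
                           subject_id = "unknown") {
  validate_atlas(atlas)
  req <- c("region_i", "region_j", "streamline_count", "mean_fa")
  missing <- setdiff(req, names(streamlines))
  if (length(missing)) {
    stop("streamlines missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  i <- streamlines$region_i
  j <- streamlines$region_j
  if (length(i) && (!all(i %in% atlas$index) || !all(j %in% atlas$index))) {
    stop("region indices must lie in 1..90", call. = FALSE)
  }
  if (any(i == j)) stop("self-pairs (i == j) are not allowed", call. = FALSE)
  if (any(i > j)) stop("records must be ordered with region_i < region_j",
                       call. = FALSE)
  if (anyDuplicated(cbind(i, j))) {
    stop("duplicate region pairs in streamline records", call. = FALSE)
  }
  fa <- streamlines$mean_fa
  if (any(fa < 0 | fa > 1)) {
    stop("mean_fa must lie in [0, 1]", call. = FALSE)
  }
  keep <- streamlines$streamline_count >= min_count & fa > fa_threshold
  wei <- matrix(0, 90, 90)
  idx <- cbind(i[keep], j[keep])
  wei[idx] <- fa[keep]
  wei[idx[, c(2, 1), drop = FALSE]] <- fa[keep]
  bin <- (wei > 0) * 1
  list(
    FA_wei = structure(wei, class = "connectivity_matrix", kind = "FA_wei",
                       subject_id = subject_id),
    FA_bin = connectivity_matrix(bin, "FA_bin", subject_id)
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  deg <- rowSums(unclass(x) > 0)
  cat(sprintf("<connectivity_matrix %s, subject %s>\n", attr(x, "kind"),
              attr(x, "subject_id")))
  cat(sprintf("  90 nodes, %d edges, mean degree %.3f\n",
              as.integer(sum(unclass(x) > 0) / 2), mean(deg)))
  invisible(x)
}
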