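#' The 90-region AAL atlas table
#'
#' Returns the Automated Anatomical Labeling (AAL) parcellation used as the
#' node set of every network in this package: 90 cerebral regions (45 per
#' hemisphere, cerebellum excluded), in standard AAL order where odd indices
#' are left-hemisphere and even indices their right homologues. Each region
#' carries a lobe label (central, frontal, temporal, parietal, occipital,
#' limbic, insula, subcortical) and a cortical-class label (primary,
#' association, paralimbic, subcortical).
#'
#' @return A data.frame with 90 rows and columns `index`, `name`,
#'   `abbreviation` (`_L`/`_R` suffixed), `hemisphere`, `lobe`, `class`.
#' @export
#' @examples
#' atlas <- aal_atlas()
#' table(atlas$lobe)
aal_atlas <- function() {
  path <- system.file("extdata", "aal90_atlas.csv", package = "fanet")
  atlas <- read.csv(path, stringsAsFactors = FALSE)
  validate_atlas(atlas)
  atlas
}

#' Region centroid coordinates
#'
#' Synthetic stand-in MNI-space centroid coordinates (millimetres) for the 90
#' AAL regions, hand-placed from gross anatomy with left/right homologues
#' mirrored in x. They drive the distance-dependent synthetic connectome
#' generator and the BrainNet Viewer `.node` export; they are not measured
#' centroids.
#'
#' @return A data.frame with 90 rows and columns `index`, `abbreviation`,
#'   `x`, `y`, `z`.
#' @export
aal_coordinates <- function() {
  path <- system.file("extdata", "aal90_centroids_synthetic.tsv",
                      package = "fanet")
  coords <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(coords) != 90L || !identical(coords$index, 1:90)) {
    stop("coordinate table must cover regions 1..90 exactly", call. = FALSE)
  }
  coords
}

validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  req <- c("index", "name", "abbreviation", "hemisphere", "lobe", "class")
  missing <- setdiff(req, names(atlas))
  if (length(missing)) {
    stop("atlas is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atlas) != 90L || !identical(atlas$index, 1:90)) {
    stop("atlas must have exactly 90 regions indexed 1..90", call. = FALSE)
  }
  if (anyDuplicated(atlas$abbreviation)) {
    stop("atlas abbreviations must be unique", call. = FALSE)
  }
  # AAL pairing: odd = left, even = right
  if (!all(atlas$hemisphere == rep(c("L", "R"), 45L))) {
    stop("atlas must alternate L/R hemispheres (odd = left)", call. = FALSE)
  }
  invisible(atlas)
}
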