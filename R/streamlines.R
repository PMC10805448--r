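#' Generate per-subject streamline summaries
#'
#' Emulates the output of deterministic tractography summarised at the
#' region-pair level: one record per template edge with a streamline count
#' (negative binomial, at least 1) and a mean-FA value equal to the template
#' weight under subject-specific modulation plus Gaussian jitter
#' (`edge_noise_sd`), clipped to (0, 1]. For patients, edges incident to
#' `affected_regions` are multiplied by
#' `fa_attenuation * (1 - duration_slope * duration)`; for every subject,
#' edges incident to `iq_regions` are multiplied by
#' `1 + iq_coupling * (performance_iq - 100) / 15`. Attenuated edges whose FA
#' falls to 0.2 or below are still emitted — they are dropped later by the
#' FA > 0.2 rule of [build_networks()], which is how planted attenuation
#' lowers the binary degree of the patient group.
#'
#' @param template a weighted `connectivity_matrix` from
#'   [generate_template_network()].
#' @param subject a single-row subject table (see
#'   [generate_clinical_cohort()]).
#' @param params a [cohort_params()] object.
#' @param seed integer seed.
#' @return A data.frame with columns `region_i`, `region_j` (1-based atlas
#'   indices, `region_i < region_j`), `streamline_count`, `mean_fa`.
#' @export
generate_subject_streamlines <- function(template, subject,
                                         params = cohort_params(),
                                         seed = 1L) {
  stopifnot(inherits(template, "connectivity_matrix"))
  validate_cohort_params(params)
  if (!is.data.frame(subject) || nrow(subject) != 1L) {
    stop("`subject` must be a single subject-table row", call. = FALSE)
  }
  group <- as.character(subject$group)
  if (!group %in% c("patient", "control")) {
    stop("subject group must be 'patient' or 'control'", call. = FALSE)
  }
  if (group == "patient" &&
      (is.na(subject$duration) || is.na(subject$onset))) {
    stop("patient records require duration and onset", call. = FALSE)
  }
  if (is.na(subject$performance_iq)) {
    stop("subject records require performance_iq", call. = FALSE)
  }
  mat <- unclass(template)
  ut <- which(upper.tri(mat) & mat > 0, arr.ind = TRUE)
  ord <- order(ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  w <- mat[ut]
  factor <- rep(1, length(w))
  touches <- function(regions) {
    ut[, 1] %in% regions | ut[, 2] %in% regions
  }
  if (group == "patient" && length(params$affected_regions)) {
    aff <- touches(params$affected_regions)
    factor[aff] <- factor[aff] * params$fa_attenuation *
      max(0, 1 - params$duration_slope * subject$duration)
  }
  if (length(params$iq_regions) && params$iq_coupling != 0) {
    iqr <- touches(params$iq_regions)
    iq_factor <- max(0, 1 + params$iq_coupling *
                       (subject$performance_iq - 100) / 15)
    factor[iqr] <- factor[iqr] * iq_factor
  }
  with_seed(seed, {
    fa <- w * factor + rnorm(length(w), 0, params$edge_noise_sd)
    fa <- pmin(pmax(fa, 1e-6), 1)
    count <- 1L + rnbinom(length(w), size = 4, mu = 25 * w)
    data.frame(
      region_i = as.integer(ut[, 1]),
      region_j = as.integer(ut[, 2]),
      streamline_count = count,
      mean_fa = fa
    )
  })
}

#' Simulate a full cohort of subjects and streamline summaries
#'
#' Convenience wrapper: draws the clinical cohort, one shared group template,
#' and per-subject streamline summaries. A single cohort seed spawns
#' deterministic per-subject seeds (`seed * 1000 + subject ordinal`,
#' kept within integer range), so any subject is independently reproducible.
#'
#' @inheritParams generate_template_network
#' @param seed integer cohort seed (kept small; per-subject seeds derive
#'   from it).
#' @return A list with elements `subjects` (subject table), `template`
#'   (`connectivity_matrix`), and `streamlines` (named list of per-subject
#'   streamline data.frames).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_params(n_patients = 2, n_controls = 2), seed = 1)
#' names(sim$streamlines)
simulate_cohort <- function(params = cohort_params(), seed = 1L,
                            atlas = aal_atlas(), coords = aal_coordinates()) {
  subjects <- generate_clinical_cohort(params, seed = seed)
  template <- generate_template_network(atlas, coords, params, seed = seed)
  base <- (as.integer(seed) %% 1000000L) * 1000L
  streamlines <- lapply(seq_len(nrow(subjects)), function(i) {
    generate_subject_streamlines(template, subjects[i, , drop = FALSE],
                                 params, seed = base + i)
  })
  names(streamlines) <- subjects$subject_id
  list(subjects = subjects, template = template, streamlines = streamlines)
}

#' Write / read streamline summary TSV files
#'
#' Plain TSV with header `region_i`, `region_j`, `streamline_count`,
#' `mean_fa`; region indices are 1-based atlas indices with
#' `region_i < region_j`.
#'
#' @param streamlines a streamline summary data.frame.
#' @param path file path.
#' @return `read_streamlines` returns the data.frame; `write_streamlines`
#'   returns `path` invisibly.
#' @export
write_streamlines <- function(streamlines, path) {
  utils::write.table(streamlines, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("region_i", "region_j", "streamline_count", "mean_fa")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("streamline file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
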