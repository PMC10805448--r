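#' Synthetic cohort parameters
#'
#' Bundles every knob of the synthetic TLE/control cohort generator. The
#' defaults reproduce the emulated study's conditions: 18 patients (10 male)
#' and 29 controls (17 male); patient age 30.4 +/- 8.16 y versus control
#' 27.8 +/- 5.78 y; epilepsy duration 13.90 +/- 7.15 y and age at seizure
#' onset 16.28 +/- 10.69 y with correlation -0.632; verbal IQ 90.00 +/- 11.57
#' (patients) versus 109.45 +/- 11.91 (controls) and performance IQ
#' 95.06 +/- 10.90 versus 109.00 +/- 10.51. Group-level network effects are
#' planted by attenuating the FA of edges incident to `affected_regions`
#' (temporal/limbic regions by default) in patients, with an extra per-year
#' attenuation in epilepsy duration, and by coupling the edges of
#' `iq_regions` to each subject's performance IQ.
#'
#' `density_calibration` is the target binary mean degree of the template
#' connectome; its default (together with `fa_attenuation`) is calibrated so
#' simulated control and patient cohorts reproduce the emulated study's
#' grand-mean binary degrees of 9.782 and 9.088.
#'
#' @param n_patients,n_controls group sizes (positive integers).
#' @param age_mean,age_sd named numeric vectors (`patient`, `control`), years.
#' @param male_count named integer vector (`patient`, `control`).
#' @param duration_mean,duration_sd epilepsy duration moments, years.
#' @param onset_mean,onset_sd age-at-onset moments, years.
#' @param duration_onset_r target correlation between duration and onset on
#'   the delivered (nonnegative) scale, in (-1, 1).
#' @param viq_mean,viq_sd,piq_mean,piq_sd named numeric vectors per group.
#' @param affected_regions atlas indices whose incident edges are attenuated
#'   in patients.
#' @param iq_regions atlas indices whose incident edges co-vary with
#'   performance IQ.
#' @param fa_attenuation multiplicative FA factor in (0, 1] applied to
#'   affected-region edges in patients.
#' @param duration_slope extra attenuation per year of epilepsy duration.
#' @param iq_coupling slope linking `iq_regions` edge strength to the
#'   subject's performance IQ (per 15-point deviation from 100).
#' @param edge_noise_sd SD of the per-subject Gaussian FA jitter.
#' @param density_calibration target binary mean degree of the template
#'   connectome, in (0, 89].
#' @param dist_scale e-folding length (mm) of the distance kernel.
#' @param hemi_boost,lobe_boost multiplicative connection-propensity boosts
#'   within a hemisphere / within a lobe.
#' @param kernel_sharpness exponent applied to the connection-propensity
#'   kernel; larger values make edge probabilities more deterministic,
#'   concentrating degree (and hence hub identity) on the highest-propensity
#'   regions.
#' @param hub_regions atlas indices of the planted hub backbone (default:
#'   the bilateral precuneus, putamen and middle temporal gyrus plus right
#'   dorsolateral superior frontal, left calcarine, left middle occipital,
#'   right superior parietal and right inferior temporal gyri — the
#'   association/subcortical hub layout of measured adult connectomes).
#' @param hub_boost multiplicative propensity boost for `hub_regions`.
#' @param fa_excess_mean mean of the exponential FA excess above the 0.2
#'   detection threshold for template edge weights.
#' @return An object of class `cohort_params` (a validated list).
#' @export
#' @examples
#' p <- cohort_params()
#' p$duration_mean
cohort_params <- function(n_patients = 18L,
                          n_controls = 29L,
                          age_mean = c(patient = 30.4, control = 27.8),
                          age_sd = c(patient = 8.16, control = 5.78),
                          male_count = c(patient = 10L, control = 17L),
                          duration_mean = 13.90,
                          duration_sd = 7.15,
                          onset_mean = 16.28,
                          onset_sd = 10.69,
                          duration_onset_r = -0.632,
                          viq_mean = c(patient = 90.00, control = 109.45),
                          viq_sd = c(patient = 11.57, control = 11.91),
                          piq_mean = c(patient = 95.06, control = 109.00),
                          piq_sd = c(patient = 10.90, control = 10.51),
                          affected_regions = c(32L, 33L, 35L, 36L, 39L, 40L,
                                               41L, 81L, 83L, 85L, 87L, 89L),
                          iq_regions = c(2L, 21L, 22L, 54L, 57L, 66L),
                          fa_attenuation = 0.775,
                          duration_slope = 0.004,
                          iq_coupling = 0.04,
                          edge_noise_sd = 0.015,
                          density_calibration = 10.17,
                          dist_scale = 30,
                          hemi_boost = 1.25,
                          lobe_boost = 1.9,
                          kernel_sharpness = 3,
                          hub_regions = c(4L, 43L, 51L, 60L, 67L, 68L,
                                          73L, 74L, 85L, 86L, 90L),
                          hub_boost = 2.1,
                          fa_excess_mean = 0.12) {
  params <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    age_mean = age_mean, age_sd = age_sd, male_count = male_count,
    duration_mean = duration_mean, duration_sd = duration_sd,
    onset_mean = onset_mean, onset_sd = onset_sd,
    duration_onset_r = duration_onset_r,
    viq_mean = viq_mean, viq_sd = viq_sd,
    piq_mean = piq_mean, piq_sd = piq_sd,
    affected_regions = as.integer(affected_regions),
    iq_regions = as.integer(iq_regions),
    fa_attenuation = fa_attenuation, duration_slope = duration_slope,
    iq_coupling = iq_coupling, edge_noise_sd = edge_noise_sd,
    density_calibration = density_calibration,
    dist_scale = dist_scale, hemi_boost = hemi_boost,
    lobe_boost = lobe_boost, kernel_sharpness = kernel_sharpness,
    hub_regions = as.integer(hub_regions), hub_boost = hub_boost,
    fa_excess_mean = fa_excess_mean
  )
  class(params) <- "cohort_params"
  validate_cohort_params(params)
}

validate_cohort_params <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  err <- function(...) stop(..., call. = FALSE)
  if (params$n_patients <= 0L || params$n_controls <= 0L) {
    err("group sizes must be positive")
  }
  grp <- c("patient", "control")
  for (f in c("age_mean", "age_sd", "male_count", "viq_mean", "viq_sd",
              "piq_mean", "piq_sd")) {
    v <- params[[f]]
    if (!all(grp %in% names(v))) err("`", f, "` needs 'patient' and 'control' entries")
  }
  sds <- c(params$age_sd, params$duration_sd, params$onset_sd,
           params$viq_sd, params$piq_sd, params$edge_noise_sd)
  if (any(sds < 0)) err("all SDs must be >= 0")
  if (abs(params$duration_onset_r) >= 1) err("|duration_onset_r| must be < 1")
  if (params$male_count[["patient"]] > params$n_patients ||
      params$male_count[["control"]] > params$n_controls) {
    err("male_count cannot exceed the group size")
  }
  if (params$fa_attenuation <= 0 || params$fa_attenuation > 1) {
    err("fa_attenuation must be in (0, 1]")
  }
  if (length(params$affected_regions) &&
      !all(params$affected_regions %in% 1:90)) {
    err("affected_regions must be atlas indices in 1..90")
  }
  if (length(params$iq_regions) && !all(params$iq_regions %in% 1:90)) {
    err("iq_regions must be atlas indices in 1..90")
  }
  if (length(params$hub_regions) && !all(params$hub_regions %in% 1:90)) {
    err("hub_regions must be atlas indices in 1..90")
  }
  if (params$hub_boost <= 0) err("hub_boost must be positive")
  if (params$density_calibration <= 0 || params$density_calibration > 89) {
    err("density_calibration must be in (0, 89]")
  }
  if (params$duration_mean < 0 || params$onset_mean < 0) {
    err("duration/onset means must be >= 0")
  }
  params
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params>\n")
  cat(sprintf("  groups: %d patients (%d male), %d controls (%d male)\n",
              x$n_patients, x$male_count[["patient"]],
              x$n_controls, x$male_count[["control"]]))
  cat(sprintf("  duration %.2f +/- %.2f y, onset %.2f +/- %.2f y, r = %.3f\n",
              x$duration_mean, x$duration_sd, x$onset_mean, x$onset_sd,
              x$duration_onset_r))
  cat(sprintf("  template target degree %.3f; fa_attenuation %.3f; %d affected regions\n",
              x$density_calibration, x$fa_attenuation,
              length(x$affected_regions)))
  invisible(x)
}
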