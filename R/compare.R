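# Cohort-level metric tables and the statistical layer mirroring the
# emulated study's Tables 3 and 5.

#' Compute per-subject metric tables for a cohort
#'
#' Builds FA_wei/FA_bin networks for every subject and returns a long table
#' of global metrics (Eg, Cp, Eloc, Lp and, optionally, small-world sigma)
#' and nodal metrics (Enodal, degree) per network kind.
#'
#' @param streamlines named list of per-subject streamline data.frames.
#' @param atlas atlas table.
#' @param fa_threshold,min_count edge rule, see [build_networks()].
#' @param weight_conversion see [distance_matrix()].
#' @param include_smallworld compute sigma per subject against a null
#'   ensemble (the expensive step; off by default).
#' @param n_null,swaps_per_edge null-ensemble settings when
#'   `include_smallworld = TRUE`.
#' @param seed base seed for the null ensembles.
#' @return A data.frame of class `metric_table` with columns `subject_id`,
#'   `kind`, `metric`, `region` (`"GLOBAL"` or the atlas index as
#'   character), `value`.
#' @export
cohort_metrics <- function(streamlines, atlas = aal_atlas(),
                           fa_threshold = 0.2, min_count = 1L,
                           weight_conversion = c("reciprocal", "one_minus"),
                           include_smallworld = FALSE, n_null = 100L,
                           swaps_per_edge = 10L, seed = 1L) {
  weight_conversion <- match.arg(weight_conversion)
  ids <- names(streamlines)
  if (is.null(ids)) ids <- sprintf("sub-%03d", seq_along(streamlines))
  rows <- vector("list", length(streamlines))
  for (si in seq_along(streamlines)) {
    nets <- build_networks(streamlines[[si]], atlas, fa_threshold, min_count,
                           subject_id = ids[si])
    sub_rows <- list()
    for (kind in c("FA_wei", "FA_bin")) {
      mat <- nets[[kind]]
      if (sum(unclass(mat) > 0) == 0) {
        warning("subject ", ids[si], " has an edgeless ", kind, " network",
                call. = FALSE)
      }
      d <- distance_matrix(mat, weight_conversion)
      gm <- global_metrics(mat, d, weight_conversion)
      nm <- nodal_metrics(mat, d, weight_conversion)
      glob <- data.frame(
        subject_id = ids[si], kind = kind,
        metric = c("Eg", "Cp", "Eloc", "Lp"), region = "GLOBAL",
        value = c(gm$Eg, gm$Cp, gm$Eloc, gm$Lp)
      )
      if (include_smallworld) {
        sw <- small_world(gm, null_ensemble(mat, n_null, swaps_per_edge,
                                            seed = seed + 7L * si +
                                              (kind == "FA_bin"),
                                            weight_conversion))
        glob <- rbind(glob, data.frame(
          subject_id = ids[si], kind = kind, metric = "sigma",
          region = "GLOBAL", value = sw$sigma
        ))
      }
      nod <- data.frame(
        subject_id = ids[si], kind = kind,
        metric = rep(c("Enodal", "degree"), each = nrow(nm)),
        region = as.character(c(nm$region, nm$region)),
        value = c(nm$Enodal, nm$degree)
      )
      sub_rows[[kind]] <- rbind(glob, nod)
    }
    rows[[si]] <- do.call(rbind, sub_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metric_table", "data.frame")
  out
}

# wide subject x value vector for one (kind, metric, region)
metric_slice <- function(metric_tbl, kind, metric, region, subjects) {
  sel <- metric_tbl$kind == kind & metric_tbl$metric == metric &
    metric_tbl$region == region
  sl <- metric_tbl[sel, c("subject_id", "value")]
  sl$value[match(subjects$subject_id, sl$subject_id)]
}

#' Covariate-adjusted group comparison of every topological property
#'
#' Runs [adjusted_group_compare()] for each global metric per network kind
#' and for nodal efficiency at all 90 regions per network kind, then applies
#' Benjamini-Hochberg FDR within families: the 90 nodal tests form one
#' family per network kind and the global metrics one family per network
#' kind. Every row records its family.
#'
#' @param metric_tbl a [cohort_metrics()] table.
#' @param subjects the matching subject table.
#' @param q_level FDR level (default 0.05).
#' @param atlas atlas table for lobe labels.
#' @return A data.frame of class `comparison_table`: `metric`, `region`,
#'   `abbreviation`, `lobe`, `kind`, `mean_patient`, `mean_control`
#'   (covariate-adjusted), `t`, `p`, `q`, `significant`, `family_id`.
#' @export
compare_all <- function(metric_tbl, subjects, q_level = 0.05,
                        atlas = aal_atlas()) {
  stopifnot(all(c("subject_id", "group", "age", "gender") %in%
                  names(subjects)))
  run_one <- function(kind, metric, region) {
    y <- metric_slice(metric_tbl, kind, metric, region, subjects)
    if (any(is.na(y))) {
      stop("missing metric values for ", metric, "/", region, " (", kind,
           "): every subject needs metrics", call. = FALSE)
    }
    cmp <- adjusted_group_compare(y, subjects$group, subjects$age,
                                  subjects$gender)
    data.frame(
      metric = metric, region = region,
      abbreviation = if (region == "GLOBAL") NA_character_ else
        atlas$abbreviation[as.integer(region)],
      lobe = if (region == "GLOBAL") NA_character_ else
        atlas$lobe[as.integer(region)],
      kind = kind,
      mean_patient = cmp$adjusted_means[["patient"]],
      mean_control = cmp$adjusted_means[["control"]],
      t = cmp$t, p = cmp$p,
      stringsAsFactors = FALSE
    )
  }
  global_metrics_present <- unique(
    metric_tbl$metric[metric_tbl$region == "GLOBAL"]
  )
  out <- list()
  for (kind in unique(metric_tbl$kind)) {
    glob <- do.call(rbind, lapply(global_metrics_present, function(m) {
      run_one(kind, m, "GLOBAL")
    }))
    glob$family_id <- paste0("global_", kind)
    nod <- do.call(rbind, lapply(as.character(1:90), function(rg) {
      run_one(kind, "Enodal", rg)
    }))
    nod$family_id <- paste0("nodal_", kind)
    out[[kind]] <- rbind(glob, nod)
  }
  res <- do.call(rbind, out)
  res$q <- NA_real_
  for (fam in unique(res$family_id)) {
    sel <- res$family_id == fam
    res$q[sel] <- fdr_bh(res$p[sel], q_level)$q
  }
  res$significant <- res$q <= q_level
  rownames(res) <- NULL
  class(res) <- c("comparison_table", "data.frame")
  attr(res, "q_level") <- q_level
  res
}

#' Partial correlation of nodal efficiency with clinical characteristics
#'
#' For patients only, and for the FA-weighted network only (binarisation
#' loses information), correlates nodal efficiency at each of the 90
#' regions with duration of epilepsy, verbal IQ and performance IQ.
#' Covariates: age and gender for the IQ analyses; age, gender and age at
#' seizure onset for the duration analysis. FDR is applied per clinical
#' variable across the 90 regions. Subjects with a missing value of the
#' clinical variable are dropped from that variable's analysis.
#'
#' @param metric_tbl a [cohort_metrics()] table containing FA_wei Enodal
#'   rows.
#' @param subjects the matching subject table.
#' @param q_level FDR level.
#' @param atlas atlas table for labels.
#' @return A data.frame of class `correlation_table`: `region`,
#'   `abbreviation`, `lobe`, `clinical_variable`, `covariates`, `r`, `df`,
#'   `p`, `q`, `significant`.
#' @export
correlate_clinical <- function(metric_tbl, subjects, q_level = 0.05,
                               atlas = aal_atlas()) {
  pats <- subjects[subjects$group == "patient", , drop = FALSE]
  if (!nrow(pats)) stop("no patients in the subject table", call. = FALSE)
  specs <- list(
    duration = c("age", "gender", "onset"),
    verbal_iq = c("age", "gender"),
    performance_iq = c("age", "gender")
  )
  gender_num <- as.numeric(pats$gender == "male")
  out <- list()
  for (var in names(specs)) {
    xvar <- pats[[var]]
    covn <- specs[[var]]
    Z <- cbind(age = pats$age, gender = gender_num,
               if ("onset" %in% covn) cbind(onset = pats$onset))
    keep <- !is.na(xvar) & stats::complete.cases(Z)
    rows <- lapply(as.character(1:90), function(rg) {
      y <- metric_slice(metric_tbl[metric_tbl$kind == "FA_wei", ], "FA_wei",
                        "Enodal", rg, pats)
      pc <- partial_correlation(xvar[keep], y[keep],
                                Z[keep, , drop = FALSE])
      data.frame(
        region = as.integer(rg),
        abbreviation = atlas$abbreviation[as.integer(rg)],
        lobe = atlas$lobe[as.integer(rg)],
        clinical_variable = var,
        covariates = paste(covn, collapse = "+"),
        r = pc$r, df = pc$df, p = pc$p,
        stringsAsFactors = FALSE
      )
    })
    block <- do.call(rbind, rows)
    adj <- fdr_bh(block$p, q_level)
    block$q <- adj$q
    block$significant <- adj$reject
    out[[var]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("correlation_table", "data.frame")
  attr(res, "q_level") <- q_level
  res
}
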