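# File-format plumbing: whitespace-delimited matrices (BrainNet Viewer
# .edge), subject CSVs, BrainNet .node exports, long-format metric TSVs,
# YAML run configs and reproducibility manifests. Delimited text only, so
# every artifact is diffable.

#' Read / write connectivity matrices
#'
#' Whitespace/tab-delimited 90x90 text, one row per line — exactly the
#' BrainNet Viewer `.edge` format. Round trip preserves values to full
#' precision.
#'
#' @param matrix a `connectivity_matrix` or plain 90x90 matrix.
#' @param path file path.
#' @param kind matrix kind for the container on read.
#' @param subject_id subject identifier on read.
#' @return `read_matrix` returns a `connectivity_matrix`; `write_matrix`
#'   returns `path` invisibly.
#' @export
write_matrix <- function(matrix, path) {
  m <- unclass(matrix)
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                         collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, kind = c("FA_wei", "FA_bin"),
                        subject_id = "unknown") {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(ln) {
    cells <- strsplit(trimws(lines[[ln]]), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals))) {
      stop("non-numeric cell in matrix file at line ", ln, call. = FALSE)
    }
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L || length(rows) != ncols[1]) {
    stop("matrix file is not square (", length(rows), " rows, ",
         paste(unique(ncols), collapse = "/"), " columns)", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  connectivity_matrix(m, kind, subject_id)
}

#' Read / write subject tables
#'
#' CSV with header `subject_id, group, age, gender, duration, onset,
#' verbal_iq, performance_iq`; an empty field means not applicable (e.g.
#' duration for controls).
#'
#' @param subjects a subject table.
#' @param path file path.
#' @return `read_subjects` returns a `subject_table`; `write_subjects`
#'   returns `path` invisibly.
#' @export
write_subjects <- function(subjects, path) {
  write.csv(as.data.frame(subjects), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  req <- c("subject_id", "group", "age", "gender", "duration", "onset",
           "verbal_iq", "performance_iq")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("subject file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$group <- factor(df$group, levels = c("patient", "control"))
  df$gender <- factor(df$gender, levels = c("male", "female"))
  class(df) <- c("subject_table", "data.frame")
  df
}

#' Write a long-format metric table
#'
#' TSV with columns `subject_id`, `kind`, `metric`, `region`, `value`.
#'
#' @param metric_tbl a [cohort_metrics()] table.
#' @param path file path.
#' @export
write_metrics <- function(metric_tbl, path) {
  utils::write.table(as.data.frame(metric_tbl), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a hub table in BrainNet Viewer .node format
#'
#' Six whitespace-delimited columns: x, y, z, color, size, label. Size is
#' proportional to the group-mean degree; hubs get color 2, other regions
#' color 1.
#'
#' @param hub_table a [hub_detection()] result.
#' @param coords coordinate table from [aal_coordinates()].
#' @param path file path.
#' @export
export_brainnet_node <- function(hub_table, coords = aal_coordinates(),
                                 path) {
  idx <- match(hub_table$region, coords$index)
  if (any(is.na(idx))) stop("hub table regions missing from coordinates",
                            call. = FALSE)
  lines <- sprintf("%g %g %g %d %.4f %s",
                   coords$x[idx], coords$y[idx], coords$z[idx],
                   ifelse(hub_table$hub, 2L, 1L),
                   hub_table$mean_degree,
                   hub_table$abbreviation)
  writeLines(lines, path)
  invisible(path)
}

#' Run configuration files
#'
#' YAML files with sections `cohort` (any [cohort_params()] field),
#' `network` (`fa_threshold`, `min_count`), `metrics`
#' (`weight_conversion`, `n_null`, `swaps_per_edge`, `sd_multiplier`) and
#' `statistics` (`q_level`). Missing fields take the package defaults; the
#' shipped default config lives at
#' `system.file("extdata", "default_config.yaml", package = "fanet")`.
#'
#' @param path YAML file path; `NULL` loads the shipped defaults.
#' @return A list of class `run_config` with elements `cohort`
#'   (a `cohort_params`), `network`, `metrics`, `statistics`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml", package = "fanet")
  }
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  cohort_args <- raw$cohort
  if (!is.null(cohort_args)) {
    for (nm in c("age_mean", "age_sd", "male_count", "viq_mean", "viq_sd",
                 "piq_mean", "piq_sd")) {
      if (!is.null(cohort_args[[nm]])) {
        cohort_args[[nm]] <- unlist(cohort_args[[nm]])
      }
    }
  }
  cohort <- do.call(cohort_params, cohort_args %||% list())
  network <- modifyList(list(fa_threshold = 0.2, min_count = 1L),
                        raw$network %||% list())
  metrics <- modifyList(list(weight_conversion = "reciprocal",
                             n_null = 100L, swaps_per_edge = 10L,
                             sd_multiplier = 1.0),
                        raw$metrics %||% list())
  statistics <- modifyList(list(q_level = 0.05), raw$statistics %||% list())
  if (statistics$q_level <= 0 || statistics$q_level >= 1) {
    stop("q_level must lie in (0, 1)", call. = FALSE)
  }
  if (network$fa_threshold < 0 || network$fa_threshold >= 1) {
    stop("fa_threshold must lie in [0, 1)", call. = FALSE)
  }
  structure(list(cohort = cohort, network = network, metrics = metrics,
                 statistics = statistics, source = path),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reproducibility manifest
#'
#' JSON recording the config path, a hash of the resolved configuration,
#' the master seed and the package version — enough to rerun any stage.
#'
#' @param config a `run_config`.
#' @param seed master seed of the run.
#' @param path output path.
#' @export
write_manifest <- function(config, seed, path) {
  cfg <- config
  cfg$source <- NULL
  hash <- sum(utf8ToInt(paste(deparse(cfg), collapse = ""))) %% 1000000007
  jsonlite::write_json(
    list(config_hash = hash, seed = as.integer(seed),
         package = "fanet",
         version = as.character(packageVersion("fanet"))),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
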