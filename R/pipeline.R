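#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, constructs FA_wei/FA_bin networks,
#' computes all topological properties including per-subject small-world
#' sigma, runs the covariate-adjusted group comparison with FDR and the
#' clinical partial-correlation analysis, detects hubs per group, and
#' (optionally) writes every artifact plus a reproducibility manifest to
#' `out_dir`. Fully deterministic given `(config, seed)`.
#'
#' @param config a [read_config()] object (defaults to the shipped config).
#' @param seed master seed.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param include_smallworld compute per-subject sigma (the expensive
#'   stage).
#' @return A list: `subjects`, `metric_tbl`, `comparison`, `correlation`,
#'   `hubs` (per group), `config`, `seed`.
#' @export
run_pipeline <- function(config = read_config(), seed = 1L, out_dir = NULL,
                         include_smallworld = TRUE) {
  stopifnot(inherits(config, "run_config"))
  atlas <- aal_atlas()
  coords <- aal_coordinates()
  sim <- simulate_cohort(config$cohort, seed = seed, atlas = atlas,
                         coords = coords)
  metric_tbl <- cohort_metrics(
    sim$streamlines, atlas,
    fa_threshold = config$network$fa_threshold,
    min_count = config$network$min_count,
    weight_conversion = config$metrics$weight_conversion,
    include_smallworld = include_smallworld,
    n_null = config$metrics$n_null,
    swaps_per_edge = config$metrics$swaps_per_edge,
    seed = seed
  )
  comparison <- compare_all(metric_tbl, sim$subjects,
                            q_level = config$statistics$q_level,
                            atlas = atlas)
  correlation <- correlate_clinical(metric_tbl, sim$subjects,
                                    q_level = config$statistics$q_level,
                                    atlas = atlas)
  deg <- metric_tbl[metric_tbl$metric == "degree" &
                      metric_tbl$kind == "FA_bin", ]
  deg$region <- as.integer(deg$region)
  deg$degree <- deg$value
  hubs <- lapply(c(patient = "patient", control = "control"), function(g) {
    ids <- sim$subjects$subject_id[sim$subjects$group == g]
    hub_detection(deg[deg$subject_id %in% ids, ],
                  sd_multiplier = config$metrics$sd_multiplier, atlas)
  })
  result <- list(subjects = sim$subjects, metric_tbl = metric_tbl,
                 comparison = comparison, correlation = correlation,
                 hubs = hubs, config = config, seed = as.integer(seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_subjects(sim$subjects, file.path(out_dir, "subjects.csv"))
    write_metrics(metric_tbl, file.path(out_dir, "metrics.tsv"))
    utils::write.table(as.data.frame(comparison),
                       file.path(out_dir, "comparison.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(correlation),
                       file.path(out_dir, "correlation.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    for (g in names(hubs)) {
      export_brainnet_node(hubs[[g]], coords,
                           file.path(out_dir, paste0("hubs_", g, ".node")))
    }
    write_matrix(sim$template, file.path(out_dir, "template.edge"))
    write_manifest(config, seed, file.path(out_dir, "manifest.json"))
  }
  invisible(result)
}
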