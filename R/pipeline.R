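#' Run the full reconstruction pipeline on a (synthetic or real) world
#'
#' Chains the standard stages: depth/symbiont filtering, 1-degree gridding
#' to proportional assemblages, single-genus cell exclusion, modern-fossil
#' taxon harmonization, climatology pairing, transfer-function calibration
#' (IKFA and/or ANN ensemble), fossil projection, and anomaly computation
#' against the observed modern climatology.
#'
#' @param world List with `field`, `modern_occ`, `fossil_occ` (as returned
#'   by [simulate_world()], or assembled from read files).
#' @param env `"mean_sst"` or `"stv"`.
#' @param rank `"species"` or `"genus"`.
#' @param methods Character subset of `c("ikfa", "ann")`.
#' @param k IKFA factor count.
#' @param ann Configuration from [ann_config()].
#' @param min_genera Cell-filter threshold.
#' @return List: `calibration` (modern `calibration_set`), `fossil`
#'   (harmonized fossil `assemblage_matrix`), `models`, and `anomalies` (one
#'   `anomaly_profile` per method).
#' @export
run_reconstruction <- function(world, env = "mean_sst",
                               rank = c("species", "genus"),
                               methods = c("ikfa", "ann"),
                               k = 4, ann = ann_config(n_replicates = 30),
                               min_genera = 2) {
  rank <- match.arg(rank)
  env <- match.arg(env, c("mean_sst", "stv"))
  methods <- match.arg(methods, c("ikfa", "ann"), several.ok = TRUE)
  modern <- apply_cell_filters(
    build_matrix(filter_records(world$modern_occ), rank), min_genera)
  fossil <- apply_cell_filters(
    build_matrix(filter_records(world$fossil_occ), rank), min_genera)
  harm <- harmonize_taxa(modern, fossil, min_genera)
  cal <- pair_cells(harm$modern, world$field)
  models <- list()
  anomalies <- list()
  fossil_aligned <- align_taxa(harm$fossil$props, colnames(cal$props))
  if ("ikfa" %in% methods) {
    models$ikfa <- fit_ikfa(cal, env, k = k)
    pred <- predict_ikfa(models$ikfa, fossil_aligned)
    anomalies$ikfa <- compute_anomalies(pred, harm$fossil$cells,
                                        world$field, env, "ikfa")
  }
  if ("ann" %in% methods) {
    models$ann <- train_ensemble(cal, env, ann)
    pred <- predict_ensemble(models$ann, fossil_aligned)
    anomalies$ann <- compute_anomalies(pred, harm$fossil$cells,
                                       world$field, env, "ann")
  }
  list(calibration = cal, fossil = harm$fossil, models = models,
       anomalies = anomalies, env = env, rank = rank)
}
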