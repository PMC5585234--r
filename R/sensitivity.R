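#' Cross-validated deviations of a transfer function
#'
#' Signed deviations (observed - predicted) of the calibration cells, either
#' by resubstitution (apparent error, mirroring an internal test of the
#' method) or leave-one-out (honest error: each cell predicted by a model
#' trained without it).
#'
#' @param calib A `calibration_set`, or a proportion matrix with numeric
#'   `env`.
#' @param env `"mean_sst"`, `"stv"`, or a numeric vector.
#' @param method `"ikfa"` or `"ann"`.
#' @param mode `"resubstitution"` or `"leave_one_out"`.
#' @param k Factor count for IKFA.
#' @param config [ann_config()] for the ANN.
#' @param lat Optional latitudes (taken from the calibration set when
#'   available).
#' @return List with `deviations` (data frame `lat`, `observed`,
#'   `predicted`, `deviation`), `median_deviation` and `rmse`.
#' @export
cross_validation <- function(calib, env = "mean_sst",
                             method = c("ikfa", "ann"),
                             mode = c("resubstitution", "leave_one_out"),
                             k = 5, config = ann_config(), lat = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (inherits(calib, "calibration_set")) {
    if (is.character(env)) env <- calib[[match.arg(env, c("mean_sst", "stv"))]]
    if (is.null(lat)) lat <- calib$cells$lat
    props <- calib$props
  } else {
    props <- as.matrix(calib)
  }
  if (is.null(lat)) lat <- rep(NA_real_, nrow(props))
  n <- nrow(props)
  predict_on <- function(train_idx, test_idx) {
    if (method == "ikfa") {
      m <- fit_ikfa(props[train_idx, , drop = FALSE], env[train_idx], k = k)
      predict_ikfa(m, props[test_idx, , drop = FALSE])$predicted
    } else {
      ens <- train_ensemble(props[train_idx, , drop = FALSE], env[train_idx],
                            config)
      predict_ensemble(ens, props[test_idx, , drop = FALSE])$predicted
    }
  }
  predicted <- if (mode == "resubstitution") {
    predict_on(seq_len(n), seq_len(n))
  } else {
    vapply(seq_len(n), function(i) predict_on(setdiff(seq_len(n), i), i),
           numeric(1))
  }
  dev <- data.frame(lat = lat, observed = env, predicted = predicted,
                    deviation = env - predicted)
  list(deviations = dev,
       median_deviation = stats::median(dev$deviation, na.rm = TRUE),
       rmse = sqrt(mean(dev$deviation^2, na.rm = TRUE)))
}

#' Species-pool and assemblage-count sensitivity experiment
#'
#' Degrades the calibration data by subsampling the taxon pool and/or the
#' calibration cells (without replacement, seeded), retrains both transfer
#' functions, and reports for each fraction pair the internal calibration
#' RMSE and the mean absolute shift of the fossil anomaly profile relative
#' to the full-data run. The expectation — model performance worsening
#' systematically as the pool shrinks — can be quantified by the rank
#' correlation of RMSE with fraction.
#'
#' @param calib A `calibration_set` (modern).
#' @param fossil Fossil proportion matrix or `assemblage_matrix`.
#' @param fossil_cells Fossil cell data frame (needed when `fossil` is a
#'   bare matrix).
#' @param modern_field `clim_field` with the modern reference.
#' @param env `"mean_sst"` or `"stv"`.
#' @param species_fractions,cell_fractions Fractions in `(0, 1]` to test.
#' @param k IKFA factor count.
#' @param config [ann_config()]; use a reduced `n_replicates` for
#'   desk-scale runs (the replicate count is recorded in the output).
#' @param base_seed Seed for the subsampling.
#' @return Data frame: `species_fraction`, `cell_fraction`, `method`,
#'   `n_taxa`, `n_cells`, `rmse` (internal), `anomaly_shift` (mean |change|
#'   of per-cell fossil anomalies vs the full run).
#' @export
sensitivity_experiment <- function(calib, fossil, fossil_cells = NULL,
                                   modern_field, env = "mean_sst",
                                   species_fractions = c(1, 0.5, 0.25, 0.1),
                                   cell_fractions = 1,
                                   k = 4, config = ann_config(n_replicates = 20),
                                   base_seed = 1L) {
  stopifnot_named("fractions must be in (0, 1]" =
                    all(c(species_fractions, cell_fractions) > 0) &&
                    all(c(species_fractions, cell_fractions) <= 1))
  env_name <- match.arg(env, c("mean_sst", "stv"))
  y <- calib[[env_name]]
  props <- calib$props
  if (inherits(fossil, "assemblage_matrix")) {
    fossil_cells <- fossil$cells
    fossil <- fossil$props
  }
  fossil <- align_taxa(as.matrix(fossil), colnames(props))
  run_one <- function(sf, cf, seed_i) {
    set.seed(derive_seed(base_seed, seed_i))
    n_taxa <- round(sf * ncol(props))
    if (n_taxa < 2) {
      stop("species fraction leaves fewer than 2 taxa: degenerate pool")
    }
    n_cells <- max(k + 2L, round(cf * nrow(props)))
    taxa_idx <- sort(sample.int(ncol(props), n_taxa))
    cell_idx <- sort(sample.int(nrow(props), n_cells))
    sub <- props[cell_idx, taxa_idx, drop = FALSE]
    tot <- rowSums(sub)
    ok <- tot > 0
    sub <- sub[ok, , drop = FALSE] / tot[ok]
    y_sub <- y[cell_idx][ok]
    fsub <- fossil[, taxa_idx, drop = FALSE]
    ftot <- rowSums(fsub)
    fok <- ftot > 0
    fsub <- fsub[fok, , drop = FALSE] / ftot[fok]
    fcells <- fossil_cells[fok, , drop = FALSE]
    out <- list()
    # IKFA branch
    m <- fit_ikfa(sub, y_sub, k = min(k, min(dim(sub)) - 0L))
    pr <- predict_ikfa(m, fsub)
    an <- compute_anomalies(pr, fcells, modern_field, env_name, "ikfa")
    out$ikfa <- list(rmse = m$calibration$rmse, anomalies = an)
    # ANN branch
    cfg <- config
    cfg$base_seed <- derive_seed(base_seed, seed_i + 1000L)
    ens <- train_ensemble(sub, y_sub, cfg)
    pr2 <- predict_ensemble(ens, fsub)
    cal2 <- predict_ensemble(ens, sub)
    an2 <- compute_anomalies(pr2, fcells, modern_field, env_name, "ann")
    out$ann <- list(rmse = sqrt(mean((y_sub - cal2$predicted)^2)),
                    anomalies = an2)
    out
  }
  grid <- expand.grid(species_fraction = species_fractions,
                      cell_fraction = cell_fractions)
  runs <- lapply(seq_len(nrow(grid)), function(i) {
    run_one(grid$species_fraction[i], grid$cell_fraction[i], i)
  })
  full_idx <- which(grid$species_fraction == 1 & grid$cell_fraction == 1)
  ref <- if (length(full_idx)) runs[[full_idx[1]]] else
    run_one(1, 1, nrow(grid) + 1L)
  shift_vs_full <- function(an, ref_an) {
    key <- paste(an$lat_index, an$lon_index, sep = ":")
    rkey <- paste(ref_an$lat_index, ref_an$lon_index, sep = ":")
    idx <- match(key, rkey)
    okm <- !is.na(idx)
    mean(abs(an$anomaly[okm] - ref_an$anomaly[idx[okm]]))
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- runs[[i]]
    do.call(rbind, lapply(c("ikfa", "ann"), function(mth) {
      data.frame(
        species_fraction = grid$species_fraction[i],
        cell_fraction = grid$cell_fraction[i],
        method = mth,
        n_taxa = round(grid$species_fraction[i] * ncol(props)),
        n_cells = max(k + 2L, round(grid$cell_fraction[i] * nrow(props))),
        n_replicates = config$n_replicates,
        rmse = r[[mth]]$rmse,
        anomaly_shift = shift_vs_full(r[[mth]]$anomalies,
                                      ref[[mth]]$anomalies)
      )
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
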