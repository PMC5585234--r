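#' Read and write pipeline artifacts
#'
#' All serialization is plain text: occurrence tables and gridded fields as
#' CSV, assemblage matrices as wide CSV with a JSON sidecar (rank and genus
#' map), fitted models as JSON.
#'
#' @name coralclim_io
NULL

#' @rdname coralclim_io
#' @param records Occurrence data frame.
#' @param path Output file path.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname coralclim_io
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "genus", "rank", "lat", "lon", "depth_m", "epoch",
            "zooxanthellate")
  stopifnot_named("occurrence CSV missing required columns" =
                    all(need %in% names(occ)))
  occ$zooxanthellate <- as.logical(occ$zooxanthellate)
  occ
}

#' @rdname coralclim_io
#' @param field A `clim_field`.
#' @export
write_field <- function(field, path) {
  long <- do.call(rbind, lapply(1:12, function(m) {
    data.frame(lat = field$lat, lon = field$lon, month = m,
               sst = field[[month_names[m]]])
  }))
  utils::write.csv(long[order(long$lat, long$lon, long$month), ], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname coralclim_io
#' @export
read_field <- function(path) {
  long <- utils::read.csv(path)
  stopifnot_named("field CSV needs lat, lon, month, sst" =
                    all(c("lat", "lon", "month", "sst") %in% names(long)))
  long$year <- 1L
  climatology_field(long)
}

#' @rdname coralclim_io
#' @param matrix An `assemblage_matrix`.
#' @export
write_assemblage <- function(matrix, path) {
  wide <- cbind(matrix$cells, as.data.frame(matrix$props))
  utils::write.csv(wide, path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(rank = matrix$rank,
                            taxa = matrix$taxa,
                            genus_map = as.list(matrix$genus_map)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname coralclim_io
#' @export
read_assemblage <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cells <- wide[c("lat_index", "lon_index", "epoch")]
  props <- as.matrix(wide[, meta$taxa, drop = FALSE])
  rownames(props) <- paste(cells$lat_index, cells$lon_index, sep = ":")
  structure(list(props = props, cells = cells, taxa = meta$taxa,
                 rank = meta$rank,
                 genus_map = unlist(meta$genus_map)),
            class = "assemblage_matrix")
}

#' @rdname coralclim_io
#' @param model An `ikfa_model`.
#' @export
write_ikfa <- function(model, path) {
  obj <- list(
    type = "ikfa_model", k = model$k, quadratic = model$quadratic,
    row_norm = model$row_norm, taxa = model$taxa,
    taxon_scores = model$taxon_scores, rotation = model$rotation,
    coefficients = as.list(model$coefficients),
    calibration_rmse = model$calibration$rmse
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname coralclim_io
#' @export
read_ikfa <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot_named("not an ikfa_model file" =
                    identical(obj$type, "ikfa_model"))
  scores <- matrix(as.numeric(obj$taxon_scores), ncol = obj$k)
  rownames(scores) <- obj$taxa
  structure(list(
    taxon_scores = scores,
    rotation = matrix(as.numeric(obj$rotation), ncol = obj$k),
    k = obj$k, quadratic = obj$quadratic, row_norm = obj$row_norm,
    coefficients = vapply(obj$coefficients, function(x) {
      if (is.null(x)) NA_real_ else as.numeric(x)  # aliased terms
    }, numeric(1)),
    taxa = obj$taxa,
    calibration = list(rmse = obj$calibration_rmse)
  ), class = "ikfa_model")
}

#' @rdname coralclim_io
#' @param ensemble An `ann_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  reps <- lapply(ensemble$replicates, function(r) {
    list(weights = r$weights, sse = r$sse,
         replicate_index = r$replicate_index)
  })
  first <- ensemble$replicates[[1]]
  obj <- list(type = "ann_ensemble",
              taxa = ensemble$taxa,
              n_hidden = first$n_hidden,
              x_center = first$x_center, x_scale = first$x_scale,
              y_center = first$y_center, y_scale = first$y_scale,
              config = unclass(ensemble$config),
              n_failed = ensemble$n_failed,
              replicates = reps)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname coralclim_io
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot_named("not an ann_ensemble file" =
                    identical(obj$type, "ann_ensemble"))
  common <- list(n_hidden = obj$n_hidden, taxa = obj$taxa,
                 x_center = unlist(obj$x_center),
                 x_scale = unlist(obj$x_scale),
                 y_center = obj$y_center, y_scale = obj$y_scale,
                 converged = TRUE)
  reps <- lapply(seq_len(nrow(obj$replicates)), function(i) {
    r <- common
    r$weights <- unlist(obj$replicates$weights[i])
    r$sse <- obj$replicates$sse[i]
    r$replicate_index <- obj$replicates$replicate_index[i]
    class(r) <- "ann_replicate"
    r
  })
  cfg <- do.call(ann_config, obj$config[c("n_hidden", "max_iterations",
                                          "max_weights", "n_replicates",
                                          "base_seed", "weight_decay",
                                          "abstol", "reltol", "bootstrap")])
  structure(list(replicates = reps, n_failed = obj$n_failed,
                 taxa = obj$taxa, config = cfg),
            class = "ann_ensemble")
}
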