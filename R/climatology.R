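#' Multi-year monthly series to a 12-month climatology
#'
#' Each climatological month is the mean over included years of that
#' calendar month's values; excluded years (e.g. an anomalous year left out
#' of the reference period) are dropped first. A calendar month with no data
#' after exclusion yields `NA`.
#'
#' @param series Data frame with columns `year`, `month` (1-12), `sst`.
#' @param exclude_years Integer vector of years to drop.
#' @return Numeric vector of 12 climatological monthly means.
#' @export
monthly_climatology <- function(series, exclude_years = integer()) {
  stopifnot_named(
    "series needs year, month, sst columns" =
      all(c("year", "month", "sst") %in% names(series)),
    "month must be in 1..12" = all(series$month %in% 1:12)
  )
  s <- series[!(series$year %in% exclude_years), , drop = FALSE]
  out <- rep(NA_real_, 12)
  if (nrow(s)) {
    m <- tapply(s$sst, factor(s$month, levels = 1:12),
                mean, na.rm = FALSE)
    out <- as.numeric(m)
  }
  out
}

#' Mean SST and seasonal temperature variability of a climatology
#'
#' STV is the absolute annual temperature range: warmest minus coldest
#' climatological month.
#'
#' @param climatology Numeric vector of 12 monthly means.
#' @return Named vector `c(mean_sst, stv)`; `NA` if any month is missing.
#' @export
derive_mean_and_stv <- function(climatology) {
  stopifnot_named("climatology must have 12 values" =
                    length(climatology) == 12)
  if (anyNA(climatology)) return(c(mean_sst = NA_real_, stv = NA_real_))
  c(mean_sst = mean(climatology),
    stv = max(climatology) - min(climatology))
}

#' Build a per-cell climatology field from long-format gridded SST
#'
#' @param sst Long data frame `lat`, `lon`, `year`, `month`, `sst` on a
#'   1-degree grid (coordinates are assigned to cells by floor semantics).
#' @param exclude_years Years excluded from the reference climatology.
#' @return A `clim_field` data frame (cells with any missing climatological
#'   month are dropped).
#' @export
climatology_field <- function(sst, exclude_years = integer()) {
  cell <- assign_cell(sst$lat, sst$lon)
  key <- paste(cell$lat_index, cell$lon_index, sep = ":")
  rows <- lapply(split(seq_len(nrow(sst)), key), function(idx) {
    clim <- monthly_climatology(sst[idx, ], exclude_years)
    if (anyNA(clim)) return(NULL)
    ms <- derive_mean_and_stv(clim)
    out <- data.frame(lat_index = cell$lat_index[idx[1]],
                      lon_index = cell$lon_index[idx[1]])
    out[month_names] <- as.list(clim)
    out$mean_sst <- ms[["mean_sst"]]
    out$stv <- ms[["stv"]]
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no cells with a complete climatology")
  field <- do.call(rbind, rows)
  field$lat <- field$lat_index + 0.5
  field$lon <- field$lon_index + 0.5
  field <- field[order(field$lat_index, field$lon_index),
                 c("lat_index", "lon_index", "lat", "lon", month_names,
                   "mean_sst", "stv")]
  rownames(field) <- NULL
  class(field) <- c("clim_field", "data.frame")
  field
}

#' Pair assemblage cells with their climatology
#'
#' Inner join of an assemblage matrix with a climatology field on the cell
#' id; cells lacking SST (land or missing data) are dropped and recorded.
#'
#' @param matrix An `assemblage_matrix`.
#' @param field A `clim_field`.
#' @return A `calibration_set`: list with `props` (aligned matrix), `cells`
#'   (cell metadata with `lat`), `mean_sst` and `stv` vectors; attribute
#'   `dropped_cells` lists assemblage cells without SST.
#' @export
pair_cells <- function(matrix, field) {
  mk <- paste(matrix$cells$lat_index, matrix$cells$lon_index, sep = ":")
  fk <- paste(field$lat_index, field$lon_index, sep = ":")
  idx <- match(mk, fk)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no assemblage cell has a matching climatology")
  cells <- matrix$cells[keep, , drop = FALSE]
  cells$lat <- cells$lat_index + 0.5
  rownames(cells) <- NULL
  out <- list(props = matrix$props[keep, , drop = FALSE],
              cells = cells,
              taxa = matrix$taxa, rank = matrix$rank,
              genus_map = matrix$genus_map,
              mean_sst = field$mean_sst[idx[keep]],
              stv = field$stv[idx[keep]])
  attr(out, "dropped_cells") <- matrix$cells[!keep, , drop = FALSE]
  structure(out, class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %d cells x %d taxa; SST %.1f-%.1f C\n",
              nrow(x$props), ncol(x$props),
              min(x$mean_sst), max(x$mean_sst)))
  invisible(x)
}
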