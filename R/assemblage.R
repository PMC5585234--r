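#' Filter occurrence records by depth and symbiosis
#'
#' Reef-building, warm-water coral ecology is restricted to shallow,
#' zooxanthellate taxa: records deeper than `max_depth` (boundary inclusive)
#' and, optionally, azooxanthellate records are excluded. Records with
#' missing depth are retained by default with a warning, since depth fields
#' in occurrence databases are sparse.
#'
#' @param records Occurrence data frame with at least `depth_m` and, if
#'   `require_zoox`, `zooxanthellate` columns.
#' @param max_depth Maximum depth in metres (inclusive).
#' @param require_zoox Drop records whose `zooxanthellate` flag is not TRUE.
#' @param keep_missing_depth Retain records with `NA` depth (with a warning)
#'   rather than dropping them.
#' @return The filtered records, with an attribute `dropped` giving counts
#'   by reason (`deep`, `azoox`, `missing_depth`).
#' @export
filter_records <- function(records, max_depth = 60, require_zoox = TRUE,
                           keep_missing_depth = TRUE) {
  stopifnot_named("records must contain a depth_m column" =
                    "depth_m" %in% names(records))
  n0 <- nrow(records)
  missing_depth <- is.na(records$depth_m)
  too_deep <- !missing_depth & records$depth_m > max_depth
  azoox <- if (require_zoox) !(records$zooxanthellate %in% TRUE) else
    rep(FALSE, n0)
  drop_missing <- missing_depth & !keep_missing_depth
  keep <- !too_deep & !azoox & !drop_missing
  if (keep_missing_depth && any(missing_depth & keep)) {
    warning(sum(missing_depth & keep),
            " record(s) with missing depth retained")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(deep = sum(too_deep & !azoox),
                            azoox = sum(azoox),
                            missing_depth = sum(drop_missing))
  out
}

#' Assign coordinates to 1-degree grid cells
#'
#' A cell spans `[lat_index, lat_index + 1) x [lon_index, lon_index + 1)`
#' (floor semantics; boundaries belong to the lower-left-closed cell).
#' Longitudes are first normalized to `[-180, 180)`.
#'
#' @param lat,lon Numeric vectors of coordinates in degrees; `lat` must lie
#'   in `[-90, 90)`.
#' @return Data frame with integer `lat_index` and `lon_index`.
#' @export
assign_cell <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90) || any(lat >= 90)) {
    stop("latitudes must be finite and in [-90, 90)")
  }
  lon <- lon - 360 * floor((lon + 180) / 360)
  data.frame(lat_index = as.integer(floor(lat)),
             lon_index = as.integer(floor(lon)))
}

#' Build a proportional taxon-by-cell assemblage matrix
#'
#' Occurrence counts per taxon per 1-degree cell are converted to row
#' proportions: `p[c, t] = count(t in c) / total count in c`. Proportions are
#' count-based (duplicate records count), not presence/absence; a
#' presence/absence mode is available for robustness checks. Taxa are ordered
#' alphabetically and cells by `(lat_index, lon_index)` so serialization is
#' reproducible.
#'
#' @param records Filtered occurrence data frame with `taxon`, `genus`,
#'   `lat`, `lon`, `epoch` columns.
#' @param rank `"species"` (taxon = `taxon` column) or `"genus"` (records
#'   relabelled by their `genus`).
#' @param presence_only Count each taxon at most once per cell.
#' @return An `assemblage_matrix`: list with `props` (cells x taxa matrix,
#'   rows summing to 1), `cells` (data frame `lat_index`, `lon_index`,
#'   `epoch`), `taxa`, `rank` and `genus_map` (taxon -> genus).
#' @export
build_matrix <- function(records, rank = c("species", "genus"),
                         presence_only = FALSE) {
  rank <- match.arg(rank)
  stopifnot_named(
    "records must have taxon, genus, lat, lon, epoch columns" =
      all(c("taxon", "genus", "lat", "lon", "epoch") %in% names(records)),
    "records must carry a single epoch" =
      length(unique(records$epoch)) <= 1
  )
  taxon <- if (rank == "genus") records$genus else records$taxon
  gm <- tapply(records$genus, taxon, function(g) g[[1]])
  genus_map <- stats::setNames(as.character(gm), dimnames(gm)[[1]])
  cell <- assign_cell(records$lat, records$lon)
  cell_key <- paste(cell$lat_index, cell$lon_index, sep = ":")
  if (presence_only) {
    dup <- duplicated(paste(cell_key, taxon, sep = "|"))
    taxon <- taxon[!dup]
    cell <- cell[!dup, ]
    cell_key <- cell_key[!dup]
  }
  taxa <- sort(unique(taxon))
  cells <- unique(cell)
  cells <- cells[order(cells$lat_index, cells$lon_index), , drop = FALSE]
  rownames(cells) <- NULL
  keys <- paste(cells$lat_index, cells$lon_index, sep = ":")
  counts <- table(factor(cell_key, levels = keys),
                  factor(taxon, levels = taxa))
  props <- unclass(counts) / rowSums(counts)
  dimnames(props) <- list(keys, taxa)
  cells$epoch <- if (nrow(records)) records$epoch[[1]] else character(0)
  structure(list(props = props, cells = cells, taxa = taxa, rank = rank,
                 genus_map = genus_map[taxa]),
            class = "assemblage_matrix")
}

#' @export
print.assemblage_matrix <- function(x, ...) {
  cat(sprintf("<assemblage_matrix> %d cells x %d taxa (rank: %s, epoch: %s)\n",
              nrow(x$props), ncol(x$props), x$rank,
              paste(unique(x$cells$epoch), collapse = "/")))
  invisible(x)
}

# Genus richness of every cell row of an assemblage matrix.
cell_genus_richness <- function(matrix) {
  genus <- if (matrix$rank == "genus") matrix$taxa else
    unname(matrix$genus_map[matrix$taxa])
  occ <- matrix$props > 0
  apply(occ, 1, function(row) length(unique(genus[row])))
}

#' Exclude cells occupied by too few genera
#'
#' Cells dominated by a single genus typically reflect taxonomic sampling
#' foci rather than community composition; cells whose occupied-genus count
#' is below `min_genera` are removed. Taxa are unchanged, so surviving rows
#' keep their proportions (rows are renormalized only when taxa are dropped,
#' which this operation does not do).
#'
#' @param matrix An `assemblage_matrix`.
#' @param min_genera Minimum number of distinct occupied genera per cell.
#' @return The filtered `assemblage_matrix`; an attribute `dropped_cells`
#'   records removed cells.
#' @export
apply_cell_filters <- function(matrix, min_genera = 2) {
  rich <- cell_genus_richness(matrix)
  keep <- rich >= min_genera
  if (!any(keep)) stop("all cells removed by the min-genera filter")
  out <- matrix
  out$props <- matrix$props[keep, , drop = FALSE]
  out$cells <- matrix$cells[keep, , drop = FALSE]
  rownames(out$cells) <- NULL
  attr(out, "dropped_cells") <- matrix$cells[!keep, , drop = FALSE]
  out
}

#' Restrict modern and fossil matrices to their shared taxon pool
#'
#' Transfer functions require the fossil assemblages to be expressed in the
#' calibration taxon space: both matrices are restricted to the taxon
#' intersection (identical column order), rows renormalized to sum to 1, and
#' cells falling below the genus-richness threshold after restriction are
#' re-filtered.
#'
#' @param modern,fossil `assemblage_matrix` objects at the same rank.
#' @param min_genera Genus-richness threshold re-applied after restriction.
#' @return List with elements `modern` and `fossil`.
#' @export
harmonize_taxa <- function(modern, fossil, min_genera = 2) {
  stopifnot_named("matrices must share a rank" = modern$rank == fossil$rank)
  shared <- intersect(modern$taxa, fossil$taxa)
  if (length(shared) == 0) stop("no taxa shared between modern and fossil")
  restrict <- function(m) {
    p <- m$props[, shared, drop = FALSE]
    tot <- rowSums(p)
    keep <- tot > 0
    p <- p[keep, , drop = FALSE] / tot[keep]
    m$props <- p
    m$cells <- m$cells[keep, , drop = FALSE]
    rownames(m$cells) <- NULL
    m$taxa <- shared
    m$genus_map <- m$genus_map[shared]
    apply_cell_filters(m, min_genera)
  }
  list(modern = restrict(modern), fossil = restrict(fossil))
}
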