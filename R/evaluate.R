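#' Anomalies between reconstructed fossil and modern reference values
#'
#' For each fossil cell, the anomaly is the reconstructed (e.g. Last
#' Interglacial) value minus the modern reference at the same cell. The
#' modern reference is the observed climatology, not the coral-modelled
#' modern value — the less circular baseline (a model-vs-model comparison
#' can be made by passing modelled modern values as a `clim_field`).
#'
#' @param predictions Data frame with a `predicted` column, one row per
#'   fossil cell (from [predict_ikfa()] or [predict_ensemble()]).
#' @param cells Data frame of the corresponding fossil cells (`lat_index`,
#'   `lon_index`).
#' @param modern_field `clim_field` supplying the modern reference.
#' @param variable `"mean_sst"` or `"stv"`.
#' @param method Label for the transfer method (`"ann"` or `"ikfa"`).
#' @return An `anomaly_profile` data frame: `lat`, `lat_index`, `lon_index`,
#'   `predicted`, `modern`, `anomaly`, `variable`, `method`. Cells without a
#'   modern reference are dropped and recorded in attribute
#'   `dropped_cells`.
#' @export
compute_anomalies <- function(predictions, cells, modern_field,
                              variable = c("mean_sst", "stv"),
                              method = c("ann", "ikfa")) {
  variable <- match.arg(variable)
  method <- match.arg(method)
  stopifnot_named("one prediction per cell required" =
                    nrow(predictions) == nrow(cells))
  fk <- paste(modern_field$lat_index, modern_field$lon_index, sep = ":")
  ck <- paste(cells$lat_index, cells$lon_index, sep = ":")
  idx <- match(ck, fk)
  keep <- !is.na(idx) & !is.na(predictions$predicted)
  if (!any(keep)) stop("no fossil cell overlaps the modern reference field")
  modern <- modern_field[[variable]][idx[keep]]
  out <- data.frame(
    lat = cells$lat_index[keep] + 0.5,
    lat_index = cells$lat_index[keep],
    lon_index = cells$lon_index[keep],
    predicted = predictions$predicted[keep],
    modern = modern,
    anomaly = predictions$predicted[keep] - modern,
    variable = variable, method = method
  )
  attr(out, "dropped_cells") <- cells[!keep, , drop = FALSE]
  class(out) <- c("anomaly_profile", "data.frame")
  out
}

#' LOESS-smoothed latitudinal profile
#'
#' Local polynomial regression (tricube-weighted, span = fraction of points
#' in each local window) of values against latitude, evaluated on a
#' 1-degree grid across the data range.
#'
#' @param lat Latitudes (degrees).
#' @param values Values (degrees C).
#' @param span Smoothing span in `(0, 1]`.
#' @param degree Local polynomial degree (1 or 2).
#' @return Data frame `lat`, `fit` at 1-degree steps.
#' @export
loess_profile <- function(lat, values, span = 0.8, degree = 2) {
  stopifnot_named(
    "span must be in (0, 1]" = span > 0 && span <= 1,
    "need at least degree + 2 points" = sum(is.finite(values)) >= degree + 2
  )
  fit <- stats::loess(values ~ lat, span = span, degree = degree,
                      family = "gaussian", surface = "direct")
  grid <- seq(floor(min(lat)), ceiling(max(lat)), by = 1)
  data.frame(lat = grid, fit = stats::predict(fit, newdata = data.frame(lat = grid)))
}

#' Latitudinal band means
#'
#' Bands are `width`-degree intervals anchored at multiples of `width`
#' (band of latitude x = `[width * floor(x / width), ... + width)`), so
#' bands tile the latitude axis without overlap and are identical across
#' series — the unit of cross-proxy comparison.
#'
#' @param lat Latitudes of the points (degrees).
#' @param values Anomalies or other values (degrees C).
#' @param width Band width in degrees.
#' @param range Optional length-2 latitude bounds; points outside are
#'   dropped (e.g. `c(-32, 33)` for the reef band).
#' @return Data frame `band_mid`, `band_label`, `mean`, `n` (empty bands in
#'   `range` are reported with `NA` mean).
#' @export
band_means <- function(lat, values, width = 5, range = NULL) {
  ok <- is.finite(lat) & is.finite(values)
  lat <- lat[ok]; values <- values[ok]
  if (!is.null(range)) {
    inb <- lat >= range[1] & lat <= range[2]
    lat <- lat[inb]; values <- values[inb]
    lo <- floor(range[1] / width); hi <- floor(range[2] / width)
  } else {
    lo <- floor(min(lat) / width); hi <- floor(max(lat) / width)
  }
  idx <- seq.int(lo, hi)
  band <- floor(lat / width)
  m <- tapply(values, factor(band, levels = idx), mean)
  n <- tapply(values, factor(band, levels = idx), length)
  data.frame(
    band_mid = idx * width + width / 2,
    band_label = sprintf("[%g, %g)", idx * width, (idx + 1) * width),
    mean = as.numeric(m),
    n = ifelse(is.na(n), 0L, as.integer(n))
  )
}

#' Spearman correlation matrix across anomaly series
#'
#' Pairwise complete-case Spearman rank correlations between band-mean
#' series (model variants, proxy compilations), with two-sided p-values.
#' Pairs sharing fewer than `min_shared` non-missing bands are `NA`. The
#' combined table mirrors the conventional layout: rho in the lower-left
#' triangle, p in the upper-right.
#'
#' @param series Named list of numeric vectors on a common band grid, or a
#'   data frame / matrix with one column per series.
#' @param min_shared Minimum shared non-missing bands per pair.
#' @return List with matrices `rho`, `p`, and `table` (combined layout).
#' @export
spearman_matrix <- function(series, min_shared = 4) {
  if (is.data.frame(series) || is.matrix(series)) {
    series <- as.list(as.data.frame(series))
  }
  nm <- names(series)
  k <- length(series)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(rho) <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      x <- series[[i]]; y <- series[[j]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_shared) next
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman")
      )
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  tab <- rho
  tab[upper.tri(tab)] <- p[upper.tri(p)]
  diag(tab) <- NA
  list(rho = rho, p = p, table = tab)
}

#' Compare anomaly series means across sources
#'
#' One-way ANOVA of band-mean anomalies across sources, plus pairwise
#' two-sided Wilcoxon signed-rank tests on band-matched pairs, with per
#' source means and medians. Series are restricted to a latitude range
#' first (the reef band by default).
#'
#' @param series Named list of band-mean vectors on a common band grid.
#' @param band_mid Band midpoints shared by all series.
#' @param range Latitude bounds applied to the bands.
#' @return List with `anova_p`, `wilcoxon_p` (matrix), `means`, `medians`,
#'   `n_bands`.
#' @export
compare_means <- function(series, band_mid, range = c(-32, 33)) {
  keep <- band_mid >= range[1] & band_mid <= range[2]
  series <- lapply(series, function(x) x[keep])
  nm <- names(series)
  long <- data.frame(
    value = unlist(series, use.names = FALSE),
    source = factor(rep(nm, each = sum(keep)))
  )
  long <- long[is.finite(long$value), ]
  anova_p <- stats::anova(stats::aov(value ~ source, data = long))[["Pr(>F)"]][1]
  k <- length(series)
  wp <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      x <- series[[i]]; y <- series[[j]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 2) next
      if (all(x[ok] == y[ok])) {
        # identical band series: no evidence of a shift, maximal p
        wp[i, j] <- wp[j, i] <- 1
        next
      }
      wt <- suppressWarnings(
        stats::wilcox.test(x[ok], y[ok], paired = TRUE, exact = NULL)
      )
      wp[i, j] <- wp[j, i] <- wt$p.value
    }
  }
  list(anova_p = anova_p, wilcoxon_p = wp,
       means = vapply(series, mean, numeric(1), na.rm = TRUE),
       medians = vapply(series, stats::median, numeric(1), na.rm = TRUE),
       n_bands = sum(keep))
}

#' Read a proxy anomaly compilation
#'
#' @param path CSV with columns `source`, `lat`, `lon`, `anomaly_c`,
#'   `proxy_class` (faunal / chemical / model), `season` (annual / other).
#' @return Data frame of proxy anomaly point estimates.
#' @export
read_proxies <- function(path) {
  px <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "lat", "lon", "anomaly_c", "proxy_class", "season")
  stopifnot_named("proxy CSV missing required columns" =
                    all(need %in% names(px)))
  px
}
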