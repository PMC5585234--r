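#' Synthetic reef world: SST field, species niches, occurrences, anomalies
#'
#' These generators build a self-contained toy planet on a 1-degree grid:
#' a latitudinally graded sea-surface temperature (SST) field with sinusoidal
#' monthly seasonality, a pool of species with thermal niches, binomially
#' sampled occurrence records, and a fossil scenario whose temperature anomaly
#' is known exactly. Every downstream stage of the transfer-function pipeline
#' can therefore be validated against ground truth.
#'
#' @name synthetic_world
NULL

#' Generate a gridded monthly SST climatology
#'
#' Mean SST declines linearly with absolute latitude from an equatorial
#' maximum; the seasonal cycle is a sinusoid whose full annual range (the
#' seasonal temperature variability, STV) grows linearly with absolute
#' latitude. The two hemispheres are in antiphase (austral summer offset by
#' six months).
#'
#' @param lat_extent Half-width of the latitude band in degrees; cells cover
#'   `[-lat_extent, lat_extent)`. Must lie within `[0, 40]`.
#' @param n_lon Number of 1-degree longitude columns (>= 1).
#' @param equator_mean Mean SST at the equator, degrees C.
#' @param pole_gradient Decline of mean SST per degree of absolute latitude
#'   (degrees C per degree latitude, >= 0).
#' @param seasonal_amp_equator Annual temperature range (max month - min
#'   month) at the equator, degrees C (>= 0).
#' @param seasonal_amp_per_degree Increase of the annual range per degree of
#'   absolute latitude (>= 0).
#' @param noise_sd Optional cell-level Gaussian noise added to the monthly
#'   curve (degrees C); 0 gives a deterministic field.
#' @param seed Integer seed, used only when `noise_sd > 0`.
#' @return A `clim_field` data frame with one row per cell: `lat_index`,
#'   `lon_index`, cell-center `lat`/`lon`, monthly means `sst_m1..sst_m12`,
#'   and the derived `mean_sst` and `stv`.
#' @export
make_sst_field <- function(lat_extent = 35, n_lon = 2,
                           equator_mean = 28, pole_gradient = 0.25,
                           seasonal_amp_equator = 1,
                           seasonal_amp_per_degree = 1 / 6,
                           noise_sd = 0, seed = 1L) {
  stopifnot_named(
    "lat_extent must be in [0, 40]" = lat_extent >= 0 && lat_extent <= 40,
    "n_lon must be >= 1" = n_lon >= 1,
    "pole_gradient must be non-negative" = pole_gradient >= 0,
    "seasonal amplitude must be non-negative" =
      seasonal_amp_equator >= 0 && seasonal_amp_per_degree >= 0,
    "noise_sd must be non-negative" = noise_sd >= 0
  )
  lat_index <- seq.int(-ceiling(lat_extent), ceiling(lat_extent) - 1L)
  grid <- expand.grid(lon_index = seq_len(n_lon) - 1L, lat_index = lat_index)
  lat <- grid$lat_index + 0.5
  mean_sst <- equator_mean - pole_gradient * abs(lat)
  amp <- seasonal_amp_equator + seasonal_amp_per_degree * abs(lat)
  # Peak month 8 in the north, 2 in the south: integer peaks make the
  # sampled sinusoid attain exactly +/- amp/2, so stv == amp.
  peak <- ifelse(lat >= 0, 8, 2)
  months <- outer(rep(1, length(lat)), 1:12)
  curve <- mean_sst + (amp / 2) * cospi(2 * (months - peak) / 12)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed))
    curve <- curve + matrix(stats::rnorm(length(curve), sd = noise_sd),
                            nrow = nrow(curve))
  }
  colnames(curve) <- month_names
  field <- data.frame(
    lat_index = grid$lat_index, lon_index = grid$lon_index,
    lat = lat, lon = grid$lon_index + 0.5, curve,
    mean_sst = rowMeans(curve),
    stv = apply(curve, 1, function(x) max(x) - min(x))
  )
  field <- field[order(field$lat_index, field$lon_index), ]
  rownames(field) <- NULL
  class(field) <- c("clim_field", "data.frame")
  field
}

#' Generate a species pool with thermal niches
#'
#' Each species has a unimodal (Gaussian) occupancy response to mean SST or,
#' for a minority fraction, a monotonically increasing (logistic) response —
#' mirroring real coral floras where occupancy of most genera declines with
#' SST while a few families show positive correlations.
#'
#' @param n_species Number of species.
#' @param n_genera Number of genera (<= `n_species`); every genus receives at
#'   least one species.
#' @param optimum_range Length-2 range of thermal optima (degrees C).
#' @param frac_increasing Fraction of species with increasing responses, in
#'   `[0, 0.5)`.
#' @param tolerance_range Range of Gaussian niche breadths (SD, degrees C).
#' @param peak_range Range of peak occupancy probabilities, within `(0, 1]`.
#' @param seed Integer seed; pools are fully deterministic given the seed.
#' @return A data frame of niches: `taxon_id`, `genus_id`, `optimum`,
#'   `tolerance`, `peak_occupancy`, `shape`.
#' @export
make_species_pool <- function(n_species = 30, n_genera = 10,
                              optimum_range = c(18, 30),
                              frac_increasing = 0.2,
                              tolerance_range = c(1.5, 4),
                              peak_range = c(0.3, 0.9),
                              seed = 1L) {
  stopifnot_named(
    "n_genera must be <= n_species" = n_genera <= n_species && n_genera >= 1,
    "frac_increasing must be in [0, 0.5)" =
      frac_increasing >= 0 && frac_increasing < 0.5,
    "optimum_range must be a non-empty interval" =
      length(optimum_range) == 2 && diff(optimum_range) > 0,
    "tolerance_range must be positive" = all(tolerance_range > 0),
    "peak_range must lie in (0, 1]" =
      all(peak_range > 0) && all(peak_range <= 1)
  )
  set.seed(derive_seed(seed))
  # Evenly spaced optima guarantee the range is covered; a small jitter
  # breaks exact symmetry.
  optima <- seq(optimum_range[1], optimum_range[2], length.out = n_species)
  jitter_amp <- diff(optimum_range) / (4 * n_species)
  optima <- optima + stats::runif(n_species, -jitter_amp, jitter_amp)
  n_inc <- round(frac_increasing * n_species)
  shape <- rep("gaussian", n_species)
  if (n_inc > 0) shape[sample.int(n_species, n_inc)] <- "increasing"
  genus <- c(seq_len(n_genera),
             sample.int(n_genera, n_species - n_genera, replace = TRUE))
  pool <- data.frame(
    taxon_id = sprintf("sp%03d", seq_len(n_species)),
    genus_id = sprintf("gen%02d", genus),
    optimum = optima,
    tolerance = stats::runif(n_species, tolerance_range[1], tolerance_range[2]),
    peak_occupancy = stats::runif(n_species, peak_range[1], peak_range[2]),
    shape = shape,
    stringsAsFactors = FALSE
  )
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' Occupancy probability of a niche at a given mean SST
#'
#' Gaussian niches: `peak * exp(-(sst - optimum)^2 / (2 tolerance^2))`.
#' Increasing niches: `peak * plogis((sst - optimum) / tolerance)`.
#'
#' @param niche One row of a species pool (list or single-row data frame).
#' @param sst Numeric vector of mean SST values (degrees C).
#' @return Detection probabilities in `[0, 1]`.
#' @export
occupancy_prob <- function(niche, sst) {
  if (niche$shape == "gaussian") {
    niche$peak_occupancy *
      exp(-(sst - niche$optimum)^2 / (2 * niche$tolerance^2))
  } else {
    niche$peak_occupancy * stats::plogis((sst - niche$optimum) / niche$tolerance)
  }
}

#' Sample occurrence records from a species pool over an SST field
#'
#' Per cell and taxon, the number of detections is
#' `Binomial(effort, occupancy_prob(niche, cell mean SST))`; each detection
#' becomes one occurrence record at the cell center with a depth drawn
#' uniformly from (0, 60] m (so the downstream depth filter is exercised but
#' synthetic records pass it). A contamination fraction with depth > 60 m can
#' be injected to test the filter.
#'
#' @param pool Species pool from [make_species_pool()].
#' @param field `clim_field` from [make_sst_field()] (or [apply_anomaly()]).
#' @param effort Visits per cell (>= 1).
#' @param epoch Epoch label, `"modern"` or `"LIG"`.
#' @param seed Integer seed.
#' @param cell_fraction Fraction of cells surveyed (fossil scenarios are
#'   sparser than modern ones); sampled without replacement.
#' @param deep_fraction Fraction of records whose depth is redrawn from
#'   (60, 200] m, to exercise the depth filter.
#' @return Occurrence data frame with columns `taxon`, `genus`, `rank`,
#'   `lat`, `lon`, `depth_m`, `epoch`, `zooxanthellate`.
#' @export
sample_occurrences <- function(pool, field, effort = 50, epoch = "modern",
                               seed = 1L, cell_fraction = 1,
                               deep_fraction = 0) {
  stopifnot_named(
    "effort must be >= 1" = effort >= 1,
    "cell_fraction must be in (0, 1]" = cell_fraction > 0 && cell_fraction <= 1,
    "deep_fraction must be in [0, 1)" = deep_fraction >= 0 && deep_fraction < 1
  )
  set.seed(derive_seed(seed))
  cells <- field
  if (cell_fraction < 1) {
    keep <- sort(sample.int(nrow(cells), ceiling(cell_fraction * nrow(cells))))
    cells <- cells[keep, ]
  }
  n_cell <- nrow(cells)
  recs <- vector("list", nrow(pool))
  for (i in seq_len(nrow(pool))) {
    niche <- pool[i, ]
    p <- occupancy_prob(niche, cells$mean_sst)
    n_det <- stats::rbinom(n_cell, size = effort, prob = p)
    idx <- rep.int(seq_len(n_cell), n_det)
    if (length(idx) == 0) next
    recs[[i]] <- data.frame(
      taxon = niche$taxon_id, genus = niche$genus_id, rank = "species",
      lat = cells$lat[idx], lon = cells$lon[idx],
      depth_m = 60 * (1 - stats::runif(length(idx))),
      epoch = epoch, zooxanthellate = TRUE,
      stringsAsFactors = FALSE
    )
  }
  occ <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(occ)) {
    occ <- data.frame(taxon = character(), genus = character(),
                      rank = character(), lat = numeric(), lon = numeric(),
                      depth_m = numeric(), epoch = character(),
                      zooxanthellate = logical())
  }
  if (deep_fraction > 0 && nrow(occ) > 0) {
    n_deep <- round(deep_fraction * nrow(occ))
    if (n_deep > 0) {
      ii <- sample.int(nrow(occ), n_deep)
      occ$depth_m[ii] <- stats::runif(n_deep, 60, 200)
    }
  }
  rownames(occ) <- NULL
  occ
}

#' Specify a latitudinally piecewise-linear temperature anomaly
#'
#' The mean-SST shift equals `equatorial_offset` for `|lat| <= inner_lat`,
#' `subtropical_offset` for `|lat| >= outer_lat`, and interpolates linearly
#' in between, so the function is continuous in latitude and symmetric across
#' hemispheres. Seasonal amplitude can additionally be offset per hemisphere.
#'
#' @param equatorial_offset Shift applied within `|lat| <= inner_lat`, deg C.
#' @param subtropical_offset Shift applied beyond `|lat| >= outer_lat`, deg C.
#' @param inner_lat,outer_lat Transition boundaries (degrees, inner < outer).
#' @param stv_offset_north,stv_offset_south Additive change of the annual
#'   temperature range per hemisphere, degrees C.
#' @return An `anomaly_spec` list.
#' @export
anomaly_spec <- function(equatorial_offset = -1, subtropical_offset = 2,
                         inner_lat = 15, outer_lat = 25,
                         stv_offset_north = 0, stv_offset_south = 0) {
  stopifnot_named("inner_lat must be < outer_lat" = inner_lat < outer_lat)
  structure(list(equatorial_offset = equatorial_offset,
                 subtropical_offset = subtropical_offset,
                 inner_lat = inner_lat, outer_lat = outer_lat,
                 stv_offset_north = stv_offset_north,
                 stv_offset_south = stv_offset_south),
            class = "anomaly_spec")
}

#' Evaluate the imposed mean-SST anomaly at given latitudes
#'
#' @param spec An [anomaly_spec()].
#' @param lat Latitudes in degrees.
#' @return The mean-SST shift (degrees C) at each latitude.
#' @export
anomaly_shift <- function(spec, lat) {
  a <- abs(lat)
  w <- pmin(pmax((a - spec$inner_lat) / (spec$outer_lat - spec$inner_lat), 0), 1)
  spec$equatorial_offset +
    w * (spec$subtropical_offset - spec$equatorial_offset)
}

#' Apply a temperature anomaly to a climatology field
#'
#' Shifts each cell's mean SST by the piecewise-linear latitude function and
#' rescales the seasonal amplitude by the hemisphere STV offset, keeping the
#' monthly curve internally consistent (its mean equals the shifted mean, its
#' range equals the shifted STV).
#'
#' @param field A `clim_field`.
#' @param spec An [anomaly_spec()].
#' @return A new `clim_field` with shifted monthly curves.
#' @export
apply_anomaly <- function(field, spec) {
  shift <- anomaly_shift(spec, field$lat)
  stv_off <- ifelse(field$lat >= 0, spec$stv_offset_north,
                    spec$stv_offset_south)
  new_stv <- field$stv + stv_off
  if (any(new_stv < 0)) stop("anomaly would make seasonal range negative")
  scale <- ifelse(field$stv > 0, new_stv / field$stv, 1)
  if (all(shift == 0) && all(scale == 1)) return(field)
  months <- clim_months(field)
  months <- field$mean_sst + (months - field$mean_sst) * scale + shift
  if (any(months < -2)) stop("anomaly yields non-physical SST below -2 C")
  out <- field
  out[, month_names] <- months
  out$mean_sst <- rowMeans(months)
  out$stv <- apply(months, 1, function(x) max(x) - min(x))
  out
}

#' Assemble a full synthetic study from a configuration list
#'
#' Convenience wrapper tying the generators together: builds the modern
#' field, the species pool, modern and fossil (anomaly-shifted) occurrence
#' tables, and returns everything with the imposed anomaly for ground-truth
#' comparison. Fossil sampling uses lower effort and fewer occupied cells,
#' mimicking the sparsity contrast of real fossil archives.
#'
#' @param config List of generator parameters; see [world_config()] for the
#'   defaults and [read_world_config()] for file input.
#' @return A list with `field`, `fossil_field`, `pool`, `modern_occ`,
#'   `fossil_occ`, `anomaly`, and the `config` used.
#' @export
simulate_world <- function(config = world_config()) {
  cfg <- utils::modifyList(world_config(), config)
  field <- make_sst_field(
    lat_extent = cfg$lat_extent, n_lon = cfg$n_lon,
    equator_mean = cfg$equator_mean, pole_gradient = cfg$pole_gradient,
    seasonal_amp_equator = cfg$seasonal_amp_equator,
    seasonal_amp_per_degree = cfg$seasonal_amp_per_degree,
    noise_sd = cfg$noise_sd, seed = cfg$seed
  )
  spec <- anomaly_spec(cfg$equatorial_offset, cfg$subtropical_offset,
                       cfg$inner_lat, cfg$outer_lat,
                       cfg$stv_offset_north, cfg$stv_offset_south)
  fossil_field <- apply_anomaly(field, spec)
  pool <- make_species_pool(cfg$n_species, cfg$n_genera,
                            cfg$optimum_range, cfg$frac_increasing,
                            cfg$tolerance_range, cfg$peak_range,
                            seed = cfg$seed)
  modern_occ <- sample_occurrences(pool, field, effort = cfg$modern_effort,
                                   epoch = "modern",
                                   seed = derive_seed(cfg$seed, 1L))
  fossil_occ <- sample_occurrences(pool, fossil_field,
                                   effort = cfg$fossil_effort, epoch = "LIG",
                                   seed = derive_seed(cfg$seed, 2L),
                                   cell_fraction = cfg$fossil_cell_fraction)
  list(field = field, fossil_field = fossil_field, pool = pool,
       modern_occ = modern_occ, fossil_occ = fossil_occ,
       anomaly = spec, config = cfg)
}

#' Default synthetic-world configuration
#'
#' The study conditions: a 30-species / 10-genus pool over a 70 x 2 cell
#' ocean spanning 35S-35N, equatorial mean 28 C declining 0.25 C per degree,
#' annual range 1 C at the equator rising to 6 C at 30 degrees, modern
#' sampling effort 50 visits per cell, fossil effort 10 over 60% of cells,
#' and an imposed anomaly of -1 C (inner tropics) / +2 C (subtropics).
#'
#' @param ... Overrides of individual entries.
#' @return Named list of generator parameters.
#' @export
world_config <- function(...) {
  cfg <- list(
    lat_extent = 35, n_lon = 2,
    equator_mean = 28, pole_gradient = 0.25,
    seasonal_amp_equator = 1, seasonal_amp_per_degree = 1 / 6,
    noise_sd = 0,
    n_species = 30, n_genera = 10,
    optimum_range = c(18, 30), frac_increasing = 0.2,
    tolerance_range = c(1.5, 4), peak_range = c(0.3, 0.9),
    modern_effort = 50, fossil_effort = 10, fossil_cell_fraction = 0.6,
    equatorial_offset = -1, subtropical_offset = 2,
    inner_lat = 15, outer_lat = 25,
    stv_offset_north = 0, stv_offset_south = 0,
    seed = 42L
  )
  utils::modifyList(cfg, list(...))
}

#' Read a synthetic-world configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults from
#' [world_config()].
#'
#' @param path Path to a YAML key-value file.
#' @return Named list of generator parameters.
#' @export
read_world_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(world_config())
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  utils::modifyList(world_config(), cfg)
}
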