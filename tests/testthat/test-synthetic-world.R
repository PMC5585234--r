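test_that("SST field follows the prescribed latitudinal gradient and seasonality", {
  field <- make_sst_field(lat_extent = 35, n_lon = 1, equator_mean = 28,
                          pole_gradient = 0.25,
                          seasonal_amp_equator = 1,
                          seasonal_amp_per_degree = 1 / 6)
  # linear gradient anchored at the equator
  expect_equal(field$mean_sst, 28 - 0.25 * abs(field$lat), tolerance = 1e-12)
  # gradient function itself: 28 at lat 0, 20.5 at lat 30
  expect_equal(28 - 0.25 * 0, 28)
  expect_equal(28 - 0.25 * 30, 20.5)
  # STV recomputed from the generated monthly curve equals the amplitude law
  months <- as.matrix(field[, paste0("sst_m", 1:12)])
  stv_recomputed <- apply(months, 1, function(x) max(x) - min(x))
  expect_equal(stv_recomputed, 1 + abs(field$lat) / 6, tolerance = 1e-10)
  expect_equal(field$stv, stv_recomputed)
  # monthly means are internally consistent with the stored cell mean
  expect_equal(rowMeans(months), field$mean_sst, tolerance = 1e-12)
  # monotone decline with |lat|
  north <- field[field$lat > 0, ]
  expect_true(all(diff(north$mean_sst[order(north$lat)]) < 0))
  # hemisphere antiphase: warmest month differs by 6 between hemispheres
  warm_n <- which.max(months[field$lat == 10.5, ])
  warm_s <- which.max(months[field$lat == -10.5, ])
  expect_equal(unname(warm_n - warm_s) %% 12, 6)
})

test_that("non-physical field parameters are rejected", {
  expect_error(make_sst_field(seasonal_amp_equator = -1), "non-negative")
  expect_error(make_sst_field(pole_gradient = -0.1), "non-negative")
  expect_error(make_sst_field(lat_extent = 50), "40")
})

test_that("species pool respects counts, partitions and determinism", {
  pool <- make_species_pool(n_species = 30, n_genera = 10,
                            frac_increasing = 0.2, seed = 1)
  expect_equal(nrow(pool), 30)
  expect_equal(sum(pool$shape == "increasing"), 6)
  # genus partition covers all genera and sums to the species count
  sizes <- table(pool$genus_id)
  expect_equal(length(sizes), 10)
  expect_equal(sum(sizes), 30)
  expect_true(all(sizes >= 1))
  # optima cover the requested range
  expect_lt(min(pool$optimum), 18.5)
  expect_gt(max(pool$optimum), 29.5)
  # determinism
  expect_identical(pool, make_species_pool(30, 10, frac_increasing = 0.2,
                                           seed = 1))
  # a different seed gives a different pool
  expect_false(identical(pool$tolerance,
                         make_species_pool(30, 10, seed = 2)$tolerance))
  expect_error(make_species_pool(5, 10), "n_genera")
})

test_that("occupancy probability peaks at the optimum and detection matches it", {
  niche <- list(optimum = 26, tolerance = 2, peak_occupancy = 0.7,
                shape = "gaussian")
  expect_equal(occupancy_prob(niche, 26), 0.7)
  expect_lt(occupancy_prob(niche, 30), 0.7)
  inc <- list(optimum = 24, tolerance = 1, peak_occupancy = 0.8,
              shape = "increasing")
  expect_equal(occupancy_prob(inc, 24), 0.4)  # logistic midpoint
  expect_true(all(diff(occupancy_prob(inc, 18:30)) > 0))
})

test_that("sampled detection frequencies converge to niche probabilities", {
  field <- make_sst_field(lat_extent = 5, n_lon = 1)
  pool <- make_species_pool(n_species = 5, n_genera = 3, seed = 3,
                            optimum_range = c(24, 30))
  effort <- 500
  occ <- sample_occurrences(pool, field, effort = effort, seed = 7)
  cell_key <- paste(floor(occ$lat), floor(occ$lon), sep = ":")
  field_key <- paste(field$lat_index, field$lon_index, sep = ":")
  for (i in seq_len(nrow(pool))) {
    p <- occupancy_prob(pool[i, ], field$mean_sst)
    hits <- table(factor(cell_key[occ$taxon == pool$taxon_id[i]],
                         levels = field_key))
    freq <- as.numeric(hits) / effort
    se <- sqrt(p * (1 - p) / effort)
    expect_true(all(abs(freq - p) <= 3 * se + 1e-12),
                info = pool$taxon_id[i])
  }
})

test_that("occurrence sampling is seeded and depth-bounded", {
  w <- small_world(seed = 5)
  occ2 <- sample_occurrences(w$pool, w$field, effort = 30, epoch = "modern",
                             seed = coralclim:::derive_seed(5L, 1L))
  expect_identical(w$modern_occ, occ2)
  expect_true(all(w$modern_occ$depth_m > 0 & w$modern_occ$depth_m <= 60))
  expect_error(sample_occurrences(w$pool, w$field, effort = 0), "effort")
  deep <- sample_occurrences(w$pool, w$field, effort = 5, seed = 1,
                             deep_fraction = 0.2)
  expect_equal(mean(deep$depth_m > 60), 0.2, tolerance = 0.01)
})

test_that("anomaly is piecewise linear, continuous and exactly recovered", {
  spec <- anomaly_spec(-1, 2, inner_lat = 15, outer_lat = 25)
  expect_equal(anomaly_shift(spec, 0), -1)
  expect_equal(anomaly_shift(spec, c(-10, 10)), c(-1, -1))
  expect_equal(anomaly_shift(spec, 20), -1 + (20 - 15) / 10 * 3)
  expect_equal(anomaly_shift(spec, c(-30, 30)), c(2, 2))
  # continuity at the breakpoints
  eps <- 1e-9
  expect_equal(anomaly_shift(spec, 15 + eps), -1, tolerance = 1e-6)
  expect_equal(anomaly_shift(spec, 25 - eps), 2, tolerance = 1e-6)

  field <- make_sst_field(lat_extent = 35, n_lon = 2)
  shifted <- apply_anomaly(field, spec)
  # round-trip: the mean-SST change equals the imposed function everywhere
  expect_equal(shifted$mean_sst - field$mean_sst,
               anomaly_shift(spec, field$lat), tolerance = 1e-10)
  expect_equal(shifted$stv, field$stv, tolerance = 1e-10)
  # identity spec leaves the field bit-for-bit unchanged
  ident <- apply_anomaly(field, anomaly_spec(0, 0))
  expect_identical(ident, field)
  # STV offsets shift the annual range by hemisphere
  sspec <- anomaly_spec(0, 0, stv_offset_north = 1, stv_offset_south = -0.5)
  sh2 <- apply_anomaly(field, sspec)
  expect_equal(sh2$stv - field$stv,
               ifelse(field$lat >= 0, 1, -0.5), tolerance = 1e-10)
  expect_equal(sh2$mean_sst, field$mean_sst, tolerance = 1e-10)
  # non-physical outcome rejected
  expect_error(apply_anomaly(field, anomaly_spec(-40, -40)), "non-physical")
})

test_that("world simulation is deterministic and config round-trips via YAML", {
  w1 <- small_world(seed = 11)
  w2 <- small_world(seed = 11)
  expect_identical(w1$modern_occ, w2$modern_occ)
  expect_identical(w1$fossil_occ, w2$fossil_occ)
  expect_identical(w1$field, w2$field)
  # fossil table is sparser than modern
  expect_lt(nrow(w1$fossil_occ), nrow(w1$modern_occ))

  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(lat_extent = 12, n_lon = 1, modern_effort = 30,
                        fossil_effort = 10, seed = 11L), cfg_path)
  cfg <- read_world_config(cfg_path)
  w3 <- simulate_world(cfg)
  expect_identical(w1$modern_occ, w3$modern_occ)
  yaml::write_yaml(list(bogus_key = 1), cfg_path)
  expect_error(read_world_config(cfg_path), "unknown config key")
})
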