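test_that("varimax rotation is orthogonal, criterion-improving and matches a grid scan", {
  set.seed(10)
  # k = 1: identity rotation
  L1 <- matrix(rnorm(8), 8, 1)
  v1 <- varimax_rotation(L1)
  expect_identical(v1$rotation, diag(1))
  expect_identical(v1$loadings, L1)

  # axis-aligned block loadings are already varimax-optimal
  block <- rbind(cbind(runif(4, 0.8, 1), 0), cbind(0, runif(4, 0.8, 1)))
  vb <- varimax_rotation(block)
  expect_equal(vb$criterion, varimax_criterion(block), tolerance = 1e-10)

  for (rep in 1:10) {
    L <- matrix(rnorm(12), 6, 2)
    v <- varimax_rotation(L)
    R <- v$rotation
    # orthogonality and consistency
    expect_equal(crossprod(R), diag(2), tolerance = 1e-10)
    expect_equal(L %*% R, v$loadings, tolerance = 1e-12)
    # row communalities preserved
    expect_equal(rowSums(v$loadings^2), rowSums(L^2), tolerance = 1e-10)
    # criterion never decreases, and matches the brute-force angle scan
    expect_gte(v$criterion, varimax_criterion(L) - 1e-12)
    expect_equal(v$criterion, varimax_grid_oracle(L), tolerance = 1e-4)
  }

  # agreement with the independent base-R implementation (raw criterion)
  L <- matrix(rnorm(40), 10, 4)
  v <- varimax_rotation(L)
  ref <- stats::varimax(L, normalize = FALSE, eps = 1e-10)
  expect_equal(v$criterion, varimax_criterion(ref$loadings), tolerance = 1e-8)
})

test_that("pre-rotation rank-k reconstruction equals the truncated SVD", {
  set.seed(20)
  for (rep in 1:10) {
    n <- sample(5:12, 1); p <- sample(3:8, 1)
    X <- matrix(runif(n * p), n, p)
    X <- X / rowSums(X)
    k <- sample(2:min(n - 2, p), 1)
    m <- fit_ikfa(X, env = rnorm(n), k = k, row_norm = "none")
    # loadings via the model's own projection path
    L <- X %*% m$taxon_scores
    expect_equal(L %*% t(m$taxon_scores), svd_truncate(X, k),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("rank-2 archetype mixtures are recovered essentially exactly", {
  am <- archetype_matrix(n_cells = 40, n_taxa = 12, r = 2, seed = 5)
  env <- 20 + 8 * am$mix[, 1]  # linear in the mixing proportion
  m <- fit_ikfa(am$props, env, k = 2, row_norm = "none")
  L <- am$props %*% m$taxon_scores
  expect_lt(max(abs(L %*% t(m$taxon_scores) - am$props)), 1e-8)
  expect_lt(m$calibration$rmse, 1e-6)
  # unit-length scaling still reconstructs the scaled matrix
  mu <- fit_ikfa(am$props, env, k = 2)
  W <- am$props / sqrt(rowSums(am$props^2))
  Lu <- W %*% mu$taxon_scores
  expect_lt(max(abs(Lu %*% t(mu$taxon_scores) - W)), 1e-8)
})

test_that("complete basis and constant environments behave as edge cases demand", {
  set.seed(30)
  X <- matrix(runif(16), 4, 4) + diag(4)
  X <- X / rowSums(X)
  # k = n_taxa on a full-rank square matrix: perfect reconstruction
  m <- fit_ikfa(rbind(X, X[1:2, ] + 0.01), env = rnorm(6), k = 4,
                row_norm = "none")
  Xall <- rbind(X, X[1:2, ] + 0.01)
  L <- Xall %*% m$taxon_scores
  expect_lt(max(abs(L %*% t(m$taxon_scores) - Xall)), 1e-10)

  # constant env: intercept carries everything
  mc <- fit_ikfa(Xall, env = rep(21.5, 6), k = 2)
  expect_equal(unname(mc$coefficients[1]), 21.5, tolerance = 1e-10)
  expect_equal(unname(mc$coefficients[-1]), rep(0, 2), tolerance = 1e-10)

  expect_error(fit_ikfa(Xall, env = rnorm(6), k = 7), "k must satisfy")
})

test_that("calibration predictions are invariant to factor rotation", {
  am <- archetype_matrix(30, 10, r = 3, seed = 6)
  env <- 18 + 10 * am$mix[, 1] + 2 * am$mix[, 2]
  m <- fit_ikfa(am$props, env, k = 3)
  # refit on unrotated loadings: same fitted values (regression absorbs
  # any orthogonal rotation of the factor basis)
  W <- am$props / sqrt(rowSums(am$props^2))
  sv <- svd(W, nu = 3, nv = 3)
  L0 <- W %*% sv$v
  fit0 <- lm.fit(cbind(1, L0), env)
  expect_equal(m$calibration$fitted, env - fit0$residuals, tolerance = 1e-8)
})

test_that("calibration RMSE is non-increasing in the factor count", {
  w <- small_world(seed = 13)
  cal <- pair_cells(apply_cell_filters(build_matrix(filter_records(w$modern_occ))),
                    w$field)
  rmse <- vapply(1:6, function(k) fit_ikfa(cal, "mean_sst", k = k)$calibration$rmse,
                 numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("fossil projection is self-consistent and flags no-analog assemblages", {
  am <- archetype_matrix(25, 8, r = 3, seed = 7)
  env <- 20 + 5 * am$mix[, 1]
  m <- fit_ikfa(am$props, env, k = 3)  # k = matrix rank
  pred <- predict_ikfa(m, am$props)
  expect_equal(pred$predicted, m$calibration$fitted, tolerance = 1e-10)
  expect_true(all(pred$communality >= 1 - 1e-8))
  expect_false(any(pred$no_analog_flag))

  # an assemblage orthogonal to every factor: zero communality, flagged
  ns <- MASS::Null(m$taxon_scores)
  ortho <- matrix(ns[, 1], nrow = 1)
  colnames(ortho) <- m$taxa
  po <- predict_ikfa(m, ortho)
  expect_equal(po$communality, 0, tolerance = 1e-10)
  expect_true(po$no_analog_flag)

  # all-zero fossil row: missing prediction, flagged
  zero <- matrix(0, 1, 8, dimnames = list(NULL, m$taxa))
  pz <- predict_ikfa(m, zero)
  expect_true(is.na(pz$predicted))
  expect_true(pz$no_analog_flag)
})

test_that("fossil SST is recovered from the synthetic anomaly world", {
  w <- study_world(seed = 42)
  run <- run_reconstruction(w, methods = "ikfa", k = 4)
  # subsample the calibration to 60 cells and refit: mean signed error of
  # predicted - true fossil SST stays below 0.5 C
  set.seed(1)
  idx <- sort(sample.int(nrow(run$calibration$props), 60))
  m <- fit_ikfa(run$calibration$props[idx, ], run$calibration$mean_sst[idx],
                k = 4)
  pred <- predict_ikfa(m, run$fossil$props)
  fk <- paste(w$fossil_field$lat_index, w$fossil_field$lon_index, sep = ":")
  ck <- paste(run$fossil$cells$lat_index, run$fossil$cells$lon_index, sep = ":")
  truth <- w$fossil_field$mean_sst[match(ck, fk)]
  expect_lt(abs(mean(pred$predicted - truth)), 0.5)
})

test_that("fitted models survive JSON serialization", {
  am <- archetype_matrix(20, 6, r = 2, seed = 8)
  m <- fit_ikfa(am$props, 20 + 5 * am$mix[, 1], k = 2, quadratic = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_ikfa(m, path)
  m2 <- read_ikfa(path)
  pred1 <- predict_ikfa(m, am$props)
  pred2 <- predict_ikfa(m2, am$props)
  expect_equal(pred2$predicted, pred1$predicted, tolerance = 1e-12)
})
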