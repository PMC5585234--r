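#' Configuration for the neural-network transfer function
#'
#' A single-hidden-layer feed-forward regression network: logistic hidden
#' activation, linear output, squared-error loss minimized by quasi-Newton
#' (BFGS) iteration. The architecture is capped both in hidden units and in
#' total weight count — with `p` inputs and `h` hidden units the network has
#' `(p + 1) h + (h + 1)` weights, which must not exceed `max_weights` (946
#' for 187 species inputs at h = 5, cap 1000; 341 for 66 genus inputs, cap
#' 400). Many replicates differing only in their random initial weights are
#' trained and aggregated by the per-cell median, which is robust to
#' replicates stuck in poor local minima.
#'
#' @param n_hidden Hidden units (>= 1).
#' @param max_iterations Optimizer iteration cap.
#' @param max_weights Total weight-count cap.
#' @param n_replicates Replicates in the ensemble (>= 1).
#' @param base_seed Integer; together with the replicate index it fully
#'   determines a replicate.
#' @param weight_decay L2 penalty on the weights (0 = none).
#' @param abstol Absolute convergence tolerance on the (standardized)
#'   squared-error criterion: training stops once the fit is this good.
#' @param reltol Relative convergence tolerance of the optimizer.
#' @param bootstrap Resample calibration cells with replacement per
#'   replicate (off by default: replicates differ in initialization only).
#' @return An `ann_config` list.
#' @export
ann_config <- function(n_hidden = 5, max_iterations = 100000,
                       max_weights = 1000, n_replicates = 1000,
                       base_seed = 1L, weight_decay = 0,
                       abstol = 1e-4, reltol = 1e-8,
                       bootstrap = FALSE) {
  stopifnot_named(
    "n_hidden must be >= 1" = n_hidden >= 1,
    "n_replicates must be >= 1" = n_replicates >= 1,
    "weight_decay must be non-negative" = weight_decay >= 0
  )
  structure(list(n_hidden = as.integer(n_hidden),
                 max_iterations = as.integer(max_iterations),
                 max_weights = as.integer(max_weights),
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 weight_decay = weight_decay,
                 abstol = abstol, reltol = reltol,
                 bootstrap = isTRUE(bootstrap)),
            class = "ann_config")
}

#' Weight count of a single-hidden-layer network
#'
#' @param n_inputs Input taxa.
#' @param n_hidden Hidden units.
#' @return `(n_inputs + 1) * n_hidden + (n_hidden + 1)`.
#' @export
ann_weight_count <- function(n_inputs, n_hidden) {
  (n_inputs + 1L) * n_hidden + (n_hidden + 1L)
}

# Split a flat weight vector into the two layer matrices.
ann_unpack <- function(w, p, h) {
  n1 <- (p + 1L) * h
  list(W1 = matrix(w[seq_len(n1)], nrow = p + 1L, ncol = h),
       w2 = w[n1 + seq_len(h + 1L)])
}

# SSE objective and analytic gradient on standardized data; X1 = cbind(1, X).
# Pure-R reference versions of the compiled ann_obj_cpp / ann_grad_cpp used
# in training; kept for verification.
ann_objective <- function(w, X1, y, h, decay) {
  p <- ncol(X1) - 1L
  n1 <- (p + 1L) * h
  W1 <- matrix(w[seq_len(n1)], p + 1L, h)
  w2 <- w[n1 + seq_len(h + 1L)]
  a <- 1 / (1 + exp(-(X1 %*% W1)))
  r <- a %*% w2[-1L] + w2[1L] - y
  sum(r * r) + decay * sum(w * w)
}

ann_gradient <- function(w, X1, y, h, decay) {
  p <- ncol(X1) - 1L
  n1 <- (p + 1L) * h
  W1 <- matrix(w[seq_len(n1)], p + 1L, h)
  w2 <- w[n1 + seq_len(h + 1L)]
  a <- 1 / (1 + exp(-(X1 %*% W1)))
  r <- 2 * (a %*% w2[-1L] + w2[1L] - y)
  delta <- (r %*% w2[-1L]) * a * (1 - a)
  c(crossprod(X1, delta), sum(r), crossprod(a, r)) + 2 * decay * w
}

#' Train one network replicate
#'
#' Deterministic given `(base_seed, replicate_index)`: the initial weights
#' are drawn uniformly in `[-0.5, 0.5]` from the derived seed, then refined
#' by BFGS until the relative objective change is negligible or the
#' iteration cap is reached. Inputs and output are standardized internally
#' (constants are returned, so the replicate predicts on the original
#' scale).
#'
#' @param props Cells x taxa proportion matrix.
#' @param env Per-cell environmental values (degrees C).
#' @param config An [ann_config()]; the weight-count invariant is enforced
#'   (violations are refused with the computed count).
#' @param replicate_index Replicate number (>= 1).
#' @return An `ann_replicate` list: weights, standardization constants,
#'   final SSE, convergence flag.
#' @export
train_ann <- function(props, env, config = ann_config(),
                      replicate_index = 1L) {
  X <- as.matrix(props)
  stopifnot_named(
    "need at least 2 calibration cells" = nrow(X) >= 2,
    "env must match calibration cells" = length(env) == nrow(X)
  )
  p <- ncol(X)
  h <- config$n_hidden
  nw <- ann_weight_count(p, h)
  if (nw > config$max_weights) {
    stop(sprintf("network needs %d weights, exceeding the cap of %d",
                 nw, config$max_weights))
  }
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(env)
  y_scale <- stats::sd(env)
  if (is.na(y_scale) || y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (env - y_center) / y_scale
  set.seed(derive_seed(config$base_seed, replicate_index))
  if (config$bootstrap) {
    idx <- sample.int(nrow(Xs), replace = TRUE)
    Xs <- Xs[idx, , drop = FALSE]
    ys <- ys[idx]
  }
  w0 <- stats::runif(nw, -0.5, 0.5)
  X1 <- cbind(1, Xs)
  opt <- ann_train_cpp(w0, X1, ys, h, config$weight_decay,
                       config$max_iterations, abstol = config$abstol,
                       reltol = config$reltol)
  structure(list(weights = drop(opt$par), n_hidden = h, taxa = colnames(X),
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 sse = opt$value, converged = opt$convergence == 0,
                 replicate_index = as.integer(replicate_index)),
            class = "ann_replicate")
}

#' Predict from a single network replicate
#'
#' @param object An `ann_replicate`.
#' @param newdata Cells x taxa matrix (columns matched by name, zero-filled
#'   absences).
#' @param ... Unused.
#' @return Numeric predictions on the original environmental scale.
#' @export
predict.ann_replicate <- function(object, newdata, ...) {
  X <- align_taxa(as.matrix(newdata), object$taxa)
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  wm <- ann_unpack(object$weights, ncol(Xs), object$n_hidden)
  a <- stats::plogis(cbind(1, Xs) %*% wm$W1)
  drop(cbind(1, a) %*% wm$w2) * object$y_scale + object$y_center
}

#' Train an ensemble of network replicates
#'
#' Replicates share architecture and taxon order and differ only in their
#' seeded weight initialization (optionally also a bootstrap resample).
#' Non-converged replicates are dropped from aggregation with a recorded
#' count; the run fails if more than 20% fail.
#'
#' @inheritParams train_ann
#' @param env Environmental values, or (for a `calibration_set` in `props`)
#'   the name `"mean_sst"` or `"stv"`.
#' @return An `ann_ensemble` holding the replicates.
#' @export
train_ensemble <- function(props, env = "mean_sst", config = ann_config()) {
  if (inherits(props, "calibration_set")) {
    if (is.character(env)) env <- props[[match.arg(env, c("mean_sst", "stv"))]]
    props <- props$props
  }
  reps <- lapply(seq_len(config$n_replicates), function(i) {
    train_ann(props, env, config, replicate_index = i)
  })
  conv <- vapply(reps, `[[`, logical(1), "converged")
  if (mean(conv) < 0.8) {
    stop(sprintf("%d of %d replicates failed to converge",
                 sum(!conv), length(conv)))
  }
  structure(list(replicates = reps[conv], n_failed = sum(!conv),
                 taxa = reps[[1]]$taxa, config = config),
            class = "ann_ensemble")
}

#' @export
print.ann_ensemble <- function(x, ...) {
  cat(sprintf("<ann_ensemble> %d replicates (%d dropped), %d taxa, %d hidden units\n",
              length(x$replicates), x$n_failed, length(x$taxa),
              x$config$n_hidden))
  invisible(x)
}

#' Ensemble median prediction
#'
#' Per-cell median over converged replicates, with the inter-replicate
#' interquartile range as a spread diagnostic.
#'
#' @param ensemble An `ann_ensemble`.
#' @param newdata Cells x taxa matrix or `assemblage_matrix` (columns
#'   matched by name, zero-filled absences).
#' @return Data frame with `predicted` (median) and `iqr` per cell.
#' @export
predict_ensemble <- function(ensemble, newdata) {
  if (inherits(newdata, "assemblage_matrix")) newdata <- newdata$props
  if (inherits(newdata, "calibration_set")) newdata <- newdata$props
  if (length(ensemble$replicates) == 0) stop("no converged replicates")
  preds <- vapply(ensemble$replicates, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  preds <- matrix(preds, nrow = nrow(newdata))
  data.frame(
    predicted = apply(preds, 1, stats::median),
    iqr = apply(preds, 1, stats::IQR)
  )
}

#' Internal (resubstitution) validation of the network transfer function
#'
#' Trains an ensemble on the calibration set and predicts the same cells,
#' reporting per-cell signed deviations (observed - predicted) with
#' latitude attached for spatial diagnostics, and their median.
#'
#' @param calib A `calibration_set`, or a proportion matrix (then `env` must
#'   be numeric and `lat` supplied).
#' @param env `"mean_sst"`, `"stv"`, or a numeric vector.
#' @param config An [ann_config()].
#' @param lat Optional per-cell latitudes.
#' @return List with `deviations` (data frame `lat`, `observed`,
#'   `predicted`, `deviation`) and `median_deviation`.
#' @export
internal_validation <- function(calib, env = "mean_sst",
                                config = ann_config(), lat = NULL) {
  if (inherits(calib, "calibration_set")) {
    if (is.character(env)) env <- calib[[match.arg(env, c("mean_sst", "stv"))]]
    if (is.null(lat)) lat <- calib$cells$lat
    props <- calib$props
  } else {
    props <- as.matrix(calib)
  }
  if (is.null(lat)) lat <- rep(NA_real_, nrow(props))
  ens <- train_ensemble(props, env, config)
  pred <- predict_ensemble(ens, props)
  dev <- data.frame(lat = lat, observed = env, predicted = pred$predicted,
                    deviation = env - pred$predicted)
  list(deviations = dev, median_deviation = stats::median(dev$deviation),
       ensemble = ens)
}
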