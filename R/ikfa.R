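#' Varimax rotation by pairwise planar (Kaiser) sweeps
#'
#' Maximizes the raw varimax simplicity criterion — the summed column
#' variance of squared loadings — over orthogonal rotations, by cycling
#' through column pairs and solving each planar rotation angle in closed
#' form. Any orthogonal rotation preserves row communalities and the column
#' space; varimax only redistributes variance among factors to sparsify
#' them.
#'
#' @param loadings An `n x k` loadings matrix.
#' @param tol Convergence tolerance on the relative criterion increase per
#'   sweep.
#' @param max_sweeps Maximum number of full pairwise sweeps.
#' @return List with `loadings` (rotated), `rotation` (`k x k` orthogonal,
#'   `loadings %*% rotation`), `criterion`, `sweeps` and a logical
#'   `converged` (FALSE triggers a warning and returns the best found).
#' @export
varimax_rotation <- function(loadings, tol = 1e-10, max_sweeps = 1000L) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  n <- nrow(L)
  R <- diag(k)
  if (k < 2) {
    return(list(loadings = L, rotation = R,
                criterion = varimax_criterion(L), sweeps = 0L,
                converged = TRUE))
  }
  crit <- varimax_criterion(L)
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(max_sweeps)) {
    for (p in 1:(k - 1)) {
      for (q in (p + 1):k) {
        x <- L[, p]; y <- L[, q]
        u <- x^2 - y^2
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * A * B / n
        den <- C - (A^2 - B^2) / n
        if (num == 0 && den == 0) next
        phi <- atan2(num, den) / 4
        cs <- cos(phi); sn <- sin(phi)
        L[, p] <- cs * x + sn * y
        L[, q] <- -sn * x + cs * y
        rp <- R[, p]; rq <- R[, q]
        R[, p] <- cs * rp + sn * rq
        R[, q] <- -sn * rp + cs * rq
      }
    }
    sweeps <- s
    new_crit <- varimax_criterion(L)
    if (new_crit - crit <= tol * max(1, abs(crit))) {
      crit <- new_crit
      converged <- TRUE
      break
    }
    crit <- new_crit
  }
  if (!converged) warning("varimax did not converge in ", max_sweeps,
                          " sweeps; returning best rotation found")
  list(loadings = L, rotation = R, criterion = crit, sweeps = sweeps,
       converged = converged)
}

#' Raw varimax simplicity criterion
#'
#' Sum over factors of the variance of squared loadings,
#' `sum_j [ sum_i L_ij^4 / n - (sum_i L_ij^2 / n)^2 ]`.
#'
#' @param loadings Loadings matrix.
#' @return Scalar criterion value (larger = simpler structure).
#' @export
varimax_criterion <- function(loadings) {
  L2 <- as.matrix(loadings)^2
  sum(colMeans(L2^2) - colMeans(L2)^2)
}

# Canonical factor orientation: order columns by explained variance (sum of
# squared loadings, descending) and flip signs so each factor's
# largest-magnitude taxon score is positive. Makes serialized models
# reproducible across platforms.
canonicalize_factors <- function(sample_loadings, taxon_scores) {
  k <- ncol(sample_loadings)
  ord <- order(colSums(sample_loadings^2), decreasing = TRUE)
  signs <- numeric(k)
  for (j in seq_len(k)) {
    i <- which.max(abs(taxon_scores[, ord[j]]))
    signs[j] <- if (taxon_scores[i, ord[j]] < 0) -1 else 1
  }
  # signed permutation: column j of the output is signs[j] * input column ord[j]
  P <- matrix(0, k, k)
  P[cbind(ord, seq_len(k))] <- signs
  list(sample_loadings = sample_loadings %*% P,
       taxon_scores = taxon_scores %*% P,
       perm = P)
}

# Design matrix for the environmental regression: loadings plus, when
# quadratic, their squares and pairwise products.
ikfa_design <- function(L, quadratic) {
  X <- L
  colnames(X) <- paste0("f", seq_len(ncol(L)))
  if (quadratic) {
    k <- ncol(L)
    extra <- list()
    for (p in seq_len(k)) {
      for (q in p:k) {
        extra[[paste0("f", p, "f", q)]] <- L[, p] * L[, q]
      }
    }
    X <- cbind(X, do.call(cbind, extra))
  }
  X
}

#' Fit an Imbrie-Kipp style factor-analysis transfer function
#'
#' The classic Q-mode recipe: (1) each assemblage row is scaled to unit
#' Euclidean length, so factors represent end-member assemblages; (2) the
#' scaled matrix is decomposed to rank `k` by singular value decomposition,
#' `W = L F'` with orthonormal taxon scores `F`; (3) the sample loadings `L`
#' are varimax-rotated for interpretability; (4) the environmental variable
#' is regressed on the rotated loadings by least squares (optionally with
#' squared and cross terms). Because the regression absorbs any orthogonal
#' rotation, calibration predictions do not depend on the rotation — the
#' rotation matters only for factor interpretation and serialization.
#'
#' @param props Cells x taxa proportion matrix (rows summing to 1), or a
#'   `calibration_set`.
#' @param env Per-cell environmental values (degrees C); required unless
#'   `props` is a `calibration_set` and `env` names one of its variables
#'   (`"mean_sst"` or `"stv"`).
#' @param k Number of factors (1 <= k <= min(cells, taxa)).
#' @param quadratic Add squared and pairwise product terms to the
#'   regression.
#' @param row_norm `"unit_length"` (classic Q-mode) or `"none"` (for
#'   numerical tests).
#' @return An `ikfa_model`: taxon scores (taxa x k, rotated), the rotation,
#'   regression coefficients, fitted values, residuals and calibration RMSE.
#' @export
fit_ikfa <- function(props, env = "mean_sst", k = 5, quadratic = FALSE,
                     row_norm = c("unit_length", "none")) {
  row_norm <- match.arg(row_norm)
  if (inherits(props, "calibration_set")) {
    if (is.character(env)) env <- props[[match.arg(env, c("mean_sst", "stv"))]]
    props <- props$props
  }
  X <- as.matrix(props)
  stopifnot_named(
    "env must have one value per calibration cell" = length(env) == nrow(X),
    "k must satisfy 1 <= k <= min(cells, taxa)" =
      k >= 1 && k <= min(dim(X)),
    "need at least k + 2 calibration cells" = nrow(X) >= k + 2
  )
  norms <- sqrt(rowSums(X^2))
  if (any(norms == 0)) stop("all-zero calibration rows are not allowed")
  W <- if (row_norm == "unit_length") X / norms else X
  sv <- svd(W, nu = k, nv = k)
  F0 <- sv$v                       # taxa x k, orthonormal
  L0 <- W %*% F0                   # sample loadings = U_k D_k
  vr <- varimax_rotation(L0)
  canon <- canonicalize_factors(vr$loadings, F0 %*% vr$rotation)
  L <- canon$sample_loadings
  scores <- canon$taxon_scores
  design <- ikfa_design(L, quadratic)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, design), env)
  fitted <- env - fit$residuals
  model <- structure(list(
    taxon_scores = scores, rotation = vr$rotation %*% canon$perm, k = k,
    quadratic = quadratic, row_norm = row_norm,
    coefficients = fit$coefficients,
    taxa = colnames(X),
    calibration = list(fitted = fitted, residuals = fit$residuals,
                       rmse = sqrt(mean(fit$residuals^2)),
                       env = env, loadings = L),
    varimax_converged = vr$converged
  ), class = "ikfa_model")
  rownames(model$taxon_scores) <- colnames(X)
  model
}

#' @export
print.ikfa_model <- function(x, ...) {
  cat(sprintf("<ikfa_model> k = %d factors over %d taxa; calibration RMSE %.3f\n",
              x$k, length(x$taxa), x$calibration$rmse))
  invisible(x)
}

#' Project fossil assemblages through a fitted IKFA model
#'
#' Fossil rows are aligned to the calibration taxon order (structural zeros
#' for absent taxa), scaled like the calibration rows, projected onto the
#' taxon scores to estimate loadings, and passed through the regression. The
#' communality — the fraction of the scaled row's squared norm captured by
#' the retained factors — diagnoses no-analog assemblages: values below
#' `communality_threshold` are flagged (but retained in the output).
#'
#' @param model An `ikfa_model`.
#' @param fossil Cells x taxa proportion matrix (any taxon set; columns
#'   matched by name) or an `assemblage_matrix`.
#' @param communality_threshold Flagging threshold in `[0, 1]`.
#' @return Data frame per fossil cell: `predicted`, `communality`,
#'   `no_analog_flag` (all-zero rows give `NA` predictions and a flag).
#' @export
predict_ikfa <- function(model, fossil, communality_threshold = 0.5) {
  if (inherits(fossil, "assemblage_matrix")) fossil <- fossil$props
  fossil <- as.matrix(fossil)
  X <- if (is.null(colnames(fossil)) || is.null(model$taxa)) {
    stopifnot_named("fossil taxa must align with the calibration" =
                      ncol(fossil) == nrow(model$taxon_scores))
    fossil
  } else {
    align_taxa(fossil, model$taxa)
  }
  norms <- sqrt(rowSums(X^2))
  ok <- norms > 0
  W <- X
  if (model$row_norm == "unit_length") W[ok, ] <- X[ok, , drop = FALSE] / norms[ok]
  L <- W %*% model$taxon_scores
  design <- cbind(1, ikfa_design(L, model$quadratic))
  coef <- model$coefficients
  coef[is.na(coef)] <- 0  # aliased regression terms contribute nothing
  pred <- drop(design %*% coef)
  denom <- rowSums(W^2)
  communality <- ifelse(ok, rowSums(L^2) / pmax(denom, .Machine$double.eps), 0)
  pred[!ok] <- NA_real_
  data.frame(
    predicted = pred,
    communality = communality,
    no_analog_flag = !ok | communality < communality_threshold
  )
}
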