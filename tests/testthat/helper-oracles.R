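# Independent oracles used across the test suite. Each is a brute-force or
# closed-form computation kept deliberately separate from the package's own
# code paths.

# Best achievable raw varimax criterion for an n x 2 loadings matrix, by a
# dense scan over planar rotation angles (criterion has period pi/2 in the
# angle, up to column sign/permutation).
varimax_grid_oracle <- function(L, step = 0.001) {
  angles <- seq(0, pi / 2, by = step)
  best <- -Inf
  for (phi in angles) {
    R <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
    best <- max(best, varimax_criterion(L %*% R))
  }
  best
}

# Exact two-sided Wilcoxon signed-rank p-value by enumeration of all 2^n
# sign assignments (assumes distinct non-zero differences).
wilcoxon_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Spearman p-value by enumeration of all n! rank
# permutations (assumes no ties).
spearman_enum_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  s_obs <- sum((rx - ry)^2)
  perms <- permutations_all(n)
  s_all <- apply(perms, 1, function(pm) sum((rx - ry[pm])^2))
  min(1, 2 * min(mean(s_all <= s_obs), mean(s_all >= s_obs)))
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Closed-form truncated-SVD reconstruction of a matrix at rank k.
svd_truncate <- function(X, k) {
  sv <- svd(X)
  sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k) %*% t(sv$v[, seq_len(k), drop = FALSE])
}

# Numerical gradient by central differences.
num_gradient <- function(f, w, eps = 1e-6) {
  vapply(seq_along(w), function(i) {
    wp <- wm <- w
    wp[i] <- wp[i] + eps
    wm[i] <- wm[i] - eps
    (f(wp) - f(wm)) / (2 * eps)
  }, numeric(1))
}
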