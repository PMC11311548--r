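# Independent oracles used across test files. These deliberately follow
# different computational routes than the package implementation.

# PLS1 fitted values via the Krylov-subspace closed form (Helland 1988):
# the A-component PLS1 coefficient vector is the least-squares solution
# restricted to span{s, Ms, ..., M^(A-1) s} with s = X'y, M = X'X.
krylov_pls_fitted <- function(X, y, n_lv) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  s <- crossprod(Xc, yc)
  M <- crossprod(Xc)
  # Lanczos-style orthonormal basis of the Krylov space (raw power bases
  # are numerically rank-deficient); re-orthogonalised for stability
  K <- matrix(0, ncol(X), n_lv)
  v <- s / sqrt(sum(s^2))
  for (a in seq_len(n_lv)) {
    K[, a] <- v
    v <- drop(M %*% v)
    for (rep in 1:2)
      v <- v - K[, 1:a, drop = FALSE] %*% crossprod(K[, 1:a, drop = FALSE], v)
    v <- v / sqrt(sum(v^2))
  }
  Z <- Xc %*% K
  theta <- qr.coef(qr(Z), yc)
  drop(Z %*% theta) + ym
}

# Naive double-loop LOOCV: an independent re-implementation of the CV
# bookkeeping around the package's own fit/predict pair.
naive_loocv <- function(X, y, n_lv) {
  n <- nrow(X)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- pls_fit(X[-i, , drop = FALSE], y[-i], n_lv)
    preds[i] <- pls_predict(fit, X[i, , drop = FALSE])
  }
  res <- y - preds
  list(predictions = preds,
       rmse = sqrt(sum(res^2) / n),
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       rpd = sd(y) / sqrt(sum(res^2) / n))
}

# OLS slope/intercept by explicit normal equations (oracle for lm-based
# kinetic fits).
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Small, fast synthetic config for tests that do not need the full grid.
tiny_config <- function(seed = 1L, n_channels = 300L, ...) {
  synthetic_config(seed = seed, n_channels = n_channels, ...)
}

# A noiseless config: every stochastic component switched off.
noiseless_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, noise_sd = c(PV = 0, TBARS = 0),
                   scatter_sd = 0, baseline_slope_sd = 0,
                   baseline_offset_sd = 0, spectral_noise_sd = 0, ...)
}

band_covers <- function(bands, center) {
  any(bands$low_cm1 <= center & bands$high_cm1 >= center)
}

arr_truth_rate <- function(Ea, k0, temp_C) {
  k0 * exp(-Ea / (gas_constant * (temp_C + 273.15)))
}
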