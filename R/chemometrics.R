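# PLS1 regression (NIPALS), cross-validation metrics, VIP band selection
# and PCA -- the multivariate layer linking spectra to oxidation markers.

#' Fit a PLS1 regression model by NIPALS
#'
#' Univariate-response partial least squares with X-deflation. X columns
#' and y are mean-centred (no variance scaling, the standard choice for
#' derivative spectra; disable with `center = FALSE`). For each latent
#' variable: the weight vector is the normalised covariance `X'y`, scores
#' `t = Xw`, loadings `p = X't/t't`, `q = y't/t't`, then X and y are
#' deflated. The regression vector `b = W (P'W)^-1 q` reproduces fitted
#' values as `X_centred b + y_mean`.
#'
#' @param X Numeric matrix, samples x channels, no missing values.
#' @param y Numeric response vector.
#' @param n_lv Number of latent variables (default 10).
#' @param center Mean-centre X and y (default TRUE).
#' @return A `pls_model` with weights `W`, loadings `P`, `q`, scores
#'   `scores`, regression vector `b`, centring vectors and fitted values.
#' @export
pls_fit <- function(X, y, n_lv = 10L, center = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X) || anyNA(y)) stop("pls_fit(): missing values not allowed")
  if (length(y) != n) stop("pls_fit(): length(y) != nrow(X)")
  if (n < 3) stop("pls_fit(): need at least 3 samples")
  if (stats::var(y) < .Machine$double.eps)
    stop("pls_fit(): response has zero variance")
  n_lv <- as.integer(n_lv)
  max_lv <- min(n - 1L, p)
  if (n_lv < 1L || n_lv > max_lv)
    stop(sprintf("pls_fit(): n_lv must be in [1, %d] for this matrix", max_lv))

  x_mean <- if (center) colMeans(X) else numeric(p)
  y_mean <- if (center) mean(y) else 0
  Xa <- sweep(X, 2, x_mean)
  ya <- y - y_mean
  Xc <- Xa

  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  scale0 <- sqrt(sum(Xc^2)) * sqrt(sum(ya^2)) + .Machine$double.eps
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * scale0)
      stop(sprintf(
        "pls_fit(): X deflated to numerical rank %d; maximum usable n_lv is %d",
        a - 1L, a - 1L))
    w <- w / nw
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    if (tt < .Machine$double.eps)
      stop(sprintf("pls_fit(): degenerate score at component %d", a))
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  fitted <- drop(Xc %*% b) + y_mean
  structure(
    list(n_lv = n_lv, x_mean = x_mean, y_mean = y_mean,
         weights = W, x_loadings = P, y_loadings = q, scores = Tm,
         b = b, fitted = fitted, n_samples = n, n_channels = p),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d LVs, %d samples x %d channels\n",
              x$n_lv, x$n_samples, x$n_channels))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param model A [pls_fit()] model.
#' @param X_new Matrix (or vector) with the model's channel count.
#' @return Predicted response vector.
#' @export
pls_predict <- function(model, X_new) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != model$n_channels)
    stop(sprintf("pls_predict(): %d channels supplied, model has %d",
                 ncol(X_new), model$n_channels))
  drop(sweep(X_new, 2, model$x_mean) %*% model$b) + model$y_mean
}

cv_metrics <- function(observed, predicted, scheme) {
  res <- observed - predicted
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- 1 - sum(res^2) / ss_tot
  r2_corr <- if (stats::sd(predicted) > 0)
    stats::cor(observed, predicted)^2 else NA_real_
  structure(
    list(rmse = rmse, r_squared = r2, r_squared_corr = r2_corr,
         rpd = stats::sd(observed) / rmse,
         predictions = predicted, observed = observed, scheme = scheme),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> scheme=%s  RMSE=%.4g  R2=%.4g  RPD=%.4g\n",
              x$scheme, x$rmse, x$r_squared, x$rpd))
  invisible(x)
}

#' Leave-one-out cross-validation of a PLS model
#'
#' Refits the model n times, each time excluding one sample and predicting
#' it. RMSECV is the root mean squared held-out error, R^2 is
#' `1 - SS_res/SS_tot` over held-out predictions, and RPD is
#' `sd(y)/RMSECV`.
#'
#' @inheritParams pls_fit
#' @return A `cv_result` with `scheme = "loocv"`.
#' @export
loocv <- function(X, y, n_lv = 10L, center = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < n_lv + 2) stop("loocv(): need at least n_lv + 2 samples")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      pls_fit(X[-i, , drop = FALSE], y[-i], n_lv, center),
      error = function(e)
        stop(sprintf("loocv(): fit failed with sample %d held out: %s",
                     i, conditionMessage(e)), call. = FALSE))
    preds[i] <- pls_predict(fit, X[i, , drop = FALSE])
  }
  cv_metrics(y, preds, "loocv")
}

#' Auto-prediction (training-set) metrics of a PLS model
#'
#' Fits on all samples and evaluates on the same samples. Auto-prediction
#' metrics are optimistic relative to cross-validation and are reported
#' alongside LOOCV for comparability.
#'
#' @inheritParams pls_fit
#' @return A `cv_result` with `scheme = "auto"`.
#' @export
auto_predict <- function(X, y, n_lv = 10L, center = TRUE) {
  fit <- pls_fit(X, y, n_lv, center)
  cv_metrics(as.numeric(y), fit$fitted, "auto")
}

#' Variable importance in projection (VIP) scores
#'
#' Wold's VIP: `VIP_j = sqrt( p * sum_a[ SSY_a (w_ja/||w_a||)^2 ] /
#' sum_a SSY_a )` with `SSY_a = q_a^2 t_a't_a`. The mean of the squared
#' scores is 1 by construction, which motivates the conventional
#' `VIP >= 1` selection threshold. Components with zero score norm are
#' dropped with a warning.
#'
#' @param model A fitted [pls_fit()] model.
#' @param threshold Selection threshold stored with the result (default 1).
#' @return A `vip_result` with per-channel `scores` and the `threshold`.
#' @export
vip_scores <- function(model, threshold = 1) {
  stopifnot(inherits(model, "pls_model"))
  tt <- colSums(model$scores^2)
  keep <- tt > 0
  if (!all(keep))
    warning(sprintf("vip_scores(): dropping %d degenerate component(s)",
                    sum(!keep)))
  ssy <- (model$y_loadings^2 * tt)[keep]
  Wn <- model$weights[, keep, drop = FALSE]
  Wn <- sweep(Wn, 2, sqrt(colSums(Wn^2)), "/")
  p <- model$n_channels
  scores <- sqrt(p * drop(Wn^2 %*% ssy) / sum(ssy))
  structure(list(scores = scores, threshold = threshold),
            class = "vip_result")
}

#' Contiguous wavenumber bands above a VIP threshold
#'
#' Finds maximal runs of consecutive channels whose VIP score meets the
#' threshold and reports them as `[low, high]` wavenumber intervals in
#' descending-wavenumber order (the reporting convention of the IR
#' literature).
#'
#' @param vip A `vip_result` from [vip_scores()], or a numeric score
#'   vector.
#' @param wavenumbers Ascending wavenumber grid aligned with the scores.
#' @param threshold Selection threshold; defaults to the one stored in
#'   `vip` (or 1).
#' @return Data frame with columns `low_cm1`, `high_cm1`, `n_channels`,
#'   possibly empty.
#' @export
select_bands <- function(vip, wavenumbers, threshold = NULL) {
  scores <- if (inherits(vip, "vip_result")) vip$scores else as.numeric(vip)
  if (is.null(threshold))
    threshold <- if (inherits(vip, "vip_result")) vip$threshold else 1
  if (length(scores) != length(wavenumbers))
    stop("select_bands(): scores and wavenumbers differ in length")
  sel <- scores >= threshold
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(low_cm1 = wavenumbers[starts[keep]],
                    high_cm1 = wavenumbers[ends[keep]],
                    n_channels = r$lengths[keep])
  out[order(-out$high_cm1), , drop = FALSE]
}

#' Principal component analysis by SVD
#'
#' Column mean-centring (optionally unit-variance scaling) followed by
#' singular value decomposition. Explained-variance percentages come from
#' the squared singular values.
#'
#' @param X Numeric matrix, samples x variables.
#' @param n_components Number of components to keep; default
#'   `min(n - 1, p)`.
#' @param center,scale. Passed to [scale()]. Defaults: centre, no scaling.
#' @return A `pca_result` with `scores`, `loadings` and
#'   `explained_variance_pct` (non-increasing, for the kept components).
#' @export
pca <- function(X, n_components = NULL, center = TRUE, scale. = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  max_pc <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- max_pc
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > max_pc)
    stop(sprintf("pca(): n_components must be in [1, %d]", max_pc))
  Xc <- scale(X, center = center, scale = scale.)
  s <- svd(Xc, nu = n_components, nv = n_components)
  var_pct <- 100 * s$d^2 / sum(s$d^2)
  scores <- s$u %*% diag(s$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(X)
  colnames(scores) <- sprintf("PC%d", seq_len(n_components))
  loadings <- s$v
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- colnames(scores)
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_pct = var_pct[seq_len(n_components)],
         total_components = length(s$d)),
    class = "pca_result")
}

#' Flag cross-validation outliers by robust residual scale
#'
#' Deterministic flagging rule: a sample is flagged when its held-out
#' residual exceeds 3 times the robust residual scale (median absolute
#' deviation scaled by 1.4826). Samples are only ever flagged, never
#' silently removed.
#'
#' @param cv A `cv_result` (typically from [loocv()]).
#' @param k Multiplier on the robust scale (default 3).
#' @return Integer indices of flagged samples (possibly empty).
#' @export
flag_outliers <- function(cv, k = 3) {
  stopifnot(inherits(cv, "cv_result"))
  res <- cv$observed - cv$predictions
  scale <- stats::mad(res, constant = 1.4826)
  if (scale == 0) return(integer(0))
  which(abs(res) > k * scale)
}

#' Select the number of latent variables by minimum RMSECV
#'
#' Convenience selector: runs [loocv()] for 1..`max_lv` latent variables
#' and returns the count minimising RMSECV.
#'
#' @inheritParams pls_fit
#' @param max_lv Largest number of latent variables to try.
#' @return List with `n_lv` (the minimiser) and `rmsecv` (the profile).
#' @export
select_n_lv <- function(X, y, max_lv = 10L, center = TRUE) {
  rmse <- vapply(seq_len(max_lv),
                 function(a) loocv(X, y, a, center)$rmse, 0)
  list(n_lv = which.min(rmse), rmsecv = rmse)
}
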