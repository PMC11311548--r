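# Spectral container and pretreatments: standard normal variate and
# Savitzky-Golay derivative, the two transforms applied before PLS.

#' Construct a spectral dataset
#'
#' Container for a samples x wavenumbers absorbance matrix plus per-sample
#' metadata and an ordered log of applied preprocessing transforms. The
#' wavenumber grid must be strictly increasing and match the number of
#' matrix columns; missing values are not allowed.
#'
#' @param wavenumbers Strictly increasing numeric grid, cm^-1.
#' @param absorbance Numeric matrix, one row per sample, one column per
#'   wavenumber. Row names are used as sample ids if `metadata` is absent.
#' @param metadata Data frame with one row per sample; expected columns
#'   `sample_id`, `process`, `temperature_C`, `day`, `replicate` (extra
#'   columns are kept).
#' @param preprocessing_log List of applied transforms (name + parameters),
#'   in application order.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavenumbers, absorbance, metadata = NULL,
                             preprocessing_log = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  if (length(wavenumbers) != ncol(absorbance))
    stop("spectral_dataset(): channel count != wavenumber count")
  if (any(diff(wavenumbers) <= 0))
    stop("spectral_dataset(): wavenumbers must be strictly increasing")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("spectral_dataset(): absorbance contains missing/non-finite values")
  if (is.null(metadata)) {
    ids <- rownames(absorbance)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(absorbance)))
    metadata <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  if (nrow(metadata) != nrow(absorbance))
    stop("spectral_dataset(): metadata rows != spectra rows")
  if (!"sample_id" %in% names(metadata))
    stop("spectral_dataset(): metadata must contain a sample_id column")
  rownames(absorbance) <- metadata$sample_id
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         metadata = metadata, preprocessing_log = preprocessing_log),
    class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d channels, %.1f-%.1f cm^-1\n",
              nrow(x$absorbance), ncol(x$absorbance),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$preprocessing_log))
    cat("  preprocessing:",
        paste(vapply(x$preprocessing_log, `[[`, "", "name"), collapse = " -> "),
        "\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$absorbance)

#' Standard normal variate (SNV) scatter correction
#'
#' Each spectrum is independently centred to mean 0 and scaled to unit
#' sample standard deviation (n-1 denominator). SNV removes per-spectrum
#' multiplicative scatter and additive offset: any affine transform
#' `a*x + b` (a > 0) of a spectrum has the same SNV output.
#'
#' @param dataset A [spectral_dataset()]. Every spectrum must have
#'   non-zero standard deviation.
#' @return The transformed dataset, with `snv` appended to the log.
#' @export
snv <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  A <- dataset$absorbance
  m <- rowMeans(A)
  s <- apply(A, 1, stats::sd)
  bad <- which(s == 0)
  if (length(bad))
    stop(sprintf("snv(): constant spectrum (sd = 0) for sample '%s'",
                 dataset$metadata$sample_id[bad[1]]))
  A <- (A - m) / s
  spectral_dataset(dataset$wavenumbers, A, dataset$metadata,
                   c(dataset$preprocessing_log, list(list(name = "snv"))))
}

# Least-squares polynomial design matrix at offsets x (local coordinates)
sg_design <- function(x, polyorder) outer(x, 0:polyorder, `^`)

# Row matrix evaluating the first derivative of a fitted polynomial
# (coefficients c0..cP) at offsets d
sg_deriv_eval <- function(d, polyorder) {
  V <- matrix(0, length(d), polyorder + 1)
  for (j in seq_len(polyorder)) V[, j + 1] <- j * d^(j - 1)
  V
}

#' Savitzky-Golay first derivative
#'
#' First derivative with respect to the physical wavenumber axis (units:
#' absorbance per cm^-1), computed by local polynomial least squares on a
#' sliding window. Interior channels use the central convolution weights;
#' the first and last `(window-1)/2` channels are handled by fitting the
#' polynomial on the truncated end window and differentiating it at each
#' edge position, so the output grid is identical to the input grid. The
#' filter is exact on polynomials up to degree `polyorder`.
#'
#' @param dataset A [spectral_dataset()] on a uniform grid.
#' @param window Odd window length, `> polyorder` and `<=` channel count.
#'   Default 11.
#' @param polyorder Degree of the local polynomial. Default 2.
#' @return The differentiated dataset, with the transform logged.
#' @export
first_derivative <- function(dataset, window = 11L, polyorder = 2L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  p <- length(dataset$wavenumbers)
  if (window %% 2L != 1L) stop("first_derivative(): window must be odd")
  if (window <= polyorder)
    stop("first_derivative(): window must exceed polyorder")
  if (polyorder < 1L) stop("first_derivative(): polyorder must be >= 1")
  if (window > p)
    stop("first_derivative(): window exceeds channel count")
  dw <- diff(dataset$wavenumbers)
  h <- mean(dw)
  if (max(abs(dw - h)) > 1e-6 * h)
    stop("first_derivative(): wavenumber grid must be uniformly spaced")
  m <- (window - 1L) %/% 2L
  x <- (-m:m) * h
  A <- sg_design(x, polyorder)
  G <- solve(crossprod(A), t(A))      # (polyorder+1) x window projector
  w1 <- G[2L, ]                       # central first-derivative weights
  X <- dataset$absorbance
  n <- nrow(X)
  D <- matrix(0, n, p, dimnames = dimnames(X))
  idx <- (m + 1L):(p - m)
  for (k in seq_len(window))
    D[, idx] <- D[, idx] + w1[k] * X[, idx + (k - m - 1L), drop = FALSE]
  if (m > 0L) {
    # left edge: polynomial fitted on channels 1..window, centred at m+1
    C_left <- G %*% t(X[, 1:window, drop = FALSE])
    D[, 1:m] <- t(sg_deriv_eval(x[1:m], polyorder) %*% C_left)
    # right edge: polynomial on the last `window` channels, centred at p-m
    C_right <- G %*% t(X[, (p - window + 1L):p, drop = FALSE])
    D[, (p - m + 1L):p] <-
      t(sg_deriv_eval(x[(m + 2L):window], polyorder) %*% C_right)
  }
  spectral_dataset(
    dataset$wavenumbers, D, dataset$metadata,
    c(dataset$preprocessing_log,
      list(list(name = "deriv1", window = window, polyorder = polyorder))))
}

transform_registry <- function() {
  list(
    snv = function(ds, params) snv(ds),
    deriv1 = function(ds, params) {
      do.call(first_derivative,
              c(list(dataset = ds),
                params[names(params) %in% c("window", "polyorder")]))
    })
}

#' Apply an ordered preprocessing recipe
#'
#' Applies the named transforms in order. Each recipe entry is either a
#' transform name (`"snv"`, `"deriv1"`) or a list with a `name` element and
#' transform parameters (e.g. `list(name = "deriv1", window = 11,
#' polyorder = 2)`). Transform order matters: SNV-then-derivative and
#' derivative-then-SNV give different matrices on scattered data. The
#' default recipe is SNV followed by the first derivative.
#'
#' @param dataset A [spectral_dataset()].
#' @param recipe Ordered list of transforms.
#' @return The transformed dataset, with every step logged.
#' @export
preprocess <- function(dataset,
                       recipe = list("snv",
                                     list(name = "deriv1", window = 11,
                                          polyorder = 2))) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  reg <- transform_registry()
  for (step in recipe) {
    if (is.character(step)) step <- list(name = step)
    nm <- step$name
    if (is.null(nm) || !nm %in% names(reg))
      stop(sprintf("preprocess(): unknown transform '%s' (known: %s)",
                   if (is.null(nm)) "<missing>" else nm,
                   paste(names(reg), collapse = ", ")))
    dataset <- reg[[nm]](dataset, step[setdiff(names(step), "name")])
  }
  dataset
}
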