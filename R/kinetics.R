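# Oxidation kinetics: per-temperature zero/first-order fits, Arrhenius
# temperature dependence, and closed-form shelf-life prediction.

#' Molar gas constant used throughout the kinetics module
#'
#' 8.3144 J K^-1 mol^-1.
#' @export
gas_constant <- 8.3144

#' Construct an oxidation time series
#'
#' One oxidation response (e.g. PV in meq/kg or TBARS in nmol/g) followed
#' over storage time at a single temperature, with replicate-resolved
#' values. `times_days` and `values` are parallel vectors; replicate ids
#' are optional labels used when resampling fits.
#'
#' @param response Response label, e.g. `"PV"` or `"TBARS"`.
#' @param process Processing label, e.g. `"DP"` or `"HP"`.
#' @param temperature_C Storage temperature in degrees Celsius (converted
#'   internally as K = degC + 273.15). Exactly one of `temperature_C` /
#'   `temperature_K` must be given.
#' @param times_days Storage times in days.
#' @param values Observed response values (same length as `times_days`).
#' @param replicate Optional replicate ids (same length), recycled if
#'   length 1.
#' @param temperature_K Storage temperature in kelvin.
#' @return An object of class `oxidation_series`.
#' @export
oxidation_series <- function(response, process, times_days, values,
                             replicate = NULL, temperature_C = NULL,
                             temperature_K = NULL) {
  if (is.null(temperature_K) == is.null(temperature_C))
    stop("oxidation_series(): give exactly one of temperature_C, temperature_K")
  if (is.null(temperature_K)) temperature_K <- temperature_C + 273.15
  if (temperature_K <= 0) stop("oxidation_series(): temperature_K must be > 0")
  times_days <- as.numeric(times_days)
  values <- as.numeric(values)
  if (length(times_days) != length(values))
    stop("oxidation_series(): times_days and values differ in length")
  if (anyNA(times_days) || anyNA(values))
    stop("oxidation_series(): missing values not allowed")
  if (is.null(replicate)) replicate <- rep(1L, length(values))
  if (length(replicate) == 1L) replicate <- rep(replicate, length(values))
  structure(
    list(response = response, process = process,
         temperature_K = temperature_K,
         times_days = times_days, values = values,
         replicate = replicate),
    class = "oxidation_series")
}

#' @export
print.oxidation_series <- function(x, ...) {
  cat(sprintf("<oxidation_series> %s / %s at %.2f K: %d observations over days [%g, %g]\n",
              x$process, x$response, x$temperature_K, length(x$values),
              min(x$times_days), max(x$times_days)))
  invisible(x)
}

check_fittable <- function(series) {
  if (!inherits(series, "oxidation_series"))
    stop("expected an oxidation_series object")
  if (length(unique(series$times_days)) < 3)
    stop("kinetic fit requires >= 3 distinct timepoints")
  if (length(unique(series$times_days)) == 1L)
    stop("all times identical: singular fit")
  invisible(series)
}

new_kinetic_fit <- function(order, rate_k, intercept, r_squared, n_points,
                            temperature_K, zero_variance = FALSE) {
  structure(
    list(order = order, rate_k = rate_k, intercept = intercept,
         r_squared = r_squared, n_points = n_points,
         temperature_K = temperature_K, zero_variance = zero_variance),
    class = "kinetic_fit")
}

fit_ols_line <- function(x, y) {
  # plain OLS; kept explicit so the numerics are transparent
  fit <- stats::lm.fit(cbind(1, x), y)
  coefs <- fit$coefficients
  fitted <- fit$fitted.values
  if (stats::var(y) < .Machine$double.eps) {
    list(slope = 0, intercept = mean(y), r_squared = 0, zero_variance = TRUE)
  } else {
    r2 <- stats::cor(fitted, y)^2
    if (!is.finite(r2)) r2 <- 0  # fitted values constant (slope ~ 0)
    list(slope = unname(coefs[2]), intercept = unname(coefs[1]),
         r_squared = r2, zero_variance = FALSE)
  }
}

#' Fit a zero-order kinetic model
#'
#' Ordinary least squares of the response on storage time:
#' `y(t) = y0 + k * t`. Replicates are pooled into one regression. The
#' reported R^2 is the squared Pearson correlation between fitted and
#' observed values; a zero-variance (constant) series is reported with
#' `r_squared = 0` and `zero_variance = TRUE`.
#'
#' @param series An [oxidation_series()] with at least 3 distinct
#'   timepoints.
#' @return A `kinetic_fit` with `order = "zero"`, `rate_k` in response
#'   units per day and `intercept` = y0 in response units.
#' @export
fit_zero_order <- function(series) {
  check_fittable(series)
  f <- fit_ols_line(series$times_days, series$values)
  new_kinetic_fit("zero", f$slope, f$intercept, f$r_squared,
                  length(series$values), series$temperature_K,
                  f$zero_variance)
}

#' Fit a first-order kinetic model
#'
#' The integrated first-order law `ln y(t) = ln y0 + k * t`, fitted by OLS
#' of `log(values)` on time. All values must be strictly positive.
#'
#' @param series An [oxidation_series()]; all values > 0.
#' @return A `kinetic_fit` with `order = "first"`, `rate_k` in 1/day and
#'   `intercept` = ln(y0).
#' @export
fit_first_order <- function(series) {
  check_fittable(series)
  bad <- which(series$values <= 0)
  if (length(bad))
    stop(sprintf(
      "fit_first_order(): non-positive value %.6g at day %g (observation %d); log fit undefined",
      series$values[bad[1]], series$times_days[bad[1]], bad[1]))
  f <- fit_ols_line(series$times_days, log(series$values))
  new_kinetic_fit("first", f$slope, f$intercept, f$r_squared,
                  length(series$values), series$temperature_K,
                  f$zero_variance)
}

#' Choose between zero- and first-order fits
#'
#' Returns the order with the higher R^2. Ties go to first order, whose
#' form the closed-form shelf-life expression assumes.
#'
#' @param zero_fit,first_fit `kinetic_fit` objects for the same series.
#' @return `"zero"` or `"first"`.
#' @export
select_order <- function(zero_fit, first_fit) {
  stopifnot(zero_fit$order == "zero", first_fit$order == "first")
  if (zero_fit$r_squared > first_fit$r_squared) "zero" else "first"
}

#' Fit the Arrhenius temperature dependence of rate constants
#'
#' Linearised Arrhenius regression `ln k = ln k0 - Ea / (R T)` by OLS of
#' `log(rate)` on `1/T`. The activation energy is `Ea = -slope * R` and the
#' pre-exponential factor `k0 = exp(intercept)`.
#'
#' @param fits A list of `kinetic_fit` objects of the same kinetic order at
#'   two or more distinct temperatures, all with positive rates.
#' @return An `arrhenius_model` with fields `Ea` (J/mol),
#'   `k0_pre_exponential`, `r_squared`, `order`, and `per_temperature_k`
#'   (named by kelvin).
#' @export
fit_arrhenius <- function(fits) {
  if (!length(fits) || !all(vapply(fits, inherits, TRUE, "kinetic_fit")))
    stop("fit_arrhenius(): expected a list of kinetic_fit objects")
  orders <- unique(vapply(fits, `[[`, "", "order"))
  if (length(orders) != 1L)
    stop("fit_arrhenius(): all fits must share the same kinetic order")
  temps <- vapply(fits, `[[`, 0, "temperature_K")
  rates <- vapply(fits, `[[`, 0, "rate_k")
  if (length(unique(temps)) < 2)
    stop("fit_arrhenius(): need rates at >= 2 distinct temperatures")
  if (any(rates <= 0))
    stop(sprintf("fit_arrhenius(): non-positive rate %.6g at T = %.2f K",
                 rates[rates <= 0][1], temps[rates <= 0][1]))
  f <- fit_ols_line(1 / temps, log(rates))
  structure(
    list(Ea = -f$slope * gas_constant,
         k0_pre_exponential = exp(f$intercept),
         r_squared = if (f$zero_variance) 1 else f$r_squared,
         order = orders,
         R_gas = gas_constant,
         per_temperature_k = stats::setNames(rates, sprintf("%.2f", temps))),
    class = "arrhenius_model")
}

#' Evaluate the Arrhenius rate at a temperature
#'
#' @param model An `arrhenius_model`.
#' @param temperature_K Absolute temperature(s), K.
#' @return Rate constant(s) `k0 * exp(-Ea / (R T))`.
#' @export
arrhenius_rate <- function(model, temperature_K) {
  stopifnot(inherits(model, "arrhenius_model"))
  model$k0_pre_exponential *
    exp(-model$Ea / (gas_constant * temperature_K))
}

#' Predict shelf life from an Arrhenius model
#'
#' First-order form: `SL = (ln(endpoint) - ln(y0)) / k(T)`; zero-order
#' form: `SL = (endpoint - y0) / k(T)`, where
#' `k(T) = k0 exp(-Ea / (R T))`. An endpoint below the initial value gives
#' a negative shelf life, returned with a warning; a rate of zero gives an
#' infinite shelf life with `infinite = TRUE`.
#'
#' @param model An `arrhenius_model` from [fit_arrhenius()].
#' @param y0 Initial response value (> 0 for first order).
#' @param endpoint Response value defining end of shelf life (> 0 for
#'   first order).
#' @param temperature_K Storage temperature, K.
#' @param order Kinetic order to use; defaults to the model's own.
#' @return A `shelf_life_prediction` with `shelf_life_days`,
#'   `temperature_K`, `endpoint_value`, `initial_value`, `order_used`, and
#'   an `infinite` flag.
#' @export
predict_shelf_life <- function(model, y0, endpoint, temperature_K,
                               order = model$order) {
  stopifnot(inherits(model, "arrhenius_model"))
  order <- match.arg(order, c("zero", "first"))
  if (order == "first" && (y0 <= 0 || endpoint <= 0))
    stop("predict_shelf_life(): y0 and endpoint must be > 0 for first order")
  k <- arrhenius_rate(model, temperature_K)
  infinite <- k == 0
  if (infinite) {
    warning("predict_shelf_life(): rate is zero; shelf life is infinite")
    sl <- Inf
  } else {
    sl <- if (order == "first") (log(endpoint) - log(y0)) / k
          else (endpoint - y0) / k
    if (sl < 0)
      warning("predict_shelf_life(): endpoint below initial value; ",
              "negative shelf life returned")
  }
  structure(
    list(temperature_K = temperature_K, endpoint_value = endpoint,
         initial_value = y0, shelf_life_days = sl, order_used = order,
         infinite = infinite),
    class = "shelf_life_prediction")
}

subset_series <- function(series, keep) {
  oxidation_series(series$response, series$process,
                   series$times_days[keep], series$values[keep],
                   replicate = series$replicate[keep],
                   temperature_K = series$temperature_K)
}

fit_order <- function(series, order) {
  if (order == "zero") fit_zero_order(series) else fit_first_order(series)
}

#' Shelf-life summary table over a collection of oxidation series
#'
#' For each process x response group: fits both kinetic orders per
#' temperature (replicates pooled), selects the order with the higher total
#' R^2 (ties to first), fits the Arrhenius model across temperatures, and
#' predicts shelf life at every design temperature from the configured
#' endpoint. The per-cell SD is obtained by refitting the whole chain on
#' each replicate separately. The initial value y0 is the mean of the
#' observed day-0 (earliest-day) values in the group.
#'
#' @param series_list A list of [oxidation_series()] objects covering a
#'   full process x response x temperature design.
#' @param endpoints Named numeric vector of endpoint values per response,
#'   e.g. `c(PV = 2, TBARS = 12)`.
#' @param order `"auto"` (default), `"zero"` or `"first"`.
#' @return A data frame with columns `process`, `response`,
#'   `temperature_C`, `order`, `r_squared`, `shelf_life_days`, `sd_days`,
#'   `endpoint_used` — one row per process x response x temperature.
#' @export
shelf_life_table <- function(series_list, endpoints, order = "auto") {
  stopifnot(is.list(series_list), length(series_list) > 0)
  order <- match.arg(order, c("auto", "zero", "first"))
  key <- vapply(series_list, function(s) paste(s$process, s$response, sep = "\r"), "")
  rows <- list()
  for (grp in unique(key)) {
    members <- series_list[key == grp]
    resp <- members[[1]]$response
    proc <- members[[1]]$process
    if (!resp %in% names(endpoints))
      stop(sprintf("shelf_life_table(): no endpoint given for response '%s'", resp))
    endpoint <- endpoints[[resp]]
    temps <- vapply(members, `[[`, 0, "temperature_K")
    members <- members[order(temps)]
    temps <- sort(temps)

    zero_fits <- lapply(members, fit_zero_order)
    first_fits <- lapply(members, fit_first_order)
    use <- if (order == "auto") {
      r2z <- sum(vapply(zero_fits, `[[`, 0, "r_squared"))
      r2f <- sum(vapply(first_fits, `[[`, 0, "r_squared"))
      if (r2z > r2f) "zero" else "first"
    } else order
    fits <- if (use == "zero") zero_fits else first_fits
    arr <- fit_arrhenius(fits)
    t0 <- min(unlist(lapply(members, `[[`, "times_days")))
    y0 <- mean(unlist(lapply(members, function(s) s$values[s$times_days == t0])))

    # replicate-resampled shelf lives for the SD column
    reps <- unique(unlist(lapply(members, `[[`, "replicate")))
    sl_rep <- matrix(NA_real_, length(reps), length(members))
    if (length(reps) > 1) {
      for (ri in seq_along(reps)) {
        ok <- TRUE
        rfits <- vector("list", length(members))
        for (mi in seq_along(members)) {
          keep <- members[[mi]]$replicate == reps[ri]
          sub <- subset_series(members[[mi]], keep)
          rfits[[mi]] <- tryCatch(fit_order(sub, use), error = function(e) NULL)
          if (is.null(rfits[[mi]])) ok <- FALSE
        }
        if (!ok) next
        rarr <- tryCatch(fit_arrhenius(rfits), error = function(e) NULL)
        if (is.null(rarr)) next
        ry0 <- mean(unlist(lapply(members, function(s)
          s$values[s$times_days == t0 & s$replicate == reps[ri]])))
        for (mi in seq_along(members))
          sl_rep[ri, mi] <- suppressWarnings(
            predict_shelf_life(rarr, ry0, endpoint, temps[mi], use)$shelf_life_days)
      }
    }

    for (mi in seq_along(members)) {
      sl <- suppressWarnings(
        predict_shelf_life(arr, y0, endpoint, temps[mi], use))
      rows[[length(rows) + 1L]] <- data.frame(
        process = proc, response = resp,
        temperature_C = temps[mi] - 273.15,
        order = use,
        r_squared = fits[[mi]]$r_squared,
        shelf_life_days = sl$shelf_life_days,
        sd_days = if (length(reps) > 1)
          stats::sd(sl_rep[, mi], na.rm = TRUE) else NA_real_,
        endpoint_used = endpoint,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$process, out$response, out$temperature_C), , drop = FALSE]
}
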