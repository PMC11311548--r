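# Synthetic accelerated-storage study generator. Emulates the statistical
# structure the downstream analysis assumes -- first/zero-order oxidation
# trajectories with Arrhenius temperature dependence, and stylised FTIR
# spectra whose band amplitudes respond linearly to the latent PV/TBARS
# state -- so every stage is testable against known ground truth.

# Deterministic 31-bit stream seed derived from the config seed and a key,
# so independent generator calls draw from reproducible, distinct streams.
stream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "|")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2147480009
  as.integer((abs(seed) %% 65536) * 32749 + h) %% 2147483647L
}

#' Default kinetic ground truth for the synthetic study
#'
#' First-order kinetics with a 50 kJ/mol activation energy for both
#' processes and both responses. Initial values and pre-exponential
#' factors are chosen so that, over 20 days at 30-50 degC, PV rises within
#' roughly 0.7-3.2 meq/kg and TBARS within roughly 7-27 nmol/g -- the
#' ranges typical of green coffee beans under accelerated storage.
#'
#' @return Nested list `kinetics[[process]][[response]]` with elements
#'   `order`, `Ea` (J/mol), `k0` (1/day for first order), `y0`.
#' @export
default_kinetics <- function() {
  list(
    DP = list(PV = list(order = "first", Ea = 50000, k0 = 6.86e6, y0 = 0.73),
              TBARS = list(order = "first", Ea = 50000, k0 = 6.33e6, y0 = 9.48)),
    HP = list(PV = list(order = "first", Ea = 50000, k0 = 7.37e6, y0 = 0.93),
              TBARS = list(order = "first", Ea = 50000, k0 = 7.71e6, y0 = 6.81)))
}

#' Default synthetic band table
#'
#' Twelve Gaussian bands at the absorbance maxima characteristic of green
#' coffee beans (O-H stretch, olefinic and aliphatic C-H stretches, ester
#' carbonyl, C=C stretch, and the fingerprint region). The oxidation-linked
#' bands at 2854 cm^-1 (aliphatic C-H of the fatty-acid backbone) and
#' 1745 cm^-1 (ester carbonyl of triglycerides) carry non-zero
#' coefficients on the latent PV and TBARS values; the remaining bands are
#' static background chemistry.
#'
#' @return Data frame with columns `center` (cm^-1), `width_sigma`
#'   (cm^-1), `base_amplitude`, `pv_coeff` (absorbance per meq/kg),
#'   `tbars_coeff` (absorbance per nmol/g).
#' @export
default_band_table <- function() {
  data.frame(
    center         = c(3313, 3010, 2925, 2854, 1745, 1645,
                       1458, 1377, 1248, 1157, 1049, 715),
    width_sigma    = 15,
    base_amplitude = c(0.45, 0.12, 0.30, 0.28, 0.35, 0.25,
                       0.18, 0.15, 0.14, 0.20, 0.30, 0.10),
    pv_coeff       = c(0, 0, 0, 0.05, 0.05, 0, 0, 0, 0, 0, 0, 0),
    tbars_coeff    = c(0, 0, 0, 0.005, 0.005, 0, 0, 0, 0, 0, 0, 0))
}

#' Configuration of a synthetic accelerated-storage study
#'
#' The default design mirrors a two-process (DP/HP), three-temperature
#' (30/40/50 degC), five-timepoint (0/5/10/15/20 day) study with three
#' replicates, where day 0 is a single unpackaged control per process
#' shared across temperatures: 2 x 3 x 4 stored samples + 2 controls = 26
#' distinct samples, 78 spectra at 3 replicates. Spectra live on 1869
#' equally spaced channels over 401-4000 cm^-1.
#'
#' @param seed Integer seed; every stochastic draw is derived from it.
#' @param processes Process labels.
#' @param temperatures_C Storage temperatures, degC, strictly increasing.
#' @param days Storage timepoints, days, strictly increasing,
#'   non-negative.
#' @param replicates Positive integer replicate count.
#' @param kinetics Ground-truth kinetic parameters, see
#'   [default_kinetics()].
#' @param noise_sd Gaussian measurement noise on the responses; a scalar
#'   or a named vector per response (default `c(PV = 0.05, TBARS = 0.5)`).
#' @param band_table Band definitions, see [default_band_table()].
#' @param scatter_sd SD of the per-spectrum lognormal multiplicative
#'   scatter (log scale, dimensionless).
#' @param baseline_slope_sd SD of the per-spectrum linear baseline slope,
#'   absorbance per cm^-1.
#' @param baseline_offset_sd SD of the per-spectrum baseline offset,
#'   absorbance.
#' @param spectral_noise_sd SD of the additive channel noise, absorbance.
#' @param n_channels Number of spectral channels (default 1869).
#' @param wn_min,wn_max Wavenumber range, cm^-1 (defaults 401, 4000).
#' @param decline Optional list `list(after_day, rate)` making the mean
#'   trajectory decline linearly after `after_day` (default `NULL`: pure
#'   kinetic growth, which is what the kinetic models assume).
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(seed = 1L,
                             processes = c("DP", "HP"),
                             temperatures_C = c(30, 40, 50),
                             days = c(0, 5, 10, 15, 20),
                             replicates = 3L,
                             kinetics = default_kinetics(),
                             noise_sd = c(PV = 0.05, TBARS = 0.5),
                             band_table = default_band_table(),
                             scatter_sd = 0.05,
                             baseline_slope_sd = 2e-5,
                             baseline_offset_sd = 0.01,
                             spectral_noise_sd = 0.002,
                             n_channels = 1869L,
                             wn_min = 401, wn_max = 4000,
                             decline = NULL) {
  if (any(diff(temperatures_C) <= 0))
    stop("synthetic_config(): temperatures_C must be strictly increasing")
  if (any(diff(days) <= 0))
    stop("synthetic_config(): days must be strictly increasing")
  if (any(days < 0)) stop("synthetic_config(): days must be non-negative")
  if (replicates < 1) stop("synthetic_config(): replicates must be >= 1")
  sds <- c(noise_sd, scatter_sd, baseline_slope_sd, baseline_offset_sd,
           spectral_noise_sd)
  if (any(sds < 0)) stop("synthetic_config(): sd parameters must be >= 0")
  for (proc in names(kinetics))
    for (resp in names(kinetics[[proc]])) {
      kk <- kinetics[[proc]][[resp]]
      if (kk$y0 <= 0)
        stop(sprintf("synthetic_config(): y0 must be > 0 (%s/%s)", proc, resp))
      if (!kk$order %in% c("zero", "first"))
        stop("synthetic_config(): kinetic order must be 'zero' or 'first'")
    }
  if (n_channels < 2) stop("synthetic_config(): n_channels must be >= 2")
  if (wn_min >= wn_max) stop("synthetic_config(): wn_min must be < wn_max")
  if (any(band_table$center < wn_min | band_table$center > wn_max))
    stop("synthetic_config(): band centers must lie within [wn_min, wn_max]")
  if (any(band_table$width_sigma <= 0))
    stop("synthetic_config(): band widths must be > 0")
  structure(
    list(seed = as.integer(seed), processes = processes,
         temperatures_C = temperatures_C, days = days,
         replicates = as.integer(replicates), kinetics = kinetics,
         noise_sd = noise_sd, band_table = band_table,
         scatter_sd = scatter_sd, baseline_slope_sd = baseline_slope_sd,
         baseline_offset_sd = baseline_offset_sd,
         spectral_noise_sd = spectral_noise_sd,
         n_channels = as.integer(n_channels),
         wn_min = wn_min, wn_max = wn_max, decline = decline),
    class = "synthetic_config")
}

noise_for <- function(config, response) {
  ns <- config$noise_sd
  if (!is.null(names(ns)) && response %in% names(ns)) unname(ns[[response]])
  else unname(ns[[1]])
}

kinetic_mean <- function(order, k, y0, t, decline = NULL) {
  y <- if (order == "zero") y0 + k * t else y0 * exp(k * t)
  if (!is.null(decline)) {
    y_break <- if (order == "zero") y0 + k * decline$after_day
               else y0 * exp(k * decline$after_day)
    past <- t > decline$after_day
    y[past] <- y_break - decline$rate * (t[past] - decline$after_day)
  }
  y
}

# Replicate-resolved day-0 control values for one process/response,
# shared across all temperature series of that process.
control_values <- function(config, process, response) {
  kk <- config$kinetics[[process]][[response]]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(config$seed, "control", process, response))
  kk$y0 + stats::rnorm(config$replicates, 0, noise_for(config, response))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate one synthetic oxidation time series
#'
#' The mean trajectory follows the configured kinetic order with rate
#' `k(T) = k0 exp(-Ea / (R T))`; replicate observations are the mean plus
#' i.i.d. Gaussian noise. Day-0 values (if day 0 is in the design) are the
#' shared unpackaged-control draws for that process/response, identical
#' across temperatures. Deterministic for a fixed config.
#'
#' @param config A [synthetic_config()].
#' @param process,response Labels present in `config$kinetics`.
#' @param temperature_C One of `config$temperatures_C`.
#' @return An [oxidation_series()] with `config$replicates` values per
#'   timepoint.
#' @export
generate_oxidation_series <- function(config, process, response,
                                      temperature_C) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!process %in% names(config$kinetics) ||
      !response %in% names(config$kinetics[[process]]))
    stop(sprintf("generate_oxidation_series(): no kinetics for %s/%s",
                 process, response))
  if (!temperature_C %in% config$temperatures_C)
    stop(sprintf("generate_oxidation_series(): %g degC not in the design",
                 temperature_C))
  kk <- config$kinetics[[process]][[response]]
  k <- kk$k0 * exp(-kk$Ea / (gas_constant * (temperature_C + 273.15)))
  sdv <- noise_for(config, response)
  R <- config$replicates
  stored_days <- config$days[config$days > 0]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(config$seed, "oxidation", process, response,
                       temperature_C))
  mean_stored <- kinetic_mean(kk$order, k, kk$y0, stored_days, config$decline)
  vals_stored <- rep(mean_stored, each = R) +
    stats::rnorm(length(stored_days) * R, 0, sdv)
  days <- rep(stored_days, each = R)
  reps <- rep(seq_len(R), times = length(stored_days))
  if (0 %in% config$days) {
    ctrl <- control_values(config, process, response)
    days <- c(rep(0, R), days)
    vals_stored <- c(ctrl, vals_stored)
    reps <- c(seq_len(R), reps)
  }
  oxidation_series(response, process, days, vals_stored,
                   replicate = reps, temperature_C = temperature_C)
}

#' Generate stylised FTIR spectra from latent oxidation states
#'
#' Each spectrum is
#' `scatter * (sum_b amp_b * exp(-(nu - center_b)^2 / (2 sigma_b^2)) +
#' baseline(nu)) + noise`, with band amplitudes
#' `amp_b = base + pv_coeff * PV + tbars_coeff * TBARS`, a per-spectrum
#' linear baseline, lognormal multiplicative scatter and i.i.d. channel
#' noise. Negative amplitudes are clipped to zero with a warning. The
#' wavenumber grid is `n_channels` equally spaced points on
#' `[wn_min, wn_max]`. Deterministic for a fixed config.
#'
#' @param config A [synthetic_config()].
#' @param latent_states Data frame with one row per sample: `sample_id`,
#'   `PV`, `TBARS` plus any metadata columns (`process`, `temperature_C`,
#'   `day`, `replicate`), carried into the dataset metadata.
#' @return A [spectral_dataset()].
#' @export
generate_spectra <- function(config, latent_states) {
  stopifnot(inherits(config, "synthetic_config"),
            is.data.frame(latent_states),
            all(c("sample_id", "PV", "TBARS") %in% names(latent_states)))
  n <- nrow(latent_states)
  bt <- config$band_table
  wn <- seq(config$wn_min, config$wn_max, length.out = config$n_channels)
  amps <- outer(rep(1, n), bt$base_amplitude) +
    outer(latent_states$PV, bt$pv_coeff) +
    outer(latent_states$TBARS, bt$tbars_coeff)
  if (any(amps < 0)) {
    warning("generate_spectra(): negative band amplitude(s) clipped to 0")
    amps[amps < 0] <- 0
  }
  G <- exp(-sweep(outer(bt$center, wn, `-`)^2, 1,
                  2 * bt$width_sigma^2, `/`))   # bands x channels
  clean <- amps %*% G
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(config$seed, "spectra"))
  scatter <- exp(stats::rnorm(n, 0, config$scatter_sd))
  offsets <- stats::rnorm(n, 0, config$baseline_offset_sd)
  slopes <- stats::rnorm(n, 0, config$baseline_slope_sd)
  baseline <- outer(offsets, rep(1, config$n_channels)) +
    outer(slopes, wn - config$wn_min)
  noise <- matrix(stats::rnorm(n * config$n_channels, 0,
                               config$spectral_noise_sd),
                  n, config$n_channels)
  A <- scatter * (clean + baseline) + noise
  meta_cols <- intersect(c("sample_id", "process", "temperature_C", "day",
                           "replicate"), names(latent_states))
  spectral_dataset(wn, A, latent_states[, meta_cols, drop = FALSE])
}

#' Generate a complete synthetic accelerated-storage study
#'
#' Builds the replicate-resolved latent PV/TBARS states for the full
#' design (stored samples per temperature and day, plus the shared day-0
#' controls), the corresponding oxidation series (one per process x
#' temperature x response) and the spectra. Oxidation series and spectra
#' share the same latent states, so the generating truth is recoverable
#' end to end.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_study` list with elements `config`, `oxidation`
#'   (named list of [oxidation_series()]), `spectra`
#'   (a [spectral_dataset()]) and `truth` (latent states + generating
#'   kinetics).
#' @export
make_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  responses <- unique(unlist(lapply(config$kinetics, names)))
  series <- list()
  for (proc in config$processes)
    for (resp in responses)
      for (temp in config$temperatures_C)
        series[[paste(proc, resp, temp, sep = "_")]] <-
          generate_oxidation_series(config, proc, resp, temp)

  # latent states: one row per distinct sample x replicate, in canonical
  # order (controls first, then stored cells by temperature and day)
  rows <- list()
  stored_days <- config$days[config$days > 0]
  has_ctrl <- 0 %in% config$days
  for (proc in config$processes) {
    if (has_ctrl) {
      ctrl <- sapply(responses, function(resp) {
        s <- series[[paste(proc, resp, config$temperatures_C[1], sep = "_")]]
        s$values[s$times_days == 0][order(s$replicate[s$times_days == 0])]
      })
      if (is.null(dim(ctrl)))
        ctrl <- matrix(ctrl, nrow = 1, dimnames = list(NULL, responses))
      for (r in seq_len(config$replicates))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_ctrl_R%d", proc, r), process = proc,
          temperature_C = NA_real_, day = 0, replicate = r,
          PV = ctrl[r, "PV"], TBARS = ctrl[r, "TBARS"],
          stringsAsFactors = FALSE)
    }
    for (temp in config$temperatures_C)
      for (d in stored_days)
        for (r in seq_len(config$replicates)) {
          vals <- vapply(responses, function(resp) {
            s <- series[[paste(proc, resp, temp, sep = "_")]]
            s$values[s$times_days == d & s$replicate == r]
          }, 0)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_T%g_D%g_R%d", proc, temp, d, r),
            process = proc, temperature_C = temp, day = d, replicate = r,
            PV = vals[["PV"]], TBARS = vals[["TBARS"]],
            stringsAsFactors = FALSE)
        }
  }
  latents <- do.call(rbind, rows)
  spectra <- generate_spectra(config, latents)
  structure(
    list(config = config, oxidation = series, spectra = spectra,
         truth = list(latents = latents, kinetics = config$kinetics)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d spectra, %d oxidation series (seed %d)\n",
              nrow(x$spectra$absorbance), length(x$oxidation),
              x$config$seed))
  invisible(x)
}
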