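# End-to-end orchestration: simulate (or load) -> kinetics -> preprocess
# -> PLS/VIP/PCA -> CSV reports + JSON manifest.

# FNV-1a hash of a string, reported as hex; used to fingerprint the run
# configuration in the manifest without external dependencies.
fnv1a <- function(s) {
  # 32-bit xor in two 16-bit halves (bitwXor is limited to signed ints)
  xor32 <- function(a, b) {
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536)) +
      bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536
  }
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- xor32(h, b)
    # 32-bit modular multiply by the FNV prime 16777619, in two halves to
    # stay inside double precision
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

canonical_json <- function(x)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))

#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (optionally loaded from a JSON file
#' with [read_run_config()]) with exactly one input source: a `synthetic`
#' block (arguments to [synthetic_config()]) or an `input` block with
#' paths `spectra`, `metadata`, `oxidation` (+ optional `dialect`).
#' Optional fields with defaults: `responses` (`c("PV","TBARS")`),
#' `endpoints` (`c(PV = 2, TBARS = 12)`), `recipe` (SNV + first
#' derivative), `n_lv` (10), `vip_threshold` (1), `pca_augment` (TRUE),
#' `seed` (1).
#'
#' @param config A list as described above.
#' @return The validated, default-filled configuration.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp)
    stop("run config must contain exactly one of 'synthetic' or 'input'")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$responses)) config$responses <- c("PV", "TBARS")
  if (is.null(config$endpoints)) config$endpoints <- c(PV = 2, TBARS = 12)
  config$endpoints <- unlist(config$endpoints)
  if (!all(config$responses %in% names(config$endpoints)))
    stop("run config: every response needs an endpoint")
  if (is.null(config$recipe))
    config$recipe <- list("snv", list(name = "deriv1", window = 11,
                                      polyorder = 2))
  if (is.null(config$n_lv)) config$n_lv <- 10L
  if (is.null(config$vip_threshold)) config$vip_threshold <- 1
  if (is.null(config$pca_augment)) config$pca_augment <- TRUE
  if (has_inp) {
    need <- c("spectra", "metadata", "oxidation")
    if (!all(need %in% names(config$input)))
      stop("run config input block needs paths: ",
           paste(need, collapse = ", "))
    if (is.null(config$input$dialect)) config$input$dialect <- "wide"
  }
  config
}

#' Read a pipeline run configuration from JSON
#'
#' @param path Path to a JSON document mirroring the fields described in
#'   [validate_run_config()].
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  validate_run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

# Per-sample response vector aligned with the spectra, from the latent
# truth (synthetic) or by joining the oxidation table on the design cell.
response_per_sample <- function(meta, series_list, response) {
  vals <- rep(NA_real_, nrow(meta))
  for (s in series_list) {
    if (s$response != response) next
    tc <- s$temperature_K - 273.15
    for (j in seq_along(s$values)) {
      d <- s$times_days[j]
      hit <- meta$process == s$process & meta$day == d &
        meta$replicate == s$replicate[j] &
        (if (d == 0) TRUE else !is.na(meta$temperature_C) &
           meta$temperature_C == tc)
      vals[hit] <- s$values[j]
    }
  }
  if (anyNA(vals))
    stop(sprintf("no %s value for sample(s): %s", response,
                 paste(meta$sample_id[is.na(vals)], collapse = ", ")))
  vals
}

#' Run the full analysis pipeline
#'
#' Stages: obtain a study (simulate from `config$synthetic`, or load the
#' CSV inputs), fit the shelf-life table, preprocess the spectra, fit PLS
#' models per response (auto-prediction and LOOCV), compute VIP scores and
#' selected bands, run PCA, and write all reports plus a JSON manifest to
#' `out_dir`. All computation happens before any file is written, so a
#' failing stage leaves the output directory untouched. Re-running with an
#' identical configuration reproduces identical files.
#'
#' @param config A run configuration (see [validate_run_config()]) or a
#'   path to its JSON file.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results (`shelf_life`,
#'   `pls_summary`, `vip`, `bands`, `pca`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)

  if (!is.null(config$synthetic)) {
    syn_args <- config$synthetic
    if (is.null(syn_args$seed)) syn_args$seed <- config$seed
    scfg <- do.call(synthetic_config, syn_args)
    study <- make_study(scfg)
    spectra <- study$spectra
    series <- study$oxidation
  } else {
    spectra <- read_spectra_csv(config$input$spectra, config$input$metadata,
                                config$input$dialect)
    series <- read_oxidation_csv(config$input$oxidation)
  }

  shelf <- shelf_life_table(series, config$endpoints)

  pre <- preprocess(spectra, config$recipe)
  X <- pre$absorbance

  pls_rows <- list(); vip_list <- list(); band_list <- list()
  obs_pred <- list()
  resp_values <- list()
  for (resp in config$responses) {
    y <- response_per_sample(spectra$metadata, series, resp)
    resp_values[[resp]] <- y
    cv <- loocv(X, y, config$n_lv)
    ap <- auto_predict(X, y, config$n_lv)
    fit <- pls_fit(X, y, config$n_lv)
    vip <- vip_scores(fit, config$vip_threshold)
    bands <- select_bands(vip, pre$wavenumbers)
    pls_rows[[resp]] <- data.frame(
      response = resp, n = nrow(X),
      processing = paste(vapply(pre$preprocessing_log, `[[`, "", "name"),
                         collapse = "+"),
      n_lv = config$n_lv,
      rmsecv = cv$rmse, r2_cv = cv$r_squared, rpd_cv = cv$rpd,
      rmse_auto = ap$rmse, r2_auto = ap$r_squared, rpd_auto = ap$rpd,
      stringsAsFactors = FALSE)
    vip_list[[resp]] <- data.frame(wavenumber_cm1 = pre$wavenumbers,
                                   vip = vip$scores)
    band_list[[resp]] <- bands
    obs_pred[[resp]] <- data.frame(
      sample_id = spectra$metadata$sample_id, observed = y,
      predicted_loocv = cv$predictions, predicted_auto = ap$predictions)
  }
  pls_summary <- do.call(rbind, pls_rows)
  rownames(pls_summary) <- NULL

  pca_X <- if (isTRUE(config$pca_augment))
    cbind(spectra$absorbance, do.call(cbind, resp_values))
  else spectra$absorbance
  pc <- pca(pca_X, n_components = min(5L, nrow(pca_X) - 1L))

  manifest <- list(
    package = "oxishelf",
    version = as.character(utils::packageVersion("oxishelf")),
    seed = config$seed,
    config = config[setdiff(names(config), NULL)],
    config_hash = fnv1a(canonical_json(config)),
    preprocessing_log = pre$preprocessing_log)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(shelf, file.path(out_dir, "shelf_life.csv"),
                   row.names = FALSE)
  utils::write.csv(pls_summary, file.path(out_dir, "pls_summary.csv"),
                   row.names = FALSE)
  for (resp in config$responses) {
    utils::write.csv(vip_list[[resp]],
                     file.path(out_dir, sprintf("vip_scores_%s.csv", resp)),
                     row.names = FALSE)
    utils::write.csv(band_list[[resp]],
                     file.path(out_dir, sprintf("vip_bands_%s.csv", resp)),
                     row.names = FALSE)
    utils::write.csv(obs_pred[[resp]],
                     file.path(out_dir,
                               sprintf("observed_predicted_%s.csv", resp)),
                     row.names = FALSE)
  }
  pc_df <- data.frame(sample_id = spectra$metadata$sample_id,
                      pc$scores[, 1:2, drop = FALSE])
  utils::write.csv(pc_df, file.path(out_dir, "pca_scores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(shelf_life = shelf, pls_summary = pls_summary,
                 vip = vip_list, bands = band_list, pca = pc,
                 manifest = manifest))
}
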