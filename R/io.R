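# Plain-CSV persistence for spectra (wide/long dialects plus a metadata
# sidecar) and oxidation tables.

#' Write a spectral dataset to CSV
#'
#' Wide dialect: one file with a `wavenumber_cm1` column followed by one
#' column per sample id. Long dialect: `sample_id, wavenumber_cm1,
#' absorbance`. A metadata sidecar (`<basename>_metadata.csv`) and, when
#' the preprocessing log is non-empty, a JSON provenance sidecar
#' (`<basename>_preprocessing.json`) are written alongside.
#'
#' @param dataset A [spectral_dataset()].
#' @param dir Output directory (created if needed).
#' @param dialect `"wide"` (default) or `"long"`.
#' @param basename File stem, default `"spectra"`.
#' @return Invisibly, the paths written.
#' @export
write_spectra_csv <- function(dataset, dir, dialect = c("wide", "long"),
                              basename = "spectra") {
  stopifnot(inherits(dataset, "spectral_dataset"))
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spectra_path <- file.path(dir, paste0(basename, ".csv"))
  meta_path <- file.path(dir, paste0(basename, "_metadata.csv"))
  if (dialect == "wide") {
    df <- data.frame(wavenumber_cm1 = dataset$wavenumbers,
                     t(dataset$absorbance), check.names = FALSE)
    utils::write.csv(df, spectra_path, row.names = FALSE)
  } else {
    ids <- dataset$metadata$sample_id
    df <- data.frame(
      sample_id = rep(ids, each = length(dataset$wavenumbers)),
      wavenumber_cm1 = rep(dataset$wavenumbers, times = length(ids)),
      absorbance = as.vector(t(dataset$absorbance)))
    utils::write.csv(df, spectra_path, row.names = FALSE)
  }
  utils::write.csv(dataset$metadata, meta_path, row.names = FALSE)
  paths <- c(spectra = spectra_path, metadata = meta_path)
  if (length(dataset$preprocessing_log)) {
    log_path <- file.path(dir, paste0(basename, "_preprocessing.json"))
    jsonlite::write_json(dataset$preprocessing_log, log_path,
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, log = log_path)
  }
  invisible(paths)
}

#' Read a spectral dataset from CSV
#'
#' Counterpart of [write_spectra_csv()]. A descending wavenumber grid is
#' reversed to ascending with a message. Every sample in the spectra file
#' must have a metadata row; ragged per-sample channel counts in the long
#' dialect are an error.
#'
#' @param path Path to the spectra CSV.
#' @param metadata_path Path to the metadata sidecar CSV.
#' @param dialect `"wide"` (default) or `"long"`.
#' @return A [spectral_dataset()].
#' @export
read_spectra_csv <- function(path, metadata_path,
                             dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("spectra file not found: %s", path))
  if (!file.exists(metadata_path))
    stop(sprintf("metadata file not found: %s", metadata_path))
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("read_spectra_csv(): metadata lacks a sample_id column")
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (names(raw)[1] != "wavenumber_cm1")
      stop("read_spectra_csv(): wide file must start with wavenumber_cm1")
    wn <- raw$wavenumber_cm1
    A <- t(as.matrix(raw[, -1, drop = FALSE]))
    ids <- rownames(A)
  } else {
    need <- c("sample_id", "wavenumber_cm1", "absorbance")
    if (!all(need %in% names(raw)))
      stop("read_spectra_csv(): long file needs columns ",
           paste(need, collapse = ", "))
    ids <- unique(raw$sample_id)
    counts <- table(raw$sample_id)
    if (length(unique(counts)) != 1L)
      stop("read_spectra_csv(): ragged channel counts across samples")
    wn <- raw$wavenumber_cm1[raw$sample_id == ids[1]]
    A <- do.call(rbind, lapply(ids, function(id) {
      sub <- raw[raw$sample_id == id, ]
      if (!isTRUE(all.equal(sub$wavenumber_cm1, wn)))
        stop(sprintf("read_spectra_csv(): grid mismatch for sample '%s'", id))
      sub$absorbance
    }))
    rownames(A) <- ids
  }
  if (all(diff(wn) < 0)) {
    message("read_spectra_csv(): descending grid reversed to ascending")
    wn <- rev(wn)
    A <- A[, rev(seq_len(ncol(A))), drop = FALSE]
  }
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing))
    stop(sprintf("read_spectra_csv(): no metadata for sample(s): %s",
                 paste(missing, collapse = ", ")))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  spectral_dataset(wn, A, meta)
}

#' Write oxidation series to a tidy CSV
#'
#' Columns: `process, response, temperature_C, day, replicate, value`.
#'
#' @param series_list A list of [oxidation_series()] (e.g.
#'   `study$oxidation`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_oxidation_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s)
    data.frame(process = s$process, response = s$response,
               temperature_C = s$temperature_K - 273.15,
               day = s$times_days, replicate = s$replicate,
               value = s$values, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read oxidation series from a tidy CSV
#'
#' @param path CSV with columns `process, response, temperature_C, day,
#'   replicate, value`.
#' @return Named list of [oxidation_series()], one per process x response
#'   x temperature.
#' @export
read_oxidation_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("oxidation file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("process", "response", "temperature_C", "day", "replicate",
            "value")
  if (!all(need %in% names(df)))
    stop("read_oxidation_csv(): need columns ", paste(need, collapse = ", "))
  key <- paste(df$process, df$response, df$temperature_C, sep = "_")
  out <- lapply(split(df, key), function(sub)
    oxidation_series(sub$response[1], sub$process[1], sub$day, sub$value,
                     replicate = sub$replicate,
                     temperature_C = sub$temperature_C[1]))
  out[unique(key)]
}
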