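# Assay arithmetic: conversion of raw wet-lab readings into the derived
# oxidation / quality quantities used by the kinetics and chemometrics
# stages. All functions are vectorised over their measurement arguments.

#' Moisture content on a wet basis
#'
#' Gravimetric moisture content from oven drying to constant weight:
#' `100 * weight_loss / sample_weight`, expressed as percent wet basis.
#'
#' @param weight_loss_g Weight loss on drying, in grams. Must satisfy
#'   `0 <= weight_loss_g <= sample_weight_g`.
#' @param sample_weight_g Initial sample weight, in grams (> 0).
#' @return Moisture content in percent (wet basis), in `[0, 100]`.
#' @examples
#' moisture_percent(0.5, 5)   # 10 %
#' @export
moisture_percent <- function(weight_loss_g, sample_weight_g) {
  if (any(!is.finite(weight_loss_g)) || any(!is.finite(sample_weight_g)))
    stop("moisture_percent(): inputs must be finite numbers")
  if (any(sample_weight_g <= 0))
    stop("moisture_percent(): sample_weight_g must be > 0")
  if (any(weight_loss_g < 0))
    stop("moisture_percent(): weight_loss_g must be >= 0")
  if (any(weight_loss_g > sample_weight_g))
    stop("moisture_percent(): weight loss exceeds sample weight")
  100 * weight_loss_g / sample_weight_g
}

#' Peroxide value from an iodometric titration
#'
#' Primary lipid-oxidation marker in milliequivalents of peroxide per kg of
#' oil: `PV = 2 * (titre_sample - titre_blank) / oil_mass`. The factor 2
#' folds the thiosulfate normality and unit scaling into a single constant,
#' as is conventional for 0.002 M titrant.
#'
#' A negative result (blank exceeding sample) signals assay failure; it is
#' returned as-is with a warning rather than clipped, so that QC can see it.
#'
#' @param titre_sample_mL Titrant volume for the sample, mL (>= 0).
#' @param titre_blank_mL Titrant volume for the blank, mL (>= 0).
#' @param oil_mass_g Mass of oil titrated, g (> 0).
#' @return Peroxide value in meq peroxide / kg oil.
#' @examples
#' peroxide_value(2.0, 0.5, 1.0)  # 3 meq/kg
#' @export
peroxide_value <- function(titre_sample_mL, titre_blank_mL, oil_mass_g) {
  if (any(oil_mass_g <= 0))
    stop("peroxide_value(): oil_mass_g must be > 0")
  if (any(titre_sample_mL < 0) || any(titre_blank_mL < 0))
    stop("peroxide_value(): titre volumes must be >= 0")
  pv <- 2 * (titre_sample_mL - titre_blank_mL) / oil_mass_g
  if (any(pv < 0))
    warning("peroxide_value(): blank titre exceeds sample titre; ",
            "negative PV returned (possible assay failure)")
  pv
}

#' Malondialdehyde concentration from a TBARS assay
#'
#' Converts baseline-corrected absorbance (532 nm minus 600 nm) into nmol
#' malondialdehyde (MDA) per gram of sample. The chain is: molar
#' concentration in the extract `(A532 - A600) / (epsilon * path)` (mM,
#' i.e. umol/mL), times extract volume (mL) gives umol, times 1000 gives
#' nmol, times the dilution factor, divided by the sample mass (g).
#'
#' @param a532 Absorbance at 532 nm.
#' @param a600 Absorbance at 600 nm (turbidity baseline). Expected
#'   `a532 >= a600`; a warning is issued otherwise.
#' @param extract_volume_mL Volume of the assay extract, mL (> 0).
#' @param sample_mass_g Mass of sample extracted, g (> 0).
#' @param epsilon_mM_cm Molar extinction coefficient of the MDA-TBA adduct,
#'   per mM per cm. Default 155.
#' @param path_cm Optical path length, cm. Default 1.
#' @param dilution_factor Dimensionless dilution applied before reading.
#'   Default 1.
#' @return MDA content in nmol per g of sample.
#' @examples
#' tbars_mda(0.310, 0, extract_volume_mL = 4.5, sample_mass_g = 0.2)  # 45
#' @export
tbars_mda <- function(a532, a600, extract_volume_mL, sample_mass_g,
                      epsilon_mM_cm = 155, path_cm = 1,
                      dilution_factor = 1) {
  if (any(epsilon_mM_cm <= 0) || any(path_cm <= 0))
    stop("tbars_mda(): epsilon and path length must be > 0")
  if (any(extract_volume_mL <= 0) || any(sample_mass_g <= 0))
    stop("tbars_mda(): extract volume and sample mass must be > 0")
  if (any(a532 < a600))
    warning("tbars_mda(): a532 < a600 for some readings; ",
            "negative MDA returned (check baseline)")
  conc_mM <- (a532 - a600) / (epsilon_mM_cm * path_cm)
  conc_mM * extract_volume_mL * 1000 * dilution_factor / sample_mass_g
}

#' Convert MDA from nmol/g to mg/kg
#'
#' Unit helper: 1 nmol MDA/g equals `72.07 * 1e-9 * 1e6` mg/kg = 0.07207
#' mg/kg, using the molar mass of malondialdehyde (72.07 g/mol).
#'
#' @param nmol_per_g MDA content in nmol per g.
#' @return The same content in mg MDA per kg.
#' @export
mda_nmol_g_to_mg_kg <- function(nmol_per_g) {
  nmol_per_g * 72.07e-3
}

#' Append derived oxidation columns to a raw assay table
#'
#' Given a data frame of raw readings, computes `pv_meq_kg` from titration
#' columns (`titre_sample_mL`, `titre_blank_mL`, `oil_mass_g`) and/or
#' `tbars_nmol_g` from spectrophotometric columns (`a532`, `a600`,
#' `extract_volume_mL`, `sample_mass_g`, optional `dilution_factor`),
#' whichever sets are present.
#'
#' @param df A data frame of raw assay readings.
#' @return `df` with derived columns appended.
#' @export
augment_assay_table <- function(df) {
  stopifnot(is.data.frame(df))
  pv_cols <- c("titre_sample_mL", "titre_blank_mL", "oil_mass_g")
  tb_cols <- c("a532", "a600", "extract_volume_mL", "sample_mass_g")
  found <- FALSE
  if (all(pv_cols %in% names(df))) {
    df$pv_meq_kg <- peroxide_value(df$titre_sample_mL, df$titre_blank_mL,
                                   df$oil_mass_g)
    found <- TRUE
  }
  if (all(tb_cols %in% names(df))) {
    dil <- if ("dilution_factor" %in% names(df)) df$dilution_factor else 1
    df$tbars_nmol_g <- tbars_mda(df$a532, df$a600, df$extract_volume_mL,
                                 df$sample_mass_g, dilution_factor = dil)
    found <- TRUE
  }
  if (!found)
    stop("augment_assay_table(): no recognised raw assay columns found")
  df
}
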