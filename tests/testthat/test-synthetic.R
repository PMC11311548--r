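test_that("config invariants are enforced", {
  expect_error(synthetic_config(temperatures_C = c(40, 30)), "increasing")
  expect_error(synthetic_config(days = c(0, 5, 5)), "increasing")
  expect_error(synthetic_config(scatter_sd = -0.1), ">= 0")
  expect_error(synthetic_config(
    kinetics = list(DP = list(PV = list(order = "first", Ea = 1, k0 = 1,
                                        y0 = -1)))), "y0")
  bt <- default_band_table(); bt$center[1] <- 5000
  expect_error(synthetic_config(band_table = bt), "within")
  expect_error(synthetic_config(n_channels = 1), "n_channels")
})

test_that("oxidation trajectories follow the configured kinetics exactly when noiseless", {
  # first order, Ea = 0 so k = k0 = 0.1: y(10) = e
  cfg <- noiseless_config(
    days = c(0, 5, 10), replicates = 1,
    kinetics = list(DP = list(
      PV = list(order = "first", Ea = 0, k0 = 0.1, y0 = 1),
      TBARS = list(order = "zero", Ea = 0, k0 = 0.05, y0 = 0.8))))
  s <- generate_oxidation_series(cfg, "DP", "PV", 30)
  expect_equal(s$values[s$times_days == 0], 1, tolerance = 1e-12)
  expect_equal(s$values[s$times_days == 10], exp(1), tolerance = 1e-12)
  # zero order linear accumulation at day 20 from y0 = 0.8, k = 0.05
  cfg2 <- noiseless_config(
    days = c(0, 10, 20), replicates = 1,
    kinetics = list(DP = list(
      PV = list(order = "zero", Ea = 0, k0 = 0.05, y0 = 0.8),
      TBARS = list(order = "zero", Ea = 0, k0 = 0.05, y0 = 0.8))))
  s2 <- generate_oxidation_series(cfg2, "DP", "PV", 30)
  expect_equal(s2$values[s2$times_days == 20], 1.8, tolerance = 1e-12)
  # noiseless limit: whole default design obeys the kinetic law <= 1e-12
  cfg3 <- noiseless_config()
  for (tc in cfg3$temperatures_C) {
    s3 <- generate_oxidation_series(cfg3, "HP", "TBARS", tc)
    kk <- cfg3$kinetics$HP$TBARS
    k <- arr_truth_rate(kk$Ea, kk$k0, tc)
    expect_equal(s3$values, kk$y0 * exp(k * s3$times_days),
                 tolerance = 1e-12)
  }
})

test_that("generation is deterministic and replicate noise is independent", {
  cfg <- synthetic_config(seed = 42)
  a <- generate_oxidation_series(cfg, "DP", "PV", 40)
  b <- generate_oxidation_series(cfg, "DP", "PV", 40)
  expect_identical(a, b)
  # different replicates at the same day get different noise draws
  d5 <- a$values[a$times_days == 5]
  expect_gt(min(dist(d5)), 0)
  # day-0 controls are shared across temperature series of a process
  s30 <- generate_oxidation_series(cfg, "DP", "PV", 30)
  s50 <- generate_oxidation_series(cfg, "DP", "PV", 50)
  expect_identical(s30$values[s30$times_days == 0],
                   s50$values[s50$times_days == 0])
  expect_error(generate_oxidation_series(cfg, "XX", "PV", 30), "kinetics")
  expect_error(generate_oxidation_series(cfg, "DP", "PV", 35), "design")
})

test_that("spectra match the analytic band model", {
  # single noiseless band on a grid containing its center exactly
  bt <- data.frame(center = 1745, width_sigma = 10, base_amplitude = 0.2,
                   pv_coeff = 0, tbars_coeff = 0)
  cfg <- noiseless_config(band_table = bt, n_channels = 601,
                          wn_min = 1445, wn_max = 2045)
  lat <- data.frame(sample_id = "s1", PV = 1, TBARS = 10)
  ds <- generate_spectra(cfg, lat)
  expect_equal(ds$absorbance[1, ds$wavenumbers == 1745], 0.2,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.numeric(ds$absorbance[1, ]),
               0.2 * exp(-(ds$wavenumbers - 1745)^2 / 200),
               tolerance = 1e-12)
  # linearity of the amplitude model: pv_coeff * dPV at the apex
  bt$pv_coeff <- 0.1
  cfg2 <- noiseless_config(band_table = bt, n_channels = 601,
                           wn_min = 1445, wn_max = 2045)
  lat2 <- data.frame(sample_id = c("a", "b"), PV = c(2, 0), TBARS = 0)
  ds2 <- generate_spectra(cfg2, lat2)
  apex <- which(ds2$wavenumbers == 1745)
  expect_equal(ds2$absorbance[1, apex] - ds2$absorbance[2, apex], 0.2,
               tolerance = 1e-12, ignore_attr = TRUE)
  # negative amplitudes are clipped with a warning
  bt$pv_coeff <- -1
  cfg3 <- noiseless_config(band_table = bt, n_channels = 601,
                           wn_min = 1445, wn_max = 2045)
  expect_warning(ds3 <- generate_spectra(cfg3, lat2), "clipped")
  expect_true(all(ds3$absorbance >= 0))
})

test_that("make_study reproduces the 26 x 3 = 78 sample accounting", {
  study <- make_study(synthetic_config(seed = 42))
  expect_equal(nrow(study$spectra$absorbance), 78)
  expect_equal(length(unique(sub("_R\\d+$", "",
                                 study$truth$latents$sample_id))), 26)
  expect_equal(length(study$oxidation), 12)  # 2 proc x 2 resp x 3 temps
  expect_equal(ncol(study$spectra$absorbance), 1869)
  expect_equal(range(study$spectra$wavenumbers), c(401, 4000))
  # replicates = 1 scales the design down to 26 spectra
  expect_equal(nrow(make_study(synthetic_config(replicates = 1,
                                                n_channels = 50))
                    $spectra$absorbance), 26)
  # bitwise determinism of the full study
  again <- make_study(synthetic_config(seed = 42))
  expect_identical(study$spectra$absorbance, again$spectra$absorbance)
  expect_identical(study$truth$latents, again$truth$latents)
})

test_that("oxidation series and spectra share latent states", {
  study <- make_study(tiny_config(seed = 9))
  lat <- study$truth$latents
  s <- study$oxidation[["HP_PV_40"]]
  for (d in c(5, 20)) {
    row <- lat[lat$process == "HP" & !is.na(lat$temperature_C) &
               lat$temperature_C == 40 & lat$day == d & lat$replicate == 2, ]
    expect_equal(row$PV, s$values[s$times_days == d & s$replicate == 2])
  }
  # day-0 control rows carry the shared control values
  ctrl <- lat[lat$day == 0 & lat$process == "HP", ]
  expect_equal(sort(ctrl$PV), sort(s$values[s$times_days == 0]))
})

test_that("band apex intensity tracks its latent variable as noise vanishes", {
  study <- make_study(noiseless_config(seed = 2))
  wn <- study$spectra$wavenumbers
  apex <- which.min(abs(wn - 1745))
  r <- cor(study$spectra$absorbance[, apex], study$truth$latents$PV +
             0.1 * study$truth$latents$TBARS)
  expect_gt(r, 0.999)
})

test_that("the decline hook bends the mean trajectory after the break day", {
  cfg <- noiseless_config(
    days = c(0, 5, 10, 15, 20), replicates = 1,
    kinetics = list(DP = list(
      PV = list(order = "zero", Ea = 0, k0 = 0.05, y0 = 1),
      TBARS = list(order = "zero", Ea = 0, k0 = 0.05, y0 = 1))),
    decline = list(after_day = 15, rate = 0.1))
  s <- generate_oxidation_series(cfg, "DP", "PV", 30)
  expect_equal(s$values[s$times_days == 15], 1.75)
  expect_equal(s$values[s$times_days == 20], 1.75 - 0.5)
})
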