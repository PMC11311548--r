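make_series <- function(days, values, reps = 1L, temp_C = 30,
                        response = "PV", process = "DP") {
  oxidation_series(response, process, days, values, replicate = reps,
                   temperature_C = temp_C)
}

test_that("zero-order fit recovers an exact line and agrees with the OLS oracle", {
  s <- make_series(c(0, 5, 10), c(1, 2, 3))
  f <- fit_zero_order(s)
  expect_equal(f$rate_k, 0.2)
  expect_equal(f$intercept, 1.0)
  expect_equal(f$r_squared, 1.0)
  expect_equal(f$order, "zero")

  # noisy case against explicit normal equations
  set.seed(11)
  d <- rep(c(0, 5, 10, 15, 20), each = 3)
  v <- 0.8 + 0.05 * d + rnorm(length(d), 0, 0.05)
  f2 <- fit_zero_order(make_series(d, v, reps = rep(1:3, 5)))
  o <- ols_oracle(d, v)
  expect_equal(f2$rate_k, o$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, o$intercept, tolerance = 1e-10)
})

test_that("constant series is reported as a degenerate zero-variance fit", {
  f <- fit_zero_order(make_series(c(0, 5, 10), c(0.8, 0.8, 0.8)))
  expect_equal(f$rate_k, 0)
  expect_equal(f$r_squared, 0)
  expect_true(f$zero_variance)
})

test_that("first-order fit is exact on exponentials and guards the log domain", {
  d <- c(0, 5, 10, 15)
  f <- fit_first_order(make_series(d, exp(0.05 * d)))
  expect_equal(f$rate_k, 0.05, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1.0)
  expect_error(fit_first_order(make_series(c(0, 5, 10), c(1, 0, 2))),
               "day 5")
  expect_error(fit_zero_order(make_series(c(0, 5), c(1, 2))),
               "3 distinct timepoints")
})

test_that("select_order takes the higher R^2 with ties to first order", {
  z <- fit_zero_order(make_series(c(0, 5, 10), c(1, 2, 3)))          # R2 = 1
  fo <- fit_first_order(make_series(c(0, 5, 10), c(1, 2, 2.5)))      # R2 < 1
  expect_equal(select_order(z, fo), "zero")
  fo_exact <- fit_first_order(make_series(c(0, 5, 10), exp(0.1 * c(0, 5, 10))))
  expect_equal(select_order(z, fo_exact), "first")  # tie at R2 = 1
  # exact exponential data: first order always wins
  for (k in c(0.02, 0.08, 0.2)) {
    d <- c(0, 4, 8, 12, 16)
    s <- make_series(d, 1.3 * exp(k * d))
    expect_equal(select_order(fit_zero_order(s), fit_first_order(s)), "first")
  }
})

test_that("Arrhenius fit matches the two-point closed form and exact recovery", {
  mk_fit <- function(k, T_K)
    structure(list(order = "first", rate_k = k, intercept = 0,
                   r_squared = 1, n_points = 5, temperature_K = T_K),
              class = "kinetic_fit")
  m <- fit_arrhenius(list(mk_fit(0.01, 300), mk_fit(0.1, 350)))
  expect_equal(m$Ea, gas_constant * log(10) / (1 / 300 - 1 / 350),
               tolerance = 1e-12)

  # flat rates: Ea = 0, k0 = k
  m0 <- fit_arrhenius(list(mk_fit(0.05, 300), mk_fit(0.05, 320),
                           mk_fit(0.05, 340)))
  expect_equal(m0$Ea, 0)
  expect_equal(m0$k0_pre_exponential, 0.05)

  # three exact Arrhenius rates: parameters recovered to <= 1e-9 relative
  Ea <- 5e4; k0 <- 1e6
  temps <- c(303.15, 313.15, 323.15)
  fits <- lapply(temps, function(T_K)
    mk_fit(k0 * exp(-Ea / (gas_constant * T_K)), T_K))
  m3 <- fit_arrhenius(fits)
  expect_equal(m3$Ea, Ea, tolerance = 1e-9)
  expect_equal(m3$k0_pre_exponential, k0, tolerance = 1e-9)
  expect_error(fit_arrhenius(list(mk_fit(0.01, 300))), "2 distinct")
  expect_error(fit_arrhenius(list(mk_fit(-0.01, 300), mk_fit(0.1, 350))),
               "non-positive rate")
})

test_that("shelf-life prediction matches its closed forms", {
  mk_model <- function(Ea, k0, order = "first")
    structure(list(Ea = Ea, k0_pre_exponential = k0, r_squared = 1,
                   order = order, R_gas = gas_constant,
                   per_temperature_k = numeric(0)),
              class = "arrhenius_model")
  m <- mk_model(0, 0.1)   # k(T) = 0.1 everywhere
  expect_equal(predict_shelf_life(m, 1, 1, 300)$shelf_life_days, 0)
  expect_equal(predict_shelf_life(m, 1, exp(1), 300)$shelf_life_days, 10)
  # zero-order variant
  mz <- mk_model(0, 0.05, "zero")
  expect_equal(predict_shelf_life(mz, 0.8, 1.8, 310)$shelf_life_days, 20)
  # Arrhenius consistency: SL(T) * k(T) = ln(endpoint / y0)
  m2 <- mk_model(5e4, 1e6)
  for (T_K in seq(290, 330, by = 10)) {
    sl <- predict_shelf_life(m2, 0.8, 2.5, T_K)
    expect_equal(sl$shelf_life_days * arrhenius_rate(m2, T_K),
                 log(2.5 / 0.8), tolerance = 1e-12)
  }
  expect_warning(predict_shelf_life(m, 2, 1, 300), "negative shelf life")
  expect_warning(p0 <- predict_shelf_life(mk_model(0, 0), 1, 2, 300),
                 "infinite")
  expect_true(p0$infinite && is.infinite(p0$shelf_life_days))
})

test_that("full pipeline on synthetic first-order data matches analytic truth", {
  kk <- default_kinetics()$DP$PV
  truth_m <- structure(list(Ea = kk$Ea, k0_pre_exponential = kk$k0,
                            r_squared = 1, order = "first",
                            R_gas = gas_constant,
                            per_temperature_k = numeric(0)),
                       class = "arrhenius_model")
  sl_true <- predict_shelf_life(truth_m, kk$y0, 2.0, 303.15)$shelf_life_days
  sl_err <- function(temp_K) {
    sl_t <- predict_shelf_life(truth_m, kk$y0, 2.0, temp_K)$shelf_life_days
    vapply(1:20, function(s) {
      cfg <- synthetic_config(seed = s, noise_sd = c(PV = 0.05, TBARS = 0.5))
      fits <- lapply(cfg$temperatures_C, function(tc)
        fit_first_order(generate_oxidation_series(cfg, "DP", "PV", tc)))
      arr <- fit_arrhenius(fits)
      sl_hat <- predict_shelf_life(arr, kk$y0, 2.0, temp_K)$shelf_life_days
      abs(sl_hat - sl_t) / sl_t
    }, 0)
  }
  # mid-range temperature (Arrhenius interpolation): within 5% (median)
  expect_lt(median(sl_err(313.15)), 0.05)
  # all design temperatures, including the 30 degC edge: within 10%
  for (temp_K in c(303.15, 313.15, 323.15))
    expect_lt(median(sl_err(temp_K)), 0.10)
})

test_that("shelf_life_table reproduces the design structure", {
  study <- make_study(synthetic_config(seed = 5))
  tab <- shelf_life_table(study$oxidation, c(PV = 2, TBARS = 12))
  expect_equal(nrow(tab), 12)  # 2 processes x 2 responses x 3 temperatures
  expect_setequal(names(tab),
                  c("process", "response", "temperature_C", "order",
                    "r_squared", "shelf_life_days", "sd_days",
                    "endpoint_used"))
  # Ea > 0 ground truth: SL strictly decreasing with temperature per cell
  for (proc in c("DP", "HP"))
    for (resp in c("PV", "TBARS")) {
      sub <- tab[tab$process == proc & tab$response == resp, ]
      sub <- sub[order(sub$temperature_C), ]
      expect_true(all(diff(sub$shelf_life_days) < 0))
    }
  expect_true(all(tab$endpoint_used %in% c(2, 12)))

  # replicate SD collapses in the noiseless limit
  study0 <- make_study(noiseless_config(seed = 5))
  tab0 <- shelf_life_table(study0$oxidation, c(PV = 2, TBARS = 12))
  expect_true(all(tab0$sd_days < 1e-8))
})
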