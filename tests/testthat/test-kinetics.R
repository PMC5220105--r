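test_that("initial atom fraction mixes tracer and ambient pools correctly", {
  k <- iso_constants()
  f_nat <- k$r15_air / (1 + k$r15_air)
  # independent arithmetic: (1*0.985 + 0.47*f_nat) / 1.47
  expect_equal(initial_atom_fraction(1, 0.985, 0.47),
               (0.985 + 0.47 * f_nat) / 1.47)
  expect_equal(round(initial_atom_fraction(1, 0.985, 0.47), 2), 0.67)
  expect_equal(initial_atom_fraction(0, NA, 1), f_nat)
  expect_equal(initial_atom_fraction(1, 1, 0), 1)
  expect_error(initial_atom_fraction(0, NA, 0), "positive")
  expect_error(initial_atom_fraction(-1, 0.99, 1), ">= 0")
})

test_that("15NOx regression estimator divides the slope by the dilution factor", {
  # perfectly linear series, slope 0.24 uM/day, f0 = 0.67 -> 0.358 uM/day
  d <- tibble::tibble(time_h = c(0, 5, 17, 30),
                      n15_nox = 0.24 * c(0, 5, 17, 30) / 24)
  r <- quietly_fit(ammonia_oxidation_rate_regression(d, f0 = 0.67))
  expect_equal(r$r_amm_ox, 0.24 / 0.67, tolerance = 1e-12)
  expect_equal(round(r$r_amm_ox, 3), 0.358)

  # flat series -> zero rate
  d$n15_nox <- 0.5
  r <- quietly_fit(ammonia_oxidation_rate_regression(d, f0 = 0.67))
  expect_equal(r$r_amm_ox, 0)

  expect_error(
    ammonia_oxidation_rate_regression(
      tibble::tibble(time_h = c(0, 5), n15_nox = c(0, 1)), f0 = 0.5),
    "insufficient")
  expect_error(ammonia_oxidation_rate_regression(d, f0 = 0), "0, 1")
})

test_that("regression estimator recovers the generating rate exactly on noise-free data", {
  tr <- lake_truth(noise = 0)
  b <- simulate_experiment(one_treatment(tracers = "NH4_labeled"), tr)
  f0 <- initial_atom_fraction(1, 0.985, 0.47)
  r <- quietly_fit(ammonia_oxidation_rate_regression(b, f0 = f0))
  expect_equal(r$r_amm_ox, 0.5, tolerance = 1e-9)
})

test_that("zero-order pool model inverts the generator exactly and degenerates sensibly", {
  tr <- ground_truth(r_amm_ox = 0.5, r_nit_ox = 0.64, noise = 0)
  b <- simulate_experiment(one_treatment(tracers = "NO2_labeled"), tr)
  r <- zero_order_rates(b)
  expect_equal(r$r_amm_ox, 0.5, tolerance = 1e-9)
  expect_equal(r$r_nit_ox, 0.64, tolerance = 1e-9)
  expect_equal(r$method, "zero_order_pool_model")

  # all pools constant -> both rates zero
  flat <- tibble::tibble(time_h = c(0, 5, 17, 30), conc_no2 = 1.2,
                         f15_no2 = 0.8, conc_no3 = 80, f15_no3 = 0.004)
  r <- zero_order_rates(flat, timepoints = c(17, 30))
  expect_equal(r$r_amm_ox, 0); expect_equal(r$r_nit_ox, 0)

  # no nitrite oxidation: 15F_NO3 stays at natural abundance, R_nit_ox = 0
  tr0 <- ground_truth(r_amm_ox = 0.5, r_nit_ox = 0, noise = 0)
  b0 <- simulate_experiment(one_treatment(tracers = "NO2_labeled"), tr0)
  expect_equal(unique(b0$f15_no3), iso_constants()$f15_natural, tolerance = 1e-12)
  r0 <- zero_order_rates(b0)
  expect_equal(r0$r_nit_ox, 0, tolerance = 1e-12)
  expect_equal(r0$r_amm_ox, 0.5, tolerance = 1e-9)

  # requesting t = 0 or missing kill control errors
  expect_error(zero_order_rates(b, timepoints = 0), "> 0")
  expect_error(zero_order_rates(b[b$time_h > 0, ]), "t = 0")

  # unlabeled nitrite with growing 15NO3 is flagged as inconsistent
  odd <- tibble::tibble(time_h = c(0, 17, 30), conc_no2 = 1.2,
                        f15_no2 = 0.0037, conc_no3 = 80,
                        f15_no3 = c(0.0037, 0.005, 0.006))
  expect_warning(zero_order_rates(odd, timepoints = c(17, 30)), "inconsistent")
})

test_that("regression and zero-order estimators agree on shared noise-free truth", {
  tr <- lake_truth(noise = 0)
  d <- one_treatment()
  b <- simulate_experiment(d, tr)
  f0 <- initial_atom_fraction(1, 0.985, 0.47)
  r_reg <- quietly_fit(ammonia_oxidation_rate_regression(
    b[b$tracer == "NH4_labeled", ], f0 = f0))
  r_zo <- zero_order_rates(b[b$tracer == "NO2_labeled", ])
  expect_lt(abs(r_reg$r_amm_ox - r_zo$r_amm_ox) / r_zo$r_amm_ox, 0.01)
})

test_that("first-order fit recovers exponential decay and the two-point closed form", {
  t_h <- c(0, 6, 12, 20, 30)
  d <- tibble::tibble(time_h = t_h, conc_nh4 = 2 * exp(-0.46 * t_h / 24))
  fit <- quietly_fit(first_order_fit(d))
  expect_equal(fit$k_per_day, 0.46, tolerance = 1e-9)

  d$conc_nh4 <- 1.5
  expect_equal(quietly_fit(first_order_fit(d))$k_per_day, 0)

  # two points, 0.5 day apart: k = ln(1.92/1.56)/0.5
  d2 <- tibble::tibble(time_h = c(0, 12), conc_nh4 = c(1.92, 1.56))
  expect_equal(quietly_fit(first_order_fit(d2))$k_per_day,
               log(1.92 / 1.56) / 0.5, tolerance = 1e-12)
  expect_equal(round(quietly_fit(first_order_fit(d2))$k_per_day, 3), 0.415)

  expect_error(first_order_fit(tibble::tibble(time_h = 0:3, conc_nh4 = c(1, 1, 0, 1))),
               "positive")
  td <- quietly_fit(tidy(first_order_fit(d2)))
  expect_named(td, c("term", "estimate", "std.error", "p.value"))
  gl <- quietly_fit(glance(first_order_fit(d2)))
  expect_equal(gl$nobs, 2)
})

test_that("percent rate change and net nitrite consumption match the printed comparisons", {
  expect_equal(percent_rate_change(0.356, 0.314, digits = 0), 12)
  expect_equal(percent_rate_change(0.380, 0.325, digits = 0), 14)
  expect_equal(percent_rate_change(0.4, 0.4), 0)
  expect_error(percent_rate_change(0, 0.1), "positive")

  expect_equal(net_nitrite_consumption(0.50, 0.64), 0.14)
  expect_equal(net_nitrite_consumption(0.54, 0.72), 0.18)
  expect_equal(net_nitrite_consumption(0.3, 0.3), 0)
})

test_that("estimate_rates dispatches per treatment and returns a tidy rates table", {
  tr <- lake_truth(noise = 0)
  b <- simulate_experiment(experiment_design(), tr)
  rz <- estimate_rates(b, method = "zero_order")
  expect_s3_class(rz, "n2o_rates")
  expect_setequal(unique(rz$quantity), c("r_amm_ox", "r_nit_ox"))
  expect_equal(nrow(rz), 8)  # 4 treatments x 2 quantities
  expect_true(all(abs(rz$rate[rz$quantity == "r_amm_ox"] - 0.5) < 1e-9))

  rr <- quietly_fit(estimate_rates(b, method = "regression"))
  expect_true(all(abs(rr$rate - 0.5) < 1e-9))

  rf <- quietly_fit(estimate_rates(b, method = "first_order"))
  expect_equal(unique(rf$quantity), "k_first_order")
  expect_true(all(rf$rate > 0))
})

test_that("propagated measurement uncertainty covers what across-timepoint sd misses", {
  tr <- lake_truth(noise = 0.02, rng_seed = 11)
  b <- simulate_experiment(one_treatment(tracers = "NO2_labeled"), tr)
  r <- zero_order_rates(b, timepoints = c(5, 17, 30),
                        measurement_sd = list(conc = 0.02, f15 = 0.002))
  expect_true(all(c("r_amm_ox_sd_prop", "r_nit_ox_sd_prop") %in% names(r)))
  expect_gt(r$r_amm_ox_sd_prop, 0)
  # propagated sd includes the shared kill-control blank, so it should not
  # be smaller than the scatter-based sd by construction on typical draws
  expect_gt(r$r_nit_ox_sd_prop, 0)
})
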