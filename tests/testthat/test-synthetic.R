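test_that("simulation is deterministic given the seed and varies across seeds", {
  d <- one_treatment()
  b1 <- simulate_experiment(d, lake_truth(rng_seed = 7))
  b2 <- simulate_experiment(d, lake_truth(rng_seed = 7))
  b3 <- simulate_experiment(d, lake_truth(rng_seed = 8))
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_false(isTRUE(all.equal(b1$conc_no2, b3$conc_no2)))
})

test_that("noise-free simulator conserves dissolved inorganic nitrogen and 15N", {
  d <- one_treatment()
  b <- simulate_experiment(d, lake_truth(noise = 0))
  din <- b$conc_nh4 + b$conc_no2 + b$conc_no3
  expect_equal(din, rep(din[1], nrow(b)), tolerance = 1e-9)

  # N2O-N tracked on top of the pools stays far below measurement resolution
  v <- b$volume_l[1]
  n2o_n_um <- 2 * (b$n2o_total_nmol - b$n2o_total_nmol[b$time_h == 0][1]) /
    v / 1000
  expect_lt(max(abs(n2o_n_um)), 2e-4)

  # 15N balance in the NO2-labeled regime: what leaves nitrite arrives in nitrate
  no2l <- b[b$tracer == "NO2_labeled", ]
  n15 <- no2l$conc_no2 * no2l$f15_no2 + no2l$conc_no3 * no2l$f15_no3
  expect_equal(n15, rep(n15[1], nrow(no2l)), tolerance = 1e-9)

  # pool mass balance: the NOx gain equals R_amm_ox * t exactly
  t0 <- no2l[no2l$time_h == 0, ][1, ]
  gain <- (no2l$conc_no2 + no2l$conc_no3) - (t0$conc_no2 + t0$conc_no3)
  expect_equal(gain, 0.5 * no2l$time_h / 24, tolerance = 1e-9)
})

test_that("simulator errors when a rate would drive a pool negative, naming it", {
  d <- one_treatment()
  expect_error(simulate_experiment(d, ground_truth(r_amm_ox = 5, noise = 0)),
               "r_amm_ox.*NH4")
  expect_error(
    simulate_experiment(d, ground_truth(r_amm_ox = 0.1, r_nit_ox = 3, noise = 0)),
    "r_nit_ox.*NO2")
})

test_that("measurement noise respects physical ranges and the stated model", {
  d <- one_treatment()
  big <- ground_truth(noise = list(conc = 0.3, n2o = 0.3, ratio = 0.3, f15 = 0.1),
                      rng_seed = 2)
  b <- simulate_experiment(d, big)
  expect_true(all(b$conc_nh4 >= 0 & b$conc_no2 >= 0 & b$conc_no3 >= 0))
  expect_true(all(b$f15_no2 >= 0 & b$f15_no2 <= 1))
  expect_true(all(b$f15_no3 >= 0 & b$f15_no3 <= 1))
  expect_true(all(b$r45 >= 0 & b$r46 >= 0))

  # default noise scatters triplicates at the expected order (2% on conc)
  bn <- simulate_experiment(d, lake_truth(rng_seed = 4))
  reps <- bn[bn$tracer == "NO2_labeled" & bn$time_h == 17, ]
  expect_gt(stats::sd(reps$conc_no3) / mean(reps$conc_no3), 0.001)
  expect_lt(stats::sd(reps$conc_no3) / mean(reps$conc_no3), 0.1)
})

test_that("ammonium regeneration dilutes the tracer and biases the regression low", {
  d <- one_treatment(tracers = "NH4_labeled")
  f0 <- initial_atom_fraction(1, 0.985, 0.47)
  clean <- simulate_experiment(d, lake_truth(noise = 0))
  regen <- simulate_experiment(d, lake_truth(noise = 0, nh4_regeneration = 0.4))
  r_clean <- quietly_fit(ammonia_oxidation_rate_regression(clean, f0 = f0))
  r_regen <- quietly_fit(ammonia_oxidation_rate_regression(regen, f0 = f0))
  expect_equal(r_clean$r_amm_ox, 0.5, tolerance = 1e-9)
  expect_lt(r_regen$r_amm_ox, 0.5)   # the bias narrative: estimate drops
  expect_gt(r_regen$r_amm_ox, 0.3)   # but stays the right order
})

test_that("nitrite-pair generation yields the binomial 46:45 production ratio", {
  # ambient NO2- of 0.0444 uM puts the labeled pool at 15F ~ 0.95; a slow
  # ammonia-oxidation influx and short timepoints keep the labeling near
  # its initial value (the 46:45 ratio is very sensitive to 15F near 1)
  d <- one_treatment(tracers = "NO2_labeled", ambient_no2_um = 0.0444,
                     timepoints = c(0, 1, 2, 3))
  tr <- ground_truth(r_amm_ox = 0.01, r_nit_ox = 0.02,
                     mechanism = "nitrite_pair", n2o_yield = 5e-2, noise = 0)
  b <- simulate_experiment(d, tr)
  f0 <- initial_atom_fraction(1, 0.992, 0.0444)
  expect_equal(round(f0, 2), 0.95)
  pr <- quietly_fit(production_rates(b))
  ratio <- pr$rates$rate_nmol_day[2] / pr$rates$rate_nmol_day[1]
  expect_equal(ratio, binomial_expected_ratio(f0), tolerance = 0.02)
  expect_equal(ratio, 9.5, tolerance = 0.07)
})

test_that("periplasmic exchange below one shifts nitrite-pair labeling toward the ammonium pool", {
  d <- one_treatment(tracers = "NO2_labeled", timepoints = c(0, 2, 4, 6))
  mixed <- ground_truth(mechanism = "nitrite_pair", periplasmic_exchange = 0.2,
                        n2o_yield = 1e-2, noise = 0)
  full <- ground_truth(mechanism = "nitrite_pair", periplasmic_exchange = 1,
                       n2o_yield = 1e-2, noise = 0)
  p_mixed <- quietly_fit(production_rates(simulate_experiment(d, mixed)))
  p_full <- quietly_fit(production_rates(simulate_experiment(d, full)))
  # less exchange with the labeled exogenous pool -> less 45/46 production
  expect_lt(p_mixed$rates$rate_nmol_day[1], p_full$rates$rate_nmol_day[1])
  expect_lt(p_mixed$rates$rate_nmol_day[2], p_full$rates$rate_nmol_day[2])
})

test_that("simulated profiles mix site-preference end-members by weight", {
  expect_equal(unique(simulate_profile(4, weight_high = 1)$sp_permil), 34)
  expect_equal(unique(simulate_profile(4, weight_high = 0)$sp_permil), -5)
  expect_equal(unique(simulate_profile(4, weight_high = 0.5)$sp_permil), 14.5)

  p <- simulate_profile(6)
  expect_equal(p$sp_permil, p$d15n_alpha - p$d15n_beta)
  expect_true(all(diff(p$depth_m) > 0))
  expect_error(simulate_profile(3, weight_high = 1.2), "\\[0, 1\\]")

  # noise is seeded and reproducible
  p1 <- simulate_profile(5, noise = 0.05, seed = 3)
  p2 <- simulate_profile(5, noise = 0.05, seed = 3)
  expect_identical(p1$conc_n2o_nm, p2$conc_n2o_nm)
})
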