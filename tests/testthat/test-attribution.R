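test_that("isotopologue production rates are the OLS slopes of blank-corrected amounts", {
  # synthetic bottles: n45 grows at 0.01 nmol/day, n46 flat
  t_h <- c(0, rep(c(5, 17, 30), each = 3))
  n44 <- 3; n45 <- 0.02 + 0.01 * t_h / 24; n46 <- 0.01
  b <- tibble::tibble(time_h = t_h, n2o_total_nmol = n44 + n45 + n46,
                      r45 = n45 / n44, r46 = n46 / n44, volume_l = 0.12)
  pr <- quietly_fit(production_rates(b))
  expect_equal(pr$rates$rate_nmol_day[1], 0.01, tolerance = 1e-9)
  expect_lt(pr$rates$p_value[1], 0.05)
  expect_equal(pr$rates$rate_nmol_day[2], 0, tolerance = 1e-12)
  expect_gte(pr$rates$p_value[2], 0.05)
  expect_equal(pr$rates$rate_nm_day[1], 0.01 / 0.12, tolerance = 1e-9)

  # all bottles identical to t0 -> both rates zero
  b0 <- b; b0$r45 <- 0.02 / 3; b0$n2o_total_nmol <- 3.04
  pr0 <- quietly_fit(production_rates(b0))
  expect_equal(pr0$rates$rate_nmol_day, c(0, 0), tolerance = 1e-12)

  expect_error(production_rates(b[1:3, ]), ">= 3 post-t0")
  expect_error(production_rates(b[-1, ]), "kill control")

  td <- quietly_fit(tidy(production_rates(b)))
  expect_named(td, c("term", "estimate", "std.error", "p.value", "estimate_nm_day"))
  gl <- quietly_fit(glance(production_rates(b)))
  expect_equal(gl$incorporation_nm_day,
               (0.01 + 2 * 0) / 0.12, tolerance = 1e-9)
})

test_that("noisy triplicate production slopes land within 3 standard errors of truth", {
  t_h <- c(0, rep(c(5, 17, 30), each = 3))
  truth45 <- 0.01
  hits <- withr::with_seed(99, {
    replicate(50, {
      n45 <- 0.02 + truth45 * t_h / 24
      n44 <- 3
      b <- tibble::tibble(
        time_h = t_h,
        n2o_total_nmol = (n44 + n45 + 0.01) * (1 + stats::rnorm(length(t_h), 0, 0.05)),
        r45 = (n45 / n44) * (1 + stats::rnorm(length(t_h), 0, 0.05)),
        r46 = 0.01 / n44, volume_l = 0.12)
      pr <- production_rates(b)
      abs(pr$rates$rate_nmol_day[1] - truth45) <= 3 * pr$rates$se_nmol_day[1]
    })
  })
  expect_gte(mean(hits), 0.9)
})

test_that("15N incorporation, dilution factor, and yield reproduce the printed arithmetic", {
  expect_equal(total_15n_incorporation(0.004, 0.0023), 0.0086)
  expect_equal(total_15n_incorporation(0, 0), 0)
  expect_equal(total_15n_incorporation(0.7, 0), 0.7)

  expect_equal(round(isotope_dilution_factor(0.67), 2), 1.49)
  expect_equal(round(isotope_dilution_factor(0.62), 2), 1.61)
  expect_equal(isotope_dilution_factor(1), 1)
  expect_error(isotope_dilution_factor(0), "\\(0, 1\\]")

  # printed inputs reproduce the printed yields within rounding (3%)
  expect_equal(n2o_yield(0.0086, 0.356, 0.67)$yield, 3.64e-5, tolerance = 0.03)
  expect_equal(n2o_yield(0.043, 0.325, 0.62)$yield, 21.0e-5, tolerance = 0.03)
  expect_equal(n2o_yield(0, 0.5, 0.67)$yield, 0)
  expect_error(n2o_yield(0.01, 0, 0.67), "positive")
})

test_that("binomial pairing expectation follows f/(2(1-f)) and is increasing", {
  expect_equal(round(binomial_expected_ratio(0.67), 1), 1.0)
  expect_equal(round(binomial_expected_ratio(0.62), 2), 0.82)
  expect_equal(binomial_expected_ratio(0.5), 0.5)
  expect_equal(binomial_expected_ratio(0), 0)
  expect_error(binomial_expected_ratio(1), "diverges")

  f <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(binomial_expected_ratio(f)) > 0))
})

test_that("mechanism isotopologue distributions are valid probabilities", {
  d <- mechanism_isotopologue_distribution("hybrid", f_nh4 = 0.94, f_no2 = 0)
  expect_equal(as.numeric(d), c(0.06, 0.94, 0))

  d <- mechanism_isotopologue_distribution("binomial_NH4", f_nh4 = 0.94)
  expect_equal(as.numeric(d), c(0.0036, 0.1128, 0.8836), tolerance = 1e-12)

  # property: sums to one, all entries in [0,1], for random pools/mechanisms
  withr::with_seed(3, {
    for (i in 1:30) {
      kind <- sample(c("binomial_NH4", "hybrid", "nitrite_pair"), 1)
      d <- mechanism_isotopologue_distribution(
        kind, f_nh4 = stats::runif(1), f_no2 = stats::runif(1))
      expect_equal(d$p44 + d$p45 + d$p46, 1, tolerance = 1e-12)
      expect_true(all(as.numeric(d) >= 0 & as.numeric(d) <= 1))
    }
  })

  expect_error(mechanism_isotopologue_distribution("hybrid", f_nh4 = 0.5),
               "source pool")
})

test_that("delta trajectories conserve moles and separate binomial from hybrid labeling", {
  bg <- fractions_to_amounts(0.0079, 0.0021, 3)

  m <- mechanism_spec("binomial_NH4", f_nh4 = 0.94)
  expect_equal(as.numeric(predict_delta_trajectory(bg, m, 0)[1, 1:4]),
               c(0, 0, 0, 0))

  # adding N2O isotopically identical to the background changes nothing
  fr <- ratios_to_fractions(bg$n45 / bg$n44, bg$n46 / bg$n44)
  manual <- fractions_to_amounts(fr$f45, fr$f46, bg$total + 0.3)
  expect_equal(manual$n45 / manual$n44, bg$n45 / bg$n44, tolerance = 1e-12)

  # exact mole balance
  tr <- predict_delta_trajectory(bg, m, 0.05)
  expect_equal(tr$total, bg$total + 0.05, tolerance = 1e-12)

  # mass-46 discrimination: binomial pairing of a 0.94-labeled pool moves the
  # 46 signal >10x more than hybrid pairing with an unlabeled partner, while
  # the bulk 15N change stays within 2x
  hyb <- mechanism_spec("hybrid", f_nh4 = 0.94, f_no2 = 0.0037)
  t_bin <- predict_delta_trajectory(bg, m, 0.05)
  t_hyb <- predict_delta_trajectory(bg, hyb, 0.05)
  expect_gt(t_bin$d_r46 / t_hyb$d_r46, 10)
  # each binomial molecule carries ~2 labeled atoms vs ~1 for hybrid
  expect_lt(t_bin$d_d15n_bulk / t_hyb$d_d15n_bulk, 2.1)
  expect_gt(t_bin$d_d15n_bulk / t_hyb$d_d15n_bulk, 1.9)

  # d18O mixing: unlabeled-oxygen source drags the pool toward its own value
  hyb18 <- mechanism_spec("hybrid", f_nh4 = 0.94, f_no2 = 0.0037,
                          source_d18o = 0)
  t18 <- predict_delta_trajectory(bg, hyb18, 0.05, background_d18o = 44)
  expect_lt(t18$d_d18o, 0)
  t_same <- predict_delta_trajectory(bg, hyb, 0.05, background_d18o = 44)
  expect_equal(t_same$d_d18o, 0)
})

test_that("mechanism classification recovers the generating mechanism and flags hybrid deficits", {
  for (mech in c("binomial_NH4", "hybrid", "nitrite_pair")) {
    tr <- lake_truth(mechanism = mech, noise = 0)
    b <- simulate_experiment(one_treatment(), tr)
    att <- quietly_fit(attribute_n2o(b))
    rk <- att$ranking[[1]]
    expect_equal(rk$mechanism[1], mech)
  }

  # printed comparison: observed 46:45 below the binomial expectation of 1.0
  obs <- tibble::tibble(
    tracer = "NH4_labeled", rate45 = 0.010, se45 = 0.001, p45 = 0.001,
    rate46 = 0.005, se46 = 0.001, p46 = 0.003,  # observed ratio 0.5, in 0.38-0.67
    f_nh4 = 0.67, f_no2 = 0.01)
  rk <- classify_mechanism(obs)
  expect_match(attr(rk, "notes"), "below the binomial expectation")
  expect_match(attr(rk, "notes"), "hybrid contribution")

  # nitrite-pair rejection in a 15NO2- regime with 45 but no 46 production
  obs2 <- tibble::tibble(
    tracer = "NO2_labeled", rate45 = 0.010, se45 = 0.001, p45 = 0.001,
    rate46 = 0.0001, se46 = 0.0004, p46 = 0.8,
    f_nh4 = 0.0037, f_no2 = 0.8)
  rk2 <- classify_mechanism(obs2)
  expect_true(rk2$rejected[rk2$mechanism == "nitrite_pair"])
  expect_equal(rk2$mechanism[1], "hybrid")

  # no significant production anywhere -> indeterminate
  obs3 <- obs2
  obs3$p45 <- 0.6; obs3$p46 <- 0.9
  rk3 <- classify_mechanism(obs3)
  expect_equal(rk3$mechanism, "indeterminate")
  expect_equal(attr(rk3, "status"), "indeterminate")
})

test_that("attribution pipeline produces the report table on noisy multi-treatment data", {
  tr <- lake_truth(mechanism = "hybrid", rng_seed = 5)
  b <- simulate_experiment(experiment_design(), tr)
  att <- attribute_n2o(b)
  expect_equal(nrow(att), 8)  # 4 treatments x 2 regimes
  expect_true(all(c("rate45", "rate46", "p45", "p46", "observed_46_45",
                    "binomial_expected_46_45", "ranking") %in% names(att)))
  top <- vapply(att$ranking, function(r) r$mechanism[1], character(1))
  expect_true(all(top == "hybrid"))
  # NH4-labeled binomial expectation reflects the 0.67 labeling
  nh4 <- att[att$tracer == "NH4_labeled", ]
  expect_equal(unique(round(nh4$binomial_expected_46_45, 1)), 1.0)
})
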