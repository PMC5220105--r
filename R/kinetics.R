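#' Initial 15N atom fraction of a tracer-amended pool
#'
#' Mixes the added labeled tracer with the ambient pool to give the atom
#' fraction at the start of the incubation,
#' 15F0 = (added x purity + ambient x f_ambient) / (added + ambient),
#' where f_ambient is the atom fraction implied by the ambient pool's
#' delta15N on the atmospheric-N2 scale (0 permil, i.e. natural abundance,
#' unless measured).
#'
#' @param added_tracer Added tracer concentration (uM), >= 0.
#' @param tracer_purity 15N atom fraction of the tracer salt (e.g. 0.985).
#' @param ambient_conc Ambient pool concentration before addition (uM), >= 0.
#' @param ambient_delta15 delta15N of the ambient pool, permil (default 0).
#' @param constants Constants list from [iso_constants()].
#' @return Numeric vector of initial atom fractions in \[0, 1\].
#' @examples
#' initial_atom_fraction(1, 0.985, 0.47)   # ~0.67
#' initial_atom_fraction(0, NA, 1)         # natural abundance
#' @export
initial_atom_fraction <- function(added_tracer, tracer_purity, ambient_conc,
                                  ambient_delta15 = 0,
                                  constants = iso_constants()) {
  check_numeric(added_tracer, "added_tracer")
  check_numeric(ambient_conc, "ambient_conc")
  if (any(added_tracer < 0, na.rm = TRUE) || any(ambient_conc < 0, na.rm = TRUE)) {
    abort("concentrations must be >= 0")
  }
  if (any(added_tracer + ambient_conc <= 0, na.rm = TRUE)) {
    abort("total pool (added + ambient) must be positive")
  }
  purity <- ifelse(added_tracer > 0, tracer_purity, 0)
  if (any(added_tracer > 0 & (is.na(tracer_purity) | tracer_purity < 0 |
                                tracer_purity > 1))) {
    abort("tracer_purity must be in [0, 1] when tracer is added")
  }
  f_amb <- atom_fraction_from_delta(ambient_delta15, constants)
  (added_tracer * purity + ambient_conc * f_amb) / (added_tracer + ambient_conc)
}

#' Ammonia oxidation rate from 15NOx accumulation (regression estimator)
#'
#' Ordinary least-squares slope of the labeled NOx- concentration
#' (\[15NO2-\] + \[15NO3-\], uM) against time during a 15NH4+ incubation,
#' multiplied by the isotope dilution factor 1/15F0 of the ammonium pool to
#' convert the labeled production rate into a total-pool ammonia oxidation
#' rate. The slope standard error is propagated through the same factor.
#'
#' @param data A data frame with a time column (hours) and either a labeled
#'   NOx column `n15_nox` (uM) or the four columns `conc_no2`, `f15_no2`,
#'   `conc_no3`, `f15_no3` from which it is formed.
#' @param f0 Initial 15N atom fraction of the NH4+ pool
#'   (see [initial_atom_fraction()]), in (0, 1\].
#' @param time Name of the time column (hours). Default `"time_h"`.
#' @return One-row tibble: `method`, `r_amm_ox` (uM/day), `r_amm_ox_sd`,
#'   `slope_p` (two-sided p-value of the slope), `n`.
#' @examples
#' d <- tibble::tibble(time_h = c(0, 5, 17, 30),
#'                     n15_nox = 0.01 * c(0, 5, 17, 30) / 24)
#' ammonia_oxidation_rate_regression(d, f0 = 0.67)
#' @export
ammonia_oxidation_rate_regression <- function(data, f0, time = "time_h") {
  stopifnot(is.data.frame(data))
  if (!is.numeric(f0) || length(f0) != 1L || is.na(f0) || f0 <= 0 || f0 > 1) {
    abort("f0 must be a single atom fraction in (0, 1]")
  }
  if (!time %in% names(data)) abort(paste0("no time column '", time, "'"))
  if (!"n15_nox" %in% names(data)) {
    need <- c("conc_no2", "f15_no2", "conc_no3", "f15_no3")
    if (!all(need %in% names(data))) {
      abort("data needs either 'n15_nox' or conc_no2/f15_no2/conc_no3/f15_no3")
    }
    data$n15_nox <- data$conc_no2 * data$f15_no2 + data$conc_no3 * data$f15_no3
  }
  tt <- data[[time]]
  if (length(unique(tt)) < 3L) {
    abort("insufficient data: need >= 3 distinct timepoints for the regression")
  }
  fit <- lm(n15_nox ~ t, data = data.frame(t = tt, n15_nox = data$n15_nox))
  sm <- summary(fit)$coefficients
  slope <- sm["t", "Estimate"] * 24          # uM 15N / day
  se    <- sm["t", "Std. Error"] * 24
  tibble(
    method      = "regression_15NOx",
    r_amm_ox    = slope / f0,
    r_amm_ox_sd = se / f0,
    slope_p     = sm["t", "Pr(>|t|)"],
    n           = length(tt)
  )
}

#' Zero-order ammonia and nitrite oxidation rates from a 15NO2- incubation
#'
#' Inverts the four zero-order pool balance equations for the nitrite and
#' nitrate sub-pools under a 15NO2- tracer with unlabeled ammonium:
#' \deqn{[^{14}NO_2^-](t) = R_{amm\_ox} t - (1-^{15}F_{NO_2^-}) R_{nit\_ox} t + [^{14}NO_2^-]_0}
#' \deqn{[^{15}NO_2^-](t) = -^{15}F_{NO_2^-} R_{nit\_ox} t + [^{15}NO_2^-]_0}
#' \deqn{[^{14}NO_3^-](t) = (1-^{15}F_{NO_2^-}) R_{nit\_ox} t + [^{14}NO_3^-]_0}
#' \deqn{[^{15}NO_3^-](t) = ^{15}F_{NO_2^-} R_{nit\_ox} t + [^{15}NO_3^-]_0}
#' Sub-pools are constructed from total concentrations and measured atom
#' fractions (conc x 15F and conc x (1-15F)); the atom fraction coefficient
#' is taken as the mean of the values at 0 and t, which is the second-order
#' accurate treatment of the slow downward drift of 15F_NO2- as unlabeled
#' nitrite is produced. R_nit_ox is estimated from the 15N balance using
#' both the nitrite-loss and the nitrate-gain equation, combined by weighted
#' least squares (equal weights by default); R_amm_ox then follows from the
#' 14NO2- balance. Rates are computed for each requested timepoint and
#' averaged, with the standard deviation across timepoints as uncertainty.
#'
#' All ammonia-oxidation influx is assigned to the 14NO2- pool, as the
#' ammonium pool is unlabeled in these incubations; `na_influx = TRUE`
#' instead splits the influx at natural 15N abundance.
#'
#' @param data Bottle measurements for one 15NO2--labeled treatment: columns
#'   `time_h`, `conc_no2`, `f15_no2`, `conc_no3`, `f15_no3`; replicate rows
#'   per timepoint are averaged. A `time_h == 0` group must be present.
#' @param timepoints Which post-t0 timepoints (hours) to use. Default: all
#'   timepoints later than 12 h.
#' @param weights Length-2 weights for the nitrite-loss and nitrate-gain
#'   estimates of R_nit_ox. Default equal.
#' @param na_influx Split the ammonia-oxidation influx at natural abundance
#'   instead of all-14N? Default `FALSE` (the printed balance equations).
#' @param measurement_sd Optional measurement uncertainty model: a list
#'   with `conc` (relative sd of the concentration measurements) and `f15`
#'   (absolute sd of the atom-fraction measurements). When supplied, the
#'   measurement error is propagated through the per-timepoint solves
#'   (accounting for the kill-control blank shared by all timepoints,
#'   which the across-timepoint sd cannot see) and reported as
#'   `r_amm_ox_sd_prop` / `r_nit_ox_sd_prop` next to the across-timepoint
#'   sds.
#' @param constants Constants list from [iso_constants()].
#' @return One-row tibble: `method`, `r_amm_ox`, `r_amm_ox_sd`, `r_nit_ox`,
#'   `r_nit_ox_sd` (uM/day), `n_timepoints`, `timepoints` (comma-separated),
#'   plus propagated sds when `measurement_sd` is given.
#' @examples
#' tr <- ground_truth(r_amm_ox = 0.5, r_nit_ox = 0.64, noise = 0)
#' b <- simulate_experiment(experiment_design(tracers = "NO2_labeled"), tr)
#' zero_order_rates(b)
#' @export
zero_order_rates <- function(data, timepoints = NULL, weights = c(1, 1),
                             na_influx = FALSE, measurement_sd = NULL,
                             constants = iso_constants()) {
  stopifnot(is.data.frame(data))
  need <- c("time_h", "conc_no2", "f15_no2", "conc_no3", "f15_no3")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (length(weights) != 2L || any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be two non-negative numbers, not both zero")
  }

  avg <- data %>%
    group_by(time_h) %>%
    summarise(across(all_of(need[-1]), ~ mean(.x, na.rm = TRUE)), .groups = "drop") %>%
    arrange(time_h)
  if (!any(avg$time_h == 0)) abort("a t = 0 (kill control) timepoint is required")
  t0 <- avg[avg$time_h == 0, ]
  if (is.null(timepoints)) timepoints <- avg$time_h[avg$time_h > 12]
  timepoints <- sort(unique(timepoints))
  if (any(timepoints <= 0)) abort("timepoints must be > 0 hours")
  use <- avg[avg$time_h %in% timepoints, ]
  if (nrow(use) == 0L) abort("no measurements at the requested timepoints")

  w <- weights / sum(weights)
  influx_14 <- if (na_influx) 1 - constants$f15_natural else 1
  t_d <- use$time_h / 24 # days

  # per-timepoint solve as a function of the averaged measurement vector
  # m = (no2_0, f15_no2_0, no3_0, f15_no3_0, then per timepoint the same
  # four quantities); kept as one function so measurement error can be
  # pushed through it numerically
  core <- function(m) {
    k <- length(t_d)
    m0 <- m[1:4]
    mt <- matrix(m[-(1:4)], nrow = k, byrow = TRUE)
    no2_15_0 <- m0[1] * m0[2]; no2_14_0 <- m0[1] * (1 - m0[2])
    no3_15_0 <- m0[3] * m0[4]
    no2_15_t <- mt[, 1] * mt[, 2]; no2_14_t <- mt[, 1] * (1 - mt[, 2])
    no3_15_t <- mt[, 3] * mt[, 4]
    fbar <- (m0[2] + mt[, 2]) / 2
    r_nit <- w[1] * (no2_15_0 - no2_15_t) / (fbar * t_d) +
      w[2] * (no3_15_t - no3_15_0) / (fbar * t_d)
    r_amm <- ((no2_14_t - no2_14_0) / t_d + (1 - fbar) * r_nit) / influx_14
    cbind(r_amm, r_nit)
  }

  m <- c(t0$conc_no2, t0$f15_no2, t0$conc_no3, t0$f15_no3,
         t(as.matrix(use[, c("conc_no2", "f15_no2", "conc_no3", "f15_no3")])))
  est <- core(m)

  if (t0$f15_no2 < 2 * constants$f15_natural &&
      any(use$conc_no3 * use$f15_no3 - t0$conc_no3 * t0$f15_no3 > 1e-6)) {
    warn(paste("inconsistent data: 15F_NO2- is at natural abundance but the",
               "15NO3- pool grows; R_nit_ox from the 15N balance is unreliable"))
  }

  out <- tibble(
    method       = "zero_order_pool_model",
    r_amm_ox     = mean(est[, "r_amm"]),
    r_amm_ox_sd  = if (nrow(est) > 1) sd(est[, "r_amm"]) else NA_real_,
    r_nit_ox     = mean(est[, "r_nit"]),
    r_nit_ox_sd  = if (nrow(est) > 1) sd(est[, "r_nit"]) else NA_real_,
    n_timepoints = length(t_d),
    timepoints   = paste(use$time_h, collapse = ",")
  )

  if (!is.null(measurement_sd)) {
    sd_conc <- measurement_sd$conc %||% 0
    sd_f15  <- measurement_sd$f15 %||% 0
    reps <- data %>% group_by(time_h) %>% summarise(k = n(), .groups = "drop")
    n_of <- function(tt) reps$k[match(tt, reps$time_h)]
    # sd of each averaged measurement (sem over its replicates)
    sd_quad <- function(conc, tt) c((sd_conc * conc[1]) / sqrt(n_of(tt)),
                                    sd_f15 / sqrt(n_of(tt)),
                                    (sd_conc * conc[2]) / sqrt(n_of(tt)),
                                    sd_f15 / sqrt(n_of(tt)))
    m_sd <- c(sd_quad(c(t0$conc_no2, t0$conc_no3), 0),
              unlist(lapply(seq_len(nrow(use)), function(i) {
                sd_quad(c(use$conc_no2[i], use$conc_no3[i]), use$time_h[i])
              })))
    # numerical gradient of the mean rates wrt every averaged measurement;
    # the shared t0 entries correlate the per-timepoint estimates, which
    # this captures and the across-timepoint sd cannot
    mean_rates <- function(mm) colMeans(core(mm))
    jac <- vapply(seq_along(m), function(j) {
      h <- max(1e-7, 1e-7 * abs(m[j]))
      mp <- m; mp[j] <- m[j] + h
      mn <- m; mn[j] <- m[j] - h
      (mean_rates(mp) - mean_rates(mn)) / (2 * h)
    }, numeric(2))
    var_prop <- (jac^2) %*% (m_sd^2)
    out$r_amm_ox_sd_prop <- sqrt(var_prop[1])
    out$r_nit_ox_sd_prop <- sqrt(var_prop[2])
  }
  out
}

#' Net nitrite consumption
#'
#' The difference R_nit_ox - R_amm_ox: when nitrite oxidation outpaces the
#' ammonia-oxidation influx, the nitrite pool is drawn down.
#'
#' @param r_amm_ox,r_nit_ox Rates in uM/day (vectors recycle).
#' @return Net NO2- consumption, uM/day (positive = net loss of nitrite).
#' @examples
#' net_nitrite_consumption(0.50, 0.64)  # 0.14
#' @export
net_nitrite_consumption <- function(r_amm_ox, r_nit_ox) {
  check_numeric(r_amm_ox, "r_amm_ox"); check_numeric(r_nit_ox, "r_nit_ox")
  r_nit_ox - r_amm_ox
}

#' First-order rate constant for ammonium drawdown
#'
#' Least-squares fit of log(\[NH4+\]) against time; the negated slope is the
#' first-order rate constant k (per day). Offered as the alternative to the
#' zero-order model where the ambient ammonium concentration sits near or
#' below the half-saturation range of the ammonia oxidizers present.
#'
#' @param data Data frame with a time column (hours) and an ammonium
#'   concentration column (uM), all concentrations > 0.
#' @param time,conc Column names. Defaults `"time_h"`, `"conc_nh4"`.
#' @return An object of class `first_order_fit` with components `k_per_day`,
#'   `k_sd`, `n`, and the underlying `lm` fit; see [tidy()] and [glance()].
#' @examples
#' d <- tibble::tibble(time_h = c(0, 12, 24), conc_nh4 = 2 * exp(-0.46 * c(0, 0.5, 1)))
#' first_order_fit(d)$k_per_day
#' @export
first_order_fit <- function(data, time = "time_h", conc = "conc_nh4") {
  stopifnot(is.data.frame(data))
  if (!time %in% names(data)) abort(paste0("no time column '", time, "'"))
  if (!conc %in% names(data)) abort(paste0("no concentration column '", conc, "'"))
  cc <- data[[conc]]; tt <- data[[time]]
  if (any(!is.finite(cc)) || any(cc <= 0)) {
    abort("all concentrations must be positive for the log-linear fit")
  }
  if (length(unique(tt)) < 2L) abort("need at least two distinct timepoints")
  fit <- lm(y ~ t, data = data.frame(t = tt / 24, y = log(cc)))
  sm <- summary(fit)$coefficients
  structure(
    list(
      k_per_day = -unname(sm["t", "Estimate"]),
      k_sd      = unname(sm["t", "Std. Error"]),
      n         = length(tt),
      fit       = fit
    ),
    class = "first_order_fit"
  )
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat("First-order ammonium drawdown fit\n")
  cat(sprintf("  k = %.4g +/- %.2g per day (n = %d)\n", x$k_per_day, x$k_sd, x$n))
  invisible(x)
}

#' Percent change between two rates
#'
#' (1 - rate_b/rate_a) x 100: the percent decrease from `rate_a` (the
#' reference, e.g. untreated) to `rate_b` (the treatment).
#'
#' @param rate_a Reference rate(s), > 0.
#' @param rate_b Comparison rate(s).
#' @param digits Optional rounding of the result.
#' @return Percent decrease (negative = increase).
#' @examples
#' percent_rate_change(0.356, 0.314, digits = 0)  # 12
#' @export
percent_rate_change <- function(rate_a, rate_b, digits = NULL) {
  check_numeric(rate_a, "rate_a"); check_numeric(rate_b, "rate_b")
  if (any(rate_a <= 0, na.rm = TRUE)) abort("rate_a must be positive")
  out <- (1 - rate_b / rate_a) * 100
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Estimate nitrification rates for every treatment in a bottle table
#'
#' Data-frame-first wrapper over the per-treatment estimators. Groups the
#' bottle table by the treatment descriptors present (`treatment`, `ph`,
#' `o2_um`, `tracer`), applies the chosen estimator to each group, and
#' returns one tidy rates table. The regression estimator is applied to
#' NH4+-labeled groups (15F0 of the ammonium pool is computed from the
#' `tracer_added_um`, `tracer_purity` and `ambient_nh4_um` columns unless
#' `f0` is given); the zero-order and first-order estimators to
#' NO2--labeled groups.
#'
#' @param bottles A bottle-measurement table, e.g. from
#'   [simulate_experiment()] or [read_bottle_table()].
#' @param method `"zero_order"`, `"regression"`, or `"first_order"`.
#' @param timepoints Passed to [zero_order_rates()].
#' @param f0 Optional initial NH4+ atom fraction override for the
#'   regression estimator.
#' @param ... Further arguments passed to the underlying estimator.
#' @return A tibble of class `n2o_rates`: treatment columns plus `method`,
#'   `quantity` (`"r_amm_ox"`, `"r_nit_ox"` or `"k_first_order"`), `rate`,
#'   `rate_sd`, `n`, `timepoints`.
#' @examples
#' b <- simulate_experiment(experiment_design(), ground_truth(noise = 0))
#' estimate_rates(b, method = "zero_order")
#' @export
estimate_rates <- function(bottles, method = c("zero_order", "regression",
                                               "first_order"),
                           timepoints = NULL, f0 = NULL, ...) {
  method <- match.arg(method)
  stopifnot(is.data.frame(bottles))
  keys <- intersect(c("experiment", "treatment", "ph", "o2_um", "tracer"),
                    names(bottles))
  if (!"tracer" %in% keys) abort("bottle table must carry a 'tracer' column")

  want <- switch(method,
    zero_order  = "NO2_labeled",
    first_order = "NO2_labeled",
    regression  = "NH4_labeled"
  )
  sub <- bottles %>% filter(tracer == want)
  if (nrow(sub) == 0L) {
    abort(paste0("no bottles with tracer == '", want, "' for method ", method))
  }

  groups <- sub %>% dplyr::group_split(dplyr::across(all_of(keys)))
  out <- purrr::map_dfr(groups, function(g) {
    lab <- g %>% select(all_of(keys)) %>% distinct()
    res <- switch(method,
      zero_order = {
        r <- zero_order_rates(g, timepoints = timepoints, ...)
        tibble(
          method = r$method,
          quantity = c("r_amm_ox", "r_nit_ox"),
          rate = c(r$r_amm_ox, r$r_nit_ox),
          rate_sd = c(r$r_amm_ox_sd, r$r_nit_ox_sd),
          n = r$n_timepoints, timepoints = r$timepoints
        )
      },
      regression = {
        f0g <- f0 %||% derive_f0_nh4(g)
        r <- ammonia_oxidation_rate_regression(g, f0 = f0g, ...)
        tibble(method = r$method, quantity = "r_amm_ox", rate = r$r_amm_ox,
               rate_sd = r$r_amm_ox_sd, n = r$n,
               timepoints = paste(sort(unique(g$time_h)), collapse = ","))
      },
      first_order = {
        r <- first_order_fit(g, ...)
        tibble(method = "first_order", quantity = "k_first_order",
               rate = r$k_per_day, rate_sd = r$k_sd, n = r$n,
               timepoints = paste(sort(unique(g$time_h)), collapse = ","))
      }
    )
    dplyr::bind_cols(lab[rep(1, nrow(res)), , drop = FALSE], res)
  })
  class(out) <- c("n2o_rates", class(out))
  out
}

# f0 of the NH4 pool from the design columns of a bottle table
derive_f0_nh4 <- function(g) {
  need <- c("tracer_added_um", "tracer_purity", "ambient_nh4_um")
  if (!all(need %in% names(g))) {
    abort(paste("cannot derive 15F0 of NH4+: supply f0= or include columns",
                paste(need, collapse = ", ")))
  }
  initial_atom_fraction(g$tracer_added_um[1], g$tracer_purity[1],
                        g$ambient_nh4_um[1])
}
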