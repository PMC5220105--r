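#' Convert N2O molecular ion ratios to molecular fractions
#'
#' Converts calibrated molecular ratios 45R = \[45N2O\]/\[44N2O\] and
#' 46R = \[46N2O\]/\[44N2O\] into the molecular fractions
#' 45F = \[45N2O\]/(\[44N2O\]+\[45N2O\]+\[46N2O\]) and the analogous 46F.
#' Algebraically 45F = 1/(1 + 46R/45R + 1/45R) = 45R/(1 + 45R + 46R); the
#' second form is used because it is also defined when a ratio is zero.
#'
#' @param r45,r46 Numeric vectors of molecular ratios (dimensionless, >= 0).
#'
#' @return A tibble with columns `f45`, `f46` (and implied
#'   `f44 = 1 - f45 - f46`).
#' @examples
#' ratios_to_fractions(0.01, 0.005)
#' ratios_to_fractions(1, 1)  # equal abundances: 1/3 each
#' @seealso [fractions_to_amounts()], [amounts_to_ratios()]
#' @export
ratios_to_fractions <- function(r45, r46) {
  check_numeric(r45, "r45"); check_numeric(r46, "r46")
  if (any(r45 < 0, na.rm = TRUE) || any(r46 < 0, na.rm = TRUE)) {
    abort("molecular ratios must be non-negative")
  }
  denom <- 1 + r45 + r46
  tibble(f45 = r45 / denom, f46 = r46 / denom)
}

#' Convert molecular fractions and total N2O to isotopologue amounts
#'
#' Applies 45N2O = 45F x \[total N2O\] (and likewise for mass 46) and assigns
#' the remainder to 44N2O, so the three amounts add up to the total exactly.
#'
#' @param f45,f46 Molecular fractions in \[0, 1\] with `f45 + f46 <= 1`.
#' @param total_n2o Total N2O amount (nmol), >= 0.
#'
#' @return A tibble with columns `n44`, `n45`, `n46`, `total` (nmol).
#' @examples
#' fractions_to_amounts(0.01, 0.005, total_n2o = 3)
#' @export
fractions_to_amounts <- function(f45, f46, total_n2o) {
  check_numeric(f45, "f45"); check_numeric(f46, "f46")
  check_numeric(total_n2o, "total_n2o")
  if (any(f45 < 0 | f46 < 0, na.rm = TRUE)) abort("fractions must be >= 0")
  if (any(f45 + f46 > 1 + 1e-9, na.rm = TRUE)) abort("f45 + f46 must not exceed 1")
  if (any(total_n2o < 0, na.rm = TRUE)) abort("total_n2o must be >= 0")
  n45 <- f45 * total_n2o
  n46 <- f46 * total_n2o
  tibble(n44 = total_n2o - n45 - n46, n45 = n45, n46 = n46,
         total = n44 + n45 + n46)
}

#' Recover molecular ratios from isotopologue amounts
#'
#' @param n44,n45,n46 Isotopologue amounts (nmol), `n44 > 0`.
#' @return A tibble with columns `r45`, `r46`.
#' @examples
#' amounts_to_ratios(2.955, 0.03, 0.015)
#' @export
amounts_to_ratios <- function(n44, n45, n46) {
  check_numeric(n44, "n44"); check_numeric(n45, "n45"); check_numeric(n46, "n46")
  if (any(n44 <= 0, na.rm = TRUE)) abort("n44 must be positive to form ratios")
  tibble(r45 = n45 / n44, r46 = n46 / n44)
}

#' Delta notation conversions
#'
#' `delta_from_ratio()` expresses a sample isotope ratio in permil deviation
#' from a reference ratio, delta = (R_sample/R_reference - 1) x 1000;
#' `ratio_from_delta()` is its exact inverse. The relevant references are
#' atmospheric N2 for 15N/14N and VSMOW for 18O/16O (see [iso_constants()]).
#'
#' @param r_sample Sample ratio(s), >= 0.
#' @param delta Delta value(s) in permil, > -1000.
#' @param r_reference Reference ratio, > 0.
#'
#' @return Numeric vector: permil values, or ratios.
#' @examples
#' k <- iso_constants()
#' delta_from_ratio(k$r15_air * 1.01, k$r15_air)  # 10 permil
#' ratio_from_delta(34.4, k$r15_air)
#' @export
delta_from_ratio <- function(r_sample, r_reference) {
  check_numeric(r_sample, "r_sample"); check_numeric(r_reference, "r_reference")
  if (any(r_reference <= 0, na.rm = TRUE)) abort("reference ratio must be positive")
  (r_sample / r_reference - 1) * 1000
}

#' @rdname delta_from_ratio
#' @export
ratio_from_delta <- function(delta, r_reference) {
  check_numeric(delta, "delta"); check_numeric(r_reference, "r_reference")
  if (any(r_reference <= 0, na.rm = TRUE)) abort("reference ratio must be positive")
  if (any(delta <= -1000, na.rm = TRUE)) abort("delta must be > -1000 permil")
  r_reference * (1 + delta / 1000)
}

#' Atom fraction from delta value (and back)
#'
#' The 15N atom fraction 15F = \[15N\]/(\[15N\]+\[14N\]) implied by a delta
#' value on the atmospheric-N2 scale, 15F = R/(1+R) with
#' R = R_air x (1 + delta/1000).
#'
#' @inheritParams delta_from_ratio
#' @param f15 Atom fraction(s) in \[0, 1).
#' @param constants Constants list from [iso_constants()].
#' @return Numeric vector of atom fractions (or permil values).
#' @examples
#' atom_fraction_from_delta(0)   # natural abundance, ~0.003663
#' @export
atom_fraction_from_delta <- function(delta, constants = iso_constants()) {
  r <- ratio_from_delta(delta, constants$r15_air)
  r / (1 + r)
}

#' @rdname atom_fraction_from_delta
#' @export
delta_from_atom_fraction <- function(f15, constants = iso_constants()) {
  check_numeric(f15, "f15")
  if (any(f15 < 0 | f15 >= 1, na.rm = TRUE)) abort("atom fraction must be in [0, 1)")
  delta_from_ratio(f15 / (1 - f15), constants$r15_air)
}

#' Site preference of N2O
#'
#' SP = delta15N(alpha) - delta15N(beta): the permil difference between the
#' central (alpha, internal) and terminal (beta, external) nitrogen atoms of
#' the linear N2O molecule. SP is a pathway fingerprint: hydroxylamine-
#' dependent N2O production sits near +34 permil, denitrification and
#' nitrifier denitrification near 0 to -5 permil.
#'
#' @param d15n_alpha,d15n_beta Permil values of the central and terminal N.
#' @return Numeric vector, SP in permil.
#' @examples
#' site_preference(20.0, -14.4)  # 34.4
#' @export
site_preference <- function(d15n_alpha, d15n_beta) {
  check_numeric(d15n_alpha, "d15n_alpha"); check_numeric(d15n_beta, "d15n_beta")
  d15n_alpha - d15n_beta
}

#' Assemble a positional N2O isotope signature
#'
#' Builds the bulk delta15N (mean of alpha and beta) and site preference from
#' the positional values, as one row per sample.
#'
#' @inheritParams site_preference
#' @param d18o Permil vs VSMOW of the N2O oxygen.
#' @return A tibble with `d15n_alpha`, `d15n_beta`, `d15n_bulk`, `sp`, `d18o`.
#' @examples
#' n2o_signature(20, -14.4, d18o = 44.5)
#' @export
n2o_signature <- function(d15n_alpha, d15n_beta, d18o = NA_real_) {
  tibble(
    d15n_alpha = d15n_alpha,
    d15n_beta  = d15n_beta,
    d15n_bulk  = (d15n_alpha + d15n_beta) / 2,
    sp         = site_preference(d15n_alpha, d15n_beta),
    d18o       = d18o
  )
}

#' Two-point linear calibration of delta values
#'
#' Maps measured delta values onto the reference scale through the straight
#' line defined by two standards of known isotopic composition, the usual
#' IRMS normalization step after instrument-internal referencing.
#'
#' @param measured Measured delta value(s), permil.
#' @param std1_measured,std1_true Measured and accepted value of standard 1.
#' @param std2_measured,std2_true Measured and accepted value of standard 2.
#' @return Calibrated delta value(s), permil.
#' @examples
#' two_point_calibration(5, 0, 0, 10, 20)  # slope-2 line: 10
#' @export
two_point_calibration <- function(measured, std1_measured, std1_true,
                                  std2_measured, std2_true) {
  for (v in list(measured, std1_measured, std1_true, std2_measured, std2_true)) {
    check_numeric(v, "delta value")
  }
  if (isTRUE(all.equal(std1_measured, std2_measured, tolerance = 0))) {
    abort("degenerate calibration: the two standards have identical measured values")
  }
  slope <- (std2_true - std1_true) / (std2_measured - std1_measured)
  std1_true + slope * (measured - std1_measured)
}

#' Subtract the time-zero blank from an isotopologue state
#'
#' Incubation bottles killed immediately after tracer addition (t0) carry the
#' background N2O of the sampled water; subtracting their isotopologue
#' amounts from later bottles isolates the tracer-derived excess. Negative
#' excesses are retained (not clipped): downstream regression and
#' significance testing handle them, and clipping would bias slopes.
#'
#' @param state,t0_state Tibbles (or lists) with `n44`, `n45`, `n46` (nmol),
#'   e.g. from [fractions_to_amounts()]. `state` may have multiple rows;
#'   `t0_state` must be a single row (average your t0 replicates first).
#' @param sd,t0_sd Optional per-isotopologue standard deviations, same
#'   shape as the states; when both are given the excess sd is propagated in
#'   quadrature.
#' @return A tibble with `excess_n44`, `excess_n45`, `excess_n46` and, when
#'   uncertainties were supplied, `sd_n44`, `sd_n45`, `sd_n46`.
#' @examples
#' a <- fractions_to_amounts(0.012, 0.006, 3.1)
#' b <- fractions_to_amounts(0.010, 0.006, 3.0)
#' subtract_t0_blank(a, b)
#' @export
subtract_t0_blank <- function(state, t0_state, sd = NULL, t0_sd = NULL) {
  need <- c("n44", "n45", "n46")
  for (nm in need) {
    if (is.null(state[[nm]]) || is.null(t0_state[[nm]])) {
      abort(paste0("states must carry column ", nm))
    }
  }
  if (length(t0_state$n44) != 1L) abort("t0_state must be a single (averaged) state")
  out <- tibble(
    excess_n44 = state$n44 - t0_state$n44,
    excess_n45 = state$n45 - t0_state$n45,
    excess_n46 = state$n46 - t0_state$n46
  )
  if (!is.null(sd) && !is.null(t0_sd)) {
    for (nm in need) {
      out[[paste0("sd_", nm)]] <- sqrt(sd[[nm]]^2 + t0_sd[[nm]]^2)
    }
  }
  out
}

#' Strip the 17O contribution from a measured 45R
#'
#' The mass-45 ion beam of N2O includes 14N14N17O in addition to the two
#' singly-15N-substituted isotopologues. At natural abundance this matters;
#' in tracer work (15F above about 1 percent anywhere in the system) it is
#' negligible next to the tracer 15N signal. With `correct = TRUE` the 17O
#' abundance is scaled mass-dependently from the measured delta18O:
#' 17R = 17R_ref x (1 + d18o/1000)^0.516. With `correct = FALSE` the input
#' is returned unchanged (the tracer-mode path).
#'
#' @param r45 Measured 45/44 molecular ratio(s).
#' @param d18o delta18O of the N2O vs VSMOW, permil.
#' @param correct Apply the natural-abundance 17O correction?
#' @param constants Constants list from [iso_constants()].
#' @return The 15N-only part of `r45` (dimensionless).
#' @examples
#' strip_17o(0.0082, d18o = 0)     # subtracts the reference 17R
#' strip_17o(0.0082, d18o = 0, correct = FALSE)
#' @export
strip_17o <- function(r45, d18o, correct = TRUE, constants = iso_constants()) {
  check_numeric(r45, "r45")
  if (!correct) return(r45)
  check_numeric(d18o, "d18o")
  r17 <- constants$r17_vsmow * (1 + d18o / 1000)^constants$beta_17
  r45 - r17
}

# shared input check: numeric, no NULLs
check_numeric <- function(x, what) {
  if (!is.numeric(x)) abort(paste0(what, " must be numeric"))
  invisible(x)
}
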