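#' Nitrous acid concentration from pH and total nitrite
#'
#' Henderson-Hasselbalch speciation of the NO2-/HNO2 couple:
#' \[HNO2\] = total / (1 + 10^(pH - pKa)). With pKa(HNO2) = 2.8, only a
#' ~1e-5 fraction of a circumneutral nitrite pool is protonated, which is
#' what makes uncatalyzed HNO2 chemistry so slow at lake and ocean pH.
#'
#' @param ph pH value(s).
#' @param total_nitrite Total NO2- + HNO2 concentration (M), >= 0.
#' @param constants Constants list from [iso_constants()] (uses `pka_hno2`).
#' @return \[HNO2\] in M.
#' @examples
#' hno2_concentration(7.54, 1e-6)  # ~1.8e-11 M
#' hno2_concentration(7.20, 1e-6)  # ~4.0e-11 M
#' @export
hno2_concentration <- function(ph, total_nitrite, constants = iso_constants()) {
  check_numeric(ph, "ph"); check_numeric(total_nitrite, "total_nitrite")
  if (any(total_nitrite < 0, na.rm = TRUE)) abort("total_nitrite must be >= 0")
  total_nitrite / (1 + 10^(ph - constants$pka_hno2))
}

#' Fraction of the ammonium pool present as free ammonia
#'
#' NH3 fraction = 1 / (1 + 10^(pKa - pH)) with pKa(NH4+) = 9.25 at 25 C.
#' Ammonia monooxygenase acts on NH3, not NH4+, so this fraction sets the
#' effective substrate concentration for ammonia oxidizers and shrinks as
#' the water acidifies.
#'
#' @param ph pH value(s).
#' @param constants Constants list from [iso_constants()] (uses `pka_nh4`).
#' @return Fraction(s) in (0, 1).
#' @examples
#' nh3_fraction(9.25)  # 0.5 at the pKa
#' nh3_fraction(7.54)  # ~0.019
#' @export
nh3_fraction <- function(ph, constants = iso_constants()) {
  check_numeric(ph, "ph")
  1 / (1 + 10^(constants$pka_nh4 - ph))
}

#' Instantaneous rates of the abiotic N2O-forming reaction network
#'
#' Mass-action rates of the four-reaction chain that can form hybrid N2O
#' without catalysis: HNO2 disproportionation (2 HNO2 <-> NO2 + NO + H2O,
#' second order in \[HNO2\]), NO + NO2 <-> N2O3, the N2O-forming step
#' N2O3 + NH2OH -> N2O + HNO2 + H2O, and the NO sink 2 NO + O2 -> 2 NO2.
#'
#' @param concentrations Named list or vector with entries `hno2`, `no`,
#'   `no2g` (aqueous NO2 radical), `n2o3`, `nh2oh`, `o2`, all in M.
#'   Missing entries default to 0.
#' @param constants Constants list from [iso_constants()] (rate constants
#'   `k_hno2_disprop`, `k_no_no2`, `k_n2o3_nh2oh`, `k_no_o2`).
#' @return A tibble with one row per reaction: `reaction`, `rate_m_day`.
#' @examples
#' abiotic_pathway_rates(list(hno2 = 1.8e-11))
#' abiotic_pathway_rates(list(no = 6.5e-8, o2 = 7e-5))
#' @export
abiotic_pathway_rates <- function(concentrations, constants = iso_constants()) {
  conc <- function(nm) {
    v <- concentrations[[nm]] %||% 0
    check_numeric(v, nm)
    if (v < 0) abort(paste0("concentration ", nm, " must be >= 0"))
    v
  }
  hno2 <- conc("hno2"); no <- conc("no"); no2g <- conc("no2g")
  n2o3 <- conc("n2o3"); nh2oh <- conc("nh2oh"); o2 <- conc("o2")
  tibble(
    reaction = c("hno2_disproportionation", "no_no2_combination",
                 "n2o3_nh2oh_to_n2o", "no_oxidation_by_o2"),
    rate_m_day = c(
      constants$k_hno2_disprop * hno2^2,
      constants$k_no_no2 * no * no2g,
      constants$k_n2o3_nh2oh * n2o3 * nh2oh,
      constants$k_no_o2 * no^2 * o2
    )
  )
}

#' Time-integrate the abiotic network (illustration)
#'
#' Integrates the mass-action ODEs of the four-reaction network with
#' `deSolve::ode`. The network is normally argued from instantaneous rate
#' magnitudes ([abiotic_pathway_rates()]); the integrator exists to show
#' trajectories, e.g. how slowly N2O accumulates from uncatalyzed
#' chemistry at realistic HNO2 levels.
#'
#' @param init Named numeric vector of initial concentrations (M):
#'   `hno2`, `no`, `no2g`, `n2o3`, `nh2oh`, `o2`, `n2o` (missing -> 0).
#' @param times Output times (days).
#' @param constants Constants list from [iso_constants()].
#' @return A tibble: `time_day` plus one concentration column per species.
#' @examples
#' if (requireNamespace("deSolve", quietly = TRUE)) {
#'   integrate_abiotic_network(c(hno2 = 1e-7, nh2oh = 1e-8), times = c(0, 1))
#' }
#' @export
integrate_abiotic_network <- function(init, times = seq(0, 1, by = 0.1),
                                      constants = iso_constants()) {
  if (!requireNamespace("deSolve", quietly = TRUE)) {
    abort("integrate_abiotic_network() needs the deSolve package")
  }
  species <- c("hno2", "no", "no2g", "n2o3", "nh2oh", "o2", "n2o")
  y0 <- setNames(numeric(length(species)), species)
  y0[names(init)] <- init
  if (any(y0 < 0)) abort("initial concentrations must be >= 0")
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0) # the solver may probe marginally negative states
    r <- abiotic_pathway_rates(as.list(y), constants)$rate_m_day
    list(c(
      hno2  = -2 * r[1] + r[3],
      no    = r[1] - r[2] - 2 * r[4],
      no2g  = r[1] - r[2] + 2 * r[4],
      n2o3  = r[2] - r[3],
      nh2oh = -r[3],
      o2    = -r[4],
      n2o   = r[3]
    ))
  }
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL)
  out <- as_tibble(as.data.frame(out))
  names(out)[1] <- "time_day"
  out
}

#' Equilibrium N2O concentration in natural waters
#'
#' Solubility-function concentration of dissolved N2O in equilibrium with a
#' moist atmosphere of given dry mole fraction, as a function of
#' temperature and salinity:
#' ln F = A1 + A2 (100/T) + A3 ln(T/100) + A4 (T/100)^2 +
#' S (B1 + B2 (T/100) + B3 (T/100)^2), with F in mol L^-1 atm^-1 and T in
#' kelvin; the published coefficient set lives in [iso_constants()].
#'
#' @param temperature Water temperature, degrees C (plausible -2 to 40;
#'   outside gives a warning).
#' @param salinity Practical salinity (0 to 40; outside warns).
#' @param x_n2o Atmospheric N2O dry mole fraction (default from the
#'   constants table, 327e-9).
#' @param pressure_atm Total pressure, atm (default 1).
#' @param constants Constants list from [iso_constants()].
#' @return Equilibrium concentration(s), nM.
#' @examples
#' n2o_equilibrium(11.74, 35.06)
#' @export
n2o_equilibrium <- function(temperature, salinity, x_n2o = NULL,
                            pressure_atm = 1, constants = iso_constants()) {
  check_numeric(temperature, "temperature"); check_numeric(salinity, "salinity")
  x_n2o <- x_n2o %||% constants$x_n2o_atm
  if (any(temperature < -2 | temperature > 40, na.rm = TRUE)) {
    warn("temperature outside -2..40 C: solubility function extrapolated")
  }
  if (any(salinity < 0 | salinity > 40, na.rm = TRUE)) {
    warn("salinity outside 0..40: solubility function extrapolated")
  }
  tk <- temperature + 273.15
  a <- constants$n2o_sol_a; b <- constants$n2o_sol_b
  lnf <- a[1] + a[2] * (100 / tk) + a[3] * log(tk / 100) + a[4] * (tk / 100)^2 +
    salinity * (b[1] + b[2] * (tk / 100) + b[3] * (tk / 100)^2)
  exp(lnf) * x_n2o * pressure_atm * 1e9 # mol/L -> nM
}

#' N2O saturation disequilibrium
#'
#' Delta-N2O = measured - equilibrium concentration; positive values mean
#' oversaturation (a net in-situ source or a physical history of
#' supersaturation).
#'
#' @param measured Measured dissolved N2O, nM.
#' @param equilibrium Air-water equilibrium N2O, nM
#'   (see [n2o_equilibrium()]).
#' @return A tibble: `measured`, `equilibrium`, `delta_n2o` (all nM).
#' @examples
#' delta_n2o(37, 15)
#' @export
delta_n2o <- function(measured, equilibrium) {
  check_numeric(measured, "measured"); check_numeric(equilibrium, "equilibrium")
  tibble(measured = measured, equilibrium = equilibrium,
         delta_n2o = measured - equilibrium)
}

#' Add equilibrium and saturation-anomaly columns to a depth profile
#'
#' Data-frame-first wrapper: computes the equilibrium N2O concentration at
#' each depth from `temperature_c` and `salinity`, and the saturation
#' anomaly from the measured `conc_n2o_nm`.
#'
#' @param profile A profile table (see [read_profile_table()]) with columns
#'   `temperature_c`, `salinity`, `conc_n2o_nm`.
#' @param x_n2o Atmospheric N2O dry mole fraction (default from constants).
#' @param constants Constants list from [iso_constants()].
#' @return The profile with added `n2o_equilibrium_nm` and `delta_n2o_nm`.
#' @examples
#' p <- simulate_profile(n_depths = 5, seed = 1)
#' profile_saturation(p)[, c("depth_m", "n2o_equilibrium_nm", "delta_n2o_nm")]
#' @export
profile_saturation <- function(profile, x_n2o = NULL,
                               constants = iso_constants()) {
  stopifnot(is.data.frame(profile))
  need <- c("temperature_c", "salinity", "conc_n2o_nm")
  miss <- setdiff(need, names(profile))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  profile %>%
    mutate(
      n2o_equilibrium_nm = n2o_equilibrium(temperature_c, salinity,
                                           x_n2o = x_n2o, constants = constants),
      delta_n2o_nm = conc_n2o_nm - n2o_equilibrium_nm
    )
}

utils::globalVariables(c("temperature_c", "salinity", "conc_n2o_nm",
                         "n2o_equilibrium_nm"))
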