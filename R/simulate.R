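#' Describe a bottle-sacrifice incubation design
#'
#' Captures the experimental layout of a 15N-tracer incubation: treatments
#' (pH and O2 manipulations), tracer regimes, sacrifice timepoints,
#' replication, tracer additions, and the ambient pools of the sampled
#' water. Defaults mirror a lake hypolimnion experiment: four pH x O2
#' treatments, both tracer regimes (1 uM 15NH4+ + 1 uM unlabeled NO2-, or
#' 1 uM unlabeled NH4+ + 1 uM 15NO2-), bottles sacrificed at 0, 5, 17 and
#' 30 h (one kill control at t0, triplicates later), 120 mL of water per
#' bottle, tracer purities 98.5% (15NH4+) and 99.2% (15NO2-).
#'
#' @param treatments A tibble with columns `treatment`, `ph`, `o2_um`; the
#'   default crosses untreated/reduced pH (7.54 / 7.20) with
#'   untreated/reduced O2 (290 / 70 uM).
#' @param tracers Character subset of `c("NH4_labeled", "NO2_labeled")`.
#' @param timepoints Sacrifice times, hours, ascending, starting at 0.
#' @param replicates Bottles per post-t0 timepoint (default 3).
#' @param t0_replicates Kill-control bottles at t = 0 (default 1).
#' @param tracer_added_um Tracer addition, uM (default 1).
#' @param purity_nh4,purity_no2 15N atom fractions of the tracer salts.
#' @param ambient_nh4_um,ambient_no2_um,ambient_no3_um Ambient pools before
#'   any addition, uM.
#' @param volume_l Incubation water volume per bottle, L (default 0.12).
#' @param name Experiment id written into the bottle table.
#' @return An object of class `experiment_design` (a named list).
#' @examples
#' experiment_design(tracers = "NO2_labeled", replicates = 2)
#' @export
experiment_design <- function(treatments = NULL,
                              tracers = c("NH4_labeled", "NO2_labeled"),
                              timepoints = c(0, 5, 17, 30),
                              replicates = 3, t0_replicates = 1,
                              tracer_added_um = 1,
                              purity_nh4 = 0.985, purity_no2 = 0.992,
                              ambient_nh4_um = 0.47, ambient_no2_um = 0.2,
                              ambient_no3_um = 80, volume_l = 0.12,
                              name = "sim") {
  treatments <- treatments %||% tibble(
    treatment = c("untreated_ph-untreated_o2", "untreated_ph-reduced_o2",
                  "reduced_ph-untreated_o2", "reduced_ph-reduced_o2"),
    ph    = c(7.54, 7.54, 7.20, 7.20),
    o2_um = c(290, 70, 290, 70)
  )
  stopifnot(is.data.frame(treatments),
            all(c("treatment", "ph", "o2_um") %in% names(treatments)))
  tracers <- match.arg(tracers, c("NH4_labeled", "NO2_labeled"),
                       several.ok = TRUE)
  if (is.unsorted(timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly ascending")
  }
  if (timepoints[1] != 0) abort("the design must include a t = 0 kill control")
  if (replicates < 1 || t0_replicates < 1) abort("replicates must be >= 1")
  structure(
    list(treatments = as_tibble(treatments), tracers = tracers,
         timepoints = timepoints, replicates = replicates,
         t0_replicates = t0_replicates, tracer_added_um = tracer_added_um,
         purity_nh4 = purity_nh4, purity_no2 = purity_no2,
         ambient_nh4_um = ambient_nh4_um, ambient_no2_um = ambient_no2_um,
         ambient_no3_um = ambient_no3_um, volume_l = volume_l, name = name),
    class = "experiment_design"
  )
}

#' Ground truth driving a simulated incubation
#'
#' The hidden parameters of the forward model: zero-order ammonia- and
#' nitrite-oxidation rates, the N2O formation mechanism and its yield,
#' background N2O and its isotopic signature, optional ammonium
#' regeneration (a tracer-dilution bias injector), the periplasmic nitrite
#' exchange fraction, and the measurement noise model.
#'
#' Noise defaults (2% relative on concentrations, 1% on total N2O, 1% on
#' molecular ratios, 0.002 absolute on atom fractions) reproduce the order
#' of replicate standard deviations typical of incubation GC-IRMS work;
#' `noise = 0` switches all of them off.
#'
#' @param r_amm_ox,r_nit_ox Zero-order rates, uM/day.
#' @param mechanism Mechanism kind: `"binomial_NH4"`, `"hybrid"` or
#'   `"nitrite_pair"` (see [mechanism_spec()]).
#' @param n2o_yield N2O-N produced per mol NOx- produced (dimensionless).
#' @param background_n2o_nmol Background N2O per bottle, nmol.
#' @param background_d15n,background_d18o Isotopic signature of the
#'   background N2O, permil.
#' @param nh4_regeneration Ammonium regeneration rate, uM/day (adds
#'   unlabeled NH4+, continuously diluting the tracer).
#' @param periplasmic_exchange Fraction of the nitrite-derived N2O atoms
#'   drawn from the bulk (exogenous) NO2- pool; the remainder comes from
#'   endogenous nitrite freshly produced from the NH4+ pool. Default 1
#'   (fully mixed nitrite).
#' @param noise Either a single number applied as relative sd to
#'   concentrations/N2O/ratios (with `f15` absolute sd scaled by 0.1x), or
#'   a named list with entries `conc`, `n2o`, `ratio` (relative sds) and
#'   `f15` (absolute sd). `0` disables noise.
#' @param rng_seed Integer seed making the simulation reproducible.
#' @return An object of class `ground_truth` (a named list).
#' @examples
#' ground_truth(r_amm_ox = 0.5, r_nit_ox = 0.64, mechanism = "hybrid")
#' @export
ground_truth <- function(r_amm_ox = 0.5, r_nit_ox = 0.64,
                         mechanism = "hybrid", n2o_yield = 1e-4,
                         background_n2o_nmol = 3,
                         background_d15n = 5, background_d18o = 44,
                         nh4_regeneration = 0, periplasmic_exchange = 1,
                         noise = NULL, rng_seed = 1L) {
  if (r_amm_ox < 0 || r_nit_ox < 0) abort("rates must be >= 0")
  if (n2o_yield < 0) abort("n2o_yield must be >= 0")
  if (periplasmic_exchange < 0 || periplasmic_exchange > 1) {
    abort("periplasmic_exchange must be in [0, 1]")
  }
  mechanism <- match.arg(mechanism,
                         c("binomial_NH4", "hybrid", "nitrite_pair"))
  default_noise <- list(conc = 0.02, n2o = 0.01, ratio = 0.01, f15 = 0.002)
  if (is.null(noise)) {
    noise <- default_noise
  } else if (is.numeric(noise) && length(noise) == 1L) {
    noise <- list(conc = noise, n2o = noise, ratio = noise, f15 = 0.1 * noise)
  } else {
    noise <- utils::modifyList(default_noise, as.list(noise))
  }
  structure(
    list(r_amm_ox = r_amm_ox, r_nit_ox = r_nit_ox, mechanism = mechanism,
         n2o_yield = n2o_yield, background_n2o_nmol = background_n2o_nmol,
         background_d15n = background_d15n, background_d18o = background_d18o,
         nh4_regeneration = nh4_regeneration,
         periplasmic_exchange = periplasmic_exchange,
         noise = noise, rng_seed = as.integer(rng_seed)),
    class = "ground_truth"
  )
}

# Molecular ratios of an N2O pool at a given bulk d15N / d18O signature.
# r45 carries both singly-substituted 15N isotopologues plus 14N14N17O;
# r46 carries 14N14N18O plus the doubly-15N and 15N-17O terms.
background_ratios <- function(d15n, d18o, constants = iso_constants()) {
  r15 <- ratio_from_delta(d15n, constants$r15_air)
  r18 <- ratio_from_delta(d18o, constants$r18_vsmow)
  r17 <- constants$r17_vsmow * (1 + d18o / 1000)^constants$beta_17
  tibble(r45 = 2 * r15 + r17,
         r46 = r18 + r15^2 + 2 * r15 * r17)
}

# 15NO2- at time t under the trapezoid-consistent zero-order transfer:
# the 15N moved to NO3- over [0, t] is T = R_nit * t * (f(0) + f(t))/2,
# solved in closed form for the endpoint 15NO2-.
transfer_15no2 <- function(a15, inflow15, n0, nt, r_nit, t_d) {
  cc <- r_nit * t_d / 2
  x <- (a15 + inflow15 - cc * a15 / n0) / (1 + cc / nt)
  list(n15 = x, transfer = a15 + inflow15 - x)
}

#' Simulate a complete 15N-tracer incubation experiment
#'
#' Generates a bottle-measurement table from an [experiment_design()] and a
#' [ground_truth()]. Dissolved pools evolve by zero-order mass balance:
#' ammonia oxidation moves N from NH4+ to NO2-, nitrite oxidation from
#' NO2- to NO3-; the 15N transferred from nitrite to nitrate over \[0, t\]
#' is R_nit_ox x t x (15F_NO2(0) + 15F_NO2(t))/2 (solved in closed form),
#' so the per-timepoint pool-model estimator is the exact inverse of the
#' generator on noise-free data. In 15NO2--labeled regimes the
#' ammonia-oxidation influx enters the 14NO2- sub-pool (the ammonium pool
#' is unlabeled); in 15NH4+-labeled regimes it carries the ammonium pool's
#' atom fraction, which ammonium regeneration dilutes continuously when
#' enabled. N2O accumulates on top of the bottle background at
#' yield x R_amm_ox with isotopologues drawn per the mechanism from the
#' interval-averaged pool atom fractions. Produced N2O-N (order 1e-4 uM
#' over 30 h at realistic yields) is tracked separately and not debited
#' from the uM-scale dissolved pools, which is far below measurement
#' resolution. Measurements are then perturbed: multiplicative Gaussian
#' noise on concentrations, total N2O and molecular ratios (truncated at
#' 0), additive Gaussian on atom fractions (truncated to \[0, 1\]).
#'
#' @param design An [experiment_design()].
#' @param truth A [ground_truth()].
#' @return A bottle-measurement tibble (one row per bottle): `experiment`,
#'   `treatment`, `ph`, `o2_um`, `tracer`, `bottle`, `time_h`, `conc_nh4`,
#'   `conc_no2`, `conc_no3` (uM), `f15_no2`, `f15_no3`, `n2o_total_nmol`,
#'   `r45`, `r46`, plus the design columns `volume_l`, `tracer_added_um`,
#'   `tracer_purity`, `ambient_nh4_um`. Deterministic given
#'   `truth$rng_seed`. The generating objects are attached as attributes
#'   `design` and `truth`.
#' @examples
#' b <- simulate_experiment(experiment_design(), ground_truth(noise = 0))
#' head(b)
#' @export
simulate_experiment <- function(design, truth) {
  stopifnot(inherits(design, "experiment_design"), inherits(truth, "ground_truth"))
  constants <- iso_constants()
  f_nat <- constants$f15_natural

  grid <- tidyr::expand_grid(design$treatments, tracer = design$tracers)
  post_t <- design$timepoints[design$timepoints > 0]
  times <- c(rep(0, design$t0_replicates), rep(post_t, each = design$replicates))

  bg <- background_ratios(truth$background_d15n, truth$background_d18o, constants)
  bg_fr <- ratios_to_fractions(bg$r45, bg$r46)
  bg_state <- fractions_to_amounts(bg_fr$f45, bg_fr$f46, truth$background_n2o_nmol)

  sim_condition <- function(treatment, ph, o2_um, tracer) {
    added <- design$tracer_added_um
    nh4_0 <- design$ambient_nh4_um + added
    no2_0 <- design$ambient_no2_um + added
    no3_0 <- design$ambient_no3_um
    purity <- if (tracer == "NH4_labeled") design$purity_nh4 else design$purity_no2
    f_nh4_0 <- if (tracer == "NH4_labeled") {
      initial_atom_fraction(added, design$purity_nh4, design$ambient_nh4_um,
                            constants = constants)
    } else f_nat
    f_no2_0 <- if (tracer == "NO2_labeled") {
      initial_atom_fraction(added, design$purity_no2, design$ambient_no2_um,
                            constants = constants)
    } else f_nat

    t_d <- times / 24
    ramm <- truth$r_amm_ox; rnit <- truth$r_nit_ox; rho <- truth$nh4_regeneration

    nh4_t <- nh4_0 + (rho - ramm) * t_d
    if (any(nh4_t < 0)) {
      abort(sprintf("r_amm_ox = %.3g uM/day drives the NH4+ pool negative within %g h",
                    ramm, max(times)))
    }
    no2_t <- no2_0 + (ramm - rnit) * t_d
    if (any(no2_t < 0)) {
      abort(sprintf("r_nit_ox = %.3g uM/day drives the NO2- pool negative within %g h",
                    rnit, max(times)))
    }
    no3_t <- no3_0 + rnit * t_d

    # NH4+ atom fraction: constant without regeneration; with regeneration,
    # unlabeled influx dilutes it along the closed-form power law of the
    # linear pool trajectory. fbar is its mean over [0, t].
    if (rho > 0 && abs(f_nh4_0 - f_nat) > 1e-12) {
      f_nh4_at <- function(tt) {
        n_t <- nh4_0 + (rho - ramm) * tt
        if (abs(rho - ramm) < 1e-12) {
          f_nat + (f_nh4_0 - f_nat) * exp(-rho * tt / nh4_0)
        } else {
          f_nat + (f_nh4_0 - f_nat) * (n_t / nh4_0)^(-rho / (rho - ramm))
        }
      }
      f_nh4_t <- vapply(t_d, f_nh4_at, numeric(1))
      fbar_nh4 <- vapply(t_d, function(tt) {
        if (tt == 0) return(f_nh4_0)
        integrate(function(u) vapply(u, f_nh4_at, numeric(1)), 0, tt,
                  rel.tol = 1e-10)$value / tt
      }, numeric(1))
    } else {
      f_nh4_t <- rep(f_nh4_0, length(t_d))
      fbar_nh4 <- rep(f_nh4_0, length(t_d))
    }

    # labeled influx into NO2-: the NH4+ label in NH4-labeled regimes;
    # zero (all-14N) in NO2-labeled regimes per the pool balance equations
    inflow15 <- if (tracer == "NH4_labeled") fbar_nh4 * ramm * t_d else 0
    n15_no2_0 <- f_no2_0 * no2_0
    tr <- transfer_15no2(n15_no2_0, inflow15, no2_0, no2_t, rnit, t_d)
    n15_no2 <- tr$n15
    n15_no3 <- f_nat * no3_0 + tr$transfer
    f_no2_t <- n15_no2 / no2_t
    f_no3_t <- n15_no3 / no3_t

    # N2O production on top of the background
    fbar_no2 <- (f_no2_0 + f_no2_t) / 2
    px <- truth$periplasmic_exchange
    f_no2_eff <- px * fbar_no2 + (1 - px) * fbar_nh4
    prod_nm_day <- truth$n2o_yield * ramm * 1000 / 2 # molecules, nM/day
    prod_nmol <- prod_nm_day * t_d * design$volume_l
    dist <- mechanism_isotopologue_distribution(truth$mechanism,
                                                f_nh4 = fbar_nh4,
                                                f_no2 = f_no2_eff)
    n44 <- bg_state$n44 + prod_nmol * dist$p44
    n45 <- bg_state$n45 + prod_nmol * dist$p45
    n46 <- bg_state$n46 + prod_nmol * dist$p46

    tibble(
      experiment = design$name, treatment = treatment, ph = ph, o2_um = o2_um,
      tracer = tracer,
      bottle = sprintf("%s_%s_b%02d", treatment, tracer, seq_along(times)),
      time_h = times,
      conc_nh4 = nh4_t, conc_no2 = no2_t, conc_no3 = no3_t,
      f15_no2 = f_no2_t, f15_no3 = f_no3_t,
      n2o_total_nmol = n44 + n45 + n46,
      r45 = n45 / n44, r46 = n46 / n44,
      volume_l = design$volume_l, tracer_added_um = added,
      tracer_purity = purity, ambient_nh4_um = design$ambient_nh4_um
    )
  }

  out <- withr::with_seed(truth$rng_seed, {
    clean <- purrr::pmap_dfr(
      list(grid$treatment, grid$ph, grid$o2_um, grid$tracer), sim_condition)
    nz <- truth$noise
    mult <- function(x, s) if (s > 0) pmax(x * (1 + stats::rnorm(length(x), 0, s)), 0) else x
    addn <- function(x, s) if (s > 0) pmin(pmax(x + stats::rnorm(length(x), 0, s), 0), 1) else x
    clean %>% mutate(
      conc_nh4 = mult(conc_nh4, nz$conc),
      conc_no2 = mult(conc_no2, nz$conc),
      conc_no3 = mult(conc_no3, nz$conc),
      f15_no2 = addn(f15_no2, nz$f15),
      f15_no3 = addn(f15_no3, nz$f15),
      n2o_total_nmol = mult(n2o_total_nmol, nz$n2o),
      r45 = mult(r45, nz$ratio),
      r46 = mult(r46, nz$ratio)
    )
  })
  attr(out, "design") <- design
  attr(out, "truth") <- truth
  out
}

#' Simulate a geochemical depth profile
#'
#' Builds a small synthetic water-column profile whose N2O site preference
#' at each depth is the mole-weighted mixture of two end-members — a
#' high-SP source (hydroxylamine-dependent production, default 34 permil)
#' and a low-SP source (denitrification-type, default -5 permil) — and
#' whose dissolved N2O is the air-water equilibrium concentration plus a
#' prescribed saturation anomaly.
#'
#' @param n_depths Number of depths.
#' @param depths Depths in m (default `seq(5, 50, length.out = n_depths)`).
#' @param weight_high Mixing weight(s) of the high-SP end-member in
#'   \[0, 1\]; scalar or per depth. Default ramps 0 to 1 with depth.
#' @param sp_high,sp_low End-member site preferences, permil.
#' @param delta_n2o_nm Saturation anomaly per depth, nM (default ramps 0
#'   to 25).
#' @param temperature_c,salinity,ph,o2_um Hydrographic columns, scalar or
#'   per depth.
#' @param d15n_bulk Bulk delta15N-N2O per depth, permil (default 5).
#' @param noise Relative Gaussian sd applied to concentrations (default 0).
#' @param seed RNG seed used when `noise > 0`.
#' @param constants Constants list from [iso_constants()].
#' @return A profile tibble with the columns of [read_profile_table()].
#' @examples
#' simulate_profile(n_depths = 4, weight_high = 1)$sp_permil  # all 34
#' @export
simulate_profile <- function(n_depths = 12, depths = NULL, weight_high = NULL,
                             sp_high = 34, sp_low = -5, delta_n2o_nm = NULL,
                             temperature_c = 8, salinity = 0.2, ph = 7.5,
                             o2_um = 150, d15n_bulk = 5, noise = 0, seed = 1L,
                             constants = iso_constants()) {
  depths <- depths %||% seq(5, 50, length.out = n_depths)
  n <- length(depths)
  weight_high <- weight_high %||% seq(0, 1, length.out = n)
  if (any(weight_high < 0 | weight_high > 1)) abort("weights must be in [0, 1]")
  delta_n2o_nm <- delta_n2o_nm %||% seq(0, 25, length.out = n)
  rep_n <- function(x) rep_len(x, n)

  sp <- weight_high * sp_high + (1 - weight_high) * sp_low
  eq <- n2o_equilibrium(rep_n(temperature_c), rep_n(salinity),
                        constants = constants)
  out <- tibble(
    depth_m = depths,
    temperature_c = rep_n(temperature_c), salinity = rep_n(salinity),
    ph = rep_n(ph), o2_um = rep_n(o2_um),
    conc_nh4 = rep_n(1), conc_no2 = rep_n(0.3), conc_no3 = rep_n(60),
    conc_n2o_nm = eq + rep_n(delta_n2o_nm),
    d15n_n2o = rep_n(d15n_bulk),
    d18o_n2o = rep_n(44.5),
    d15n_alpha = rep_n(d15n_bulk) + sp / 2,
    d15n_beta = rep_n(d15n_bulk) - sp / 2,
    sp_permil = sp,
    d15n_no3 = rep_n(6), d18o_no3 = rep_n(3)
  )
  if (noise > 0) {
    out <- withr::with_seed(as.integer(seed), {
      out %>% mutate(across(
        c(conc_nh4, conc_no2, conc_no3, conc_n2o_nm),
        ~ pmax(.x * (1 + stats::rnorm(n, 0, noise)), 0)))
    })
  }
  out
}
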