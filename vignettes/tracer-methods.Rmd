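---
title: "Models and conventions behind n2otracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind n2otracer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2otracer)
```

This vignette documents the models implemented by `n2otracer`, the
conventions and defaults that a user may want to change, and what the
package's synthetic-data validation does and does not demonstrate.

## The measurement model

An incubation bottle delivers, per sacrifice time: total concentrations of
NH₄⁺, NO₂⁻ and NO₃⁻ (µM), measured ¹⁵N atom fractions of NO₂⁻ and NO₃⁻,
the total dissolved N₂O (nmol), and calibrated molecular ion ratios
⁴⁵R = [⁴⁵N₂O]/[⁴⁴N₂O] and ⁴⁶R = [⁴⁶N₂O]/[⁴⁴N₂O]. Ratios become molecular
fractions through

$$^{45}F = \frac{^{45}R}{1 + {}^{45}R + {}^{46}R}, \qquad
  ^{46}F = \frac{^{46}R}{1 + {}^{45}R + {}^{46}R},$$

which is algebraically identical to the reciprocal form
$1/(1 + {}^{46}R/^{45}R + 1/^{45}R)$ but remains defined when a ratio is
zero. Amounts follow as $^{45}\mathrm{N_2O} = {}^{45}F \times
[\mathrm{total\ N_2O}]$, with mass 44 taking the remainder so the three
amounts sum to the total exactly. Kill-control (t₀) bottles define the
background; their average isotopologue amounts are subtracted from every
later bottle. Negative blank-corrected excesses are deliberately retained:
clipping at zero would bias the production-rate regressions upward.

Mass 45 contains ¹⁴N¹⁴N¹⁷O in addition to the two ¹⁵N isotopologues. In
tracer work the label dominates and the ¹⁷O term is negligible; for
natural-abundance applications `strip_17o()` applies the mass-dependent
scaling $^{17}R = {}^{17}R_{ref}\,(1+\delta^{18}O/1000)^{0.516}$ and
subtracts it. The correction is off along the tracer path and explicit
everywhere else, so the no-correction path is exactly the identity.

## Rate estimators

**Regression estimator (¹⁵NH₄⁺ regime).** [¹⁵NOₓ⁻] = [NO₂⁻]·¹⁵F_NO₂ +
[NO₃⁻]·¹⁵F_NO₃ grows linearly when ammonia oxidation is zero order and the
ammonium labeling is constant; the OLS slope divided by the initial atom
fraction ¹⁵F₀ of the ammonium pool gives the ammonia oxidation rate. ¹⁵F₀
comes from the tracer addition, its purity, the ambient pool size, and an
assumed ambient δ¹⁵N of 0‰ (configurable). The slope's standard error is
scaled by the same 1/¹⁵F₀.

**Zero-order pool model (¹⁵NO₂⁻ regime).** The four balance equations for
the nitrite and nitrate sub-pools are inverted per timepoint:
R_nit_ox from the ¹⁵N balance (loss of ¹⁵NO₂⁻ and gain of ¹⁵NO₃⁻, combined
by weighted least squares, equal weights by default), then R_amm_ox from
the ¹⁴NO₂⁻ balance. The equations treat ¹⁵F_NO₂ as a constant coefficient
over [0, t]; because the fraction actually drifts downward as unlabeled
nitrite is produced, the estimator uses the mean of the measured fractions
at 0 and t. That choice is also the model definition in the package's
simulator: the ¹⁵N transferred over [0, t] is defined as
$T = R_{nit}\,t\,(f(0)+f(t))/2$, the second-order-accurate (trapezoid)
discretization of the continuous isotope-dilution ODE, solved in closed
form. Simulator and estimator are therefore exact inverses of each other
on noise-free data — the parameter-recovery tests check equality at 1e-9
relative, not approximate agreement.

Per-timepoint estimates are averaged over a user-selected set of
timepoints (default: all later than 12 h, where the signal has developed);
the reported uncertainty is the standard deviation among the per-timepoint
estimates, the convention used with sacrifice designs. That scatter-based
sd is blind to one error source: every timepoint shares the *same*
kill-control blank, so blank error moves all per-timepoint estimates
together. Supplying `measurement_sd` (relative sd of concentrations,
absolute sd of atom fractions) adds a propagated uncertainty computed by a
numerical delta method through the per-timepoint solves, shared-blank
correlation included. In simulation the ±2 propagated-sd interval covers
the truth ~97% of the time, while the scatter-based interval under-covers
for R_amm_ox (~82%) for exactly this reason.

The ammonia-oxidation influx is booked entirely as ¹⁴NO₂⁻ (the ammonium
pool is unlabeled in ¹⁵NO₂⁻ regimes); `na_influx = TRUE` splits it at
natural abundance instead, which changes rates by ~0.4% at most.

**First-order alternative.** A log-linear fit of [NH₄⁺] vs time returns a
rate constant per day. First-order constants have dimension time⁻¹; the
per-day unit is used throughout even where source literature prints
otherwise. The estimator requires strictly positive concentrations and is
intended for settings where ambient NH₄⁺ sits near the oxidizers'
half-saturation range; Michaelis–Menten fitting is out of scope.

## N₂O attribution

Production rates of ⁴⁵N₂O and ⁴⁶N₂O are OLS slopes of the blank-corrected
amounts over the post-t₀ bottles, with two-sided t-tests on the slopes
(α = 0.05 by default). Total ¹⁵N incorporation is Rate₄₅ + 2·Rate₄₆
(mass 46 carries two labeled atoms). The N₂O yield divides incorporation
by the ¹⁵NOₓ⁻ production rate, R_amm_ox · ¹⁵F₀ · 1000 in nM/day — the only
denominator arithmetically consistent with quoting yields per mol of NOₓ⁻
produced from the labeled ammonium pool.

Mechanisms are modeled by where the two N atoms of each product molecule
come from. With source atom fractions $f_a, f_b$:
$p_{46} = f_a f_b$, $p_{45} = f_a(1-f_b) + f_b(1-f_a)$,
$p_{44} = (1-f_a)(1-f_b)$; binomial-NH₄ sets $f_a = f_b = f_{NH_4}$,
hybrid uses $(f_{NH_4}, f_{NO_2})$, nitrite-pair $f_a = f_b = f_{NO_2}$.
Under binomial pairing the expected production ratio is
$^{46}:{}^{45} = f/(2(1-f))$ — about 1.0 at $f = 0.67$ — so an observed
ratio well below that expectation is the signature of hybrid formation.

`classify_mechanism()` ranks the three mechanisms by a chi-square-style
distance between observed and predicted ⁴⁶:⁴⁵ production, summed over the
available tracer regimes:
$\sum_r (r_{46} - \rho_m r_{45})^2 / (se_{46}^2 + \rho_m^2 se_{45}^2 +
(10^{-6} r_{45})^2)$. The floor term keeps noise-free data (zero standard
errors) finite without affecting noisy data; it acts as a tie-break scale,
not a tuning constant. Two hard rules sit on top: significant ⁴⁵N₂O
without significant ⁴⁶N₂O in a ¹⁵NO₂⁻ regime rejects nitrite-pair whenever
its predicted ratio exceeds the observed upper bound
$(r_{46} + 2\,se_{46})/r_{45}$; and an observed ratio below the binomial
expectation in the ¹⁵NH₄⁺ regime flags an inferred hybrid contribution.
With no significant production anywhere the result is "indeterminate"
rather than a forced ranking.

For small signals that never reach significant daily rates,
`predict_delta_trajectory()` adds mechanism-distributed molecules to the
background pool by exact mole balance and reports the changes in bulk
δ¹⁵N, δ¹⁸O and the mass-46 ratio. Producing from a highly labeled pool by
binomial pairing moves mass 46 over an order of magnitude more than hybrid
production does at the same amount, while the δ¹⁵N responses differ only
by the ~2× atom-count factor — that contrast is the discrimination. The
δ¹⁸O of produced N₂O defaults to the background's value unless a source
δ¹⁸O is specified; oxygen isotope systematics beyond this mixing are out
of scope. Amount-weighted delta mixing and isotopologue-count mixing agree
to first order; the package uses exact isotopologue mole balance.

## Aquatic chemistry

Speciation is Henderson–Hasselbalch with pKa(NH₄⁺) = 9.25 and
pKa(HNO₂) = 2.8, used as temperature-independent constants; both are
overridable through the constants table for temperature-corrected work.
The abiotic network evaluates mass-action rates for HNO₂
disproportionation (second order, k = 1.6 M⁻¹day⁻¹), NO + NO₂ → N₂O₃
(9.5×10⁷ M⁻¹day⁻¹), N₂O₃ + NH₂OH → N₂O (1.7×10¹³ M⁻¹day⁻¹) and
2NO + O₂ → 2NO₂ (1.8×10¹¹ M⁻²day⁻¹). Rates are reported instantaneously
because the scientific argument is one of magnitudes: at [HNO₂] ≈ 2×10⁻¹¹ M
the disproportionation step runs ten orders of magnitude below observed
⁴⁵N₂O production, excluding uncatalyzed HNO₂ chemistry as the source. An
ODE integrator (deSolve) is provided for illustration only; reverse
reactions are not modeled since no reverse constants are available.

Air–water equilibrium uses the standard N₂O solubility polynomial in
temperature and salinity (mol L⁻¹ atm⁻¹, moist-atmosphere form), with the
coefficient set stored in the constants table and an atmospheric dry mole
fraction defaulting to 327 ppb (configurable; the appropriate value drifts
with the year of sampling). ΔN₂O is measured minus equilibrium. The
speciation examples use the 1 µM added nitrite pool; ambient nitrite can
simply be added to the `total_nitrite` argument.

## The synthetic-data generator

`simulate_experiment()` emulates a triplicate bottle-sacrifice design:
four pH × O₂ treatments, both tracer regimes (1 µM labeled substrate plus
1 µM unlabeled counterpart), sacrifices at 0/5/17/30 h with one kill
control and triplicates, 0.12 L bottles, tracer purities 0.985 / 0.992.
Default ambient pools (NH₄⁺ 0.47, NO₂⁻ 0.2, NO₃⁻ 80 µM) put the initial
ammonium labeling at 0.67, the hypolimnion condition the default
treatments represent. Noise defaults — 2% relative on concentrations, 1%
on total N₂O and on ion ratios, 0.002 absolute on atom fractions —
reproduce the order of replicate scatter typical of incubation GC-IRMS
work; all are configurable and `noise = 0` gives the analytic forward
model exactly.

Produced N₂O-N is tracked on top of the bottle background but *not*
debited from the µM-scale dissolved pools: at realistic yields (~10⁻⁴) it
amounts to ≲2×10⁻⁴ µM over 30 h, four orders of magnitude below
concentration measurement noise, and the pool balance equations being
inverted contain no N₂O sink. The conservation tests therefore assert
exact closure of dissolved inorganic N and bound the N₂O term separately.
Ammonium regeneration, when enabled, adds unlabeled NH₄⁺ continuously and
dilutes the tracer along a closed-form power law — the bias that makes the
regression estimator read low relative to the pool model. The
`periplasmic_exchange` parameter mixes the nitrite-derived atoms between
the bulk (labeled) pool and endogenous nitrite carrying the ammonium
pool's signature; it exists only in the generator, as a way to produce
data from the two-pool hypothesis, and deliberately has no counterpart in
the classifier, which cannot distinguish it from hybrid formation on
these observables.

What passing tests show — and what they do not. Parameter recovery, the
calibration of the propagated uncertainty (bias < 2%, ±2 sd coverage
≥ 90% over 500 noisy runs at 0.5 µM/day and 2% noise), and 100% mechanism
identification on noise-free data are statements about the estimators
being correct inverses of the stated forward model under its noise
assumptions. Real incubations add features the generator does not
emulate: bottle effects and community drift over 30 h, non-Gaussian IRMS
error at very low signal, O₂ drawdown, gas–liquid partitioning of NO and
N₂O, and Michaelis–Menten saturation. Agreement on synthetic data bounds
implementation error, not these model errors.

## Numerical conventions and degenerate inputs

Time is carried in hours and rates reported per day. Fraction invariants
are checked at 1e-9 absolute, amounts at 1e-6 nmol; ratio/fraction round
trips hold to 1e-12 relative. Flat production series yield rate 0 with
p = 1 (an undefined slope test is reported as "no evidence", not an
error). Degenerate calibrations (identical standards), empty pools,
non-positive reference ratios, atom fractions outside [0, 1] and
descending depths all raise errors that name the offending row or rate.
Table IO serializes doubles with 17 significant digits and re-parses them
through `strtod`, so write/read round trips are bit-identical; problem
sizes throughout the test suite (500 calibration runs, 100 classification
draws) were chosen to characterize the estimators well while keeping the
default suite around half a minute.
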