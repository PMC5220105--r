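# n2otracer

Isotopologue accounting and rate inference for ¹⁵N-tracer N₂O incubation
experiments with aquatic ammonia oxidizers.

Ammonia-oxidizing bacteria and archaea release the greenhouse gas N₂O as a
byproduct of nitrification, and the pathway they use leaves a fingerprint in
the molecular masses of the product. In a bottle incubation amended with
¹⁵NH₄⁺ or ¹⁵NO₂⁻, N₂O formed by pairing two atoms from the labeled pool
accumulates doubly-substituted ⁴⁶N₂O; "hybrid" N₂O — one atom from the
NH₄⁺/NH₂OH pool and one from the NO₂⁻ pool — accumulates ⁴⁵N₂O with almost no
⁴⁶N₂O; nitrifier denitrification draws both atoms from nitrite. `n2otracer`
implements the quantitative machinery that turns raw incubation measurements
into rates, yields, and a mechanism attribution, and ships a synthetic
experiment generator with known ground truth so the whole pipeline is
testable end to end.

## What it computes

**Isotopologue accounting.** Calibrated ion-current ratios
⁴⁵R = [⁴⁵N₂O]/[⁴⁴N₂O] and ⁴⁶R = [⁴⁶N₂O]/[⁴⁴N₂O] are converted to molecular
fractions ⁴⁵F = ⁴⁵R/(1 + ⁴⁵R + ⁴⁶R) (likewise ⁴⁶F), then to amounts
⁴⁵N₂O = ⁴⁵F × [total N₂O]; kill-control (t₀) blanks are subtracted, and
delta/ratio/atom-fraction conversions, two-point calibration, site
preference SP = δ¹⁵Nᵅ − δ¹⁵Nᵝ, and an optional mass-dependent ¹⁷O
correction round out the toolbox.

**Rate inference.** Two estimators for the ammonia oxidation rate:

- regression: the OLS slope of [¹⁵NOₓ⁻] vs time in a ¹⁵NH₄⁺ incubation,
  multiplied by the isotope dilution factor 1/¹⁵F₀ of the ammonium pool;
- zero-order pool model: per-timepoint inversion of the four balance
  equations for the ¹⁴/¹⁵N sub-pools of NO₂⁻ and NO₃⁻ in a ¹⁵NO₂⁻
  incubation, yielding both R_amm_ox and R_nit_ox (and hence the net
  nitrite consumption R_nit_ox − R_amm_ox);

plus a first-order alternative (log-linear fit of [NH₄⁺]) and treatment
comparisons in percent.

**Attribution.** ⁴⁵/⁴⁶N₂O production slopes with significance tests, total
¹⁵N incorporation (Rate₄₅ + 2·Rate₄₆), N₂O yield per mol NOₓ⁻ produced, the
binomial pairing expectation ⁴⁶:⁴⁵ = f²/(2f(1−f)), per-mechanism
isotopologue distributions, predicted δ¹⁵N/δ¹⁸O trajectories of the
dissolved N₂O pool under each mechanism, and a ranked mechanism
classification.

**Aquatic chemistry.** Henderson–Hasselbalch speciation of NH₄⁺/NH₃ and
NO₂⁻/HNO₂, the four-reaction abiotic N₂O-forming network (HNO₂
disproportionation → NO/NO₂ → N₂O₃ → N₂O with NH₂OH) as instantaneous
mass-action rates or an ODE integration, and air–water N₂O equilibrium /
saturation anomaly ΔN₂O from the standard solubility function.

## Worked example

Simulate a four-treatment lake experiment with a known hybrid mechanism,
recover the rates, and attribute the mechanism:

```r
library(n2otracer)

design  <- experiment_design()   # 4 pH x O2 treatments, both tracers, t = 0/5/17/30 h
truth   <- ground_truth(r_amm_ox = 0.5, r_nit_ox = 0.64,
                        mechanism = "hybrid", rng_seed = 42)
bottles <- simulate_experiment(design, truth)

estimate_rates(bottles, method = "zero_order")
#> # A tibble: 8 × 11
#>   experiment treatment      ph o2_um tracer method quantity  rate rate_sd     n timepoints
#> 1 sim        reduced_ph…  7.2     70 NO2_l… zero_… r_amm_ox 0.500 2.08e-3     2 17,30
#> 2 sim        reduced_ph…  7.2     70 NO2_l… zero_… r_nit_ox 0.653 2.21e-2     2 17,30
#> 3 sim        reduced_ph…  7.2    290 NO2_l… zero_… r_amm_ox 0.447 1.34e-2     2 17,30
#> ...
```

Under 2% measurement noise the estimator lands on the generating rates
(0.5 and 0.64 µM/day) within its reported uncertainty. The attribution
report ranks mechanisms per treatment:

```r
att <- attribute_n2o(bottles)
att$ranking[[1]]
#> Mechanism ranking (best first):
#> # A tibble: 3 × 4
#>   mechanism    score rejected note
#> 1 hybrid        8.81 FALSE    ""
#> 2 binomial_NH4 74.0  FALSE    ""
#> 3 nitrite_pair 90.7  FALSE    ""
#> note: observed 46:45 (0.154) in the 15NH4+ regime is below the binomial
#> expectation (1.02): hybrid contribution inferred
```

The generating hybrid mechanism is ranked first, and the diagnostic that
motivates it — observed ⁴⁶:⁴⁵ production far below the binomial pairing
expectation of ~1.0 at ¹⁵F₀ = 0.67 — is flagged. Yields chain the pieces
together:

```r
f0  <- initial_atom_fraction(1, 0.985, 0.47)        # 0.671
pr  <- production_rates(subset(bottles,
         treatment == "untreated_ph-untreated_o2" & tracer == "NH4_labeled"))
inc <- total_15n_incorporation(pr)                  # 0.0233 nM-N/day
n2o_yield(inc, amm_ox_rate = 0.445, f0 = f0)
#>       yield incorporation_nm_day nox15_rate_nm_day
#> 1 0.0000780               0.0233              299.
```

i.e. roughly 8 in 100,000 nitrogen atoms passing through nitrification end
up in N₂O under this simulated truth.

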