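# shared fixtures: compact single-treatment designs built in code

one_treatment <- function(...) {
  experiment_design(
    treatments = data.frame(treatment = "t1", ph = 7.54, o2_um = 290), ...)
}

# noise-free data makes lm() warn about perfect fits; that is expected here
quietly_fit <- function(expr) suppressWarnings(expr)

# paper-scale truth used across tests (hybrid mechanism, lake-like rates)
lake_truth <- function(...) {
  ground_truth(r_amm_ox = 0.5, r_nit_ox = 0.64, n2o_yield = 1e-4, ...)
}
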