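#' Isotope and chemistry constants
#'
#' Reference isotope ratios, acid-base constants, rate constants of the
#' abiotic N2O-forming network, and the seawater N2O solubility coefficients,
#' collected in one overridable table.
#'
#' The reference ratios are the conventional values for the international
#' scales: `r15_air` is the 15N/14N ratio of atmospheric N2 (0.0036765),
#' `r18_vsmow` and `r17_vsmow` are the 18O/16O (0.0020052) and 17O/16O
#' (0.0003799) ratios of Vienna Standard Mean Ocean Water. `beta_17` is the
#' exponent of the mass-dependent relation used to scale the 17O abundance
#' with measured 18O (17R = 17R_ref * (18R/18R_ref)^0.516).
#'
#' Solubility coefficients (`n2o_sol_a`, `n2o_sol_b`) parameterize the
#' temperature/salinity function for the equilibrium solubility of N2O in
#' natural waters expressed in mol L^-1 atm^-1 of dry-air mole fraction
#' (moist-atmosphere form), used by [n2o_equilibrium()].
#'
#' @param ... Named overrides, e.g. `iso_constants(pka_hno2 = 3.1)`. Unknown
#'   names are an error.
#'
#' @return A named list of constants. In addition to the values above it
#'   carries `f15_natural`, the natural-abundance 15N atom fraction implied
#'   by `r15_air`.
#'
#' @examples
#' k <- iso_constants()
#' k$f15_natural       # ~0.003663
#' iso_constants(x_n2o_atm = 332e-9)$x_n2o_atm
#' @export
iso_constants <- function(...) {
  base <- list(
    r15_air       = 0.0036765,
    r18_vsmow     = 0.0020052,
    r17_vsmow     = 0.0003799,
    beta_17       = 0.516,
    pka_nh4       = 9.25,
    pka_hno2      = 2.8,
    # rate constants of the abiotic network, per day
    k_hno2_disprop = 1.6,      # M^-1 day^-1, 2 HNO2 <-> NO2 + NO + H2O
    k_no_no2       = 9.5e7,    # M^-1 day^-1, NO + NO2 <-> N2O3
    k_n2o3_nh2oh   = 1.7e13,   # M^-1 day^-1, N2O3 + NH2OH -> N2O + HNO2 + H2O
    k_no_o2        = 1.8e11,   # M^-2 day^-1, 2 NO + O2 -> 2 NO2
    x_n2o_atm      = 327e-9,   # atmospheric N2O dry mole fraction
    n2o_sol_a      = c(-165.8806, 222.8743, 92.0792, -1.48425),
    n2o_sol_b      = c(-0.056235, 0.031619, -0.0048472)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(base))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      abort(paste0("unknown constant(s): ", paste(bad, collapse = ", ")))
    }
    base[names(overrides)] <- overrides
  }
  base$f15_natural <- base$r15_air / (1 + base$r15_air)
  base
}

#' Read and write the constants table as YAML
#'
#' The constants of [iso_constants()] can be serialized to a plain YAML file
#' so an analysis records exactly which reference ratios and rate constants
#' it used. `read_iso_config()` applies the file's entries as overrides on
#' the package defaults, so a partial file is fine.
#'
#' @param constants A list as returned by [iso_constants()].
#' @param path File path of the YAML config.
#'
#' @return `write_iso_config()` returns `path` invisibly; `read_iso_config()`
#'   returns a constants list.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' write_iso_config(iso_constants(pka_hno2 = 3.0), f)
#' read_iso_config(f)$pka_hno2
#' @export
write_iso_config <- function(constants, path) {
  stopifnot(is.list(constants))
  constants$f15_natural <- NULL # derived, never stored
  yaml::write_yaml(constants, path)
  invisible(path)
}

#' @rdname write_iso_config
#' @export
read_iso_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  do.call(iso_constants, vals)
}
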