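#' Tidy a first-order ammonium drawdown fit
#'
#' @param x A `first_order_fit` from [first_order_fit()].
#' @param ... Unused.
#' @return A one-row tibble: `term`, `estimate` (per day), `std.error`,
#'   `p.value`.
#' @export
tidy.first_order_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  p <- if ("Pr(>|t|)" %in% colnames(sm) && nrow(sm) > 1) sm["t", "Pr(>|t|)"] else NA_real_
  tibble(term = "k_per_day", estimate = x$k_per_day, std.error = x$k_sd,
         p.value = unname(p))
}

#' @rdname tidy.first_order_fit
#' @return `glance()`: a one-row tibble with `r.squared`, `sigma`, `nobs`.
#' @export
glance.first_order_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(r.squared = sm$r.squared, sigma = sm$sigma, nobs = x$n)
}

#' Tidy N2O isotopologue production rates
#'
#' @param x An `n2o_production` from [production_rates()].
#' @param ... Unused.
#' @return A tibble with one row per isotopologue (`term`): `estimate`
#'   (nmol/day), `std.error`, `p.value`, `estimate_nm_day`.
#' @export
tidy.n2o_production <- function(x, ...) {
  x$rates %>%
    rename(term = isotopologue, estimate = rate_nmol_day,
           std.error = se_nmol_day, p.value = p_value) %>%
    mutate(estimate_nm_day = x$rates$rate_nm_day, .keep = "unused") %>%
    select(term, estimate, std.error, p.value, estimate_nm_day)
}

#' @rdname tidy.n2o_production
#' @return `glance()`: a one-row tibble with the incorporation rate
#'   (nM-N/day), bottle count and volume.
#' @export
glance.n2o_production <- function(x, ...) {
  tibble(incorporation_nm_day = total_15n_incorporation(x),
         nobs = x$n, volume_l = x$volume)
}

utils::globalVariables(c("rate_nmol_day", "se_nmol_day", "p_value",
                         "estimate_nm_day"))
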