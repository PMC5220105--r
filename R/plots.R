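#' Plot blank-corrected isotopologue accumulation with the fitted slopes
#'
#' @param object An `n2o_production` from [production_rates()].
#' @param ... Unused.
#' @return A ggplot: excess 45N2O and 46N2O (nmol) against time with the
#'   OLS production-rate lines.
#' @export
autoplot.n2o_production <- function(object, ...) {
  long <- object$excess %>%
    tidyr::pivot_longer(c(excess_n45, excess_n46),
                        names_to = "isotopologue", values_to = "excess_nmol") %>%
    mutate(isotopologue = ifelse(isotopologue == "excess_n45", "45N2O", "46N2O"))
  ggplot2::ggplot(long, ggplot2::aes(x = time_h, y = excess_nmol)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.4, colour = "steelblue") +
    ggplot2::facet_wrap(~isotopologue, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "excess over t0 (nmol)",
                  title = "N2O isotopologue production") +
    ggplot2::theme_minimal()
}

#' Plot a tidy rates table
#'
#' @param object An `n2o_rates` table from [estimate_rates()].
#' @param ... Unused.
#' @return A ggplot of rate point estimates with +/- 1 sd error bars, one
#'   panel per quantity, coloured by tracer regime.
#' @export
autoplot.n2o_rates <- function(object, ...) {
  d <- as_tibble(object)
  d$label <- if ("treatment" %in% names(d)) d$treatment else as.character(seq_len(nrow(d)))
  ggplot2::ggplot(d, ggplot2::aes(x = rate, y = label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = rate - rate_sd, xmax = rate + rate_sd),
      height = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(x = "rate (uM/day; k in 1/day)", y = NULL,
                  title = "Nitrification rate estimates") +
    ggplot2::theme_minimal()
}

#' Depth-profile panel plot
#'
#' Classic oceanographic presentation: one panel per variable, depth on a
#' reversed vertical axis.
#'
#' @param profile A profile table (see [read_profile_table()]).
#' @param vars Columns to plot (default the N2O panel set).
#' @return A ggplot.
#' @examples
#' plot_profile(simulate_profile(n_depths = 6))
#' @export
plot_profile <- function(profile,
                         vars = c("conc_n2o_nm", "d15n_n2o", "d18o_n2o",
                                  "sp_permil")) {
  stopifnot(is.data.frame(profile), "depth_m" %in% names(profile))
  vars <- intersect(vars, names(profile))
  if (!length(vars)) abort("none of the requested columns are in the profile")
  long <- profile %>%
    select(all_of(c("depth_m", vars))) %>%
    tidyr::pivot_longer(-depth_m, names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = value, y = depth_m)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~quantity, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "depth (m)") +
    ggplot2::theme_minimal()
}
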