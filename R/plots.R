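# ggplot2 visualisations of the result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_tile facet_wrap
#'   scale_x_log10 scale_y_log10 labs theme_minimal scale_fill_viridis_c
#'   autoplot geom_vline
NULL

#' Plot a distribution profile
#'
#' Stacked percentage bars per factor, mirroring the usual presentation of
#' tissue distribution profiles.
#'
#' @param object An `angio_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.angio_profile <- function(object, ...) {
  ggplot(object, aes(x = factor, y = percent, fill = category)) +
    geom_col() +
    labs(x = NULL, y = "% of total factor", fill = "form",
         title = "Tissue distribution of angiogenic factors") +
    theme_minimal()
}

#' Plot a secretion scan as a heatmap
#'
#' @param object An `angio_scan`.
#' @param value Column to map to fill (default `"log10_ratio"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.angio_scan <- function(object, value = "log10_ratio", ...) {
  fp <- attr(object, "factor_pair")
  ggplot(object, aes(x = .data$m2, y = .data$m1, fill = .data[[value]])) +
    geom_tile() +
    scale_x_log10() + scale_y_log10() +
    scale_fill_viridis_c() +
    labs(x = paste0(fp[[2]], " secretion (fold of baseline)"),
         y = paste0(fp[[1]], " secretion (fold of baseline)"),
         fill = value) +
    theme_minimal()
}

#' Plot a cHSPG x PF4 response grid as fold-change curves
#'
#' @param object An `angio_grid`.
#' @param observable Observable whose fold-change to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.angio_grid <- function(object, observable = "VEGF_signaling", ...) {
  col <- paste0(observable, "_fold")
  ggplot(object, aes(x = .data$pf4, y = .data[[col]],
                     colour = factor(.data$chspg), group = .data$chspg)) +
    geom_line() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "PF4 secretion (fold of baseline)",
         y = paste0(observable, " (fold of low-PF4 reference)"),
         colour = "cHSPG level") +
    theme_minimal()
}

#' Plot a pulse-release time course
#'
#' @param object An `angio_pulse`.
#' @param observables Which tracked observables to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.angio_pulse <- function(object,
                                 observables = c("PF4_unbound", "VEGF_unbound",
                                                 "VEGF_NRP1", "FGF2_dimer"),
                                 ...) {
  df <- object$trajectory %>% filter(.data$observable %in% observables)
  ggplot(df, aes(x = .data$time_days, y = .data$conc_pM)) +
    geom_line() +
    facet_wrap(~observable, scales = "free_y") +
    scale_y_log10() +
    labs(x = "time (days)", y = "concentration (pM, interstitial fluid)",
         title = sprintf("PF4 pulse release (cHSPG x%g)", object$chspg_level)) +
    theme_minimal()
}
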