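#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_col labs theme_minimal scale_y_log10
#' @export
ggplot2::autoplot

#' Plot methods for analysis results
#'
#' `autoplot()` methods render the standard figures: a slab concentration
#' profile with its interface fit overlay, a two-chain PMF with error band,
#' a cluster-size distribution, and a calibration trace of `<Rg>(a)`.
#' `plot_phase_diagram()` draws dilute/dense coexistence branches against
#' composition.
#'
#' @param object an `hp_profile`, `hp_pmf`, `hp_csd` or `hp_calibration`.
#' @param ... unused.
#' @return A ggplot object.
#' @name hpsep-plots
NULL

#' @rdname hpsep-plots
#' @export
autoplot.hp_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$z, y = .data$conc)) +
    geom_ribbon(aes(ymin = .data$conc - .data$se,
                    ymax = .data$conc + .data$se), alpha = 0.3) +
    geom_line() +
    labs(x = "z (nm)", y = "concentration (mg/mL)") +
    theme_minimal()
}

#' @rdname hpsep-plots
#' @export
autoplot.hp_pmf <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$r, y = .data$w)) +
    geom_ribbon(aes(ymin = .data$w - .data$se, ymax = .data$w + .data$se),
                alpha = 0.3) +
    geom_line() +
    labs(x = expression(r[com] ~ "(nm)"), y = "w(r) (kcal/mol)") +
    theme_minimal()
}

#' @rdname hpsep-plots
#' @export
autoplot.hp_csd <- function(object, ...) {
  ggplot(object, aes(x = .data$N_c, y = .data$P)) +
    geom_col(width = 0.9) +
    labs(x = expression(N[c] ~ "(chains)"),
         y = expression(P(N[c]))) +
    theme_minimal()
}

#' @rdname hpsep-plots
#' @export
autoplot.hp_calibration <- function(object, ...) {
  df <- object$evaluations
  ggplot(df, aes(x = .data$a, y = .data$Rg)) +
    geom_point() +
    geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = object$reference_Rg, linetype = 2) +
    labs(x = "scaling factor a", y = expression("<" * R[g] * "> (nm)")) +
    theme_minimal()
}

#' @rdname hpsep-plots
#' @param points a phase-point tibble from [threshold_scan()].
#' @export
plot_phase_diagram <- function(points, ...) {
  df <- tidyr::pivot_longer(points, c("c_dilute", "c_dense"),
                            names_to = "branch", values_to = "conc")
  ggplot(df[!is.na(df$conc), ],
         aes(x = .data$conc, y = .data$X_P, shape = .data$branch)) +
    geom_point(size = 2) +
    labs(x = "concentration (mg/mL)", y = expression(X[P])) +
    theme_minimal()
}
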