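#' Plot a frequency sweep with its gel point
#'
#' Log-log plot of storage (G') and loss (G'') moduli against frequency,
#' with the gel-point crossover marked when it exists.
#'
#' @param sweep A sweep tibble (`frequency_hz`, `g_prime_pa`,
#'   `g_double_prime_pa`).
#' @param mark_gel_point Mark the G' = G'' crossover when the sweep has
#'   exactly one (default `TRUE`).
#' @return A ggplot object.
#' @examples
#' sweep <- generate_sweep(maxwell_spectrum(c(600, 400), c(1, 0.01)),
#'                         0.05, 20, 60)
#' plot_sweep(sweep)
#' @export
plot_sweep <- function(sweep, mark_gel_point = TRUE) {
  check_columns(sweep, c("frequency_hz", "g_prime_pa", "g_double_prime_pa"),
                "`sweep`")
  long <- tidyr::pivot_longer(
    sweep, c("g_prime_pa", "g_double_prime_pa"),
    names_to = "modulus", values_to = "value_pa")
  long$modulus <- ifelse(long$modulus == "g_prime_pa", "G' (storage)",
                         "G'' (loss)")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$frequency_hz,
                                          .data$value_pa,
                                          colour = .data$modulus)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "modulus (Pa)", colour = NULL) +
    ggplot2::theme_minimal()
  if (mark_gel_point) {
    gp <- tryCatch(find_gel_point(sweep), gelstrain_error = function(cnd) NULL)
    if (!is.null(gp)) {
      p <- p +
        ggplot2::geom_vline(xintercept = gp$f_gp_hz, linetype = "dashed",
                            colour = "grey50") +
        ggplot2::annotate("point", x = gp$f_gp_hz, y = gp$g_gp_pa,
                          shape = 21, size = 3, fill = "white")
    }
  }
  p
}

#' @rdname tidy.relaxation_fit
#' @param object A `relaxation_fit` or `strain_map`.
#' @method autoplot relaxation_fit
#' @export
autoplot.relaxation_fit <- function(object, ...) {
  dense_t <- seq(min(object$data$time_s), max(object$data$time_s),
                 length.out = 400)
  fit_line <- tibble(time_s = dense_t,
                     modulus_pa = relaxation_modulus(object$spectrum,
                                                     dense_t))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_s,
                                            .data$modulus_pa)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = fit_line, colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "relaxation modulus (Pa)",
                  title = sprintf("%d-mode Maxwell fit, tau_char = %.3g s",
                                  object$n_modes,
                                  object$characteristic_time_s)) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.strain_map
#' @param object A `strain_map`.
#' @method autoplot strain_map
#' @export
autoplot.strain_map <- function(object, ...) {
  ggplot2::ggplot(object$strains,
                  ggplot2::aes(.data$time_s, .data$segment_index,
                               fill = .data$epsilon_cc_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "time (s)", y = "segment (0-based)",
                  fill = expression(epsilon[cc] ~ "(%)")) +
    ggplot2::theme_minimal()
}
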