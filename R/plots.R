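#' Plot a fitted response-surface surrogate
#'
#' Design points with the fitted quadratic `f(E)`; an optional horizontal
#' line marks a measured target so the cost-function root can be read off.
#'
#' @param object A `quad_surrogate`.
#' @param measured Optional measured observable to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quad_surrogate <- function(object, measured = NULL, ...) {
  grid <- tibble::tibble(
    E_mpa = seq(object$E_range[1], object$E_range[2], length.out = 200))
  grid$fit <- predict(object, grid$E_mpa)
  p <- ggplot2::ggplot(object$design,
                       ggplot2::aes(x = .data$E_mpa, y = .data$response)) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fit), colour = "#2166ac") +
    ggplot2::labs(x = "Young's modulus E (MPa)",
                  y = object$response_label,
                  title = "Quadratic response-surface surrogate") +
    ggplot2::theme_minimal()
  if (!is.null(measured)) {
    p <- p + ggplot2::geom_hline(yintercept = measured,
                                 linetype = "dashed", colour = "#b2182b")
  }
  p
}

#' Plot a calibration result
#'
#' Per-region surrogates (faceted), the measured strain targets and the
#' per-region roots, with the combined optimum marked.
#'
#' @param object A `calibration_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_result <- function(object, ...) {
  surr <- object$surrogates$wall
  if (is.null(surr)) abort("No wall surrogates in this result.")
  curves <- purrr::imap_dfr(surr, function(s, nm) {
    E <- seq(s$E_range[1], s$E_range[2], length.out = 200)
    tibble::tibble(region = nm, E_mpa = E, fit = predict(s, E))
  })
  pts <- purrr::imap_dfr(surr, function(s, nm) {
    dplyr::mutate(s$design, region = nm)
  })
  roots <- object$per_region_roots
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$E_mpa)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "#2166ac") +
    ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$response),
                        shape = 1) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "Young's modulus E (MPa)", y = "strain (%)",
                  title = sprintf("Calibration: E_optimal = %.2f MPa",
                                  object$E_optimal)) +
    ggplot2::theme_minimal()
  if (!is.na(object$E_optimal)) {
    p <- p + ggplot2::geom_vline(xintercept = object$E_optimal,
                                 colour = "#b2182b")
  }
  if (nrow(roots)) {
    p <- p + ggplot2::geom_vline(
      data = roots,
      ggplot2::aes(xintercept = .data$E_root_mpa),
      linetype = "dotted")
  }
  p
}

#' Plot recovery-experiment error against noise level
#'
#' @param object A `recovery_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              c("median_abs_rel_err_pct", "rmse_rel_pct"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = 100 * .data$noise_level,
                                     y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "measurement noise SD (%)",
                  y = "wall-modulus recovery error (%)",
                  title = "Parameter recovery vs measurement noise") +
    ggplot2::theme_minimal()
}

#' Plot a scaled pressure waveform
#'
#' @param hemo A [hemodynamic_record].
#' @param n_samples Samples over one beat.
#' @return A ggplot object.
#' @export
plot_waveform <- function(hemo, n_samples = 200) {
  wf <- pressure_waveform(hemo, n_samples)
  ggplot2::ggplot(wf, ggplot2::aes(x = .data$t_s, y = .data$p_mmhg)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)",
                  title = sprintf("Scaled beat: %g/%g mmHg at %g bpm",
                                  hemo$p_sys, hemo$p_dias, hemo$hr)) +
    ggplot2::theme_minimal()
}
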