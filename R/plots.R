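#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_errorbar geom_rect labs scale_x_log10 theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Provenance map of a chimera design
#'
#' Draws the chimera as a horizontal bar colored by residue source
#' (backbone, target, epitope), segmented by topology annotation.
#'
#' @param object A `chimera_design`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chimera_design <- function(object, ...) {
  blocks <- provenance_blocks(object)
  ggplot(blocks, aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                     ymin = 0, ymax = 1, fill = .data$source)) +
    geom_rect(color = "grey20", linewidth = 0.2) +
    ggplot2::geom_text(
      aes(x = (.data$start + .data$end) / 2, y = 1.15, label = .data$segment),
      angle = 90, hjust = 0, size = 2.5, inherit.aes = FALSE
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 2), breaks = NULL) +
    labs(
      x = "chimera residue", y = NULL, fill = "source",
      title = sprintf("%s (%s rules)", object$chimera$id, object$ruleset$name)
    ) +
    theme_minimal()
}

#' Normalized luminescence traces
#'
#' @param object Output of [normalize_wells()].
#' @param ... Unused.
#' @return A ggplot of fold-change over baseline per well.
#' @export
autoplot.gsx_normalized <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$time_s, .data$normalized, group = .data$well)) +
    geom_line(alpha = 0.6) +
    labs(x = "time (s)", y = "fold-change over baseline") +
    theme_minimal()
}

#' Dose-response curve with data
#'
#' @param object A `dose_response_fit`.
#' @param ... Unused.
#' @return A ggplot on a log dose axis with the fitted 4PL curve.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  grid <- tibble(dose = exp(seq(log(min(object$data$dose)),
                                log(max(object$data$dose)), length.out = 200)))
  grid$response <- predict(object, grid)
  ggplot(object$data, aes(.data$dose, .data$response)) +
    geom_point() +
    geom_line(data = grid) +
    scale_x_log10() +
    labs(
      x = "dose", y = "response",
      title = sprintf("4PL fit: EC50 = %.3g, hill = %.2f", object$ec50, object$hill)
    ) +
    theme_minimal()
}

#' Action spectrum plot
#'
#' @param object Output of [action_spectrum()].
#' @param ... Unused.
#' @return A ggplot of mean RLU maxima (+/- sd) by wavelength.
#' @export
autoplot.action_spectrum <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$wavelength_nm, .data$mean_rlu)) +
    geom_errorbar(aes(ymin = .data$mean_rlu - .data$sd_rlu,
                      ymax = .data$mean_rlu + .data$sd_rlu), width = 5) +
    geom_line() + geom_point() +
    labs(
      x = "wavelength (nm)", y = "mean RLU max",
      title = sprintf("peak at %g nm", peak_wavelength(object))
    ) +
    theme_minimal()
}

#' dF/F trace plot
#'
#' @param object Output of [dff_trace()].
#' @param ... Unused.
#' @return A ggplot of the baseline-normalized trace.
#' @export
autoplot.dff_trace <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$frame, .data$dff)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "baseline_frames") + 0.5,
                        linetype = "dashed", color = "grey40") +
    labs(x = "frame", y = expression(Delta * F / F[0])) +
    theme_minimal()
}
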