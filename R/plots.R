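#' Plot an analytic response curve and its LOD fit
#'
#' Points are the per-spot mean intensities coloured by regime (baseline,
#' slope, plateau); the line is the fitted log regression; the horizontal
#' dashed line is the detection threshold (negative-control mean + 3 SD) and
#' the vertical dashed line the estimated LOD.
#'
#' @param object A `lod_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lod_estimate <- function(object, ...) {
  curve <- object$curve
  xr <- range(curve$concentration)
  line <- tibble::tibble(
    concentration = exp(seq(log(min(xr[1], object$lod)), log(xr[2]),
                            length.out = 100))
  )
  line$intensity <- object$a * log(line$concentration) + object$b
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$concentration,
                                      y = .data$intensity)) +
    ggplot2::geom_line(data = line, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2) +
    ggplot2::geom_hline(yintercept = object$y_star, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$lod, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "HER2 concentration (molecules ERF per cell-equivalent)",
                  y = "Stain intensity (chromogen units)",
                  colour = "regime",
                  title = sprintf("LOD = %.0f molecules per cell-equivalent",
                                  object$lod)) +
    ggplot2::theme_minimal()
}

#' Plot a dynamic-range fit
#'
#' Aggregate average TMA score per LOD bin with the fitted regression line.
#'
#' @param object A `dynrange_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dynrange_fit <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$center,
                                            y = .data$aggregate_score)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(x = "Assay LOD (molecules ERF per cell-equivalent)",
                  y = "Average HER2 score",
                  title = sprintf("%s readout: slope %.3f per 10^4 LOD (p = %.3g)",
                                  object$readout, object$slope * 1e4,
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot per-score fractions across LOD bins
#'
#' @param object A `score_fractions` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_fractions <- function(object, ...) {
  fr <- object$fractions
  fr$score <- factor(fr$score)
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$center, y = .data$fraction,
                                   colour = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "Assay LOD (molecules ERF per cell-equivalent)",
                  y = "Fraction of cores", colour = "HER2 score") +
    ggplot2::theme_minimal()
}

#' Plot a laboratory cohort's LODs by assay family
#'
#' One point per laboratory, jittered within assay family, with a boxplot
#' summarising each family.
#'
#' @param labs Tibble with `assay`, `lod`.
#' @return A ggplot object.
#' @export
plot_lab_cohort <- function(labs) {
  stopifnot(all(c("assay", "lod") %in% names(labs)))
  ggplot2::ggplot(labs, ggplot2::aes(x = .data$assay, y = .data$lod)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4,
                          colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2, alpha = 0.8) +
    ggplot2::labs(x = NULL,
                  y = "Lower limit of detection (molecules ERF per cell-equivalent)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a per-laboratory accuracy profile
#'
#' Diagnostic accuracy against the LOD-defined gold standard, one point per
#' laboratory, as a function of the laboratory's LOD.
#'
#' @param profile Tibble from [lab_accuracy_profile()].
#' @return A ggplot object.
#' @export
plot_accuracy_profile <- function(profile) {
  stopifnot(all(c("lod", "accuracy") %in% names(profile)))
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$lod, y = .data$accuracy)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Assay LOD (molecules ERF per cell-equivalent)",
                  y = "Diagnostic accuracy") +
    ggplot2::theme_minimal()
}
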