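#' Classify response-curve points into baseline, slope and plateau
#'
#' Points with intensity no greater than the negative-control mean (up to a
#' small comparison tolerance at the 8-bit measurement resolution) are
#' baseline; the plateau is the largest suffix (at least two points) of the
#' concentration-ordered curve whose consecutive intensity increments are all
#' smaller in magnitude than `plateau_frac` of the observed dynamic span
#' (maximum intensity minus negative-control mean); the remaining contiguous
#' points are the slope used for the log regression.
#'
#' @param points Tibble with columns `concentration` (positive) and
#'   `intensity`; at least 4 points.
#' @param neg_mean,neg_sd Negative-control mean and SD (chromogen units).
#' @param plateau_frac Plateau increment threshold as a fraction of the
#'   dynamic span (default 0.05).
#' @param baseline_tol Numerical tolerance for the "no greater than the
#'   negative control" comparison (default 1/255, one 8-bit quantisation
#'   step); points within the tolerance of `neg_mean` count as baseline.
#' @return The points sorted by concentration with a `label` column in
#'   `{"baseline", "slope", "plateau"}`.
#' @export
classify_points <- function(points, neg_mean, neg_sd, plateau_frac = 0.05,
                            baseline_tol = 1 / 255) {
  stopifnot(all(c("concentration", "intensity") %in% names(points)),
            neg_sd >= 0, plateau_frac > 0)
  if (nrow(points) < 4) {
    abort("at least 4 response points are required",
          class = "ihcsens_too_few_points")
  }
  if (any(points$concentration <= 0)) {
    abort("concentrations must be strictly positive")
  }
  pts <- dplyr::arrange(points, .data$concentration)
  n <- nrow(pts)
  label <- rep("slope", n)
  label[pts$intensity <= neg_mean + baseline_tol] <- "baseline"
  span <- max(pts$intensity) - neg_mean
  if (span > 0) {
    inc <- abs(diff(pts$intensity))
    # largest suffix whose internal increments all sit below the threshold
    start <- n
    while (start > 1 && inc[start - 1] < plateau_frac * span) {
      start <- start - 1
    }
    if (start <= n - 1) {          # suffix of >= 2 points
      label[start:n] <- "plateau"
    }
  }
  pts$label <- label
  pts
}

#' Log regression of stain intensity on concentration
#'
#' Ordinary least squares of `intensity = a * ln(concentration) + b` over the
#' slope points of the analytic response curve.
#'
#' @param slope_points Tibble with `concentration`, `intensity`; at least 3
#'   points with distinct concentrations.
#' @return A list with `a` (slope), `b` (intercept), `r_squared`, and `n`.
#' @export
#' @examples
#' pts <- tibble::tibble(concentration = c(1e4, 3e4, 9e4),
#'                       intensity = 5 * log(c(1e4, 3e4, 9e4)) + 1)
#' fit_log_regression(pts)
fit_log_regression <- function(slope_points) {
  stopifnot(all(c("concentration", "intensity") %in% names(slope_points)))
  if (nrow(slope_points) < 3) {
    abort("insufficient slope points (need at least 3)",
          class = "ihcsens_insufficient_slope")
  }
  if (length(unique(slope_points$concentration)) < 2) {
    abort("singular design: all concentrations equal",
          class = "ihcsens_singular")
  }
  fit <- lm(intensity ~ log(concentration), data = slope_points)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((slope_points$intensity - mean(slope_points$intensity))^2)
  list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n = nrow(slope_points))
}

#' Solve the regression line for the limit of detection
#'
#' The LOD is the concentration whose fitted intensity equals the threshold
#' `y_star` (negative-control mean + 3 SD): `lod = exp((y_star - b) / a)`.
#'
#' @param a,b Log-regression slope and intercept; `a` must be positive.
#' @param y_star Threshold intensity.
#' @return The LOD in the same concentration units as the fit.
#' @export
#' @examples
#' compute_lod(a = 1, b = 0, y_star = log(30000))  # 30000
compute_lod <- function(a, b, y_star) {
  if (!is.finite(a) || a <= 0) {
    abort("non-positive slope: LOD is undefined",
          class = "ihcsens_nonpositive_slope")
  }
  exp((y_star - b) / a)
}

#' Estimate the lower limit of detection from spot summaries
#'
#' Implements the full single-slide LOD rule: the threshold intensity is the
#' negative-control mean plus three negative-control SDs; baseline and
#' plateau points are excluded; a log regression is fitted to the slope
#' points (all of them when more than five are available); and the LOD is the
#' concentration at which the fitted line predicts the threshold. LODs below
#' the lowest calibrator concentration are extrapolated and flagged.
#'
#' @param summaries Spot summary tibble from [quantify_calibrator()] or
#'   [average_duplicates()] joined with the layout: columns `spot_id`,
#'   `concentration`, `is_negative`, `mean_intensity`, `sd_intensity`.
#' @param plateau_frac See [classify_points()].
#' @param baseline_tol Baseline comparison tolerance; the default `NULL`
#'   derives it from the data as `max(1/255, 3 * SE)` where `SE` is the
#'   standard error of a negative-spot mean, so a spot statistically
#'   indistinguishable from the negative controls is treated as baseline.
#' @return An object of class `lod_estimate`: a list with `lod`, `a`, `b`,
#'   `r_squared`, `y_star`, `neg_mean`, `neg_sd`, `n_points_used`,
#'   `extrapolated_below_lowest`, and the labelled `curve` tibble.
#' @export
#' @examples
#' sl <- sim_calibrator_slide(calibrator_curve(40000), seed = 1)
#' est <- estimate_lod(quantify_calibrator(sl$image, sl$spots))
#' est$lod
estimate_lod <- function(summaries, plateau_frac = 0.05,
                         baseline_tol = NULL) {
  need <- c("concentration", "is_negative", "mean_intensity", "sd_intensity")
  stopifnot(all(need %in% names(summaries)))
  negs <- summaries[summaries$is_negative, , drop = FALSE]
  if (nrow(negs) == 0) abort("no negative-control spots in summaries")
  neg_mean <- mean(negs$mean_intensity)
  neg_sd <- sqrt(mean(negs$sd_intensity^2))
  y_star <- neg_mean + 3 * neg_sd
  if (is.null(baseline_tol)) {
    n_eff <- if ("n_beads" %in% names(negs)) stats::median(negs$n_beads) else 1
    baseline_tol <- max(1 / 255, 3 * neg_sd / sqrt(n_eff))
  }

  pts <- summaries[!summaries$is_negative,
                   c("concentration", "mean_intensity")]
  names(pts) <- c("concentration", "intensity")
  curve <- classify_points(pts, neg_mean, neg_sd, plateau_frac,
                           baseline_tol = baseline_tol)
  slope_pts <- curve[curve$label == "slope", , drop = FALSE]
  if (nrow(slope_pts) < 3) {
    abort("insufficient slope points (need at least 3)",
          class = "ihcsens_insufficient_slope")
  }
  fit <- fit_log_regression(slope_pts)
  lod <- compute_lod(fit$a, fit$b, y_star)
  structure(
    list(lod = lod, a = fit$a, b = fit$b, r_squared = fit$r_squared,
         y_star = y_star, neg_mean = neg_mean, neg_sd = neg_sd,
         n_points_used = fit$n,
         extrapolated_below_lowest = lod < min(curve$concentration),
         curve = curve),
    class = "lod_estimate"
  )
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat("LOD estimate\n")
  cat(sprintf("  LOD: %.0f molecules (ERF) per cell-equivalent%s\n", x$lod,
              if (x$extrapolated_below_lowest) {
                " (extrapolated below lowest calibrator)"
              } else ""))
  cat(sprintf("  fit: intensity = %.4f * ln(conc) %+0.4f (R^2 = %.4f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n_points_used))
  cat(sprintf("  threshold: %.4f (neg mean %.4f + 3 x SD %.4f)\n",
              x$y_star, x$neg_mean, x$neg_sd))
  invisible(x)
}

#' Tidy an LOD estimate
#'
#' @param x A `lod_estimate`.
#' @param ... Unused.
#' @return One-row tibble of the fitted quantities.
#' @export
tidy.lod_estimate <- function(x, ...) {
  tibble::tibble(lod = x$lod, a = x$a, b = x$b, y_star = x$y_star,
                 neg_mean = x$neg_mean, neg_sd = x$neg_sd,
                 r_squared = x$r_squared, n_points_used = x$n_points_used,
                 extrapolated_below_lowest = x$extrapolated_below_lowest)
}

#' @rdname tidy.lod_estimate
#' @export
glance.lod_estimate <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points_used = x$n_points_used,
                 extrapolated_below_lowest = x$extrapolated_below_lowest)
}

#' Estimate a laboratory LOD from duplicate calibrator slides
#'
#' Convenience wrapper: quantifies each image, averages the duplicates, and
#' estimates the LOD.
#'
#' @param images List of one or two RGB image arrays.
#' @param spots Spot layout shared by the duplicates.
#' @param ... Passed to [quantify_calibrator()].
#' @return A `lod_estimate`.
#' @export
estimate_lod_from_images <- function(images, spots, ...) {
  stopifnot(is.list(images), length(images) >= 1)
  runs <- lapply(images, quantify_calibrator, spots = spots, ...)
  combined <- if (length(runs) >= 2) {
    Reduce(function(a, b) {
      avg <- average_duplicates(
        a[, c("spot_id", "n_beads", "mean_intensity", "sd_intensity")],
        b[, c("spot_id", "n_beads", "mean_intensity", "sd_intensity")]
      )
      dplyr::left_join(avg, spots[, c("spot_id", "concentration",
                                      "is_negative")], by = "spot_id")
    }, runs)
  } else {
    runs[[1]]
  }
  estimate_lod(combined)
}
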