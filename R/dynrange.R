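#' Group laboratories into LOD bins
#'
#' A laboratory belongs to a bin when its LOD lies within `halfwidth` of the
#' bin centre (absolute difference, boundary inclusive). Bins may overlap:
#' a lab can fall into two adjacent bins when centres are less than
#' `2 * halfwidth` apart.
#'
#' @param labs Tibble with `lab_id`, `lod`.
#' @param centers Sorted bin centres, molecules per cell-equivalent (default
#'   round multiples of 10,000 spanning the cohort).
#' @param halfwidth Bin half-width (default 5,000).
#' @return Long membership tibble with columns `center` and the lab columns;
#'   empty bins are flagged with a warning and omitted.
#' @export
#' @examples
#' bin_labs(sim_lab_cohort(seed = 1))
bin_labs <- function(labs, centers = NULL, halfwidth = 5000) {
  stopifnot(all(c("lab_id", "lod") %in% names(labs)), halfwidth > 0)
  if (is.null(centers)) {
    centers <- seq(round(min(labs$lod) / 10000) * 10000,
                   round(max(labs$lod) / 10000) * 10000, by = 10000)
    centers <- centers[centers > 0]
  }
  stopifnot(!is.unsorted(centers))
  out <- purrr::map_dfr(centers, function(ct) {
    members <- labs[abs(labs$lod - ct) <= halfwidth, , drop = FALSE]
    if (nrow(members) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(center = rep(ct, nrow(members))), members)
  })
  empty <- setdiff(centers, unique(out$center))
  if (length(empty) > 0) {
    warn(paste0("empty LOD bins omitted: ", paste(empty, collapse = ", ")))
  }
  out
}

# Closed-form simple OLS with the slope t-test; the degenerate perfect-fit
# and flat cases get exact limits (se 0; t 0 and p 1 when the slope is 0).
slope_ols <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  rss <- sum(fit$residuals^2)
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  eps <- 1e-12 * max(abs(y), 1)
  if (se <= eps) {
    t_stat <- if (abs(slope) <= eps) 0 else Inf * sign(slope)
    p <- if (abs(slope) <= eps) 1 else 0
  } else {
    t_stat <- slope / se
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  list(slope = slope, intercept = intercept, se_slope = se,
       t_statistic = t_stat, p_value = p, n_points = n, df = n - 2)
}

#' Assay dynamic range: regression of aggregate score on LOD
#'
#' For each LOD bin, computes the aggregate average TMA score (per-core
#' consensus over the bin's member labs, then the mean over cores) for one
#' readout method, and fits ordinary least squares of aggregate score on bin
#' centre with a t-test of slope = 0 on `n - 2` degrees of freedom. A slope
#' of zero represents an absence of assay dynamic range; because LOD
#' increases as analytic sensitivity falls, a responsive assay shows a
#' negative fitted slope and the dynamic-range magnitude is `|slope|`.
#'
#' @param scores Long score tibble (see [sim_score_matrix()]).
#' @param labs Laboratory tibble with `lab_id`, `lod`.
#' @param readout Readout filter; mixing readouts in one regression is not
#'   allowed, so this is required when `scores` carries a `readout` column.
#' @param include_ultralow Passed to the consensus computation.
#' @param centers,halfwidth Passed to [bin_labs()].
#' @param lod_max Optional domain restriction: bins with centres above this
#'   are dropped before fitting (e.g. 50,000 to fit below a visual
#'   breakpoint).
#' @return Object of class `dynrange_fit`: the OLS summary plus the per-bin
#'   aggregate table (`$bins`).
#' @export
#' @examples
#' study <- sim_study(seed = 1)
#' dynamic_range_slope(study$scores, study$labs, readout = "image_analysis",
#'                     centers = seq(10000, 60000, 10000))
dynamic_range_slope <- function(scores, labs, readout = NULL,
                                include_ultralow = TRUE, centers = NULL,
                                halfwidth = 5000, lod_max = NULL) {
  if ("readout" %in% names(scores)) {
    if (is.null(readout)) {
      if (length(unique(scores$readout)) > 1) {
        abort("scores mix readout methods: pass readout explicitly")
      }
      readout <- unique(scores$readout)
    }
  }
  membership <- bin_labs(labs, centers = centers, halfwidth = halfwidth)
  if (!is.null(lod_max)) {
    membership <- membership[membership$center <= lod_max, , drop = FALSE]
  }
  bins <- membership |>
    dplyr::group_by(.data$center) |>
    dplyr::summarise(
      n_labs = dplyr::n(),
      aggregate_score = average_tma_score(
        scores, lab_ids = .data$lab_id,
        include_ultralow = include_ultralow, readout = readout),
      .groups = "drop"
    )
  if (nrow(bins) < 3) {
    abort("fewer than 3 non-empty LOD bins after restriction",
          class = "ihcsens_too_few_bins")
  }
  fit <- slope_ols(bins$center, bins$aggregate_score)
  structure(c(fit, list(bins = bins, readout = readout,
                        include_ultralow = include_ultralow,
                        domain_restriction = lod_max)),
            class = "dynrange_fit")
}

#' @export
print.dynrange_fit <- function(x, ...) {
  cat(sprintf("Dynamic range (%s readout, ultralow %s)\n", x$readout,
              if (x$include_ultralow) "included" else "excluded"))
  cat(sprintf("  slope: %.3g score units per molecule (%.3f per 10^4), se %.3g\n",
              x$slope, x$slope * 1e4, x$se_slope))
  cat(sprintf("  t = %.3f on %d df, p = %.4g; %d bins\n",
              x$t_statistic, x$df, x$p_value, x$n_points))
  invisible(x)
}

#' Tidy a dynamic-range fit
#'
#' @param x A `dynrange_fit`.
#' @param ... Unused.
#' @return One-row tibble with slope, intercept, se, t, p and bin count.
#' @export
tidy.dynrange_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 se_slope = x$se_slope, t_statistic = x$t_statistic,
                 p_value = x$p_value, n_points = x$n_points,
                 readout = x$readout, include_ultralow = x$include_ultralow)
}

#' @rdname tidy.dynrange_fit
#' @export
glance.dynrange_fit <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, n_points = x$n_points,
                 domain_restriction = x$domain_restriction %||% NA_real_)
}

#' Compare two dynamic-range slopes
#'
#' Two-sample t-test on the difference of independent regression slopes:
#' `t = (b1 - b2) / sqrt(se1^2 + se2^2)` with Welch-Satterthwaite degrees of
#' freedom from the two fits' residual degrees of freedom. Symmetric in its
#' arguments; identical fits give p = 1.
#'
#' @param result_a,result_b `dynrange_fit` objects (or any lists carrying
#'   `slope`, `se_slope`, `df`).
#' @return A list with `t_statistic`, `df`, `p_value`, and the slope
#'   difference.
#' @export
compare_slopes <- function(result_a, result_b) {
  need <- c("slope", "se_slope", "df")
  if (!all(need %in% names(result_a)) || !all(need %in% names(result_b))) {
    abort("inputs must carry slope, se_slope and df")
  }
  se1 <- result_a$se_slope; se2 <- result_b$se_slope
  if (!is.finite(se1) || !is.finite(se2) || (se1 == 0 && se2 == 0)) {
    if (identical(result_a$slope, result_b$slope)) {
      return(list(t_statistic = 0, df = result_a$df + result_b$df,
                  p_value = 1, difference = 0))
    }
    abort("degenerate fit: slope standard errors are undefined",
          class = "ihcsens_degenerate_fit")
  }
  diff <- result_a$slope - result_b$slope
  se <- sqrt(se1^2 + se2^2)
  df <- (se1^2 + se2^2)^2 / (se1^4 / result_a$df + se2^4 / result_b$df)
  t_stat <- diff / se
  list(t_statistic = t_stat, df = df,
       p_value = 2 * pt(-abs(t_stat), df = df), difference = diff)
}

#' Per-score fractions across LOD bins
#'
#' For each LOD bin, the fraction of cores whose consensus equals each score
#' level (fractions sum to 1 per bin), with a per-level OLS regression of
#' fraction on bin centre. The HER2 0 fraction rising with LOD is the
#' signature of scores responding to analytic sensitivity.
#'
#' @inheritParams dynamic_range_slope
#' @return A list of class `score_fractions` with `$fractions` (tibble:
#'   `center`, `score`, `fraction`, `n_cores`) and `$fits` (tibble: per-score
#'   slope, se, t, p).
#' @export
#' @examples
#' study <- sim_study(seed = 1)
#' sf <- per_score_fractions(study$scores, study$labs,
#'                           readout = "image_analysis",
#'                           centers = seq(10000, 60000, 10000))
#' sf$fits
per_score_fractions <- function(scores, labs, readout = NULL,
                                include_ultralow = TRUE, centers = NULL,
                                halfwidth = 5000, lod_max = NULL) {
  membership <- bin_labs(labs, centers = centers, halfwidth = halfwidth)
  if (!is.null(lod_max)) {
    membership <- membership[membership$center <= lod_max, , drop = FALSE]
  }
  levels <- score_levels(include_ultralow)
  fractions <- membership |>
    dplyr::group_by(.data$center) |>
    dplyr::reframe({
      cons <- consensus_scores(scores, lab_ids = .data$lab_id,
                               include_ultralow = include_ultralow,
                               readout = readout)
      tibble::tibble(score = levels,
                     fraction = vapply(levels, function(s) {
                       mean(cons$consensus == s)
                     }, numeric(1)),
                     n_cores = nrow(cons))
    })
  if (length(unique(fractions$center)) < 3) {
    abort("fewer than 3 non-empty LOD bins after restriction",
          class = "ihcsens_too_few_bins")
  }
  fits <- fractions |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise({
      f <- slope_ols(.data$center, .data$fraction)
      tibble::tibble(slope = f$slope, intercept = f$intercept,
                     se_slope = f$se_slope, t_statistic = f$t_statistic,
                     p_value = f$p_value)
    }, .groups = "drop")
  structure(list(fractions = fractions, fits = fits, readout = readout,
                 include_ultralow = include_ultralow),
            class = "score_fractions")
}
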