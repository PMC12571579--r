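#' Default calibrator concentration series
#'
#' Ten analyte concentrations spanning 26,000 to 1,400,000 molecules (ERF) per
#' cell-equivalent, approximately log-spaced, matching the span of a
#' commercial HER2 calibrator slide. Units are molecules per cell-equivalent
#' (an 8-micron microbead standing in for a tumour cell).
#'
#' @return Numeric vector of length 10, ascending.
#' @export
calibrator_concentrations <- function() {
  c(26, 40, 63, 98, 153, 238, 370, 577, 898, 1400) * 1000
}

#' DAB chromogen colour profile
#'
#' Unit RGB vector for the 3,3'-diaminobenzidine (DAB) chromogen, from the
#' standard colour-deconvolution stain matrix. Stain intensity is measured as
#' the dot product of the inverted pixel signal with this vector.
#'
#' @return Numeric unit 3-vector (R, G, B).
#' @export
dab_profile <- function() {
  v <- c(0.268, 0.570, 0.776)
  v / sqrt(sum(v^2))
}

#' Calibrator dose-response curve parameters
#'
#' Defines the piecewise log-linear analytic response a stained calibrator
#' slide is rendered from: chromogen intensity rises as
#' `slope * ln(concentration) + b` between a baseline clip (negative-control
#' level) and a plateau clip, the sigmoid shape an IHC calibrator produces.
#' The intercept is chosen so that the curve passes through
#' `neg_mean + 3 * noise_sd` exactly at `true_lod`: the limit of detection
#' recovered from a rendered slide is, by construction, `true_lod`.
#'
#' @param true_lod True lower limit of detection, molecules per
#'   cell-equivalent.
#' @param slope Intensity gain per natural-log unit of concentration
#'   (chromogen units); must be positive.
#' @param neg_mean Baseline stain intensity of negative-control beads
#'   (chromogen units, on the inverted white-minus-pixel scale in `[0, 1.7]`).
#' @param noise_sd Nominal per-bead intensity noise the slide will be rendered
#'   with; enters the curve through the `+ 3 SD` threshold anchoring.
#' @param plateau_conc Concentration at which the response saturates.
#' @return An object of class `calibrator_curve`: a list with the parameters
#'   plus the derived intercept `b` and plateau intensity.
#' @export
#' @examples
#' cc <- calibrator_curve(40000)
#' curve_intensity(cc, c(26000, 40000, 1400000))
calibrator_curve <- function(true_lod, slope = 0.22, neg_mean = 0.15,
                             noise_sd = 0, plateau_conc = 6e5) {
  stopifnot(true_lod > 0, plateau_conc > true_lod, noise_sd >= 0)
  if (slope <= 0 || neg_mean < 0) {
    abort("curve parameters imply a non-increasing or negative response",
          class = "ihcsens_bad_curve")
  }
  b <- neg_mean + 3 * noise_sd - slope * log(true_lod)
  plateau <- slope * log(plateau_conc) + b
  # pixel = 1 - intensity * dab; the brightest bead must stay renderable
  if (plateau * max(dab_profile()) > 1) {
    abort("curve parameters imply negative pixel values at the plateau",
          class = "ihcsens_bad_curve")
  }
  structure(
    list(true_lod = true_lod, slope = slope, neg_mean = neg_mean,
         noise_sd = noise_sd, plateau_conc = plateau_conc,
         b = b, plateau = plateau),
    class = "calibrator_curve"
  )
}

#' Evaluate a calibrator curve
#'
#' @param curve A [calibrator_curve()] object.
#' @param concentration Concentrations (molecules per cell-equivalent);
#'   `NA` denotes a negative-control spot and returns the baseline.
#' @return Clipped chromogen intensities.
#' @export
curve_intensity <- function(curve, concentration) {
  stopifnot(inherits(curve, "calibrator_curve"))
  y <- curve$slope * log(concentration) + curve$b
  y <- pmin(pmax(y, curve$neg_mean), curve$plateau)
  y[is.na(concentration)] <- curve$neg_mean
  y
}

# Spot grid layout: 10 concentration spots then 5 negative-control spots,
# arranged spot_cols x spot_rows on a cell-pitch grid.
spot_layout <- function(concentrations, n_negative = 5L, spot_cols = 5L,
                        cell = 110L) {
  n <- length(concentrations) + n_negative
  spot_rows <- ceiling(n / spot_cols)
  idx <- seq_len(n) - 1L
  tibble::tibble(
    spot_id = sprintf("S%02d", seq_len(n)),
    concentration = c(concentrations, rep(NA_real_, n_negative)),
    is_negative = c(rep(FALSE, length(concentrations)), rep(TRUE, n_negative)),
    cx = (idx %% spot_cols) * cell + (cell + 1) / 2,
    cy = (idx %/% spot_cols) * cell + (cell + 1) / 2
  )
}

# Quantise an image to 8 bits with ordered (Bayer 4x4) dithering: each pixel
# rounds its fractional 1/255 remainder up or down by a fixed spatial
# threshold pattern, so the mean over any few dozen pixels carries
# sub-quantisation accuracy. Bead geometry itself is not anti-aliased.
dither_quantise <- function(img) {
  bayer <- (matrix(c(0, 8, 2, 10,
                     12, 4, 14, 6,
                     3, 11, 1, 9,
                     15, 7, 13, 5), 4, 4, byrow = TRUE) + 0.5) / 16
  h <- dim(img)[1]; w <- dim(img)[2]
  thr <- bayer[(0:(h - 1)) %% 4 + 1, (0:(w - 1)) %% 4 + 1]
  for (ch in seq_len(dim(img)[3])) {
    v <- img[, , ch] * 255
    base <- floor(v)
    img[, , ch] <- pmin(base + ((v - base) > thr), 255) / 255
  }
  img
}

# Place n non-overlapping integer bead centres inside a spot disc.
place_beads <- function(cx, cy, n, bead_radius, spot_radius) {
  placed <- matrix(numeric(0), ncol = 2)
  min_sep <- 2 * bead_radius + 2
  tries <- 0L
  while (nrow(placed) < n) {
    tries <- tries + 1L
    if (tries > 20000L) {
      abort("could not place beads without overlap; reduce n_beads or radius")
    }
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * (spot_radius - bead_radius - 1)
    cand <- round(c(cx + rad * cos(ang), cy + rad * sin(ang)))
    if (nrow(placed) == 0 ||
        all(sqrt(rowSums(sweep(placed, 2, cand)^2)) >= min_sep)) {
      placed <- rbind(placed, cand)
    }
  }
  placed
}

#' Render a synthetic calibrator slide image
#'
#' Generates an 8-bit RGB photomicrograph of a stained calibrator slide:
#' 10 concentration spots plus 5 negative-control spots of round microbeads
#' on a white background, with per-bead chromogen intensity equal to the
#' clipped dose-response value plus Gaussian noise. Beads are filled discs
#' with integer centres and no geometric anti-aliasing, so segmentation
#' recovery is exactly checkable; each bead carries one intensity (noise is
#' per bead, not per pixel). Colours are quantised to 8 bits with ordered
#' dithering, so per-spot mean intensities remain accurate beyond the 1/255
#' step. The ground-truth spot and bead tables are returned alongside the
#' image.
#'
#' @param curve A [calibrator_curve()] object.
#' @param bead_noise_sd Per-bead Gaussian intensity noise SD (chromogen
#'   units); use `curve$noise_sd` to keep the rendered noise consistent with
#'   the curve's threshold anchoring.
#' @param seed Integer seed; identical seeds give byte-identical images.
#' @param concentrations Concentration series for the 10 spots.
#' @param n_beads Beads rendered per spot.
#' @param bead_radius Bead radius in pixels (discs are rasterised as
#'   `(x-cx)^2 + (y-cy)^2 <= r^2`).
#' @param cell Spot grid pitch in pixels.
#' @return A list of class `calibrator_slide` with elements `image` (numeric
#'   array height x width x 3 in `[0, 1]`, already quantised to 8 bits),
#'   `spots` (ground-truth spot table with intended mean intensity) and
#'   `beads` (per-bead ground truth: centre, radius, rendered intensity).
#' @export
#' @examples
#' sl <- sim_calibrator_slide(calibrator_curve(40000), seed = 1)
#' dim(sl$image)
sim_calibrator_slide <- function(curve, bead_noise_sd = curve$noise_sd,
                                 seed = 1L,
                                 concentrations = calibrator_concentrations(),
                                 n_beads = 18L, bead_radius = 5L,
                                 cell = 110L) {
  stopifnot(inherits(curve, "calibrator_curve"), bead_noise_sd >= 0)
  spots <- spot_layout(concentrations, cell = cell)
  spots$intended_intensity <- curve_intensity(curve, spots$concentration)
  spot_cols <- 5L
  spot_rows <- ceiling(nrow(spots) / spot_cols)
  w <- spot_cols * cell
  h <- spot_rows * cell
  dab <- dab_profile()

  beads <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(spots)), function(i) {
      ctr <- place_beads(spots$cx[i], spots$cy[i], n_beads, bead_radius,
                         spot_radius = cell * 0.4)
      intensity <- spots$intended_intensity[i] +
        rnorm(n_beads, 0, bead_noise_sd)
      tibble::tibble(
        spot_id = spots$spot_id[i],
        bead_cx = ctr[, 1], bead_cy = ctr[, 2],
        bead_r = bead_radius,
        intensity = pmax(intensity, 0)
      )
    })
  })

  img <- array(1, dim = c(h, w, 3))
  for (k in seq_len(nrow(beads))) {
    bx <- beads$bead_cx[k]; by <- beads$bead_cy[k]; r <- beads$bead_r[k]
    xs <- max(1, bx - r):min(w, bx + r)
    ys <- max(1, by - r):min(h, by + r)
    dx2 <- outer((ys - by)^2, (xs - bx)^2, `+`)
    inside <- dx2 <= r^2
    for (ch in 1:3) {
      plane <- img[ys, xs, ch]
      plane[inside] <- max(0, min(1, 1 - beads$intensity[k] * dab[ch]))
      img[ys, xs, ch] <- plane
    }
  }
  img <- dither_quantise(img)

  structure(list(image = img, spots = spots, beads = beads, curve = curve),
            class = "calibrator_slide")
}

#' Default laboratory cohort specification
#'
#' One row per assay family: the number of surveyed laboratories and the
#' between-laboratory mean/SD of the true LOD (molecules per
#' cell-equivalent). The unmodified 4B5 kit family uses the survey's reported
#' mean 54,436 and SD 19,569 over 18 laboratories; the remaining families are
#' placed at the LOD ranges reported for them (laboratory-developed 4B5 near
#' its ~30,000 sensitivity plateau, OptiView-detection variants at
#' 20,000-30,000, the monoclonal HercepTest at 5,000-20,000), for 54
#' laboratories in total.
#'
#' @return A tibble with columns `assay`, `n_labs`, `lod_mean`, `lod_sd`.
#' @export
default_lab_cohort_spec <- function() {
  tibble::tribble(
    ~assay,          ~n_labs, ~lod_mean, ~lod_sd,
    "4B5 per IFU",   18L,     54436,     19569,
    "4B5 LDT",       12L,     40000,     8000,
    "4B5+Optiview",   8L,     25000,     4000,
    "mHercepTest",   10L,     12000,     4000,
    "CB11/Bond",      6L,     45000,     10000
  )
}

#' Simulate a cohort of laboratories with true LODs
#'
#' Draws one true LOD per laboratory from its assay family's normal
#' distribution, truncated to be positive (redrawn while non-positive).
#'
#' @param cohort_spec Tibble with columns `assay`, `n_labs`, `lod_mean`,
#'   `lod_sd`; see [default_lab_cohort_spec()].
#' @param seed Integer seed.
#' @return Tibble with columns `lab_id`, `assay`, `lod`.
#' @export
#' @examples
#' sim_lab_cohort(seed = 1)
sim_lab_cohort <- function(cohort_spec = default_lab_cohort_spec(),
                           seed = 1L) {
  stopifnot(all(c("assay", "n_labs", "lod_mean", "lod_sd") %in%
                  names(cohort_spec)))
  if (any(cohort_spec$lod_mean <= 0) || any(cohort_spec$lod_sd < 0)) {
    abort("lod_mean must be positive and lod_sd non-negative")
  }
  labs <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(cohort_spec)), function(i) {
      n <- cohort_spec$n_labs[i]
      if (n == 0L) return(tibble::tibble(assay = character(), lod = numeric()))
      draw <- rnorm(n, cohort_spec$lod_mean[i], cohort_spec$lod_sd[i])
      while (any(draw <= 0)) {
        bad <- draw <= 0
        draw[bad] <- rnorm(sum(bad), cohort_spec$lod_mean[i],
                           cohort_spec$lod_sd[i])
      }
      tibble::tibble(assay = cohort_spec$assay[i], lod = draw)
    })
  })
  labs$lab_id <- sprintf("L%02d", seq_len(nrow(labs)))
  labs[, c("lab_id", "assay", "lod")]
}

#' Simulate tissue-microarray cores with latent HER2 expression
#'
#' Generates `4 * cores_per_category` cores, equally divided across the
#' intended HER2 score categories 0-3+. Latent expression (molecules per
#' cell-equivalent) is drawn log-normally within each category, truncated to
#' non-overlapping intervals bounded by the geometric means of adjacent
#' category medians, so the intended category ordering is preserved exactly.
#'
#' @param cores_per_category Cores per intended category (default 20, for an
#'   80-core TMA).
#' @param category_medians Median latent expression per category 0-3.
#' @param sdlog Log-scale SD within each category.
#' @param seed Integer seed.
#' @return Tibble with columns `core_id`, `category` (intended 0-3),
#'   `latent_expression`.
#' @export
#' @examples
#' table(sim_cores(seed = 1)$category)
sim_cores <- function(cores_per_category = 20L,
                      category_medians = c(8e3, 6e4, 2.5e5, 1.5e6),
                      sdlog = 0.4, seed = 1L) {
  stopifnot(length(category_medians) == 4, all(diff(category_medians) > 0),
            sdlog >= 0, cores_per_category >= 1)
  # truncation bounds: geometric means between adjacent medians
  gmid <- sqrt(category_medians[-4] * category_medians[-1])
  lo <- c(0, gmid)
  hi <- c(gmid, Inf)
  cores <- with_seed(seed, {
    purrr::map_dfr(1:4, function(k) {
      mu <- log(category_medians[k])
      p_lo <- plnorm(lo[k], mu, sdlog)
      p_hi <- plnorm(hi[k], mu, sdlog)
      u <- runif(cores_per_category, p_lo, p_hi)
      tibble::tibble(category = k - 1L,
                     latent_expression = qlnorm(u, mu, sdlog))
    })
  })
  cores$core_id <- sprintf("C%02d", seq_len(nrow(cores)))
  cores[, c("core_id", "category", "latent_expression")]
}

#' Reader noise models
#'
#' Parameters of the readout stage that converts a deterministic,
#' sensitivity-driven score into the observed score. `noise_sd` is additive
#' Gaussian noise on the ordinal score scale applied before snapping back to
#' the valid score set. `perceptual_floor` is the lowest analytic sensitivity
#' a reader can exploit: the effective LOD driving the deterministic score is
#' `max(assay LOD, perceptual_floor)`. Manual readers carry a high floor
#' (faint staining gradations below it are not resolved visually, so extra
#' assay sensitivity goes unused) and large noise; image analysis has no
#' floor and small noise.
#'
#' @param readout `"manual"` or `"image_analysis"`.
#' @param noise_sd Score-scale noise SD (defaults: manual 0.5, image
#'   analysis 0.1).
#' @param perceptual_floor Effective sensitivity floor in molecules per
#'   cell-equivalent (defaults: manual 40,000, image analysis 0).
#' @return A list of class `reader_model`.
#' @export
reader_model <- function(readout = c("manual", "image_analysis"),
                         noise_sd = NULL, perceptual_floor = NULL) {
  readout <- match.arg(readout)
  noise_sd <- noise_sd %||% if (readout == "manual") 0.5 else 0.1
  perceptual_floor <- perceptual_floor %||%
    if (readout == "manual") 40000 else 0
  stopifnot(noise_sd >= 0, perceptual_floor >= 0)
  structure(list(readout = readout, noise_sd = noise_sd,
                 perceptual_floor = perceptual_floor),
            class = "reader_model")
}

# Deterministic (noise-free) score: a monotone non-decreasing step function
# of log(latent) - log(effective LOD). Thresholds are on the log-ratio scale.
deterministic_score <- function(latent, lod, thresholds = c(0, 0.35, 1.3, 2.6)) {
  d <- log(latent) - log(lod)
  lv <- SCORE_LEVELS_UL
  score <- numeric(length(d))
  for (j in seq_along(thresholds)) score[d >= thresholds[j]] <- lv[j + 1]
  score
}

#' Simulate a TMA score matrix
#'
#' For every (core, lab) pair, the deterministic score is a monotone
#' non-decreasing step function of `log(latent_expression) - log(effective
#' LOD)` where the effective LOD is `max(assay LOD, perceptual floor)` for
#' the given reader model. The observed score adds reader noise on the score
#' scale and snaps back to the valid score set `{0, 0.5, 1, 2, 3}` (clamped
#' at both ends). Lowering a lab's LOD never decreases its noise-free score
#' on any core.
#'
#' @param cores Tibble from [sim_cores()] (needs `core_id`,
#'   `latent_expression`).
#' @param labs Tibble from [sim_lab_cohort()] (needs `lab_id`, `lod`).
#' @param reader A [reader_model()].
#' @param thresholds Log-ratio thresholds for scores 0.5, 1, 2, 3.
#' @param seed Integer seed.
#' @return Long tibble with columns `core_id`, `lab_id`, `readout`, `score`.
#' @export
#' @examples
#' labs <- sim_lab_cohort(seed = 1)
#' cores <- sim_cores(seed = 1)
#' sim_score_matrix(cores, labs, reader_model("image_analysis"), seed = 1)
sim_score_matrix <- function(cores, labs, reader = reader_model("manual"),
                             thresholds = c(0, 0.35, 1.3, 2.6), seed = 1L) {
  if (!all(c("core_id", "latent_expression") %in% names(cores))) {
    abort("cores must have columns core_id and latent_expression")
  }
  if (!all(c("lab_id", "lod") %in% names(labs))) {
    abort("labs must have columns lab_id and lod")
  }
  stopifnot(inherits(reader, "reader_model"), all(labs$lod > 0))
  grid <- tidyr::expand_grid(core_id = cores$core_id, lab_id = labs$lab_id)
  grid <- dplyr::left_join(grid, cores[, c("core_id", "latent_expression")],
                           by = "core_id")
  grid <- dplyr::left_join(grid, labs[, c("lab_id", "lod")], by = "lab_id")
  eff_lod <- pmax(grid$lod, reader$perceptual_floor)
  det <- deterministic_score(grid$latent_expression, eff_lod, thresholds)
  obs <- if (reader$noise_sd > 0) {
    noisy <- det + with_seed(derive_seed(seed, reader$readout),
                             rnorm(nrow(grid), 0, reader$noise_sd))
    round_score(pmin(pmax(noisy, 0), 3), include_ultralow = TRUE)
  } else {
    det
  }
  tibble::tibble(core_id = grid$core_id, lab_id = grid$lab_id,
                 readout = reader$readout, score = obs)
}

#' Simulate per-core ISH results
#'
#' HER2/CEP17 ratios correlated with latent expression: cores above the
#' amplification threshold draw ratios well above 2, others below 2; a
#' configurable fraction of cores has its amplification status flipped
#' (discordant cases, drawn into the intermediate 2-3.2 band when flipped
#' up). An exact count `round(nonevaluable_rate * n)` of cores is flagged
#' non-evaluable (7 of 80 at the defaults) with `NA` ratios.
#'
#' @param cores Tibble from [sim_cores()].
#' @param discordance_rate Probability a core's amplification status is
#'   flipped relative to the latent-expression threshold (default 0.086, the
#'   intermediate-ratio fraction 6/70).
#' @param nonevaluable_rate Fraction of cores not analysable by ISH
#'   (default 7/80).
#' @param amp_threshold Latent expression above which a core is truly
#'   amplified.
#' @param seed Integer seed.
#' @return Tibble with columns `core_id`, `ish_ratio`, `ish_evaluable`.
#' @export
#' @examples
#' sim_ish(sim_cores(seed = 1), seed = 1)
sim_ish <- function(cores, discordance_rate = 0.086,
                    nonevaluable_rate = 7 / 80, amp_threshold = 6e5,
                    seed = 1L) {
  stopifnot(discordance_rate >= 0, discordance_rate <= 1,
            nonevaluable_rate >= 0, nonevaluable_rate <= 1)
  n <- nrow(cores)
  with_seed(derive_seed(seed, "ish"), {
    amplified <- cores$latent_expression >= amp_threshold
    flip <- runif(n) < discordance_rate
    ratio <- ifelse(xor(amplified, flip),
                    ifelse(amplified,
                           runif(n, 2.2, 5.5),   # concordant amplified
                           runif(n, 2.0, 3.2)),  # flipped up: intermediate
                    ifelse(amplified,
                           runif(n, 1.2, 1.9),   # flipped down
                           runif(n, 0.9, 1.8)))  # concordant non-amplified
    n_ne <- round(nonevaluable_rate * n)
    ne_idx <- sample.int(n, n_ne)
    evaluable <- rep(TRUE, n)
    evaluable[ne_idx] <- FALSE
    ratio[!evaluable] <- NA_real_
    tibble::tibble(core_id = cores$core_id, ish_ratio = ratio,
                   ish_evaluable = evaluable)
  })
}

#' Simulate a complete study cohort
#'
#' Convenience wrapper generating the laboratory cohort, the 80-core TMA,
#' both manual and image-analysis score matrices over the same labs and
#' cores, and the ISH table, all from one root seed (each stage on its own
#' derived substream).
#'
#' @param seed Integer root seed.
#' @param cohort_spec See [sim_lab_cohort()].
#' @param cores_per_category See [sim_cores()].
#' @param manual,image_analysis Reader models for the two readouts.
#' @param ... Passed to [sim_ish()].
#' @return A list of class `ihc_study` with elements `labs`, `cores`,
#'   `scores` (both readouts, long), `ish`, and `seed`.
#' @export
#' @examples
#' study <- sim_study(seed = 1)
#' dplyr::count(study$scores, readout)
sim_study <- function(seed = 1L, cohort_spec = default_lab_cohort_spec(),
                      cores_per_category = 20L,
                      manual = reader_model("manual"),
                      image_analysis = reader_model("image_analysis"), ...) {
  labs <- sim_lab_cohort(cohort_spec, seed = derive_seed(seed, "labs"))
  cores <- sim_cores(cores_per_category, seed = derive_seed(seed, "cores"))
  scores <- dplyr::bind_rows(
    sim_score_matrix(cores, labs, manual, seed = derive_seed(seed, "scores")),
    sim_score_matrix(cores, labs, image_analysis,
                     seed = derive_seed(seed, "scores"))
  )
  ish <- sim_ish(cores, seed = derive_seed(seed, "ish"), ...)
  structure(list(labs = labs, cores = cores, scores = scores, ish = ish,
                 seed = seed),
            class = "ihc_study")
}
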