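#' Convert an RGB image to greyscale intensity
#'
#' Luminance-weighted combination of the three channels (Rec. 601 weights
#' 0.299, 0.587, 0.114).
#'
#' @param rgb_image Numeric array `height x width x 3` with values in
#'   `[0, 1]` (8- or 16-bit images should be scaled to this range on read).
#' @return Numeric matrix `height x width`.
#' @export
#' @examples
#' img <- array(1, dim = c(4, 4, 3))
#' to_greyscale(img)[1, 1]  # 1: pure white
to_greyscale <- function(rgb_image) {
  d <- dim(rgb_image)
  if (length(d) != 3 || d[3] != 3) {
    abort("rgb_image must be a height x width x 3 array",
          class = "ihcsens_bad_image")
  }
  0.299 * rgb_image[, , 1] + 0.587 * rgb_image[, , 2] + 0.114 * rgb_image[, , 3]
}

# 3x3 box sum of a matrix (zero padded), used to pool Hough votes that
# rounding scatters across neighbouring accumulator cells.
box3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    out <- out + p[dy + seq_len(h), dx + seq_len(w)]
  }
  out
}

#' Detect round beads with a gradient-directed circle Hough transform
#'
#' Thresholds the greyscale image against the bright background, extracts
#' boundary pixels of the dark (stained) regions, and lets each boundary
#' pixel cast one vote per candidate radius at the position one radius inward
#' along its local intensity gradient (beads are darker than the background,
#' so the gradient at the boundary points outward). Candidate centres are
#' local maxima of the 3x3-pooled accumulator whose vote count clears a
#' fraction of the ideal circumference count; each candidate's radius is then
#' validated against the segmentation mask (the largest disc around the
#' centre lying entirely inside it) and detections outside the allowable
#' radius range are discarded. Duplicate detections of one bead at
#' neighbouring scan radii are resolved by [remove_overlaps()].
#'
#' @param grey Greyscale matrix from [to_greyscale()], background bright.
#' @param radius_range Vector `c(r_min, r_max)`, `0 < r_min < r_max`;
#'   integer radii in this range are scanned.
#' @param bg_threshold Pixels with grey value below this are foreground
#'   (default 0.985; negative-control beads are faint but darker than the
#'   white background).
#' @param min_votes_frac Minimum pooled votes as a fraction of the circle
#'   circumference `2 * pi * r` (default 0.35).
#' @return Tibble with columns `cx`, `cy` (pixel coordinates, x = column,
#'   y = row), `r`, `votes`; zero rows for a blank image.
#' @export
detect_beads <- function(grey, radius_range, bg_threshold = 0.985,
                         min_votes_frac = 0.35) {
  stopifnot(is.matrix(grey), length(radius_range) == 2)
  if (radius_range[1] <= 0 || radius_range[1] >= radius_range[2]) {
    abort("radius_range must satisfy 0 < r_min < r_max",
          class = "ihcsens_bad_radius")
  }
  r_min <- as.integer(ceiling(radius_range[1]))
  r_max <- as.integer(floor(radius_range[2]))
  empty <- tibble::tibble(cx = numeric(0), cy = numeric(0), r = integer(0),
                          votes = numeric(0))
  h <- nrow(grey); w <- ncol(grey)
  mask <- grey < bg_threshold
  if (!any(mask) || r_min > r_max) return(empty)
  shift <- function(m, dy, dx, fill = FALSE) {
    out <- matrix(fill, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  # boundary pixels: foreground with at least one 4-neighbour of background
  interior <- shift(mask, 1, 0) & shift(mask, -1, 0) &
    shift(mask, 0, 1) & shift(mask, 0, -1)
  edge <- mask & !interior
  if (!any(edge)) return(empty)
  # negated central-difference gradient: at the boundary of a dark bead this
  # descent direction points into the bead, towards the centre
  pad <- function(dy, dx) shift(grey, dy, dx, fill = 1)
  gx <- (pad(0, 1) - pad(0, -1)) / 2   # -d grey / d x
  gy <- (pad(1, 0) - pad(-1, 0)) / 2   # -d grey / d y
  ey <- row(grey)[edge]
  ex <- col(grey)[edge]
  gxe <- gx[edge]; gye <- gy[edge]
  gmag <- sqrt(gxe^2 + gye^2)
  ok <- gmag > 0
  ex <- ex[ok]; ey <- ey[ok]
  ux <- gxe[ok] / gmag[ok]; uy <- gye[ok] / gmag[ok]
  if (length(ex) == 0) return(empty)

  found <- list()
  for (r in r_min:r_max) {
    vx <- round(ex + r * ux)
    vy <- round(ey + r * uy)
    inb <- vx >= 1 & vx <= w & vy >= 1 & vy <= h
    if (!any(inb)) next
    idx <- (vx[inb] - 1) * h + vy[inb]
    acc <- matrix(tabulate(idx, nbins = h * w), h, w)
    pooled <- box3(acc)
    thresh <- min_votes_frac * 2 * pi * r
    cand <- which(pooled >= thresh, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      y <- cand[i, 1]; x <- cand[i, 2]
      ys <- max(1, y - 1):min(h, y + 1)
      xs <- max(1, x - 1):min(w, x + 1)
      pooled[y, x] >= max(pooled[ys, xs])
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) next
    found[[length(found) + 1]] <- tibble::tibble(
      cx = as.numeric(cand[, 2]), cy = as.numeric(cand[, 1]),
      r = r, votes = pooled[cand]
    )
  }
  if (length(found) == 0) return(empty)
  out <- dplyr::bind_rows(found)
  # validate each candidate against the segmentation mask: the radius is the
  # largest disc around the centre lying entirely in the mask; candidates
  # whose true extent falls outside the allowable range are discarded
  out$r <- vapply(seq_len(nrow(out)), function(i) {
    inscribed_radius(mask, out$cx[i], out$cy[i], r_max + 1L)
  }, numeric(1))
  out <- out[out$r >= r_min & out$r <= r_max, , drop = FALSE]
  out
}

# Largest integer radius rr <= cap such that every pixel within distance rr
# of (cx, cy) belongs to the mask (0 when the centre itself is background).
inscribed_radius <- function(mask, cx, cy, cap) {
  h <- nrow(mask); w <- ncol(mask)
  if (cx < 1 || cx > w || cy < 1 || cy > h || !mask[cy, cx]) return(0)
  best <- 0
  for (rr in seq_len(cap)) {
    xs <- (cx - rr):(cx + rr)
    ys <- (cy - rr):(cy + rr)
    if (any(xs < 1 | xs > w) || any(ys < 1 | ys > h)) break
    inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= rr^2
    if (!all(mask[ys, xs][inside])) break
    best <- rr
  }
  best
}

#' Remove overlapping circle detections
#'
#' Deterministic greedy rule: circles are ranked by descending vote count
#' (ties broken by `cy`, then `cx`); each circle is kept only if its centre
#' distance to every already-kept circle is at least `tol` times the sum of
#' the radii. The result is conflict-free and maximal: no removed circle
#' could be added back.
#'
#' @param circles Tibble with columns `cx`, `cy`, `r` and optionally `votes`
#'   (missing votes are treated as equal).
#' @param tol Overlap tolerance multiplying the radius sum (default 0.9;
#'   1 forbids any disc contact, smaller values allow slight overlap).
#' @return The retained subset, in the original row order.
#' @export
remove_overlaps <- function(circles, tol = 0.9) {
  stopifnot(all(c("cx", "cy", "r") %in% names(circles)), tol > 0)
  n <- nrow(circles)
  if (n <= 1) return(circles)
  votes <- if ("votes" %in% names(circles)) circles$votes else rep(0, n)
  ord <- order(-votes, circles$cy, circles$cx)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0) {
      kept <- i
      next
    }
    d <- sqrt((circles$cx[kept] - circles$cx[i])^2 +
                (circles$cy[kept] - circles$cy[i])^2)
    if (all(d >= tol * (circles$r[kept] + circles$r[i]))) {
      kept <- c(kept, i)
    }
  }
  circles[sort(kept), , drop = FALSE]
}

#' Per-bead chromogen stain intensity
#'
#' Mean over in-circle pixels of the dot product of the inverted pixel signal
#' (`1 - RGB`, so more chromogen means a larger value) with the unit DAB
#' colour profile. An inset shrinks the sampled disc to avoid boundary pixels
#' when the detected radius is uncertain by a pixel.
#'
#' @param rgb_image Numeric array `height x width x 3` in `[0, 1]`.
#' @param cx,cy,r Circle centre (x = column, y = row) and radius in pixels.
#' @param profile Unit 3-vector colour profile (default [dab_profile()]).
#' @param inset Pixels subtracted from the radius before sampling
#'   (default 1); if no pixel survives the inset, the full disc is used.
#' @return A single chromogen intensity.
#' @export
stain_intensity <- function(rgb_image, cx, cy, r, profile = dab_profile(),
                            inset = 1) {
  d <- dim(rgb_image)
  if (length(d) != 3 || d[3] != 3) {
    abort("rgb_image must be a height x width x 3 array",
          class = "ihcsens_bad_image")
  }
  stopifnot(length(profile) == 3)
  if (cx - r < 1 || cx + r > d[2] || cy - r < 1 || cy + r > d[1]) {
    abort("circle extends outside the image", class = "ihcsens_bad_circle")
  }
  sample_disc <- function(rr) {
    xs <- floor(cx - rr):ceiling(cx + rr)
    ys <- floor(cy - rr):ceiling(cy + rr)
    inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= rr^2
    if (!any(inside)) return(NULL)
    sig <- 0
    for (ch in 1:3) {
      plane <- 1 - rgb_image[ys, xs, ch]
      sig <- sig + profile[ch] * mean(plane[inside])
    }
    sig
  }
  out <- sample_disc(max(r - inset, 0.5))
  if (is.null(out)) out <- sample_disc(r)
  out
}

#' Assign detected beads to calibrator spots
#'
#' Each bead is assigned to the nearest known spot centre within
#' `max_dist`; beads outside all spots are discarded.
#'
#' @param circles Tibble with `cx`, `cy` (and any other columns, retained).
#' @param spots Spot layout tibble with `spot_id`, `cx`, `cy`.
#' @param max_dist Maximum centre-to-spot distance in pixels.
#' @return `circles` with a `spot_id` column, rows outside all spots dropped.
#' @export
assign_spots <- function(circles, spots, max_dist = 50) {
  stopifnot(all(c("cx", "cy") %in% names(circles)),
            all(c("spot_id", "cx", "cy") %in% names(spots)))
  if (nrow(circles) == 0) {
    circles$spot_id <- character(0)
    return(circles)
  }
  d2 <- outer(circles$cx, spots$cx, `-`)^2 + outer(circles$cy, spots$cy, `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(nrow(circles)), nearest)])
  circles$spot_id <- spots$spot_id[nearest]
  circles[dist <= max_dist, , drop = FALSE]
}

#' Summarise per-spot stain intensities
#'
#' @param detections Tibble with columns `spot_id` and `stain_intensity`
#'   (one row per retained bead).
#' @param spots Optional spot layout; spots with no detected bead are
#'   reported with a warning and excluded.
#' @return Tibble with columns `spot_id`, `n_beads`, `mean_intensity`,
#'   `sd_intensity` (0 for a single bead).
#' @export
summarize_spots <- function(detections, spots = NULL) {
  stopifnot(all(c("spot_id", "stain_intensity") %in% names(detections)))
  out <- detections |>
    dplyr::group_by(.data$spot_id) |>
    dplyr::summarise(
      n_beads = dplyr::n(),
      mean_intensity = mean(.data$stain_intensity),
      sd_intensity = ifelse(dplyr::n() > 1, sd(.data$stain_intensity), 0),
      .groups = "drop"
    )
  if (!is.null(spots)) {
    missing <- setdiff(spots$spot_id, out$spot_id)
    if (length(missing) > 0) {
      warn(paste0("spots with no detected beads excluded: ",
                  paste(missing, collapse = ", ")))
    }
  }
  out
}

#' Average duplicate calibrator measurements
#'
#' Measurements are performed in duplicate and averaged: the combined spot
#' mean is the arithmetic mean of the two run means; the combined SD pools
#' the two run variances; bead counts add. Symmetric in its arguments.
#'
#' @param run1,run2 Spot summaries from [summarize_spots()] sharing the same
#'   spot layout.
#' @return A combined spot summary tibble.
#' @export
average_duplicates <- function(run1, run2) {
  cols <- c("spot_id", "n_beads", "mean_intensity", "sd_intensity")
  stopifnot(all(cols %in% names(run1)), all(cols %in% names(run2)))
  joined <- dplyr::inner_join(run1[cols], run2[cols], by = "spot_id",
                              suffix = c("_1", "_2"))
  if (nrow(joined) != nrow(run1) || nrow(joined) != nrow(run2)) {
    abort("duplicate runs do not share the same spot layout")
  }
  tibble::tibble(
    spot_id = joined$spot_id,
    n_beads = joined$n_beads_1 + joined$n_beads_2,
    mean_intensity = (joined$mean_intensity_1 + joined$mean_intensity_2) / 2,
    sd_intensity = sqrt((joined$sd_intensity_1^2 + joined$sd_intensity_2^2) / 2)
  ) |>
    dplyr::arrange(.data$spot_id)
}

#' Quantify a calibrator slide image into spot summaries
#'
#' Full bead-quantification chain: greyscale conversion, circle Hough
#' detection over the allowable radius range, overlap removal, per-bead DAB
#' dot-product intensity, spot assignment, per-spot mean/SD.
#'
#' @param rgb_image Numeric array `height x width x 3` in `[0, 1]`.
#' @param spots Spot layout tibble (`spot_id`, `cx`, `cy`, `concentration`,
#'   `is_negative`), e.g. the `spots` element of [sim_calibrator_slide()].
#' @param radius_range Allowable bead radius range in pixels.
#' @param profile Chromogen colour profile.
#' @param spot_radius Maximum bead-to-spot-centre distance.
#' @param ... Passed to [detect_beads()].
#' @return Spot summary tibble joined with the layout's `concentration` and
#'   `is_negative` columns.
#' @export
#' @examples
#' sl <- sim_calibrator_slide(calibrator_curve(40000), seed = 1)
#' quantify_calibrator(sl$image, sl$spots, radius_range = c(4, 9))
quantify_calibrator <- function(rgb_image, spots, radius_range = c(4, 9),
                                profile = dab_profile(), spot_radius = 50,
                                ...) {
  grey <- to_greyscale(rgb_image)
  circles <- detect_beads(grey, radius_range, ...)
  circles <- remove_overlaps(circles)
  circles <- assign_spots(circles, spots, max_dist = spot_radius)
  if (nrow(circles) == 0) {
    abort("no beads detected on the slide", class = "ihcsens_no_beads")
  }
  circles$stain_intensity <- vapply(seq_len(nrow(circles)), function(i) {
    stain_intensity(rgb_image, circles$cx[i], circles$cy[i], circles$r[i],
                    profile = profile)
  }, numeric(1))
  out <- summarize_spots(circles, spots)
  dplyr::left_join(out, spots[, c("spot_id", "concentration", "is_negative")],
                   by = "spot_id")
}
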