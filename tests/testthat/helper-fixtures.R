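# Shared fixtures, cached per test run so expensive simulations happen once.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

fixture_study <- function(seed = 1) {
  cached(paste0("study_", seed), sim_study(seed = seed))
}

fixture_slide <- function(lod = 40000, seed = 1) {
  cached(paste0("slide_", lod, "_", seed),
         sim_calibrator_slide(calibrator_curve(lod), seed = seed))
}

# Paint filled discs (no anti-aliasing) onto a white RGB canvas with the
# given chromogen intensities along the DAB profile; an independent renderer
# for detection tests.
paint_discs <- function(h, w, cx, cy, r, intensity) {
  img <- array(1, dim = c(h, w, 3))
  u <- dab_profile()
  for (k in seq_along(cx)) {
    xs <- max(1, cx[k] - r[k]):min(w, cx[k] + r[k])
    ys <- max(1, cy[k] - r[k]):min(h, cy[k] + r[k])
    inside <- outer((ys - cy[k])^2, (xs - cx[k])^2, `+`) <= r[k]^2
    for (ch in 1:3) {
      plane <- img[ys, xs, ch]
      plane[inside] <- 1 - intensity[k] * u[ch]
      img[ys, xs, ch] <- plane
    }
  }
  img
}

# Do any two circles in the set conflict under the remove_overlaps rule?
circles_conflict_free <- function(circles, tol = 0.9) {
  n <- nrow(circles)
  if (n <= 1) return(TRUE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((circles$cx[i] - circles$cx[j])^2 +
                (circles$cy[i] - circles$cy[j])^2)
    if (d < tol * (circles$r[i] + circles$r[j])) return(FALSE)
  }
  TRUE
}

# Brute-force enumeration of all maximal conflict-free subsets of <= 6
# circles (a subset is maximal when no excluded circle can be added).
brute_force_maximal_subsets <- function(circles, tol = 0.9) {
  n <- nrow(circles)
  stopifnot(n <= 6)
  subsets <- list()
  for (bits in 0:(2^n - 1)) {
    idx <- which(bitwAnd(bits, 2^(seq_len(n) - 1)) > 0)
    sub <- circles[idx, , drop = FALSE]
    if (!circles_conflict_free(sub, tol)) next
    maximal <- all(vapply(setdiff(seq_len(n), idx), function(j) {
      !circles_conflict_free(circles[c(idx, j), , drop = FALSE], tol)
    }, logical(1)))
    if (maximal) subsets[[length(subsets) + 1]] <- sort(idx)
  }
  subsets
}
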