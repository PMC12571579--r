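test_that("greyscale conversion is the stated luminance combination", {
  set.seed(1)
  img <- array(runif(5 * 4 * 3), dim = c(5, 4, 3))
  grey <- to_greyscale(img)
  manual <- matrix(0, 5, 4)
  for (y in 1:5) for (x in 1:4) {
    manual[y, x] <- sum(c(0.299, 0.587, 0.114) * img[y, x, ])
  }
  expect_equal(grey, manual)
  expect_equal(to_greyscale(array(1, dim = c(3, 3, 3))), matrix(1, 3, 3))
  expect_error(to_greyscale(matrix(1, 3, 3)), class = "ihcsens_bad_image")
  expect_error(to_greyscale(array(1, dim = c(3, 3, 2))),
               class = "ihcsens_bad_image")
})

test_that("known non-overlapping circles are recovered within one pixel", {
  cx <- c(20, 50, 80, 30, 70)
  cy <- c(25, 20, 30, 70, 75)
  img <- paint_discs(100, 100, cx, cy, r = rep(6, 5), intensity = rep(0.4, 5))
  det <- remove_overlaps(detect_beads(to_greyscale(img), c(4, 9)))
  expect_equal(nrow(det), 5)
  for (k in 1:5) {
    d <- min(sqrt((det$cx - cx[k])^2 + (det$cy - cy[k])^2))
    expect_lte(d, 1)
  }
  expect_true(all(det$r >= 4 & det$r <= 9))
})

test_that("circles outside the allowable radius range are not reported", {
  img_small <- paint_discs(60, 60, c(20, 40), c(20, 40), r = c(3, 3),
                           intensity = c(0.4, 0.4))
  det <- detect_beads(to_greyscale(img_small), c(5, 9))
  expect_equal(nrow(det), 0)
  blank <- detect_beads(matrix(1, 50, 50), c(4, 9))
  expect_equal(nrow(blank), 0)
  expect_error(detect_beads(matrix(1, 10, 10), c(9, 4)),
               class = "ihcsens_bad_radius")
})

test_that("overlap removal keeps one of two identical circles", {
  circles <- tibble::tibble(cx = c(10, 10), cy = c(10, 10), r = c(5, 5),
                            votes = c(10, 8))
  kept <- remove_overlaps(circles)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$votes, 10)
  disjoint <- tibble::tibble(cx = c(10, 40), cy = c(10, 40), r = c(5, 5))
  expect_identical(remove_overlaps(disjoint), disjoint)
})

test_that("greedy overlap removal yields a maximal conflict-free subset", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    circles <- tibble::tibble(cx = runif(n, 0, 30), cy = runif(n, 0, 30),
                              r = runif(n, 3, 8), votes = runif(n))
    kept <- remove_overlaps(circles)
    kept_idx <- sort(match(paste(kept$cx, kept$cy), paste(circles$cx, circles$cy)))
    expect_true(circles_conflict_free(kept))
    maximal <- brute_force_maximal_subsets(circles)
    expect_true(any(vapply(maximal, identical, logical(1), y = kept_idx)))
  }
})

test_that("stain intensity is the DAB dot product over in-circle pixels", {
  u <- dab_profile()
  # uniform bead whose inverted signal is parallel to the profile, magnitude m
  m <- 0.37
  img <- paint_discs(40, 40, 20, 20, r = 8, intensity = m)
  expect_equal(stain_intensity(img, 20, 20, 8), m, tolerance = 1e-12)
  # unstained region: white background reads exactly 0
  blank <- array(1, dim = c(40, 40, 3))
  expect_equal(stain_intensity(blank, 20, 20, 8), 0)
  expect_error(stain_intensity(img, 2, 2, 8), class = "ihcsens_bad_circle")
  # orthogonal colour contributes only its projection
  img2 <- array(1, dim = c(20, 20, 3))
  img2[, , 1] <- 1 - 0.5  # red-only signal of 0.5
  expect_equal(stain_intensity(img2, 10, 10, 5), 0.5 * u[1], tolerance = 1e-12)
})

test_that("spot summaries and duplicate averaging match direct computation", {
  set.seed(4)
  det <- tibble::tibble(spot_id = rep(c("S1", "S2"), each = 6),
                        stain_intensity = runif(12))
  s <- summarize_spots(det)
  expect_equal(s$mean_intensity,
               as.numeric(tapply(det$stain_intensity, det$spot_id, mean)))
  expect_equal(s$sd_intensity,
               as.numeric(tapply(det$stain_intensity, det$spot_id, sd)))
  expect_equal(s$n_beads, c(6L, 6L))

  r1 <- tibble::tibble(spot_id = "S1", n_beads = 5L, mean_intensity = 10,
                       sd_intensity = 1)
  r2 <- tibble::tibble(spot_id = "S1", n_beads = 5L, mean_intensity = 20,
                       sd_intensity = 3)
  avg <- average_duplicates(r1, r2)
  expect_equal(avg$mean_intensity, 15)
  expect_equal(avg$n_beads, 10L)
  expect_equal(avg$sd_intensity, sqrt((1 + 9) / 2))
  expect_identical(average_duplicates(r1, r2), average_duplicates(r2, r1))
  expect_equal(average_duplicates(r1, r1)$mean_intensity, r1$mean_intensity)
  expect_error(average_duplicates(r1, dplyr::mutate(r2, spot_id = "S9")))
})

test_that("spots with no beads are flagged and excluded", {
  det <- tibble::tibble(spot_id = "S1", stain_intensity = 0.5)
  spots <- tibble::tibble(spot_id = c("S1", "S2"), cx = c(1, 2), cy = c(1, 2))
  expect_warning(out <- summarize_spots(det, spots), "S2")
  expect_equal(out$spot_id, "S1")
})

test_that("full quantification recovers ground truth on a noise-free slide", {
  sl <- fixture_slide(40000)
  qs <- quantify_calibrator(sl$image, sl$spots)
  expect_equal(nrow(qs), 15)
  expect_equal(sum(qs$n_beads), nrow(sl$beads))
  # intensity ordering follows concentration on the noise-free slide (up to
  # the dithered 8-bit measurement resolution on the flat plateau)
  conc <- qs[!qs$is_negative, ]
  conc <- conc[order(conc$concentration), ]
  expect_true(all(diff(conc$mean_intensity) > -1e-3))
  # recovered spot means match the rendered intensities closely
  truth <- sl$spots$intended_intensity[match(qs$spot_id, sl$spots$spot_id)]
  expect_lt(max(abs(qs$mean_intensity - truth)), 0.002)
})
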