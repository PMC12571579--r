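test_that("identical seeds give bit-identical study outputs", {
  a <- sim_study(seed = 42)
  b <- sim_study(seed = 42)
  expect_identical(a$labs, b$labs)
  expect_identical(a$cores, b$cores)
  expect_identical(a$scores, b$scores)
  expect_identical(a$ish, b$ish)
  c <- sim_study(seed = 43)
  expect_false(identical(a$scores, c$scores))
})

test_that("calibrator slides are byte-identical under a fixed seed", {
  s1 <- sim_calibrator_slide(calibrator_curve(40000), seed = 7)
  s2 <- sim_calibrator_slide(calibrator_curve(40000), seed = 7)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$beads, s2$beads)
})

test_that("zero-noise beads carry exactly the clipped curve intensity", {
  cc <- calibrator_curve(40000)
  sl <- sim_calibrator_slide(cc, bead_noise_sd = 0, seed = 3)
  truth <- merge(sl$beads, sl$spots[, c("spot_id", "intended_intensity")],
                 by = "spot_id")
  expect_equal(truth$intensity, truth$intended_intensity)
  negs <- sl$beads$intensity[sl$beads$spot_id %in%
                               sl$spots$spot_id[sl$spots$is_negative]]
  expect_true(all(negs == cc$neg_mean))
})

test_that("curve parameters implying invalid intensities are rejected", {
  expect_error(calibrator_curve(40000, slope = -0.1), class = "ihcsens_bad_curve")
  expect_error(calibrator_curve(40000, neg_mean = -0.5), class = "ihcsens_bad_curve")
  # a plateau so strong the pixel values would go negative
  expect_error(calibrator_curve(1000, slope = 0.5), class = "ihcsens_bad_curve")
})

test_that("curve is anchored at the LOD and clipped on both ends", {
  cc <- calibrator_curve(40000, noise_sd = 0.02)
  expect_equal(curve_intensity(cc, 40000), cc$neg_mean + 3 * 0.02)
  expect_equal(curve_intensity(cc, 1000), cc$neg_mean)       # baseline clip
  expect_equal(curve_intensity(cc, 5e6), cc$plateau)         # plateau clip
  expect_equal(curve_intensity(cc, NA), cc$neg_mean)         # negative spot
})

test_that("cores are exactly balanced across intended categories", {
  cores <- sim_cores(cores_per_category = 20, seed = 5)
  expect_equal(unname(table(cores$category)), rep(20L, 4), ignore_attr = TRUE)
  expect_true(all(cores$latent_expression > 0))
  # category ordering is preserved by the truncated draws
  med <- tapply(cores$latent_expression, cores$category, median)
  expect_true(all(diff(med) > 0))
})

test_that("noise-free scores are monotone in analytic sensitivity", {
  cores <- sim_cores(seed = 2)
  labs <- tibble::tibble(lab_id = c("A", "B"), assay = "x",
                         lod = c(20000, 60000))
  quiet <- reader_model("image_analysis", noise_sd = 0, perceptual_floor = 0)
  m <- sim_score_matrix(cores, labs, quiet, seed = 1)
  wide <- tidyr::pivot_wider(m, id_cols = "core_id", names_from = "lab_id",
                             values_from = "score")
  expect_true(all(wide$A >= wide$B))
})

test_that("expression far below the most sensitive LOD scores 0 everywhere", {
  cores <- tibble::tibble(core_id = "C1", latent_expression = 100)
  labs <- tibble::tibble(lab_id = c("A", "B"), lod = c(5000, 60000))
  quiet <- reader_model("image_analysis", noise_sd = 0, perceptual_floor = 0)
  m <- sim_score_matrix(cores, labs, quiet, seed = 1)
  expect_true(all(m$score == 0))
})

test_that("average noise-free score strictly decreases in LOD", {
  cores <- sim_cores(seed = 4)
  labs <- tibble::tibble(lab_id = sprintf("L%d", 1:6), assay = "x",
                         lod = seq(10000, 60000, 10000))
  quiet <- reader_model("image_analysis", noise_sd = 0, perceptual_floor = 0)
  m <- sim_score_matrix(cores, labs, quiet, seed = 1)
  avg <- tapply(m$score, m$lab_id, mean)[labs$lab_id]
  expect_true(all(diff(avg) < 0))
})

test_that("lab cohort draws honour family means and truncation", {
  spec0 <- tibble::tibble(assay = "4B5 per IFU", n_labs = 5L,
                          lod_mean = 54436, lod_sd = 0)
  labs <- sim_lab_cohort(spec0, seed = 1)
  expect_true(all(labs$lod == 54436))
  # empty cohort is allowed
  spec_empty <- tibble::tibble(assay = "x", n_labs = 0L, lod_mean = 1,
                               lod_sd = 1)
  expect_equal(nrow(sim_lab_cohort(spec_empty, seed = 1)), 0)
  # sample CV approaches sd/mean at large n
  spec_big <- tibble::tibble(assay = "4B5 per IFU", n_labs = 20000L,
                             lod_mean = 54436, lod_sd = 19569)
  big <- sim_lab_cohort(spec_big, seed = 1)
  expect_true(all(big$lod > 0))
  cv <- sd(big$lod) / mean(big$lod) * 100
  expect_lt(abs(cv - 19569 / 54436 * 100), 1.5)
})

test_that("ISH table flags the exact non-evaluable count and is reproducible", {
  cores <- sim_cores(seed = 1)
  ish <- sim_ish(cores, seed = 9)
  expect_equal(sum(!ish$ish_evaluable), 7)
  expect_true(all(is.na(ish$ish_ratio[!ish$ish_evaluable])))
  expect_true(all(ish$ish_ratio[ish$ish_evaluable] > 0))
  expect_identical(ish, sim_ish(cores, seed = 9))
})

test_that("zero discordance makes amplification a threshold on expression", {
  cores <- sim_cores(seed = 3)
  ish <- sim_ish(cores, discordance_rate = 0, nonevaluable_rate = 0,
                 amp_threshold = 6e5, seed = 2)
  amp <- classify_ish(ish$ish_ratio) == "amplified"
  expect_identical(amp, cores$latent_expression >= 6e5)
})
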