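test_that("bin membership follows the absolute-difference rule", {
  labs <- tibble::tibble(lab_id = c("a", "b"), lod = c(42000, 45000))
  m <- bin_labs(labs, centers = c(40000, 50000), halfwidth = 5000)
  expect_equal(m$center[m$lab_id == "a"], 40000)        # bin 40 only
  expect_equal(sort(m$center[m$lab_id == "b"]), c(40000, 50000))  # both, inclusive
  expect_warning(bin_labs(labs, centers = c(40000, 90000)), "empty")
})

test_that("bin membership matches a brute-force filter on a random cohort", {
  labs <- fixture_study()$labs
  centers <- seq(10000, 60000, 10000)
  m <- bin_labs(labs, centers = centers, halfwidth = 5000)
  for (ct in centers) {
    expect_setequal(m$lab_id[m$center == ct],
                    labs$lab_id[abs(labs$lod - ct) <= 5000])
  }
})

test_that("degenerate regressions get exact slope/p limits", {
  scores <- tibble::tibble(core_id = rep(sprintf("C%d", 1:4), 6),
                           lab_id = rep(sprintf("L%d", 1:6), each = 4),
                           score = 1)
  labs <- tibble::tibble(lab_id = sprintf("L%d", 1:6),
                         lod = seq(10000, 60000, 10000))
  fit <- dynamic_range_slope(scores, labs, centers = labs$lod)
  expect_equal(fit$slope, 0)
  expect_equal(fit$t_statistic, 0)
  expect_equal(fit$p_value, 1)
  # exactly linear aggregates: slope recovered with zero standard error
  # (two cores per lab so each one-lab bin aggregate steps down by 0.5)
  lin <- tibble::tibble(
    core_id = rep(c("C1", "C2"), 6),
    lab_id = rep(sprintf("L%d", 1:6), each = 2),
    score = c(3, 3, 3, 2, 2, 2, 1, 2, 1, 1, 0, 1)
  )
  fit2 <- dynamic_range_slope(lin, labs, centers = labs$lod)
  y <- c(3, 2.5, 2, 1.5, 1, 0.5)
  x <- labs$lod
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit2$slope, a)
  expect_equal(fit2$se_slope, 0)
  expect_equal(fit2$p_value, 0)
})

test_that("OLS outputs match closed-form normal equations", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    x <- sort(runif(n, 1, 100))
    y <- 2 - 0.03 * x + rnorm(n, 0, 0.4)
    fit <- ihcsens:::slope_ols(x, y)
    sxx <- sum((x - mean(x))^2)
    a <- sum((x - mean(x)) * (y - mean(y))) / sxx
    b <- mean(y) - a * mean(x)
    res <- y - (b + a * x)
    se <- sqrt(sum(res^2) / (n - 2) / sxx)
    expect_equal(fit$slope, a, tolerance = 1e-10)
    expect_equal(fit$intercept, b, tolerance = 1e-10)
    expect_equal(fit$se_slope, se, tolerance = 1e-10)
    expect_equal(fit$p_value, 2 * pt(-abs(a / se), n - 2), tolerance = 1e-10)
  }
})

test_that("slope comparison is symmetric and exact for identical fits", {
  a <- list(slope = -0.5, se_slope = 0.1, df = 4)
  b <- list(slope = -0.1, se_slope = 0.2, df = 4)
  expect_equal(compare_slopes(a, a)$p_value, 1)
  ab <- compare_slopes(a, b); ba <- compare_slopes(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  # Welch-Satterthwaite df
  expect_equal(ab$df, (0.1^2 + 0.2^2)^2 / (0.1^4 / 4 + 0.2^4 / 4))
  bad <- list(slope = 1, se_slope = 0, df = 4)
  expect_error(compare_slopes(bad, list(slope = 2, se_slope = 0, df = 4)),
               class = "ihcsens_degenerate_fit")
})

test_that("per-bin score fractions are conserved and regress sensibly", {
  study <- fixture_study()
  centers <- seq(10000, 60000, 10000)
  sf <- per_score_fractions(study$scores, study$labs,
                            readout = "image_analysis", centers = centers)
  sums <- tapply(sf$fractions$fraction, sf$fractions$center, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # the HER2 0 fraction grows as assays get less sensitive
  fit0 <- sf$fits[sf$fits$score == 0, ]
  expect_gt(fit0$slope, 0)
  expect_lt(fit0$p_value, 0.05)
})

test_that("an all-zero matrix has fraction one at score 0 in every bin", {
  labs <- tibble::tibble(lab_id = sprintf("L%d", 1:6),
                         lod = seq(10000, 60000, 10000))
  scores <- tidyr::expand_grid(core_id = sprintf("C%d", 1:5),
                               lab_id = labs$lab_id)
  scores$score <- 0
  sf <- per_score_fractions(scores, labs, centers = labs$lod)
  f0 <- sf$fractions[sf$fractions$score == 0, ]
  expect_true(all(f0$fraction == 1))
  expect_equal(sf$fits$slope[sf$fits$score == 0], 0)
})

test_that("simulated cohort shows the expected dynamic-range contrast", {
  study <- fixture_study()
  centers <- seq(10000, 60000, 10000)
  ia <- dynamic_range_slope(study$scores, study$labs,
                            readout = "image_analysis", centers = centers)
  expect_lt(ia$slope, 0)          # scores fall as LOD rises
  expect_lt(ia$p_value, 0.05)
  man <- dynamic_range_slope(study$scores, study$labs, readout = "manual",
                             centers = centers)
  expect_gt(abs(ia$slope), abs(man$slope))
  expect_error(dynamic_range_slope(study$scores, study$labs,
                                   centers = centers),
               "mix readout")
  expect_error(dynamic_range_slope(study$scores, study$labs,
                                   readout = "image_analysis",
                                   centers = centers, lod_max = 15000),
               class = "ihcsens_too_few_bins")
  td <- tidy(ia)
  expect_equal(td$slope, ia$slope)
  expect_equal(nrow(td), 1)
})
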