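test_that("ISH amplification is a threshold at ratio 2.0", {
  expect_equal(classify_ish(c(1.0, 2.0, 3.2)),
               c("not_amplified", "amplified", "amplified"))
  expect_true(is.na(classify_ish(NA_real_)))
  expect_error(classify_ish(-1))
})

test_that("Trastuzumab confusion implements the reflex-ISH convention", {
  cons <- tibble::tibble(core_id = sprintf("c%d", 1:6),
                         consensus = c(3, 1, 2, 2, 0, 3))
  ish <- tibble::tibble(core_id = sprintf("c%d", 1:6),
                        ish_ratio = c(4, 2.5, 3, 1.2, 1, 1.5),
                        ish_evaluable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  cf <- trastuzumab_confusion(cons, ish)
  # c1: 3+/amp TP; c2: 1+/amp FN; c3: 2+/amp reflex-positive TP;
  # c4: 2+/not TN; c5: 0/not TN; c6 non-evaluable excluded
  expect_equal(cf$tp, 2)
  expect_equal(cf$fn, 1)
  expect_equal(cf$tn, 2)
  expect_equal(cf$fp, 0)
  expect_equal(cf$n, 5)
})

test_that("confusion counts equal brute-force enumeration on a cohort", {
  study <- fixture_study()
  cons <- consensus_scores(study$scores, readout = "manual")
  cf <- trastuzumab_confusion(cons, study$ish)
  dat <- merge(cons, study$ish, by = "core_id")
  dat <- dat[dat$ish_evaluable, ]
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(nrow(dat))) {
    amp <- dat$ish_ratio[i] >= 2
    pos <- dat$consensus[i] == 3 || (dat$consensus[i] == 2 && amp)
    if (pos && amp) tp <- tp + 1
    if (pos && !amp) fp <- fp + 1
    if (!pos && !amp) tn <- tn + 1
    if (!pos && amp) fn <- fn + 1
  }
  expect_equal(cf$tp, tp); expect_equal(cf$fp, fp)
  expect_equal(cf$tn, tn); expect_equal(cf$fn, fn)
  expect_equal(cf$n, nrow(dat))
})

test_that("Clopper-Pearson intervals hit the exact limits at the edges", {
  expect_equal(clopper_pearson(0, 10)$ci_low, 0)
  expect_equal(clopper_pearson(10, 10)$ci_high, 1)
  ci <- clopper_pearson(5, 10, alpha = 0.1)
  expect_equal(ci$ci_low, qbeta(0.05, 5, 6))
  expect_equal(ci$ci_high, qbeta(0.95, 6, 5))
  expect_error(clopper_pearson(1, 0))
  expect_error(clopper_pearson(5, 4))
})

test_that("diagnostic metrics follow the stated formulas with NA for 0/0", {
  m <- diagnostic_metrics(confusion_counts(tp = 3, fp = 1, tn = 5, fn = 1))
  expect_equal(m$estimate[m$metric == "accuracy"], 0.8)
  expect_equal(m$estimate[m$metric == "sensitivity"], 3 / 4)
  expect_equal(m$estimate[m$metric == "specificity"], 5 / 6)
  no_pos <- diagnostic_metrics(confusion_counts(tp = 0, fp = 0, tn = 5,
                                                fn = 0))
  expect_true(is.na(no_pos$estimate[no_pos$metric == "sensitivity"]))
  expect_true(is.na(no_pos$estimate[no_pos$metric == "ppv"]))
  expect_equal(no_pos$estimate[no_pos$metric == "accuracy"], 1)
  expect_true(all(stats::na.omit(m$ci_low <= m$estimate &
                                   m$estimate <= m$ci_high)))
})

test_that("treatment rules match exhaustive logic-table enumeration", {
  grid <- expand.grid(score = c(0, 0.5, 1, 2, 3),
                      ish = c("amplified", "not_amplified", NA),
                      stringsAsFactors = FALSE)
  # expected decisions derived by hand from the eligibility rules
  tdxd_ul <- function(s, ish) {
    if (s %in% c(0.5, 1)) return(TRUE)
    if (s == 2) return(is.na(ish) || ish != "amplified")
    FALSE
  }
  tdxd_noul <- function(s, ish) {
    if (s == 1) return(TRUE)
    if (s == 2) return(is.na(ish) || ish != "amplified")
    FALSE
  }
  tras <- function(s, ish) {
    s == 3 || (s == 2 && !is.na(ish) && ish == "amplified")
  }
  got_ul <- apply_treatment_rule(treatment_rule("t_dxd", TRUE),
                                 grid$score, grid$ish)
  got_noul <- apply_treatment_rule(treatment_rule("t_dxd", FALSE),
                                   grid$score, grid$ish)
  got_tras <- apply_treatment_rule(treatment_rule("trastuzumab"),
                                   grid$score, grid$ish)
  for (i in seq_len(nrow(grid))) {
    expect_identical(got_ul[i], tdxd_ul(grid$score[i], grid$ish[i]))
    expect_identical(got_noul[i], tdxd_noul(grid$score[i], grid$ish[i]))
    expect_identical(got_tras[i], tras(grid$score[i], grid$ish[i]))
  }
  # without ISH, 2+ counts as HER2-low for T-Dxd
  expect_true(apply_treatment_rule(treatment_rule("t_dxd"), 2))
  expect_false(apply_treatment_rule(treatment_rule("t_dxd"), 3))
  expect_false(apply_treatment_rule(treatment_rule("t_dxd"), 0))
})

test_that("gold standard consensus maps through the rule per core", {
  scores <- tibble::tibble(core_id = rep(c("c1", "c2", "c3"), 2),
                           lab_id = rep(c("a", "b"), each = 3),
                           score = c(0, 1, 3, 0, 1, 3))
  labs <- tibble::tibble(lab_id = c("a", "b"), lod = c(50000, 60000))
  gold <- tdxd_gold_standard(scores, labs, lod_gt = 40000)
  expect_equal(gold$gold_treat[match(c("c1", "c2", "c3"), gold$core_id)],
               c(FALSE, TRUE, FALSE))
})

test_that("a single-lab gold-standard group scores itself perfectly", {
  study <- fixture_study()
  one <- study$labs[which.max(study$labs$lod), ]
  gold <- tdxd_gold_standard(study$scores, study$labs,
                             lod_min = one$lod, lod_max = one$lod,
                             readout = "image_analysis")
  prof <- lab_accuracy_profile(study$scores, study$labs, gold,
                               readout = "image_analysis")
  expect_equal(prof$accuracy[prof$lab_id == one$lab_id], 1)
})

test_that("confusion totals per lab equal the number of gold cores", {
  study <- fixture_study()
  gold <- tdxd_gold_standard(study$scores, study$labs, lod_gt = 40000,
                             readout = "image_analysis")
  prof <- lab_accuracy_profile(study$scores, study$labs, gold,
                               readout = "image_analysis")
  expect_true(all(prof$tp + prof$fp + prof$tn + prof$fn == nrow(gold)))
  expect_false(is.unsorted(prof$lod))
})

test_that("accuracy mismatch inverts with the gold-standard sensitivity", {
  study <- fixture_study()
  g_hi <- tdxd_gold_standard(study$scores, study$labs, lod_gt = 40000,
                             readout = "image_analysis")
  p_hi <- lab_accuracy_profile(study$scores, study$labs, g_hi,
                               readout = "image_analysis")
  expect_gt(mean(p_hi$accuracy[p_hi$lod >= 40000]),
            mean(p_hi$accuracy[p_hi$lod < 20000]))
  g_lo <- tdxd_gold_standard(study$scores, study$labs, lod_lt = 20000,
                             readout = "image_analysis")
  p_lo <- lab_accuracy_profile(study$scores, study$labs, g_lo,
                               readout = "image_analysis")
  expect_gt(mean(p_lo$accuracy[p_lo$lod < 20000]),
            mean(p_lo$accuracy[p_lo$lod >= 40000]))
})
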