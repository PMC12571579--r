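#' Classify an ISH result
#'
#' A core is HER2 gene-amplified when its HER2/CEP17 ratio is at least 2.0.
#'
#' @param ratio Positive HER2/CEP17 ratios (`NA` for non-evaluable cores).
#' @return Character vector, `"amplified"` or `"not_amplified"` (`NA`
#'   propagated).
#' @export
#' @examples
#' classify_ish(c(1.0, 2.0, 3.2))
classify_ish <- function(ratio) {
  if (any(!is.na(ratio) & ratio <= 0)) {
    abort("HER2/CEP17 ratios must be positive")
  }
  ifelse(is.na(ratio), NA_character_,
         ifelse(ratio >= 2.0, "amplified", "not_amplified"))
}

#' Confusion counts for Trastuzumab stratification against ISH
#'
#' Gold standard: ISH amplification (ratio >= 2). The IHC call is positive
#' for a 3+ consensus score, or for a 2+ score whose reflex ISH is amplified;
#' all lower scores are negative. Non-evaluable cores are excluded.
#'
#' @param consensus Tibble with `core_id` and `consensus` (from
#'   [consensus_scores()]).
#' @param ish Tibble with `core_id`, `ish_ratio`, `ish_evaluable`.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`,
#'   and `n`.
#' @export
#' @examples
#' study <- sim_study(seed = 1)
#' cons <- consensus_scores(study$scores, readout = "manual")
#' trastuzumab_confusion(cons, study$ish)
trastuzumab_confusion <- function(consensus, ish) {
  stopifnot(all(c("core_id", "consensus") %in% names(consensus)),
            all(c("core_id", "ish_ratio", "ish_evaluable") %in% names(ish)))
  check_scores(consensus$consensus)
  dat <- dplyr::inner_join(consensus, ish, by = "core_id")
  dat <- dat[dat$ish_evaluable & !is.na(dat$ish_ratio), , drop = FALSE]
  amplified <- classify_ish(dat$ish_ratio) == "amplified"
  ihc_pos <- dat$consensus == 3 | (dat$consensus == 2 & amplified)
  confusion_counts(tp = sum(ihc_pos & amplified),
                   fp = sum(ihc_pos & !amplified),
                   tn = sum(!ihc_pos & !amplified),
                   fn = sum(!ihc_pos & amplified))
}

#' Construct confusion counts
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn),
            class = "confusion_counts")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact binomial interval: the lower bound is 0
#' when `k = 0` and the upper bound 1 when `k = n`.
#'
#' @param k Number of successes, `0 <= k <= n` (vectorised).
#' @param n Number of trials, `n >= 1`.
#' @param alpha Significance level in (0, 1); 0.05 gives a 95% interval.
#' @return Tibble with columns `estimate`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' clopper_pearson(18, 21)  # 0.6366 - 0.9695
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (any(n < 1)) abort("n must be at least 1")
  stopifnot(all(k >= 0), all(k <= n), alpha > 0, alpha < 1)
  lo <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  hi <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble::tibble(estimate = k / n, ci_low = lo, ci_high = hi)
}

#' Diagnostic metrics with exact confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)` and accuracy `(tn+tp)/(tn+fp+fn+tp)`, each with a
#' Clopper-Pearson interval on its numerator/denominator pair. Metrics with a
#' zero denominator are reported as `NA`, not 0.
#'
#' @param counts A `confusion_counts` object.
#' @param alpha Significance level for the intervals.
#' @return Tibble with columns `metric`, `k`, `n`, `estimate`, `ci_low`,
#'   `ci_high`.
#' @export
#' @examples
#' diagnostic_metrics(confusion_counts(tp = 18, fp = 0, tn = 49, fn = 3))
diagnostic_metrics <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n == 0) abort("confusion counts are all zero")
  pairs <- tibble::tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv", "accuracy"),
    k = c(counts$tp, counts$tn, counts$tp, counts$tn, counts$tp + counts$tn),
    n = c(counts$tp + counts$fn, counts$tn + counts$fp,
          counts$tp + counts$fp, counts$tn + counts$fn, counts$n)
  )
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    if (pairs$n[i] == 0) {
      return(tibble::tibble(estimate = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_))
    }
    clopper_pearson(pairs$k[i], pairs$n[i], alpha)
  })
  dplyr::bind_cols(pairs, out)
}

#' Treatment-decision rules
#'
#' Score-to-treatment mapping reconstructed from the trial eligibility
#' criteria (the study's supplementary logic table is not published, so this
#' default is a labelled reconstruction and alternatives are pluggable).
#' For T-Dxd, treatment is indicated for HER2-low consensus scores: 1+ or 2+
#' (plus ultralow 0.5 when `include_ultralow`), with 3+ routed to the
#' Trastuzumab pathway (no T-Dxd) and 2+ cores excluded when their reflex ISH
#' is amplified. For Trastuzumab, treatment is indicated for 3+, or 2+ with
#' amplified ISH.
#'
#' @param context `"t_dxd"` or `"trastuzumab"`.
#' @param include_ultralow Does ultralow (0.5) qualify for T-Dxd?
#' @return A list of class `treatment_rule`.
#' @export
treatment_rule <- function(context = c("t_dxd", "trastuzumab"),
                           include_ultralow = TRUE) {
  context <- match.arg(context)
  structure(list(context = context, include_ultralow = include_ultralow),
            class = "treatment_rule")
}

#' Apply a treatment rule to scores
#'
#' @param rule A [treatment_rule()].
#' @param score Valid HER2 scores.
#' @param ish_status Optional per-core ISH status (`"amplified"` /
#'   `"not_amplified"` / `NA`); when supplied, 2+ scores route by reflex ISH.
#' @return Logical vector: treat (`TRUE`) or no-treat (`FALSE`).
#' @export
#' @examples
#' apply_treatment_rule(treatment_rule("t_dxd"), c(0, 0.5, 1, 2, 3))
apply_treatment_rule <- function(rule, score, ish_status = NULL) {
  stopifnot(inherits(rule, "treatment_rule"))
  check_scores(score)
  amplified <- if (is.null(ish_status)) {
    rep(FALSE, length(score))
  } else {
    !is.na(ish_status) & ish_status == "amplified"
  }
  if (rule$context == "t_dxd") {
    low_pos <- if (rule$include_ultralow) c(0.5, 1, 2) else c(1, 2)
    treat <- score %in% low_pos
    # 2+ with amplified reflex ISH routes to the Trastuzumab pathway
    treat[score == 2 & amplified] <- FALSE
    treat
  } else {
    score == 3 | (score == 2 & amplified)
  }
}

#' LOD-defined gold standard for treatment decisions
#'
#' The gold standard treat/no-treat call per core is the consensus of the
#' laboratories selected by an LOD criterion (e.g. `lod_gt = 40000` for a
#' low-sensitivity clinical-trial assay, `lod_lt = 20000` for a
#' high-sensitivity one), mapped through a treatment rule.
#'
#' @param scores Long score tibble.
#' @param labs Laboratory tibble.
#' @param rule A [treatment_rule()].
#' @param readout Optional readout filter.
#' @param ish Optional ISH table for reflex routing of 2+ scores.
#' @param ... Selection criterion passed to [select_labs()] (`lod_gt`,
#'   `lod_lt`, `lod_min`, `lod_max`, `assay`).
#' @return Tibble with `core_id`, `gold_consensus`, `gold_treat`.
#' @export
#' @examples
#' study <- sim_study(seed = 1)
#' tdxd_gold_standard(study$scores, study$labs, lod_gt = 40000,
#'                    readout = "image_analysis")
tdxd_gold_standard <- function(scores, labs,
                               rule = treatment_rule("t_dxd"),
                               readout = NULL, ish = NULL, ...) {
  subset <- select_labs(labs, ...)
  cons <- consensus_scores(scores, lab_ids = subset$lab_id,
                           include_ultralow = rule$include_ultralow,
                           readout = readout)
  ish_status <- if (is.null(ish)) {
    NULL
  } else {
    status <- classify_ish(ish$ish_ratio)
    status[match(cons$core_id, ish$core_id)]
  }
  tibble::tibble(
    core_id = cons$core_id,
    gold_consensus = cons$consensus,
    gold_treat = apply_treatment_rule(rule, cons$consensus, ish_status)
  )
}

#' Per-laboratory diagnostic accuracy profile
#'
#' Maps every laboratory's individual core scores through the treatment rule,
#' compares the calls with a gold-standard treat/no-treat table, and reports
#' each laboratory's confusion counts and accuracy
#' `(tn + tp)/(tn + fp + fn + tp)`, ordered by LOD. Labs with no scored cores
#' are excluded with a warning.
#'
#' @param scores Long score tibble.
#' @param labs Laboratory tibble with `lab_id`, `lod`.
#' @param gold Gold-standard tibble from [tdxd_gold_standard()] (columns
#'   `core_id`, `gold_treat`).
#' @param rule A [treatment_rule()].
#' @param readout Optional readout filter.
#' @param ish Optional ISH table for reflex routing.
#' @return Tibble with `lab_id`, `lod`, `tp`, `fp`, `tn`, `fn`, `n_cores`,
#'   `accuracy`, ordered by `lod`.
#' @export
#' @examples
#' study <- sim_study(seed = 1)
#' gold <- tdxd_gold_standard(study$scores, study$labs, lod_gt = 40000,
#'                            readout = "image_analysis")
#' lab_accuracy_profile(study$scores, study$labs, gold,
#'                      readout = "image_analysis")
lab_accuracy_profile <- function(scores, labs, gold,
                                 rule = treatment_rule("t_dxd"),
                                 readout = NULL, ish = NULL) {
  stopifnot(all(c("core_id", "gold_treat") %in% names(gold)))
  if (!is.null(readout)) {
    scores <- scores[scores$readout == readout, , drop = FALSE]
  }
  check_scores(scores$score)
  dat <- dplyr::inner_join(scores, gold[, c("core_id", "gold_treat")],
                           by = "core_id")
  ish_status <- if (is.null(ish)) {
    NULL
  } else {
    classify_ish(ish$ish_ratio)[match(dat$core_id, ish$core_id)]
  }
  dat$call <- apply_treatment_rule(rule, dat$score, ish_status)
  prof <- dat |>
    dplyr::group_by(.data$lab_id) |>
    dplyr::summarise(
      tp = sum(.data$call & .data$gold_treat),
      fp = sum(.data$call & !.data$gold_treat),
      tn = sum(!.data$call & !.data$gold_treat),
      fn = sum(!.data$call & .data$gold_treat),
      n_cores = dplyr::n(),
      .groups = "drop"
    )
  prof$accuracy <- (prof$tp + prof$tn) / prof$n_cores
  missing <- setdiff(labs$lab_id, prof$lab_id)
  if (length(missing) > 0) {
    warn(paste0("labs with no scored cores excluded: ",
                paste(missing, collapse = ", ")))
  }
  prof <- dplyr::inner_join(labs[, c("lab_id", "lod")], prof, by = "lab_id")
  dplyr::arrange(prof, .data$lod)
}
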