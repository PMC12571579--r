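#' Round a mean score to the nearest HER2 score
#'
#' Rounds a continuous per-core average to the nearest element of the active
#' score set: `{0, 0.5, 1, 2, 3}` when the ultralow category is included,
#' `{0, 1, 2, 3}` otherwise. An average of 1.7 rounds to 2+; an average of
#' 0.7 rounds down to 0.5 when ultralow is included and up to 1+ when it is
#' not. Exact midpoints (e.g. 0.75 between 0.5 and 1, or 1.5 between 1 and 2)
#' round down to the lower score, the conservative resolution consistent with
#' the worked 0.7 -> 0.5 example.
#'
#' @param x Numeric vector of mean scores in `[0, 3]`.
#' @param include_ultralow Logical; is 0.5 a rounding target?
#' @return Numeric vector of valid score levels.
#' @export
#' @examples
#' round_score(1.7)                            # 2
#' round_score(0.7, include_ultralow = TRUE)   # 0.5
#' round_score(0.7, include_ultralow = FALSE)  # 1
round_score <- function(x, include_ultralow = TRUE) {
  stopifnot(is.numeric(x))
  if (any(!is.na(x) & (x < 0 | x > 3))) {
    abort("mean scores must lie in [0, 3]", class = "ihcsens_bad_score")
  }
  levels <- score_levels(include_ultralow)
  vapply(x, function(m) {
    if (is.na(m)) return(NA_real_)
    d <- abs(levels - m)
    # ties resolve to the lower level: levels are ascending and which.min
    # picks the first minimum
    levels[which.min(d)]
  }, numeric(1))
}

check_scores <- function(score) {
  bad <- !is.na(score) & !score %in% SCORE_LEVELS_UL
  if (any(bad)) {
    abort(paste0("invalid HER2 scores: ",
                 paste(unique(score[bad]), collapse = ", "),
                 " (valid: 0, 0.5, 1, 2, 3)"),
          class = "ihcsens_bad_score")
  }
  invisible(score)
}

#' Select laboratories by LOD or assay criterion
#'
#' Filters a laboratory table by a closed LOD interval (`lod_min`/`lod_max`,
#' both inclusive), a strict one-sided bound (`lod_gt`/`lod_lt`, matching the
#' printed ">40,000" / "<20,000" gold-standard definitions), and/or an assay
#' name.
#'
#' @param labs Tibble with columns `lab_id`, `lod` and optionally `assay`.
#' @param lod_min,lod_max Closed interval bounds on LOD (inclusive).
#' @param lod_gt,lod_lt Strict one-sided bounds on LOD.
#' @param assay Exact assay label to keep.
#' @return The filtered tibble; errors if no laboratory matches.
#' @export
#' @examples
#' labs <- sim_lab_cohort(seed = 1)
#' select_labs(labs, lod_min = 30000, lod_max = 60000)
select_labs <- function(labs, lod_min = NULL, lod_max = NULL,
                        lod_gt = NULL, lod_lt = NULL, assay = NULL) {
  stopifnot(all(c("lab_id", "lod") %in% names(labs)))
  keep <- rep(TRUE, nrow(labs))
  if (!is.null(lod_min)) keep <- keep & labs$lod >= lod_min
  if (!is.null(lod_max)) keep <- keep & labs$lod <= lod_max
  if (!is.null(lod_gt)) keep <- keep & labs$lod > lod_gt
  if (!is.null(lod_lt)) keep <- keep & labs$lod < lod_lt
  if (!is.null(assay)) keep <- keep & labs$assay == assay
  out <- labs[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no labs match criterion", class = "ihcsens_empty_selection")
  }
  out
}

#' Per-core consensus HER2 scores
#'
#' The consensus for each TMA core is the average score over the selected
#' laboratories, rounded to the nearest HER2 score via [round_score()].
#' Ultralow (0.5) inputs always contribute 0.5 to the mean; `include_ultralow`
#' only controls whether 0.5 is a rounding target. Cores with no score in the
#' subset are excluded with a warning.
#'
#' @param scores Long score tibble with columns `core_id`, `lab_id`, `score`
#'   (and optionally `readout`).
#' @param lab_ids Optional character vector restricting to a lab subset
#'   (e.g. `select_labs(...)$lab_id`); default all labs present.
#' @param include_ultralow Logical; see [round_score()].
#' @param readout Optional readout filter (`"manual"` or `"image_analysis"`)
#'   applied when the score table carries a `readout` column.
#' @return Tibble with columns `core_id`, `n_labs`, `mean_score`,
#'   `consensus`.
#' @export
#' @examples
#' study <- sim_study(seed = 1)
#' consensus_scores(study$scores, readout = "image_analysis")
consensus_scores <- function(scores, lab_ids = NULL, include_ultralow = TRUE,
                             readout = NULL) {
  stopifnot(all(c("core_id", "lab_id", "score") %in% names(scores)))
  check_scores(scores$score)
  if (!is.null(readout)) {
    if (!"readout" %in% names(scores)) {
      abort("scores has no readout column to filter on")
    }
    scores <- scores[scores$readout == readout, , drop = FALSE]
  }
  if (!is.null(lab_ids)) {
    scores <- scores[scores$lab_id %in% lab_ids, , drop = FALSE]
    if (nrow(scores) == 0) {
      abort("no labs match criterion", class = "ihcsens_empty_selection")
    }
  }
  out <- scores |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$core_id) |>
    dplyr::summarise(n_labs = dplyr::n(),
                     mean_score = mean(.data$score), .groups = "drop") |>
    dplyr::mutate(consensus = round_score(.data$mean_score,
                                          include_ultralow = include_ultralow))
  out
}

#' Aggregate average TMA score
#'
#' The study-level average for one group of laboratories: per-core consensus
#' first (average over labs, rounded to the nearest HER2 score), then the
#' arithmetic mean of the rounded consensus scores over all cores. Missing
#' cores are excluded rather than imputed.
#'
#' @inheritParams consensus_scores
#' @return A single numeric aggregate score.
#' @export
#' @examples
#' study <- sim_study(seed = 1)
#' average_tma_score(study$scores, readout = "image_analysis")
average_tma_score <- function(scores, lab_ids = NULL, include_ultralow = TRUE,
                              readout = NULL) {
  cons <- consensus_scores(scores, lab_ids = lab_ids,
                           include_ultralow = include_ultralow,
                           readout = readout)
  mean(cons$consensus)
}
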