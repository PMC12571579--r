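#' Read and write calibrator images
#'
#' 8-bit RGB PNG (via the png package) or TIFF (via the tiff package, if
#' installed) chosen by file extension. Images are numeric arrays
#' `height x width x 3` in `[0, 1]`; 16-bit inputs are rescaled to this range
#' on read with a note.
#'
#' @param image Numeric array `height x width x 3` in `[0, 1]`.
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `write_image` returns `path` invisibly; `read_image` the array.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("the tiff package is required to write TIFF images")
    }
    tiff::writeTIFF(image, where = path, bits.per.sample = 8L)
  } else {
    abort(paste0("unsupported image extension: ", ext),
          class = "ihcsens_config_error")
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image file not found: ", path),
          class = "ihcsens_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("the tiff package is required to read TIFF images")
    }
    tiff::readTIFF(path)
  } else {
    abort(paste0("unsupported image extension: ", ext),
          class = "ihcsens_config_error")
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 4) {
    img <- img[, , 1:3]  # drop alpha
  }
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    abort("expected a 3-channel RGB image", class = "ihcsens_bad_image")
  }
  img
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run into one serialisable list
#' that is echoed verbatim (with a content hash and version stamp) into the
#' run report.
#'
#' @param seed Root seed; all stage randomness derives from it.
#' @param out_dir Output directory for the report bundle.
#' @param stages Stages to execute, in pipeline order, from `"simulate"`,
#'   `"lod"`, `"consensus"`, `"dynrange"`, `"accuracy"`.
#' @param cohort_spec Laboratory cohort specification (see
#'   [sim_lab_cohort()]).
#' @param cores_per_category TMA cores per HER2 category.
#' @param write_images Render calibrator images to disk during `simulate`?
#'   (They are always rendered in memory when the `lod` stage runs.)
#' @param bead_noise_sd Per-bead intensity noise for simulated calibrators.
#' @param curve_slope,neg_mean,plateau_conc Calibrator curve parameters.
#' @param radius_range Allowable bead radius range (pixels) for detection.
#' @param plateau_frac Plateau rule fraction for LOD estimation.
#' @param consensus_lod_min,consensus_lod_max Closed LOD interval selecting
#'   the consensus group (defaults 30,000-60,000).
#' @param include_ultralow Use the ultralow rounding set throughout.
#' @param centers,halfwidth Dynamic-range LOD bins.
#' @param dynrange_lod_max Optional domain restriction for the slope fits.
#' @param gold_lod_gt,gold_lod_lt Gold-standard LOD criterion for the
#'   accuracy stage (exactly one should be set; default `gold_lod_gt =
#'   40000`).
#' @param rule_context Treatment rule context for the accuracy stage.
#' @param alpha Significance level for confidence intervals.
#' @param scores_path,ish_path,labs_path Optional CSV inputs used instead of
#'   simulation when the `simulate` stage is not run.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("ihcsens_run_"),
                            stages = c("simulate", "lod", "consensus",
                                       "dynrange", "accuracy"),
                            cohort_spec = default_lab_cohort_spec(),
                            cores_per_category = 20L, write_images = FALSE,
                            bead_noise_sd = 0.02, curve_slope = 0.22,
                            neg_mean = 0.15, plateau_conc = 6e5,
                            radius_range = c(4, 9), plateau_frac = 0.05,
                            consensus_lod_min = 30000,
                            consensus_lod_max = 60000,
                            include_ultralow = TRUE, centers = NULL,
                            halfwidth = 5000, dynrange_lod_max = NULL,
                            gold_lod_gt = 40000, gold_lod_lt = NULL,
                            rule_context = "t_dxd", alpha = 0.05,
                            scores_path = NULL, ish_path = NULL,
                            labs_path = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
         cohort_spec = cohort_spec, cores_per_category = cores_per_category,
         write_images = write_images, bead_noise_sd = bead_noise_sd,
         curve_slope = curve_slope, neg_mean = neg_mean,
         plateau_conc = plateau_conc, radius_range = radius_range,
         plateau_frac = plateau_frac,
         consensus_lod_min = consensus_lod_min,
         consensus_lod_max = consensus_lod_max,
         include_ultralow = include_ultralow, centers = centers,
         halfwidth = halfwidth, dynrange_lod_max = dynrange_lod_max,
         gold_lod_gt = gold_lod_gt, gold_lod_lt = gold_lod_lt,
         rule_context = rule_context, alpha = alpha,
         scores_path = scores_path, ish_path = ish_path,
         labs_path = labs_path,
         version = as.character(utils::packageVersion("ihcsens"))),
    class = "run_config"
  )
}

write_csv_plain <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages (simulate, bead quantification + LOD,
#' consensus, dynamic range, diagnostic accuracy) in order and writes a
#' report bundle of CSV tables plus a `report.json` echoing the configuration
#' with its hash and per-stage counts. Identical configuration and seed give
#' bit-identical CSV/JSON outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 1, stages = c("simulate", "consensus"))
#' res <- run_pipeline(cfg)
#' names(res$files)
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log <- list()
  seed <- config$seed

  # ---- inputs: simulate or load --------------------------------------------
  if ("simulate" %in% config$stages) {
    study <- sim_study(seed = seed, cohort_spec = config$cohort_spec,
                       cores_per_category = config$cores_per_category)
    labs <- study$labs
    scores <- study$scores
    ish <- study$ish
    files["labs"] <- write_csv_plain(labs, file.path(config$out_dir, "labs.csv"))
    files["cores"] <- write_csv_plain(study$cores,
                                      file.path(config$out_dir, "cores.csv"))
    files["scores"] <- write_csv_plain(scores,
                                       file.path(config$out_dir, "scores.csv"))
    files["ish"] <- write_csv_plain(ish, file.path(config$out_dir, "ish.csv"))
    log$simulate <- list(n_labs = nrow(labs), n_cores = nrow(study$cores),
                         n_scores = nrow(scores))
  } else {
    if (is.null(config$scores_path) || is.null(config$labs_path)) {
      abort("scores_path and labs_path are required when simulate is not run",
            class = "ihcsens_config_error")
    }
    labs <- tibble::as_tibble(read.csv(config$labs_path))
    scores <- tibble::as_tibble(read.csv(config$scores_path))
    ish <- if (!is.null(config$ish_path)) {
      tibble::as_tibble(read.csv(config$ish_path))
    } else {
      NULL
    }
    study <- NULL
  }

  # ---- lod: calibrator rendering + bead quantification ---------------------
  if ("lod" %in% config$stages) {
    lod_rows <- purrr::map_dfr(seq_len(nrow(labs)), function(i) {
      curve <- calibrator_curve(labs$lod[i], slope = config$curve_slope,
                                neg_mean = config$neg_mean,
                                noise_sd = config$bead_noise_sd,
                                plateau_conc = config$plateau_conc)
      lab_seed <- derive_seed(seed, paste0("calibrator_", labs$lab_id[i]))
      slides <- lapply(1:2, function(rep) {
        sim_calibrator_slide(curve, seed = derive_seed(lab_seed,
                                                       paste0("rep", rep)))
      })
      if (isTRUE(config$write_images)) {
        img_dir <- file.path(config$out_dir, "calibrators")
        dir.create(img_dir, showWarnings = FALSE)
        for (rep in 1:2) {
          write_image(slides[[rep]]$image,
                      file.path(img_dir, sprintf("%s_rep%d.png",
                                                 labs$lab_id[i], rep)))
        }
        write_csv_plain(slides[[1]]$spots,
                        file.path(img_dir, sprintf("%s_spots.csv",
                                                   labs$lab_id[i])))
      }
      est <- estimate_lod_from_images(lapply(slides, `[[`, "image"),
                                      slides[[1]]$spots,
                                      radius_range = config$radius_range)
      dplyr::bind_cols(tibble::tibble(lab_id = labs$lab_id[i],
                                      true_lod = labs$lod[i]),
                       tidy(est))
    })
    files["lod"] <- write_csv_plain(lod_rows,
                                    file.path(config$out_dir,
                                              "lod_estimates.csv"))
    log$lod <- list(n_labs = nrow(lod_rows),
                    n_extrapolated = sum(lod_rows$extrapolated_below_lowest))
    # downstream stages use the measured LODs when available
    labs <- dplyr::left_join(labs,
                             lod_rows[, c("lab_id", "lod")] |>
                               dplyr::rename(lod_measured = "lod"),
                             by = "lab_id")
    labs$lod <- labs$lod_measured
    labs$lod_measured <- NULL
  }

  results <- list(labs = labs, scores = scores, ish = ish, study = study)

  # ---- consensus -----------------------------------------------------------
  if ("consensus" %in% config$stages) {
    group <- select_labs(labs, lod_min = config$consensus_lod_min,
                         lod_max = config$consensus_lod_max)
    readout <- if ("readout" %in% names(scores)) "manual" else NULL
    cons <- consensus_scores(scores, lab_ids = group$lab_id,
                             include_ultralow = config$include_ultralow,
                             readout = readout)
    files["consensus"] <- write_csv_plain(cons,
                                          file.path(config$out_dir,
                                                    "consensus.csv"))
    log$consensus <- list(n_labs = nrow(group), n_cores = nrow(cons))
    results$consensus <- cons
  }

  # ---- dynamic range -------------------------------------------------------
  if ("dynrange" %in% config$stages) {
    readouts <- if ("readout" %in% names(scores)) {
      unique(scores$readout)
    } else {
      NA_character_
    }
    dr <- purrr::map_dfr(readouts, function(ro) {
      fit <- dynamic_range_slope(
        scores, labs, readout = if (is.na(ro)) NULL else ro,
        include_ultralow = config$include_ultralow,
        centers = config$centers, halfwidth = config$halfwidth,
        lod_max = config$dynrange_lod_max)
      tidy(fit)
    })
    files["dynrange"] <- write_csv_plain(dr, file.path(config$out_dir,
                                                       "dynrange.csv"))
    log$dynrange <- list(n_fits = nrow(dr))
    results$dynrange <- dr
  }

  # ---- diagnostic accuracy -------------------------------------------------
  if ("accuracy" %in% config$stages) {
    if (is.null(ish)) {
      abort("accuracy stage requested but no ISH table is available",
            class = "ihcsens_config_error")
    }
    readout <- if ("readout" %in% names(scores)) "image_analysis" else NULL
    cons <- consensus_scores(scores, include_ultralow = TRUE,
                             readout = if (is.null(readout)) NULL else "manual")
    conf <- trastuzumab_confusion(cons, ish)
    metrics <- diagnostic_metrics(conf, alpha = config$alpha)
    files["metrics"] <- write_csv_plain(metrics,
                                        file.path(config$out_dir,
                                                  "metrics.csv"))
    rule <- treatment_rule(config$rule_context,
                           include_ultralow = config$include_ultralow)
    gold_args <- list(scores = scores, labs = labs, rule = rule,
                      readout = readout)
    if (!is.null(config$gold_lod_lt)) {
      gold_args$lod_lt <- config$gold_lod_lt
    } else {
      gold_args$lod_gt <- config$gold_lod_gt
    }
    gold <- do.call(tdxd_gold_standard, gold_args)
    prof <- lab_accuracy_profile(scores, labs, gold, rule = rule,
                                 readout = readout)
    files["accuracy_profile"] <- write_csv_plain(
      prof, file.path(config$out_dir, "accuracy_profile.csv"))
    log$accuracy <- list(n_labs = nrow(prof),
                         n_evaluable = conf$n)
    results$metrics <- metrics
    results$accuracy_profile <- prof
  }

  # ---- report --------------------------------------------------------------
  cfg_plain <- unclass(config)
  cfg_plain$cohort_spec <- as.data.frame(config$cohort_spec)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null")
  report <- list(config = cfg_plain,
                 config_hash = config_hash(as.character(cfg_json)),
                 stages = log)
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files["report"] <- report_path

  results$files <- files
  results$report <- report
  invisible(results)
}
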