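# End-to-end orchestration: simulate -> ratiometry/QC -> classify -> RMSD
# -> period -> summaries, with a deterministic JSON run report.

#' Pipeline configuration
#'
#' Bundles the synthetic-data configuration with every analysis threshold
#' the pipeline applies. Defaults are the reference settings: classifier
#' thresholds 0.5/0.33 ratio units with dips spanning more than 2 frames,
#' doubling time 4.8 h (the ATP-mutant strain; 3.6 h for wild type), foci
#' prominence tolerance 4000, RMSD windows of 30 min up to 3 h, and a
#' linear ratio-to-ATP calibration mapping ratio 1.0 to 4 mM.
#'
#' @param synthetic a [synthetic_config()].
#' @param proportions cohort class proportions (see [gen_cohort()]).
#' @param thresholds classifier thresholds, as [default_thresholds()].
#' @param doubling_time hours; stability requires an event-free span of at
#'   least twice this.
#' @param calibration a [calibration_curve()].
#' @param foci_tolerance prominence tolerance for focus detection.
#' @param rmsd_step,rmsd_horizon minutes; `rmsd_horizon` must be a multiple
#'   of `rmsd_step`.
#' @param detect_sd frame-error detection threshold (robust SDs).
#' @param seed master seed for the run.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            proportions = c(stable = 0.65, dip = 0.20,
                                            shallow_dip = 0.05, shift = 0.10,
                                            oscillating = 0),
                            thresholds = default_thresholds(),
                            doubling_time = 4.8,
                            calibration = calibration_curve(),
                            foci_tolerance = 4000,
                            rmsd_step = 30, rmsd_horizon = 180,
                            detect_sd = 5,
                            seed = 1L) {
  stopifnot(inherits(synthetic, "synthetic_config"),
            inherits(calibration, "calibration_curve"))
  check_that(thresholds$shallow < thresholds$deep, "thresholds",
             "shallow threshold must be below deep threshold")
  check_that(thresholds$min_frames >= 1, "thresholds", "min_frames must be >= 1")
  check_that(doubling_time > 0, "doubling_time", "must be positive (hours)")
  check_that(foci_tolerance > 0, "foci_tolerance", "must be positive")
  check_that(rmsd_step > 0 && rmsd_horizon > 0 &&
               abs(rmsd_horizon / rmsd_step - round(rmsd_horizon / rmsd_step)) < 1e-9,
             "rmsd_horizon", "must be a positive multiple of rmsd_step")
  check_that(detect_sd > 0, "detect_sd", "must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

#' The bundled reference configuration
#'
#' The fixed (config, seed) pair behind the packaged reference report
#' (`inst/extdata/reference_report.json`): a 60-cell cohort at the default
#' study conditions, seed 42. `run_pipeline(reference_config())` must
#' reproduce that report byte-for-byte.
#'
#' @return A [pipeline_config()].
#' @export
reference_config <- function() {
  pipeline_config(synthetic = synthetic_config(n_cells = 60), seed = 42L)
}

#' Canonical JSON serialization of a pipeline config (for hashing)
#' @noRd
config_json <- function(config) {
  strip <- function(x) {
    if (is.function(x)) return("<function>")
    if (is.list(x)) {
      out <- lapply(x, strip)
      attributes(out) <- list(names = names(x))
      return(out)
    }
    x
  }
  plain <- strip(unclass(config))
  plain$calibration <- list(model = config$calibration$model,
                            params = as.list(config$calibration$params))
  jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: (1) simulate the cohort; (2) ratiometry -- per-cell ratio from
#' the corrupted channel traces, acquisition-error detection/correction,
#' ATP calibration; (3) ATP-dynamics classification; (4) pre-dip-regression
#' RMSD time courses for dip cells and full-span RMSD for stable cells;
#' (5) period estimation; (6) population summaries. All stage outputs are
#' written under `out_dir` with stable filenames, plus a `report.json`
#' that is byte-reproducible from (config, seed) -- no timestamps.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or NULL to skip writing.
#' @return List of class `run_report` (also serialized to
#'   `out_dir/report.json`): per-stage record counts, correction-rate QC,
#'   classification fractions, population CV summary, RMSD cohort summary,
#'   period summary, package version, config hash and seed.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  # -- stage 1: simulate -----------------------------------------------------
  cohort <- gen_cohort(config$synthetic, seed = config$seed,
                       proportions = config$proportions)
  n <- length(cohort$traces)

  # -- stage 2: ratiometry + QC ---------------------------------------------
  dt <- config$synthetic$frame_interval
  corrected <- lapply(cohort$channels, function(ch) {
    tr <- compute_ratio_trace(ch, frame_interval = dt)
    flagged <- detect_frame_errors(ch, threshold_sd = config$detect_sd)
    tr <- suppressWarnings(correct_frame_errors(tr, flagged))
    ratio_to_atp(tr, config$calibration)
  })
  n_corrected <- sum(vapply(corrected, function(tr) length(tr$corrected_frames),
                            integer(1)))
  correction_rate <- n_corrected / (n * config$synthetic$n_frames)

  # -- stage 3: classification ----------------------------------------------
  cls <- cohort_classify(corrected, thresholds = config$thresholds,
                         doubling_time = config$doubling_time)

  # -- stage 4: RMSD ---------------------------------------------------------
  onset_of <- function(id) {
    ev <- cls$events
    if (is.null(ev)) return(NA_integer_)
    sub <- ev[ev$cell_id == id & ev$recovered &
                ev$depth > config$thresholds$deep, , drop = FALSE]
    if (nrow(sub)) sub$onset[1] else NA_integer_
  }
  rmsd_cells <- lapply(seq_len(n), function(i) {
    id <- cls$cells$cell_id[i]
    lab <- cls$cells$label[i]
    list(agg = cohort$agg[[i]],
         dip_onset = if (identical(lab, "dip")) onset_of(id) else NA_integer_)
  })
  rmsd_rep <- cohort_rmsd_report(rmsd_cells, step = config$rmsd_step,
                                 horizon = config$rmsd_horizon)

  # -- stage 5: periods ------------------------------------------------------
  periods <- cohort_periods(corrected)
  n_periodic <- sum(periods$significant)

  # -- stage 6: summaries ----------------------------------------------------
  pop <- population_summary(corrected)

  report <- structure(list(
    package_version = as.character(getNamespaceVersion("atpflux")),
    seed = config$seed,
    config_hash = fnv1a32(as.character(config_json(config))),
    counts = list(cells = n, frames_per_cell = config$synthetic$n_frames,
                  corrected_frames = n_corrected,
                  dip_cells = rmsd_rep$summary$n_dip,
                  stable_rmsd_cells = rmsd_rep$summary$n_stable,
                  periodic_cells = n_periodic),
    qc = list(correction_rate = correction_rate,
              reference_error_rate = config$synthetic$frame_error_rate),
    fractions = cls$fractions,
    population = pop,
    rmsd = rmsd_rep$summary,
    periods = list(n_significant = n_periodic,
                   median_period_min = if (n_periodic) stats::median(
                     periods$period_min[periods$significant]) else NA_real_)),
    class = "run_report")

  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
    utils::write.csv(traces_to_df(corrected),
                     file.path(out_dir, "traces.csv"), row.names = FALSE)
    utils::write.csv(cls$cells, file.path(out_dir, "labels.csv"), row.names = FALSE)
    if (!is.null(cls$events)) {
      utils::write.csv(cls$events, file.path(out_dir, "events.csv"), row.names = FALSE)
    }
    if (!is.null(rmsd_rep$dip)) {
      utils::write.csv(rmsd_rep$dip, file.path(out_dir, "rmsd_dip.csv"), row.names = FALSE)
    }
    if (!is.null(rmsd_rep$stable)) {
      utils::write.csv(rmsd_rep$stable, file.path(out_dir, "rmsd_stable.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(periods, file.path(out_dir, "periods.csv"), row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }
  attr(report, "details") <- list(classification = cls, rmsd = rmsd_rep,
                                  periods = periods, traces = corrected,
                                  cohort = cohort)
  report
}

#' Serialize a run report to canonical JSON
#'
#' @param report a `run_report`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d cells, seed %s, config %s\n",
              x$counts$cells, format(x$seed), x$config_hash))
  fr <- x$fractions
  cat("  dynamics:", paste(sprintf("%s %.1f%%", fr$label, 100 * fr$fraction),
                           collapse = ", "), "\n")
  cat(sprintf("  corrected frames: %d (rate %.4f vs reference %.4f)\n",
              x$counts$corrected_frames, x$qc$correction_rate,
              x$qc$reference_error_rate))
  if (!is.null(x$rmsd$mean_max_fold) && !is.na(x$rmsd$mean_max_fold)) {
    cat(sprintf("  RMSD: mean max fold %.2f, median %.2f, %.0f%% of dips > 3-fold\n",
                x$rmsd$mean_max_fold, x$rmsd$median_max_fold,
                100 * x$rmsd$frac_fold_gt3))
  }
  invisible(x)
}

#' Summary tables for a completed run
#'
#' Tidy per-panel tables: ATP-dynamics label fractions, population
#' mean/SD/CV of the ratio (and ATP), and the RMSD before/after pairs with
#' the fold distribution -- the analysis-ready inputs for downstream group
#' comparisons (Welch's t, Dunnett), which this package deliberately leaves
#' to standard tools.
#'
#' @param report a [run_pipeline()] result (with attached details).
#' @return List of data.frames: `dynamics`, `population`, `rmsd_pairs`,
#'   `rmsd_folds`.
#' @export
summarize_run <- function(report) {
  stopifnot(inherits(report, "run_report"))
  det <- attr(report, "details")
  check_that(!is.null(det), "report", "must carry run details (from run_pipeline)")
  dip <- det$rmsd$dip
  rmsd_pairs <- if (is.null(dip)) NULL else {
    fold_cols <- grep("^fold_", names(dip), value = TRUE)
    do.call(rbind, lapply(fold_cols, function(fc) {
      data.frame(cell_id = dip$cell_id, window = sub("^fold_", "", fc),
                 rmsd_before = dip$rmsd_before,
                 rmsd_after = dip$rmsd_before * dip[[fc]],
                 fold = dip[[fc]])
    }))
  }
  list(dynamics = report$fractions,
       population = report$population,
       rmsd_pairs = rmsd_pairs,
       rmsd_folds = if (is.null(dip)) NULL else
         dip[, c("cell_id", "rmsd_before", "max_fold")])
}

#' Write an image stack as multi-page 16-bit TIFF files
#'
#' One file per channel (`ex410.tif`, `ex490.tif`, `reporter.tif`; frames as
#' pages) plus the integer label mask (`mask.tif`). Intensities are scaled
#' by a common factor to the 16-bit range; the factor is returned for
#' exact inversion.
#'
#' @param stack a [gen_cell_image_stack()] result (or list with the same
#'   channel names).
#' @param dir output directory.
#' @return Invisibly, list with `paths` and `scale`.
#' @export
write_image_stack <- function(stack, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  chans <- intersect(c("ex410", "ex490", "reporter"), names(stack))
  hi <- max(vapply(chans, function(ch) max(unlist(stack[[ch]])), numeric(1)))
  scale <- (2^16 - 1) / hi
  paths <- character(0)
  for (ch in chans) {
    p <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(lapply(stack[[ch]], function(m) pmax(m, 0) * scale / (2^16 - 1)),
                    p, bits.per.sample = 16)
    paths[ch] <- p
  }
  p <- file.path(dir, "mask.tif")
  tiff::writeTIFF(stack$mask / max(1L, max(stack$mask)), p, bits.per.sample = 16)
  paths["mask"] <- p
  invisible(list(paths = paths, scale = scale))
}

#' Read ratio traces from a tidy CSV (the pipeline's trace schema)
#'
#' @param path CSV with columns cell_id, frame, time_min, ratio (optional
#'   atp_mM, corrected).
#' @return List of [ratio_trace()] objects.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("cell_id", "frame", "time_min", "ratio") %in% names(df)),
             "path", "missing required columns (cell_id, frame, time_min, ratio)")
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$frame), ]
    dt <- if (nrow(d) > 1) d$time_min[2] - d$time_min[1] else 1
    ratio_trace(d$ratio, dt, cell_id = d$cell_id[1],
                atp = if ("atp_mM" %in% names(d) && !all(is.na(d$atp_mM))) d$atp_mM else NULL,
                corrected_frames = if ("corrected" %in% names(d)) which(d$corrected) else integer(0))
  })
}
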