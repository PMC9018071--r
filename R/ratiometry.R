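# Ratiometric quantification of the QUEEN ATP biosensor.
#
# The sensor is excited at 410 nm and 490 nm; the per-cell ratio of the two
# mean fluorescence intensities is proportional to intracellular ATP. These
# functions turn raw stacks (or pre-extracted channel traces) into QC'd,
# optionally calibrated, per-cell ATP time series.

#' Construct a per-cell QUEEN ratio trace
#'
#' @param ratio numeric vector of per-frame QUEEN ratios.
#' @param frame_interval frame spacing in minutes.
#' @param cell_id identifier for the cell.
#' @param atp optional per-frame ATP in mM (filled by [ratio_to_atp()]).
#' @param corrected_frames integer indices of frames replaced by the
#'   acquisition-error correction.
#' @return An object of class `ratio_trace`: a list with elements
#'   `cell_id`, `time` (minutes, 0-based uniform grid), `ratio`, `atp`,
#'   `corrected_frames`, `frame_interval`.
#' @export
ratio_trace <- function(ratio, frame_interval, cell_id = "cell_1",
                        atp = NULL, corrected_frames = integer(0)) {
  check_that(is.numeric(ratio) && length(ratio) >= 1, "ratio", "must be a nonempty numeric vector")
  check_that(all(is.finite(ratio)), "ratio", "must be finite at every frame")
  check_that(is.numeric(frame_interval) && length(frame_interval) == 1 && frame_interval > 0,
             "frame_interval", "must be a single positive number (minutes)")
  check_that(all(corrected_frames >= 1 & corrected_frames <= length(ratio)),
             "corrected_frames", "indices must lie within the trace")
  structure(
    list(cell_id = cell_id,
         time = (seq_along(ratio) - 1) * frame_interval,
         ratio = as.numeric(ratio),
         atp = atp,
         corrected_frames = as.integer(sort(unique(corrected_frames))),
         frame_interval = frame_interval),
    class = "ratio_trace")
}

#' @export
print.ratio_trace <- function(x, ...) {
  cat(sprintf("<ratio_trace> cell %s: %d frames x %g min (span %g min)\n",
              x$cell_id, length(x$ratio), x$frame_interval,
              x$time[length(x$time)]))
  cat(sprintf("  ratio mean %.3f, range [%.3f, %.3f], %d corrected frame(s)\n",
              mean(x$ratio), min(x$ratio), max(x$ratio),
              length(x$corrected_frames)))
  invisible(x)
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a stack of optical sections to a single image by the pixelwise
#' maximum, the standard reduction for punctate reporters imaged as z-series
#' (e.g. 11 sections spaced 0.5 um).
#'
#' @param zstack a list of numeric matrices of identical dimension, or a
#'   3-d array with the z index last.
#' @return A numeric matrix.
#' @export
max_project <- function(zstack) {
  if (is.array(zstack) && length(dim(zstack)) == 3) {
    zstack <- lapply(seq_len(dim(zstack)[3]), function(k) zstack[, , k])
  }
  check_that(is.list(zstack) && length(zstack) >= 1, "zstack", "needs at least one z-slice")
  d <- dim(zstack[[1]])
  check_that(all(vapply(zstack, function(m) identical(dim(m), d), logical(1))),
             "zstack", "all slices must share the same shape")
  Reduce(pmax, zstack)
}

#' Per-cell mean-intensity traces for the two excitation channels
#'
#' @param stack a list with matrices-per-frame for each channel:
#'   `list(ex410 = list(...), ex490 = list(...))`.
#' @param label_mask integer matrix; pixels of cell `i` carry value `i`,
#'   background 0.
#' @param cell_id integer label to extract.
#' @return An object of class `channel_traces`: list with `cell_id`,
#'   `ex410`, `ex490` (per-frame mean intensities).
#' @export
extract_cell_trace <- function(stack, label_mask, cell_id) {
  check_that(all(c("ex410", "ex490") %in% names(stack)), "stack",
             "must have channels `ex410` and `ex490`")
  sel <- label_mask == cell_id
  check_that(any(sel), "cell_id",
             sprintf("label %s has no pixels in the mask", format(cell_id)))
  mean_under <- function(frames) vapply(frames, function(im) {
    check_that(identical(dim(im), dim(label_mask)), "label_mask",
               "mask shape must match the image frames")
    mean(im[sel])
  }, numeric(1))
  structure(list(cell_id = cell_id,
                 ex410 = mean_under(stack$ex410),
                 ex490 = mean_under(stack$ex490)),
            class = "channel_traces")
}

#' Per-frame QUEEN ratio from channel traces
#'
#' The ratio is `ex410 / ex490` by default so that it increases with ATP
#' (the 410-nm excitation band of this sensor family is the ATP-sensitive
#' one); set `numerator = "ex490"` for the opposite convention.
#'
#' @param channels a `channel_traces` object (or list with `ex410`, `ex490`).
#' @param frame_interval minutes between frames.
#' @param numerator which channel is the numerator, `"ex410"` (default) or
#'   `"ex490"`.
#' @return A [ratio_trace()].
#' @export
compute_ratio_trace <- function(channels, frame_interval = 4,
                                numerator = c("ex410", "ex490")) {
  numerator <- match.arg(numerator)
  num <- channels[[numerator]]
  den <- channels[[setdiff(c("ex410", "ex490"), numerator)]]
  check_that(length(num) == length(den), "channels", "channel traces must have equal length")
  check_that(all(is.finite(num)) && all(is.finite(den)), "channels", "intensities must be finite")
  check_that(all(den > 0), "channels",
             sprintf("denominator channel has non-positive frames at %s",
                     paste(which(den <= 0), collapse = ", ")))
  ratio_trace(num / den, frame_interval,
              cell_id = if (!is.null(channels$cell_id)) channels$cell_id else "cell_1")
}

#' Detect single-channel acquisition errors
#'
#' During long time-lapse runs a frame is occasionally acquired with a wrong
#' exposure, leaving exactly one of the two excitation channels anomalously
#' intense in that frame. Such frames are flagged when one channel (and only
#' one) rises above its centred running median by more than `threshold_sd`
#' robust standard deviations (MAD * 1.4826 of the median-subtracted
#' residuals). The test is one-sided on purpose: acquisition errors are
#' over-exposures, while a genuine ATP dip lowers the ATP-sensitive channel
#' and must never be "corrected" away. Frames where both channels spike
#' together are left alone: they cancel in the ratio.
#'
#' @param channels a `channel_traces` object.
#' @param threshold_sd flag threshold in robust SDs (default 5).
#' @param window centred running-median window (frames, odd).
#' @return Integer vector of flagged frame indices (possibly empty).
#' @export
detect_frame_errors <- function(channels, threshold_sd = 5, window = 7) {
  n <- length(channels$ex410)
  check_that(n >= 5, "channels", "need at least 5 frames for baseline statistics")
  flag_channel <- function(x) {
    k <- min(window, 2 * floor((n - 1) / 2) + 1)
    med <- stats::runmed(x, k, endrule = "median")
    # runmed's shrinking end windows are blind to adjacent spikes in the
    # first/last frames; anchor a full-width window at each edge instead
    half <- k %/% 2
    for (j in seq_len(min(half, n))) {
      med[j] <- stats::median(x[seq_len(min(k, n))])
      med[n - j + 1L] <- stats::median(x[seq.int(max(1L, n - k + 1L), n)])
    }
    resid <- x - med
    s <- stats::mad(resid, center = 0)
    if (!is.finite(s) || s == 0) return(rep(FALSE, n))
    resid / s > threshold_sd
  }
  f410 <- flag_channel(channels$ex410)
  f490 <- flag_channel(channels$ex490)
  which(xor(f410, f490))
}

#' Correct flagged acquisition-error frames on a ratio trace
#'
#' Each flagged frame's ratio is replaced by the mean of its nearest
#' non-flagged neighbours on either side -- for an isolated interior frame
#' this is exactly the average of the previous and next frames. Edge frames
#' take the single nearest valid neighbour; runs of adjacent flagged frames
#' are corrected against the run's valid flanks with a warning.
#'
#' @param trace a [ratio_trace()].
#' @param flagged integer frame indices from [detect_frame_errors()].
#' @return The corrected `ratio_trace`, with `corrected_frames` updated.
#' @export
correct_frame_errors <- function(trace, flagged) {
  stopifnot(inherits(trace, "ratio_trace"))
  flagged <- sort(unique(as.integer(flagged)))
  n <- length(trace$ratio)
  if (length(flagged) == 0) return(trace)
  check_that(all(flagged >= 1 & flagged <= n), "flagged", "indices outside the trace")
  if (any(diff(flagged) == 1)) {
    warning("adjacent flagged frames corrected against the run's valid flanks")
  }
  valid <- setdiff(seq_len(n), flagged)
  check_that(length(valid) > 0, "flagged", "cannot flag every frame")
  x <- trace$ratio
  for (k in flagged) {
    left <- valid[valid < k]
    right <- valid[valid > k]
    nb <- c(if (length(left)) x[max(left)], if (length(right)) x[min(right)])
    x[k] <- mean(nb)
  }
  ratio_trace(x, trace$frame_interval, cell_id = trace$cell_id,
              corrected_frames = union(trace$corrected_frames, flagged))
}

#' Ratio-to-ATP calibration curves
#'
#' The QUEEN ratio is proportional to ATP over the physiological range, so a
#' linear map is the default; a Hill-type saturation curve is available for
#' users with full sensor titration constants. Calibration constants come
#' from sensor characterization and are user-supplied; the shipped default
#' maps ratio 1.0 to 4 mM, the resting ATP level of wild-type yeast.
#'
#' @param model `"linear"` or `"hill"`.
#' @param slope,intercept linear map `atp = slope * ratio + intercept`
#'   (mM per ratio unit; mM).
#' @param r_min,r_max,k_app,hill_n Hill map: ratio spans (r_min, r_max) as
#'   ATP goes 0 -> saturation, half-saturation at `k_app` mM, coefficient
#'   `hill_n`.
#' @param range valid ratio range (ratios outside are clipped with warning).
#' @return An object of class `calibration_curve` with a `forward`
#'   (ratio -> mM) and `inverse` (mM -> ratio) function.
#' @export
calibration_curve <- function(model = c("linear", "hill"),
                              slope = 4, intercept = 0,
                              r_min = 0.6, r_max = 1.4, k_app = 4, hill_n = 1,
                              range = NULL) {
  model <- match.arg(model)
  if (model == "linear") {
    check_that(slope > 0, "slope", "must be positive for a monotone calibration")
    if (is.null(range)) range <- c(max(0, -intercept / slope) + 1e-9, Inf)
    forward <- function(r) slope * r + intercept
    inverse <- function(a) (a - intercept) / slope
  } else {
    check_that(r_max > r_min, "r_max", "must exceed r_min")
    check_that(k_app > 0 && hill_n > 0, "k_app", "k_app and hill_n must be positive")
    if (is.null(range)) range <- c(r_min + 1e-9, r_max - 1e-9)
    forward <- function(r) k_app * ((r - r_min) / (r_max - r))^(1 / hill_n)
    inverse <- function(a) {
      u <- (a / k_app)^hill_n
      (r_min + r_max * u) / (1 + u)
    }
  }
  cal <- structure(list(model = model, range = range,
                        forward = forward, inverse = inverse,
                        params = if (model == "linear") c(slope = slope, intercept = intercept)
                                 else c(r_min = r_min, r_max = r_max, k_app = k_app, hill_n = hill_n)),
                   class = "calibration_curve")
  # monotonicity checked numerically over the valid range
  hi <- if (is.finite(range[2])) range[2] else range[1] + 10
  grid <- seq(range[1], hi, length.out = 256)
  check_that(all(diff(forward(grid)) > 0), "model",
             "calibration must be strictly increasing over its valid range")
  cal
}

#' Fill the ATP channel of a ratio trace through a calibration curve
#'
#' @param trace a [ratio_trace()].
#' @param calibration a [calibration_curve()].
#' @return The trace with `$atp` filled (mM). Ratios outside the valid
#'   range are clipped to it with a warning.
#' @export
ratio_to_atp <- function(trace, calibration = calibration_curve()) {
  stopifnot(inherits(trace, "ratio_trace"), inherits(calibration, "calibration_curve"))
  r <- trace$ratio
  lo <- calibration$range[1]; hi <- calibration$range[2]
  if (any(r < lo | r > hi)) {
    warning("ratios outside the calibration's valid range were clipped")
    r <- pmin(pmax(r, lo), hi)
  }
  trace$atp <- calibration$forward(r)
  trace
}

#' Population summary of per-cell ATP readouts
#'
#' Mean, SD and coefficient of variance (CV = SD/mean) of per-cell mean
#' ratios (and ATP when present), the summary behind population dot plots.
#'
#' @param traces list of [ratio_trace()] objects, or a numeric vector of
#'   single-timepoint per-cell readouts.
#' @return A data.frame with one row per quantity (`ratio`, and `atp` when
#'   available): n, mean, sd, cv. A zero mean yields `cv = NA`.
#' @export
population_summary <- function(traces) {
  if (is.numeric(traces)) {
    vals <- list(ratio = traces)
  } else {
    check_that(length(traces) >= 2, "traces", "need at least 2 cells")
    vals <- list(ratio = vapply(traces, function(tr) mean(tr$ratio), numeric(1)))
    if (all(vapply(traces, function(tr) !is.null(tr$atp), logical(1)))) {
      vals$atp <- vapply(traces, function(tr) mean(tr$atp), numeric(1))
    }
  }
  check_that(length(vals$ratio) >= 2, "traces", "need at least 2 cells")
  do.call(rbind, lapply(names(vals), function(nm) {
    x <- vals[[nm]]
    m <- mean(x); s <- stats::sd(x)
    data.frame(quantity = nm, n = length(x), mean = m, sd = s,
               cv = if (m == 0) NA_real_ else s / m)
  }))
}

#' Tidy data.frame view of ratio traces
#'
#' @param traces list of [ratio_trace()] objects.
#' @return data.frame with columns cell_id, frame, time_min, ratio, atp_mM,
#'   corrected.
#' @export
traces_to_df <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    n <- length(tr$ratio)
    data.frame(cell_id = tr$cell_id, frame = seq_len(n), time_min = tr$time,
               ratio = tr$ratio,
               atp_mM = if (is.null(tr$atp)) NA_real_ else tr$atp,
               corrected = seq_len(n) %in% tr$corrected_frames)
  }))
}
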