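# Per-cell ATP-dynamics statistics and the dip / shallow-dip / shift /
# stable classifier.
#
# Definitions on the QUEEN-ratio scale: an "ATP dip" is a transient decrease
# of more than `deep` (0.5) ratio units spanning more than `min_frames` (2)
# frames followed by recovery; a decrease in the 0.33-0.5 range with
# recovery is a "shallow dip"; a decrease of more than 0.33 that never
# recovers within the observation period is an "ATP shift"; a cell with no
# qualifying event observed for at least twice its strain's doubling time is
# "stable".

#' Lag differences of a ratio trace
#'
#' Computes `delta(t, l) = ratio[t] - ratio[t - l]` for all valid `t`, the
#' elementary statistic for quantifying temporal fluctuations; its extreme
#' values expose rapid dips irrespective of the lag chosen.
#'
#' @param trace a [ratio_trace()].
#' @param l lag in frames, `1 <= l < T`.
#' @return List of class `lag_diff` with `l`, `diffs` (length `T - l`),
#'   `max_abs` (largest magnitude change) and `max_drop` (largest decrease,
#'   reported as a positive number; 0 if the trace never decreases).
#' @export
lag_diff <- function(trace, l) {
  stopifnot(inherits(trace, "ratio_trace"))
  T_ <- length(trace$ratio)
  check_that(l >= 1 && l < T_, "l", sprintf("lag must satisfy 1 <= l < %d", T_))
  d <- trace$ratio[(l + 1):T_] - trace$ratio[seq_len(T_ - l)]
  structure(list(l = as.integer(l), diffs = d,
                 max_abs = max(abs(d)), max_drop = max(0, -d)),
            class = "lag_diff")
}

#' Extreme lag differences across a set of lags
#'
#' @param trace a [ratio_trace()].
#' @param l_values integer lags.
#' @return data.frame with columns l, max_abs, max_drop, one row per lag;
#'   used to show that detected fluctuation extremes are insensitive to `l`.
#' @export
max_diff_profile <- function(trace, l_values = 1:5) {
  rows <- lapply(l_values, function(l) {
    ld <- lag_diff(trace, l)
    data.frame(l = ld$l, max_abs = ld$max_abs, max_drop = ld$max_drop)
  })
  do.call(rbind, rows)
}

#' Detect transient ATP-depletion events in a ratio trace
#'
#' An event opens when the ratio falls more than `enter_delta` below the
#' local baseline (trailing median over `baseline_window` frames, frozen at
#' entry), extends backwards to the first frame below that baseline, and
#' closes (recovered) at the last frame before the ratio returns above
#' `baseline - exit_frac * depth`. Depth is measured baseline-to-nadir.
#' An event still open at the end of the trace is unrecovered.
#'
#' @param trace a QC'd [ratio_trace()].
#' @param baseline_window trailing frames for the running-median baseline.
#' @param enter_delta ratio drop that opens an event (default 0.25, safely
#'   below the 0.33 shallow-dip threshold and 5 noise SD at the reference
#'   noise level).
#' @param exit_frac recovery margin as a fraction of depth (default 0.1).
#' @return data.frame of class `dip_events` with columns onset, nadir, end,
#'   baseline, depth, duration_frames, duration_min, recovered. Zero rows
#'   when no event is found.
#' @export
detect_dip_events <- function(trace, baseline_window = 5, enter_delta = 0.25,
                              exit_frac = 0.1) {
  stopifnot(inherits(trace, "ratio_trace"))
  check_that(baseline_window >= 3, "baseline_window", "must be at least 3 frames")
  x <- trace$ratio
  n <- length(x)
  check_that(n > baseline_window, "trace",
             sprintf("trace must be longer than baseline_window (%d frames)", baseline_window))
  med <- trailing_median(x, baseline_window)
  events <- list()
  i <- baseline_window + 1L
  while (i <= n) {
    b <- med[i]
    if (!is.na(b) && x[i] < b - enter_delta) {
      # extend the event backwards to where the trace first dropped below baseline
      onset <- i
      while (onset > 1L && x[onset - 1L] < b) onset <- onset - 1L
      # walk forward to recovery: ratio back above baseline - exit_frac * depth,
      # with depth the running baseline-to-nadir drop
      j <- i
      nadir <- i
      repeat {
        if (x[j] < x[nadir]) nadir <- j
        depth <- b - x[nadir]
        if (j > i && x[j] > b - exit_frac * depth) break
        if (j == n) break
        j <- j + 1L
      }
      depth <- b - x[nadir]
      recovered <- x[j] > b - exit_frac * depth && j > nadir
      last <- if (recovered) j - 1L else n
      events[[length(events) + 1L]] <- data.frame(
        onset = as.integer(onset), nadir = as.integer(nadir),
        end = if (recovered) as.integer(last) else NA_integer_,
        baseline = b, depth = depth,
        duration_frames = as.integer(last - onset + 1),
        duration_min = (last - onset + 1) * trace$frame_interval,
        recovered = recovered)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(onset = integer(0), nadir = integer(0), end = integer(0),
               baseline = numeric(0), depth = numeric(0),
               duration_frames = integer(0), duration_min = numeric(0),
               recovered = logical(0))
  class(out) <- c("dip_events", "data.frame")
  out
}

#' Default classifier thresholds (QUEEN-ratio scale)
#'
#' `deep`: depth for an ATP dip (>0.5); `shallow`: lower bound of the
#' shallow-dip range (0.33, also the shift depth threshold); `min_frames`:
#' a dip must span more than this many frames (2, i.e. >= 3 frames).
#' @export
default_thresholds <- function() list(deep = 0.5, shallow = 0.33, min_frames = 2L)

#' Classify a cell's ATP dynamics from its detected events
#'
#' Labels: `"dip"` (>= 1 recovered event deeper than `deep` spanning more
#' than `min_frames` frames), `"shift"` (>= 1 unrecovered event deeper than
#' `shallow`), `"shallow_dip"` (>= 1 recovered event with depth in the
#' shallow range), `"stable"` (no qualifying event and observation span at
#' least twice the doubling time) or `"indeterminate_stable"` (event-free
#' but observed too briefly to call stable). When several event types
#' coexist, dip takes precedence over shift over shallow_dip.
#'
#' @param trace a [ratio_trace()].
#' @param events events from [detect_dip_events()] on the same trace.
#' @param thresholds list as [default_thresholds()].
#' @param doubling_time strain doubling time in hours (3.6 for wild type,
#'   4.8 for the AMPK/ADK double deletion).
#' @return List of class `trace_classification`: `label`, `events`
#'   (qualifying events), `observation_span` (minutes),
#'   `qualifies_for_stable`.
#' @export
classify_trace <- function(trace, events = detect_dip_events(trace),
                           thresholds = default_thresholds(),
                           doubling_time = 3.6) {
  stopifnot(inherits(trace, "ratio_trace"))
  check_that(thresholds$shallow < thresholds$deep, "thresholds",
             "shallow threshold must be below deep threshold")
  span <- trace$time[length(trace$time)] - trace$time[1]
  check_that(is.numeric(doubling_time) && doubling_time > 0,
             "doubling_time", "required to judge stability")
  is_dip <- events$recovered & events$depth > thresholds$deep &
    events$duration_frames > thresholds$min_frames
  is_shift <- !events$recovered & events$depth > thresholds$shallow
  is_shallow <- events$recovered & !is_dip & events$depth >= thresholds$shallow &
    events$depth <= thresholds$deep
  qualifying <- events[is_dip | is_shift | is_shallow, , drop = FALSE]
  long_enough <- span >= 2 * doubling_time * 60
  label <- if (any(is_dip)) "dip"
    else if (any(is_shift)) "shift"
    else if (any(is_shallow)) "shallow_dip"
    else if (long_enough) "stable"
    else "indeterminate_stable"
  structure(list(label = label, events = qualifying, observation_span = span,
                 qualifies_for_stable = long_enough && nrow(qualifying) == 0),
            class = "trace_classification")
}

#' Classify a cohort of traces and tabulate label fractions
#'
#' @param traces list of [ratio_trace()] objects.
#' @param thresholds list as [default_thresholds()].
#' @param doubling_time hours (see [classify_trace()]).
#' @param ... passed to [detect_dip_events()].
#' @return List with `cells` (data.frame cell_id, label, n_events, max_depth),
#'   `events` (all qualifying events with cell_id), and `fractions`
#'   (data.frame label, n, fraction over classifiable cells;
#'   indeterminate_stable cells are excluded from the denominator).
#' @export
cohort_classify <- function(traces, thresholds = default_thresholds(),
                            doubling_time = 3.6, ...) {
  check_that(length(traces) >= 1, "traces", "need at least one trace")
  per_cell <- lapply(traces, function(tr) {
    ev <- detect_dip_events(tr, ...)
    cl <- classify_trace(tr, ev, thresholds, doubling_time)
    list(row = data.frame(cell_id = tr$cell_id, label = cl$label,
                          n_events = nrow(cl$events),
                          max_depth = if (nrow(cl$events)) max(cl$events$depth) else NA_real_),
         events = if (nrow(cl$events))
           cbind(cell_id = tr$cell_id, as.data.frame(cl$events)) else NULL)
  })
  cells <- do.call(rbind, lapply(per_cell, `[[`, "row"))
  events <- do.call(rbind, Filter(Negate(is.null), lapply(per_cell, `[[`, "events")))
  classifiable <- cells$label != "indeterminate_stable"
  lab <- factor(cells$label[classifiable],
                levels = c("stable", "dip", "shallow_dip", "shift"))
  tab <- table(lab)
  fractions <- data.frame(label = names(tab), n = as.integer(tab),
                          fraction = as.numeric(tab) / max(1L, sum(tab)))
  list(cells = cells, events = events, fractions = fractions)
}
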