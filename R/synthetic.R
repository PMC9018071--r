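# Synthetic single-cell data with known ground truth.
#
# The generator emulates the statistical structure of QUEEN time-lapse
# experiments: per-cell ratio traces with a baseline near the 4 mM-equivalent
# ratio, stochastic transient dips (~15 min of depressed ATP), irreversible
# shifts, slow (~35 min) unsynchronized oscillations, rare single-channel
# acquisition errors (~1 frame in 70), and aggregate-reporter traces that
# rise linearly (r ~ 0.99) with an optional post-dip acceleration calibrated
# so the expected maximum RMSD fold change within 3 h matches a target
# (5.6-fold at the reference setting). Every generated object carries its
# ground truth so the whole pipeline can be validated closed-loop.

#' Synthetic-data generator configuration
#'
#' Defaults are the reference study conditions: 4-min frames, baseline ratio
#' 1.0 (4 mM under the default calibration), ratio noise SD 0.05, deep dips
#' 0.55-0.85 ratio units deep lasting ~15 min, ~35-min oscillations,
#' acquisition errors once in 70 frames at 10 channel-SD, aggregate traces
#' with linearity r = 0.99 and a 5.6-fold expected maximum RMSD change
#' within 3 h of a dip.
#'
#' @param n_cells number of cells in a cohort.
#' @param n_frames frames per trace.
#' @param frame_interval minutes between frames.
#' @param baseline_atp resting ATP (mM), documentation of the intended scale.
#' @param baseline_ratio resting QUEEN ratio.
#' @param ratio_noise_sd frame-to-frame Gaussian noise on the ratio.
#' @param dip_rate dip events per hour per cell (used where events are drawn
#'   by rate rather than by class assignment).
#' @param dip_depth_range min/max depth (ratio units) of deep dips.
#' @param dip_duration total dip duration in minutes (onset to last frame
#'   below baseline).
#' @param shift_prob probability that a depletion event never recovers.
#' @param osc_period oscillation period, minutes.
#' @param osc_amplitude oscillation amplitude, ratio units.
#' @param frame_error_rate per-frame probability of a single-channel
#'   acquisition error.
#' @param frame_error_magnitude error spike size, in multiples of the
#'   channel noise SD.
#' @param agg_slope aggregate-reporter accumulation, intensity/min.
#' @param agg_intercept reporter intensity at t = 0.
#' @param agg_corr_target Pearson r of intensity vs time used to set the
#'   reporter noise SD.
#' @param post_dip_fold expected maximum RMSD fold change within
#'   `post_dip_horizon` of a dip.
#' @param post_dip_sdlog lognormal spread of the per-cell acceleration scale.
#' @param post_dip_horizon minutes after onset over which the maximum fold
#'   is taken.
#' @param image_size side of the square synthetic field, pixels.
#' @param cell_radius cell disk radius, pixels.
#' @param focus_amplitude peak intensity of a planted reporter focus.
#' @param psf_sigma Gaussian width of a planted focus, pixels.
#' @param seed default seed used when a generator is called without one.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 200,
                             n_frames = 150,
                             frame_interval = 4,
                             baseline_atp = 4,
                             baseline_ratio = 1.0,
                             ratio_noise_sd = 0.05,
                             dip_rate = 0.1,
                             dip_depth_range = c(0.55, 0.85),
                             dip_duration = 15,
                             shift_prob = 0.1,
                             osc_period = 35,
                             osc_amplitude = 0.15,
                             frame_error_rate = 1 / 70,
                             frame_error_magnitude = 10,
                             agg_slope = 1,
                             agg_intercept = 200,
                             agg_corr_target = 0.99,
                             post_dip_fold = 5.6,
                             post_dip_sdlog = 0.3,
                             post_dip_horizon = 180,
                             image_size = 96,
                             cell_radius = 8,
                             focus_amplitude = 12000,
                             psf_sigma = 1.2,
                             seed = 1L) {
  cfg <- as.list(environment())
  check_that(n_frames >= 3, "n_frames", "must be at least 3")
  check_that(frame_interval > 0, "frame_interval", "must be positive")
  check_that(n_cells >= 1, "n_cells", "must be at least 1")
  check_that(baseline_ratio > 0, "baseline_ratio", "must be positive")
  check_that(ratio_noise_sd >= 0, "ratio_noise_sd", "must be nonnegative")
  check_that(dip_rate > 0, "dip_rate", "must be positive")
  check_that(length(dip_depth_range) == 2 && dip_depth_range[1] >= 0 &&
               dip_depth_range[2] >= dip_depth_range[1],
             "dip_depth_range", "must be an increasing pair with min >= 0")
  check_that(dip_depth_range[2] > 0.5, "dip_depth_range",
             "max must exceed 0.5 to generate deep dips")
  check_that(dip_duration > 0, "dip_duration", "must be positive (minutes)")
  check_that(shift_prob >= 0 && shift_prob <= 1, "shift_prob", "must be in [0, 1]")
  check_that(osc_period > 0 && osc_amplitude >= 0, "osc_period",
             "period must be positive, amplitude nonnegative")
  check_that(frame_error_rate >= 0 && frame_error_rate <= 1, "frame_error_rate",
             "must be in [0, 1]")
  check_that(frame_error_magnitude >= 0, "frame_error_magnitude", "must be >= 0")
  check_that(agg_slope > 0 && agg_corr_target > 0 && agg_corr_target < 1,
             "agg_corr_target", "slope must be > 0 and target correlation in (0, 1)")
  check_that(post_dip_fold >= 1, "post_dip_fold", "must be >= 1")
  check_that(post_dip_horizon > 0, "post_dip_horizon", "must be positive")
  check_that(image_size >= 4 * cell_radius, "image_size",
             "must be at least 4 x cell_radius")
  check_that(psf_sigma > 0 && focus_amplitude > 0, "psf_sigma",
             "focus parameters must be positive")
  structure(cfg, class = "synthetic_config")
}

#' @noRd
dip_total_frames <- function(config) {
  max(1L, as.integer(round(config$dip_duration / config$frame_interval)))
}

#' Inject a depletion event into a baseline vector
#'
#' The drop and the recovery are instantaneous at the sampling resolution
#' (depletion takes "a few minutes", i.e. about one 4-min frame): the event
#' occupies `duration_frames` consecutive frames at `baseline - depth`,
#' spanning from one frame to the next with no intermediate levels, so a
#' lag-1 difference already sees the full depth.
#' @noRd
dip_waveform <- function(x, onset, depth, duration_frames, recover, baseline) {
  n <- length(x)
  E <- as.integer(duration_frames)
  stopifnot(E >= 1, onset >= 1)
  if (recover) {
    check_that(onset + E - 1L < n, "duration_frames", "event must fit inside the trace")
    idx <- onset:(onset + E - 1L)
  } else {
    check_that(onset <= n, "onset", "event must start inside the trace")
    idx <- onset:n
  }
  x[idx] <- x[idx] - depth
  x
}

#' Generate a stable (event-free) ratio trace
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @param cell_id identifier.
#' @return List with `trace` (a [ratio_trace()]) and `truth`
#'   (`label = "stable"`).
#' @export
gen_stable_trace <- function(config, seed = config$seed, cell_id = "cell_1") {
  stopifnot(inherits(config, "synthetic_config"))
  r <- with_seed(seed, config$baseline_ratio +
                   stats::rnorm(config$n_frames, 0, config$ratio_noise_sd))
  list(trace = ratio_trace(r, config$frame_interval, cell_id = cell_id),
       truth = list(label = "stable", events = NULL))
}

#' Generate a ratio trace with one injected depletion event
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @param depth event depth, ratio units (> 0).
#' @param duration_frames frames strictly below baseline (>= 1); defaults to
#'   the config's `dip_duration`.
#' @param recover TRUE for a transient dip, FALSE for a persistent shift.
#' @param onset onset frame; drawn uniformly so the event fits when NULL.
#' @param cell_id identifier.
#' @return List with `trace` and `truth` (label by the definitional
#'   threshold rules, plus the event record: onset, nadir, end, depth,
#'   duration_frames, recovered).
#' @export
gen_dip_trace <- function(config, seed = config$seed, depth,
                          duration_frames = dip_total_frames(config),
                          recover = TRUE, onset = NULL, cell_id = "cell_1") {
  stopifnot(inherits(config, "synthetic_config"))
  check_that(depth > 0, "depth", "must be positive")
  check_that(duration_frames >= 1, "duration_frames", "must be at least 1")
  n <- config$n_frames
  E <- as.integer(duration_frames)
  out <- with_seed(seed, {
    if (is.null(onset)) {
      lo <- 8L
      hi <- if (recover) n - E - 1L else n - E - 1L
      check_that(hi >= lo, "duration_frames",
                 sprintf("event of %d frames does not fit in %d frames", E, n))
      onset <- sample(lo:hi, 1L)
    }
    r <- config$baseline_ratio + stats::rnorm(n, 0, config$ratio_noise_sd)
    list(r = dip_waveform(r, onset, depth, if (recover) E else n - onset + 1L,
                          recover, config$baseline_ratio),
         onset = onset)
  })
  onset <- as.integer(out$onset)
  dur <- as.integer(if (recover) E else n - onset + 1L)
  label <- truth_label(depth, dur, recover)
  truth_event <- data.frame(onset = onset,
                            nadir = onset,
                            end = if (recover) onset + dur - 1L else NA_integer_,
                            depth = depth, duration_frames = dur,
                            recovered = recover)
  list(trace = ratio_trace(out$r, config$frame_interval, cell_id = cell_id),
       truth = list(label = label, events = truth_event))
}

#' Definitional threshold rules applied to injected event parameters
#'
#' The same predicate the classifier implements, evaluated directly on the
#' generator's noiseless parameters; used for truth labels and label
#' consistency checks.
#'
#' @param depth event depth, ratio units.
#' @param duration_frames frames below baseline.
#' @param recover whether the event recovers.
#' @param thresholds as [default_thresholds()].
#' @return One of `"dip"`, `"shift"`, `"shallow_dip"`, `"stable"`.
#' @export
truth_label <- function(depth, duration_frames, recover,
                        thresholds = default_thresholds()) {
  if (recover && depth > thresholds$deep && duration_frames > thresholds$min_frames) "dip"
  else if (!recover && depth > thresholds$shallow) "shift"
  else if (recover && depth >= thresholds$shallow && depth <= thresholds$deep) "shallow_dip"
  else "stable"
}

#' Generate an oscillating ratio trace
#'
#' Baseline plus a sinusoid of the configured period with a uniform random
#' phase (oscillations are unsynchronized across the population), plus noise.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @param cell_id identifier.
#' @return List with `trace` and `truth` (`label = "oscillating"`, `period`
#'   in minutes, `phase`).
#' @export
gen_oscillating_trace <- function(config, seed = config$seed, cell_id = "cell_1") {
  stopifnot(inherits(config, "synthetic_config"))
  check_that(config$osc_period > 2 * config$frame_interval, "osc_period",
             "period must exceed twice the frame interval (Nyquist)")
  t_ <- (seq_len(config$n_frames) - 1) * config$frame_interval
  out <- with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    r <- config$baseline_ratio +
      config$osc_amplitude * sin(2 * pi * t_ / config$osc_period + phase) +
      stats::rnorm(config$n_frames, 0, config$ratio_noise_sd)
    list(r = r, phase = phase)
  })
  list(trace = ratio_trace(out$r, config$frame_interval, cell_id = cell_id),
       truth = list(label = "oscillating", period = config$osc_period,
                    phase = out$phase))
}

#' Inject single-channel acquisition errors into channel traces
#'
#' At each frame independently with probability `rate`, exactly one of the
#' two channels (chosen at random) is made anomalously intense by adding
#' `magnitude` channel noise SDs. The channel SD is estimated robustly from
#' first differences unless supplied.
#'
#' @param channels a `channel_traces` object.
#' @param rate per-frame corruption probability.
#' @param magnitude spike size in channel noise SDs (>= 0).
#' @param seed RNG seed.
#' @param noise_sd optional named numeric `c(ex410 = , ex490 = )` channel
#'   noise SDs; estimated from the data when NULL.
#' @return List with `channels` (corrupted) and `truth` (data.frame frame,
#'   channel).
#' @export
inject_frame_errors <- function(channels, rate, magnitude, seed = 1L,
                                noise_sd = NULL) {
  check_that(rate >= 0 && rate <= 1, "rate", "must be in [0, 1]")
  check_that(magnitude >= 0, "magnitude", "must be >= 0")
  n <- length(channels$ex410)
  sd_of <- function(ch) {
    if (!is.null(noise_sd)) return(unname(noise_sd[ch]))
    stats::mad(diff(channels[[ch]])) / sqrt(2)
  }
  out <- with_seed(seed, {
    hit <- stats::runif(n) < rate
    ch_pick <- ifelse(stats::runif(n) < 0.5, "ex410", "ex490")
    list(hit = which(hit), ch = ch_pick[hit])
  })
  corrupted <- channels
  for (i in seq_along(out$hit)) {
    f <- out$hit[i]; ch <- out$ch[i]
    corrupted[[ch]][f] <- corrupted[[ch]][f] + magnitude * sd_of(ch)
  }
  truth <- data.frame(frame = out$hit, channel = out$ch)
  list(channels = corrupted, truth = truth)
}

#' Calibrate the post-dip acceleration scale for a target max RMSD fold
#'
#' The post-dip model adds a linear ramp `L * A * (t - t_onset)` to the
#' reporter trace, with `L` lognormal (mean 1, sdlog `post_dip_sdlog`).
#' Over the cumulative window ending at the horizon, the expected RMSD fold
#' is `E_L[sqrt(L^2 A^2 c^2 + sigma^2)] / sigma` with `c` the RMS of
#' `(t - t_onset)` over that window; `A` is solved in closed form (uniroot
#' on the exact lognormal expectation) so this equals `post_dip_fold`.
#' @noRd
calibrate_accel <- function(config, sigma) {
  f <- config$post_dip_fold
  if (f <= 1) return(0)
  dt <- config$frame_interval
  k_max <- floor(config$post_dip_horizon / dt)
  check_that(k_max >= 1, "post_dip_horizon", "must contain at least one frame")
  c2 <- mean((dt * seq_len(k_max))^2)
  s <- config$post_dip_sdlog
  Lq <- stats::qlnorm(stats::ppoints(2001), meanlog = -s^2 / 2, sdlog = s)
  expected_fold <- function(A) mean(sqrt(Lq^2 * A^2 * c2 + sigma^2)) / sigma
  upper <- 10 * f * sigma / sqrt(c2)
  stats::uniroot(function(A) expected_fold(A) - f, c(0, upper), tol = 1e-12)$root
}

#' Reporter noise SD implied by the linearity target
#' @noRd
agg_noise_sd <- function(config) {
  t_ <- (seq_len(config$n_frames) - 1) * config$frame_interval
  r <- config$agg_corr_target
  config$agg_slope * stats::sd(t_) * sqrt(1 / r^2 - 1)
}

#' Generate an aggregate-reporter intensity trace
#'
#' Intensity rises linearly with Gaussian noise calibrated so that the
#' full-trace Pearson correlation with time matches `agg_corr_target`.
#' When `dip_onset` is given, a per-cell lognormally scaled linear ramp is
#' added after the onset, calibrated so the expected maximum RMSD fold
#' within `post_dip_horizon` equals `post_dip_fold`.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @param dip_onset onset frame of the paired ATP dip, or NULL.
#' @param cell_id identifier.
#' @return List with `agg` (an [aggregation_trace()]) and `truth` (slope,
#'   intercept, noise_sd, dip_onset, accel, the realized per-cell ramp
#'   slope).
#' @export
gen_aggregation_trace <- function(config, seed = config$seed, dip_onset = NULL,
                                  cell_id = "cell_1") {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(dip_onset)) {
    check_that(dip_onset > 1 && dip_onset < config$n_frames, "dip_onset",
               "must be an interior frame")
  }
  n <- config$n_frames
  t_ <- (seq_len(n) - 1) * config$frame_interval
  sigma <- agg_noise_sd(config)
  out <- with_seed(seed, {
    y <- config$agg_intercept + config$agg_slope * t_ + stats::rnorm(n, 0, sigma)
    accel <- 0
    if (!is.null(dip_onset) && config$post_dip_fold > 1) {
      A <- calibrate_accel(config, sigma)
      s <- config$post_dip_sdlog
      L <- stats::rlnorm(1, meanlog = -s^2 / 2, sdlog = s)
      accel <- A * L
      post <- t_ > t_[dip_onset]
      y[post] <- y[post] + accel * (t_[post] - t_[dip_onset])
    }
    list(y = y, accel = accel)
  })
  list(agg = aggregation_trace(out$y, config$frame_interval, cell_id = cell_id),
       truth = list(slope = config$agg_slope, intercept = config$agg_intercept,
                    noise_sd = sigma,
                    dip_onset = if (is.null(dip_onset)) NA_integer_ else dip_onset,
                    accel = out$accel))
}

#' Generate a synthetic two-channel QUEEN + reporter image stack
#'
#' Cells are rendered as non-overlapping disks. Channel intensities are set
#' so the per-cell mean ratio reproduces each cell's generated ratio trace
#' exactly in the noiseless case (`ex490 = B * g_t`, `ex410 = B * g_t *
#' ratio_t`, with a common per-frame gain `g_t` that cancels in the ratio).
#' The reporter channel renders planted foci as Gaussian spots on a
#' cytoplasmic background. With `noise = TRUE`, pixels get Poisson shot
#' noise plus Gaussian read noise.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @param n_cells_img cells to place in the field.
#' @param n_frames_img frames to render.
#' @param noise add Poisson + Gaussian pixel noise.
#' @param foci_per_cell integer vector (recycled) of planted foci per cell;
#'   drawn as Poisson(1) when NULL.
#' @param traces optional list of [ratio_trace()] objects (one per cell) to
#'   render; stable traces are generated when NULL.
#' @return List with `ex410`, `ex490`, `reporter` (lists of matrices, one
#'   per frame), `mask` (integer label matrix) and `truth` (centers, radius,
#'   per-cell ratio matrix, planted foci data.frame).
#' @export
gen_cell_image_stack <- function(config, seed = config$seed, n_cells_img = 4,
                                 n_frames_img = 5, noise = TRUE,
                                 foci_per_cell = NULL, traces = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  sz <- config$image_size; rad <- config$cell_radius
  seeds <- derive_seeds(seed, 3)

  # -- placement: rejection-sample non-overlapping centers -------------------
  centers <- with_seed(seeds[1], {
    margin <- rad + 2
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pts) < n_cells_img) {
      tries <- tries + 1L
      if (tries > 2000L) {
        stop(sprintf("could not place %d cells of radius %d in a %d-px field",
                     n_cells_img, rad, sz), call. = FALSE)
      }
      cand <- stats::runif(2, margin + 1, sz - margin)
      if (nrow(pts) == 0 ||
          all(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2, byrow = TRUE))^2)) >
                2 * rad + 3)) {
        pts <- rbind(pts, round(cand))
      }
    }
    pts
  })

  mask <- matrix(0L, sz, sz)
  rr <- row(mask); cc <- col(mask)
  for (i in seq_len(n_cells_img)) {
    mask[(rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= rad^2] <- i
  }

  if (is.null(traces)) {
    tr_seeds <- derive_seeds(seeds[2], n_cells_img)
    traces <- lapply(seq_len(n_cells_img), function(i) {
      cfg_i <- config; cfg_i$n_frames <- n_frames_img
      gen_stable_trace(cfg_i, tr_seeds[i], cell_id = paste0("cell_", i))$trace
    })
  }
  check_that(length(traces) == n_cells_img, "traces", "one trace per cell required")
  ratio_mat <- vapply(traces, function(tr) tr$ratio[seq_len(n_frames_img)],
                      numeric(n_frames_img))
  ratio_mat <- matrix(ratio_mat, n_frames_img, n_cells_img)

  base_int <- 400; bg <- 40; cyto <- 400; read_sd <- 3
  render <- with_seed(seeds[3], {
    gains <- if (noise) 1 + stats::rnorm(n_frames_img, 0, 0.03) else rep(1, n_frames_img)
    # plant static foci inside cells (reporter channel only)
    kfoci <- if (is.null(foci_per_cell)) stats::rpois(n_cells_img, 1)
             else rep_len(foci_per_cell, n_cells_img)
    foci <- do.call(rbind, lapply(seq_len(n_cells_img), function(i) {
      if (kfoci[i] == 0) return(NULL)
      ang <- stats::runif(kfoci[i], 0, 2 * pi)
      rd <- stats::runif(kfoci[i], 0, max(0, rad - 3))
      data.frame(cell_id = i,
                 row = as.integer(round(centers[i, 1] + rd * cos(ang))),
                 col = as.integer(round(centers[i, 2] + rd * sin(ang))),
                 amplitude = config$focus_amplitude)
    }))
    reporter_base <- matrix(bg, sz, sz)
    reporter_base[mask > 0] <- cyto
    if (!is.null(foci)) {
      for (j in seq_len(nrow(foci))) {
        r0 <- foci$row[j]; c0 <- foci$col[j]
        ext <- ceiling(3 * config$psf_sigma)
        rs <- max(1, r0 - ext):min(sz, r0 + ext)
        cs <- max(1, c0 - ext):min(sz, c0 + ext)
        g <- outer(rs, cs, function(a, b)
          exp(-((a - r0)^2 + (b - c0)^2) / (2 * config$psf_sigma^2)))
        reporter_base[rs, cs] <- reporter_base[rs, cs] + foci$amplitude[j] * g
      }
    }
    frames <- lapply(seq_len(n_frames_img), function(f) {
      ex490 <- matrix(bg, sz, sz)
      ex410 <- matrix(bg, sz, sz)
      for (i in seq_len(n_cells_img)) {
        ex490[mask == i] <- base_int * gains[f]
        ex410[mask == i] <- base_int * gains[f] * ratio_mat[f, i]
      }
      rep_f <- reporter_base
      if (noise) {
        ex490 <- matrix(stats::rpois(sz^2, ex490) + stats::rnorm(sz^2, 0, read_sd), sz, sz)
        ex410 <- matrix(stats::rpois(sz^2, ex410) + stats::rnorm(sz^2, 0, read_sd), sz, sz)
        rep_f <- matrix(stats::rpois(sz^2, rep_f) + stats::rnorm(sz^2, 0, read_sd), sz, sz)
      }
      list(ex410 = ex410, ex490 = ex490, reporter = rep_f)
    })
    list(frames = frames, foci = foci)
  })

  list(ex410 = lapply(render$frames, `[[`, "ex410"),
       ex490 = lapply(render$frames, `[[`, "ex490"),
       reporter = lapply(render$frames, `[[`, "reporter"),
       mask = mask,
       truth = list(centers = centers, radius = rad, ratio = ratio_mat,
                    foci = render$foci, traces = traces))
}

#' Generate a full synthetic cohort with ground truth
#'
#' Cells are assigned to classes by a multinomial draw over `proportions`;
#' each cell gets a QUEEN ratio trace, a paired aggregate-reporter trace
#' (accelerating after the dip for dip cells), and two excitation-channel
#' traces (sharing a common per-frame gain so the ratio is exact) with
#' acquisition errors injected at the configured rate.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @param proportions named numeric over classes `stable`, `dip`,
#'   `shallow_dip`, `shift`, `oscillating`; normalized internally.
#' @param write_dir optional directory; when given, traces/agg/channel CSVs
#'   and a truth JSON are written there.
#' @return List of class `synthetic_cohort`: `config`, `traces` (list of
#'   true, uncorrupted [ratio_trace()]), `channels` (list of corrupted
#'   `channel_traces`), `agg` (list of [aggregation_trace()]), and `truth`
#'   (`cells` data.frame, `events`, `errors`, `agg` data.frame).
#' @export
gen_cohort <- function(config, seed = config$seed,
                       proportions = c(stable = 0.65, dip = 0.20,
                                       shallow_dip = 0.05, shift = 0.10,
                                       oscillating = 0),
                       write_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  classes <- c("stable", "dip", "shallow_dip", "shift", "oscillating")
  check_that(all(names(proportions) %in% classes) && all(proportions >= 0) &&
               sum(proportions) > 0, "proportions",
             "must be nonnegative over the five classes")
  p <- stats::setNames(rep(0, length(classes)), classes)
  p[names(proportions)] <- proportions
  p <- p / sum(p)
  n <- config$n_cells
  dt <- config$frame_interval
  E <- dip_total_frames(config)

  seeds <- derive_seeds(seed, 4)
  assign_cls <- with_seed(seeds[1], sample(classes, n, replace = TRUE, prob = p))

  # dip onsets leave >= 112 min of pre-dip baseline (the regression needs
  # > 92 min) and a full post-dip horizon inside the trace
  onset_lo <- ceiling(112 / dt) + 1L
  onset_hi <- config$n_frames - ceiling(config$post_dip_horizon / dt) - E - 2L
  if (any(assign_cls == "dip")) {
    check_that(onset_hi >= onset_lo, "n_frames",
               "trace too short to place a dip with pre-span and post-horizon")
  }
  trace_seeds <- derive_seeds(seeds[2], n)
  agg_seeds <- derive_seeds(seeds[3], n)
  err_seeds <- derive_seeds(seeds[4], n)

  traces <- vector("list", n); agg <- vector("list", n)
  channels <- vector("list", n)
  cells <- vector("list", n); events <- list(); errors <- list(); agg_truth <- list()

  for (i in seq_len(n)) {
    id <- sprintf("cell_%03d", i)
    cls <- assign_cls[i]
    gi <- with_seed(trace_seeds[i], list(
      depth_deep = stats::runif(1, config$dip_depth_range[1], config$dip_depth_range[2]),
      depth_shallow = stats::runif(1, 0.36, 0.44),
      depth_shift = stats::runif(1, 0.40, 0.80),
      onset = sample(onset_lo:onset_hi, 1L),
      sub = sample.int(.Machine$integer.max - 1L, 1L)))
    g <- switch(cls,
      stable = gen_stable_trace(config, gi$sub, cell_id = id),
      dip = gen_dip_trace(config, gi$sub, depth = gi$depth_deep,
                          duration_frames = E, recover = TRUE,
                          onset = gi$onset, cell_id = id),
      shallow_dip = gen_dip_trace(config, gi$sub, depth = gi$depth_shallow,
                                  duration_frames = E, recover = TRUE,
                                  onset = gi$onset, cell_id = id),
      shift = gen_dip_trace(config, gi$sub, depth = gi$depth_shift,
                            duration_frames = E, recover = FALSE,
                            onset = gi$onset, cell_id = id),
      oscillating = gen_oscillating_trace(config, gi$sub, cell_id = id))
    traces[[i]] <- g$trace
    true_label <- g$truth$label
    onset_i <- if (!is.null(g$truth$events)) g$truth$events$onset[1] else NA_integer_
    if (!is.null(g$truth$events)) {
      events[[length(events) + 1L]] <- cbind(cell_id = id, g$truth$events)
    }
    cells[[i]] <- data.frame(
      cell_id = id, class = true_label,
      depth = if (!is.null(g$truth$events)) g$truth$events$depth[1] else NA_real_,
      onset = onset_i,
      period = if (identical(cls, "oscillating")) config$osc_period else NA_real_)

    ga <- gen_aggregation_trace(config, agg_seeds[i],
                                dip_onset = if (identical(true_label, "dip")) onset_i else NULL,
                                cell_id = id)
    agg[[i]] <- ga$agg
    agg_truth[[i]] <- data.frame(cell_id = id, slope = ga$truth$slope,
                                 intercept = ga$truth$intercept,
                                 noise_sd = ga$truth$noise_sd,
                                 accel = ga$truth$accel)

    # channel traces: common per-frame gain cancels in the ratio
    ch <- with_seed(err_seeds[i], {
      gain <- 1 + stats::rnorm(config$n_frames, 0, 0.03)
      structure(list(cell_id = id,
                     ex410 = 400 * gain * g$trace$ratio,
                     ex490 = 400 * gain),
                class = "channel_traces")
    })
    inj <- inject_frame_errors(ch, config$frame_error_rate,
                               config$frame_error_magnitude,
                               seed = err_seeds[i] %% 1000000L + i)
    channels[[i]] <- inj$channels
    if (nrow(inj$truth)) {
      errors[[length(errors) + 1L]] <- cbind(cell_id = id, inj$truth)
    }
  }

  cohort <- structure(list(
    config = config,
    traces = traces, channels = channels, agg = agg,
    truth = list(cells = do.call(rbind, cells),
                 events = if (length(events)) do.call(rbind, events) else NULL,
                 errors = if (length(errors)) do.call(rbind, errors) else NULL,
                 agg = do.call(rbind, agg_truth))),
    class = "synthetic_cohort")

  if (!is.null(write_dir)) write_cohort(cohort, write_dir)
  cohort
}

#' Write a synthetic cohort to disk (tidy CSVs + truth JSON)
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  paths <- c(traces = file.path(dir, "traces.csv"),
             agg = file.path(dir, "aggregation.csv"),
             channels = file.path(dir, "channels.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(traces_to_df(cohort$traces), paths["traces"], row.names = FALSE)
  agg_df <- do.call(rbind, lapply(cohort$agg, function(a)
    data.frame(cell_id = a$cell_id, frame = seq_along(a$intensity),
               time_min = a$time, reporter_mean = a$intensity)))
  utils::write.csv(agg_df, paths["agg"], row.names = FALSE)
  ch_df <- do.call(rbind, lapply(cohort$channels, function(ch)
    data.frame(cell_id = ch$cell_id, frame = seq_along(ch$ex410),
               ex410 = ch$ex410, ex490 = ch$ex490)))
  utils::write.csv(ch_df, paths["channels"], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}
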