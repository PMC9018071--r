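# The generator is first-class code: its outputs must match its own ground
# truth by construction, be deterministic under a fixed seed, and reproduce
# the statistical structure it claims (noise level, event geometry,
# oscillation period, corruption rate, linearity).

test_that("stable traces are baseline plus calibrated iid noise", {
  cfg0 <- synthetic_config(ratio_noise_sd = 0, n_frames = 50)
  g0 <- gen_stable_trace(cfg0, seed = 1)
  expect_equal(g0$trace$ratio, rep(cfg0$baseline_ratio, 50))
  expect_identical(g0$truth$label, "stable")

  # same seed -> identical; different seed -> different
  cfg <- synthetic_config(n_frames = 300)
  expect_identical(gen_stable_trace(cfg, seed = 7)$trace$ratio,
                   gen_stable_trace(cfg, seed = 7)$trace$ratio)
  expect_false(identical(gen_stable_trace(cfg, seed = 7)$trace$ratio,
                         gen_stable_trace(cfg, seed = 8)$trace$ratio))

  # sample SD within the chi-square-motivated band in >= 95% of seeds
  ok <- vapply(1:100, function(s) {
    sdv <- sd(gen_stable_trace(cfg, seed = s)$trace$ratio)
    sdv >= 0.04 && sdv <= 0.06
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("injected depletion events carry consistent truth labels", {
  cfg0 <- synthetic_config(ratio_noise_sd = 0)
  cases <- list(list(depth = 0.6, dur = 4, rec = TRUE, lab = "dip"),
                list(depth = 0.4, dur = 4, rec = FALSE, lab = "shift"),
                list(depth = 0.4, dur = 4, rec = TRUE, lab = "shallow_dip"))
  for (cs in cases) {
    g <- gen_dip_trace(cfg0, seed = 3, depth = cs$depth, duration_frames = cs$dur,
                       recover = cs$rec, onset = 40)
    expect_identical(g$truth$label, cs$lab)
    expect_identical(truth_label(cs$depth, g$truth$events$duration_frames,
                                 cs$rec), cs$lab)
    # the trace actually contains the event: nadir depth equals `depth`
    expect_equal(cfg0$baseline_ratio - min(g$trace$ratio), cs$depth, tolerance = 1e-12)
  }
  # event must fit inside the trace
  expect_error(gen_dip_trace(synthetic_config(n_frames = 10), depth = 0.6,
                             duration_frames = 20, onset = 2),
               "fit inside")
})

test_that("oscillating traces have the configured period and uniform phases", {
  cfg <- synthetic_config(osc_period = 35, osc_amplitude = 0.15, n_frames = 300)
  g <- gen_oscillating_trace(cfg, seed = 5)
  # periodogram oracle: dominant nonzero FFT bin within one bin of 35 min
  x <- g$trace$ratio - mean(g$trace$ratio)
  pw <- Mod(fft(x))^2
  half <- 2:floor(length(x) / 2)
  kstar <- half[which.max(pw[half])] - 1
  f_star <- kstar / (length(x) * cfg$frame_interval)
  df <- 1 / (length(x) * cfg$frame_interval)
  expect_lte(abs(f_star - 1 / 35), df)

  # phases across seeds are circular-uniform (fitted by sin/cos regression)
  t_ <- g$trace$time
  phases <- vapply(1:100, function(s) {
    y <- gen_oscillating_trace(cfg, seed = 1000 + s)$trace$ratio
    co <- coef(lm(y ~ sin(2 * pi * t_ / 35) + cos(2 * pi * t_ / 35)))
    atan2(co[3], co[2])
  }, numeric(1))
  resultant <- Mod(mean(exp(1i * phases)))
  expect_lt(resultant, 0.3)

  # degenerate amplitude reduces to a stable trace
  cfg0 <- synthetic_config(osc_amplitude = 0, ratio_noise_sd = 0, n_frames = 50)
  expect_equal(gen_oscillating_trace(cfg0, seed = 1)$trace$ratio, rep(1, 50))
  # sub-Nyquist period rejected
  expect_error(gen_oscillating_trace(synthetic_config(osc_period = 7,
                                                      frame_interval = 4)),
               "Nyquist")
})

test_that("frame-error injection matches its rate and records truth", {
  ch <- make_channels(rnorm(700, 400, 5), rnorm(700, 400, 5))
  # rate 0 -> identity
  out0 <- inject_frame_errors(ch, rate = 0, magnitude = 10, seed = 1)
  expect_identical(out0$channels$ex410, ch$ex410)
  expect_equal(nrow(out0$truth), 0)
  # magnitude 0 -> truth recorded but traces unchanged
  outm <- inject_frame_errors(ch, rate = 1 / 70, magnitude = 0, seed = 2)
  expect_gt(nrow(outm$truth), 0)
  expect_identical(outm$channels$ex490, ch$ex490)
  # corrupted count ~ Binomial(700, 1/70): mean about 10 over seeds
  counts <- vapply(1:100, function(s)
    nrow(inject_frame_errors(ch, 1 / 70, 10, seed = s)$truth), numeric(1))
  expect_equal(mean(counts), 10, tolerance = 0.1 * 10)
  # exactly one channel touched per corrupted frame
  out <- inject_frame_errors(ch, 1 / 70, 10, seed = 3)
  for (i in seq_len(nrow(out$truth))) {
    f <- out$truth$frame[i]
    touched <- c(out$channels$ex410[f] != ch$ex410[f],
                 out$channels$ex490[f] != ch$ex490[f])
    expect_identical(sum(touched), 1L)
  }
})

test_that("aggregation traces hit the linearity target and calibrated fold", {
  cfg <- synthetic_config()
  # noiseless line: correlation exactly 1
  cfg1 <- synthetic_config(agg_corr_target = 1 - 1e-12)
  g1 <- gen_aggregation_trace(cfg1, seed = 1)
  expect_equal(cor(g1$agg$time, g1$agg$intensity), 1, tolerance = 1e-6)
  # calibrated noise, 20 traces: mean Pearson r >= 0.98
  rs <- vapply(1:20, function(s) {
    g <- gen_aggregation_trace(cfg, seed = 100 + s)
    cor(g$agg$time, g$agg$intensity)
  }, numeric(1))
  expect_gte(mean(rs), 0.98)
  # nonpositive horizon rejected
  expect_error(synthetic_config(post_dip_horizon = 0), "post_dip_horizon")
})

test_that("synthetic image stacks conserve the generating ratio and foci", {
  cfg <- synthetic_config(image_size = 72, cell_radius = 8)
  st <- gen_cell_image_stack(cfg, seed = 5, n_cells_img = 3, n_frames_img = 4,
                             noise = FALSE, foci_per_cell = c(1, 2, 0))
  # conservation: noiseless per-cell mean ratio equals the generating trace
  for (i in 1:3) {
    rt <- compute_ratio_trace(extract_cell_trace(st, st$mask, i),
                              frame_interval = cfg$frame_interval)
    expect_equal(rt$ratio, st$truth$ratio[, i], tolerance = 1e-9)
  }
  # planted foci recovered within 1 px
  fx <- find_maxima(st$reporter[[1]], 4000)
  expect_identical(nrow(fx), nrow(st$truth$foci))
  for (j in seq_len(nrow(st$truth$foci))) {
    d <- sqrt((fx$row - st$truth$foci$row[j])^2 + (fx$col - st$truth$foci$col[j])^2)
    expect_lte(min(d), 1)
  }
  # common gain on both channels leaves ratios unchanged
  st2 <- st
  st2$ex410 <- lapply(st$ex410, function(mm) mm * 3.7)
  st2$ex490 <- lapply(st$ex490, function(mm) mm * 3.7)
  r1 <- compute_ratio_trace(extract_cell_trace(st, st$mask, 1), 4)$ratio
  r2 <- compute_ratio_trace(extract_cell_trace(st2, st2$mask, 1), 4)$ratio
  expect_equal(r1, r2, tolerance = 1e-12)
  # impossible placement errors out
  expect_error(gen_cell_image_stack(synthetic_config(image_size = 40,
                                                     cell_radius = 10),
                                    seed = 1, n_cells_img = 10),
               "could not place")
})

test_that("cohorts are reproducible and their truth matches the mix", {
  cfg <- synthetic_config(n_cells = 50)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_cohort(cfg, seed = 3, write_dir = d1)
  gen_cohort(cfg, seed = 3, write_dir = d2)
  for (f in c("traces.csv", "aggregation.csv", "channels.csv", "truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6), label = f)
  }
  # all-stable proportions give all-stable truth
  co1 <- gen_cohort(synthetic_config(n_cells = 20), seed = 4,
                    proportions = c(stable = 1))
  expect_true(all(co1$truth$cells$class == "stable"))
  # 65/35 split recovered within the exact binomial 95% CI at n = 200
  co <- gen_cohort(synthetic_config(n_cells = 200), seed = 5)
  n_stable <- sum(co$truth$cells$class == "stable")
  ci <- binom.test(n_stable, 200, p = 0.65)$conf.int
  expect_true(ci[1] <= 0.65 && 0.65 <= ci[2])
})
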