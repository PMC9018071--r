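# Ratio computation, acquisition-error QC and calibration.

test_that("max projection is the pixelwise maximum across slices", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(max_project(list(img)), img)
  # 11 slices, one bright pixel in slice 6 survives
  slices <- replicate(11, matrix(0, 8, 8), simplify = FALSE)
  slices[[6]][3, 5] <- 9
  proj <- max_project(slices)
  expect_equal(proj[3, 5], 9)
  expect_equal(sum(proj), 9)
  # permutation invariance
  expect_identical(max_project(slices[sample(11)]), proj)
  expect_error(max_project(list()), "z-slice")
})

test_that("per-cell channel extraction averages under the mask", {
  mask <- matrix(0L, 6, 6); mask[2:4, 2:4] <- 1L; mask[6, 6] <- 2L
  stack <- list(ex410 = list(matrix(5, 6, 6), matrix(7, 6, 6)),
                ex490 = list(matrix(2, 6, 6), matrix(2, 6, 6)))
  ct <- extract_cell_trace(stack, mask, 1)
  expect_equal(ct$ex410, c(5, 7))
  expect_equal(ct$ex490, c(2, 2))
  # 1-pixel mask returns that pixel's series
  stack$ex410[[1]][6, 6] <- 42
  expect_equal(extract_cell_trace(stack, mask, 2)$ex410[1], 42)
  expect_error(extract_cell_trace(stack, mask, 9), "no pixels")
})

test_that("ratio is ex410/ex490, gain-invariant, and guards the denominator", {
  ch <- make_channels(c(2, 2, 2), c(2, 2, 2))
  expect_equal(compute_ratio_trace(ch, 4)$ratio, c(1, 1, 1))
  expect_equal(compute_ratio_trace(make_channels(2, 0.5), 4)$ratio, 4)
  ch2 <- make_channels(ch$ex410 * 11, ch$ex490 * 11)
  expect_equal(compute_ratio_trace(ch2, 4)$ratio,
               compute_ratio_trace(ch, 4)$ratio)
  expect_error(compute_ratio_trace(make_channels(c(1, 1), c(1, 0)), 4),
               "non-positive")
})

test_that("single-channel spikes are flagged; dual spikes and dips are not", {
  set.seed(11)
  n <- 200
  ch <- make_channels(rnorm(n, 400, 5), rnorm(n, 400, 5))
  expect_length(detect_frame_errors(ch), 0)
  # 10-SD spike on ex490 at one frame
  ch$ex490[77] <- ch$ex490[77] + 50
  expect_identical(detect_frame_errors(ch), 77L)
  # a simultaneous equal spike on both channels is not an error (ratio is safe)
  ch2 <- make_channels(rnorm(n, 400, 5), rnorm(n, 400, 5))
  ch2$ex410[50] <- ch2$ex410[50] + 60
  ch2$ex490[50] <- ch2$ex490[50] + 60
  expect_length(detect_frame_errors(ch2), 0)
  # a genuine multi-frame dip (ATP-sensitive channel drops) is never flagged
  ch3 <- make_channels(rnorm(n, 400, 5), rnorm(n, 400, 5))
  ch3$ex410[100:104] <- ch3$ex410[100:104] - 240
  expect_length(detect_frame_errors(ch3), 0)
})

test_that("correction replaces flagged frames by neighbour averages only", {
  tr <- make_trace(c(1.0, 9.0, 1.2))
  out <- correct_frame_errors(tr, 2L)
  expect_equal(out$ratio, c(1.0, 1.1, 1.2))
  expect_identical(out$corrected_frames, 2L)
  # edge frame takes its single valid neighbour
  out0 <- correct_frame_errors(make_trace(c(9, 1.5, 1.6)), 1L)
  expect_equal(out0$ratio[1], 1.5)
  # empty flag set is the identity
  expect_identical(correct_frame_errors(tr, integer(0))$ratio, tr$ratio)
  # locality: unflagged frames are bit-identical
  set.seed(2)
  tr2 <- make_trace(rnorm(50, 1, 0.05))
  out2 <- correct_frame_errors(tr2, c(10L, 30L))
  expect_identical(out2$ratio[-c(10, 30)], tr2$ratio[-c(10, 30)])
  # adjacent flagged frames: corrected against the valid flanks, with warning
  tr3 <- make_trace(c(1.0, 5.0, 6.0, 1.4))
  expect_warning(out3 <- correct_frame_errors(tr3, c(2L, 3L)), "adjacent")
  expect_equal(out3$ratio, c(1.0, 1.2, 1.2, 1.4))
})

test_that("detect+correct is idempotent on isolated synthetic errors", {
  cfg <- synthetic_config(n_frames = 300)
  g <- gen_stable_trace(cfg, seed = 9)
  ch <- make_channels(400 * g$trace$ratio, rep(400, 300) + rnorm(300, 0, 5))
  inj <- inject_frame_errors(ch, rate = 1 / 70, magnitude = 12, seed = 4)
  pass1 <- correct_frame_errors(compute_ratio_trace(inj$channels, 4),
                                detect_frame_errors(inj$channels))
  # after correcting the ratio there is nothing left to flag on a re-run of
  # the full detect+correct pass over reconstructed channels
  ch2 <- inj$channels
  ch2$ex410 <- pass1$ratio * ch2$ex490
  pass2 <- correct_frame_errors(compute_ratio_trace(ch2, 4),
                                detect_frame_errors(ch2))
  expect_equal(pass2$ratio, pass1$ratio, tolerance = 1e-12)
})

test_that("calibration maps are monotone, invertible, and fill ATP", {
  lin <- calibration_curve("linear", slope = 1, intercept = 0)
  tr <- ratio_to_atp(make_trace(c(4, 4.2)), lin)
  expect_equal(tr$atp, c(4, 4.2))
  # default linear map: ratio 1.0 -> 4 mM
  expect_equal(ratio_to_atp(make_trace(1))$atp, 4)
  # hill at the midpoint with n = 1 gives the half-saturation constant
  hill <- calibration_curve("hill", r_min = 0.6, r_max = 1.4, k_app = 4, hill_n = 1)
  expect_equal(hill$forward(1.0), 4)
  # numerical inverse round trip on a grid
  grid <- seq(0.61, 1.39, length.out = 101)
  expect_equal(hill$inverse(hill$forward(grid)), grid, tolerance = 1e-9)
  # atp nondecreasing in ratio over the valid range
  expect_true(all(diff(hill$forward(grid)) > 0))
  # non-monotone calibration rejected at construction
  expect_error(calibration_curve("linear", slope = -2), "slope")
  # out-of-range ratios clipped with a warning
  expect_warning(ratio_to_atp(make_trace(c(0.7, 2.0)), hill), "clipped")
})

test_that("population summaries report mean, SD and CV", {
  expect_equal(population_summary(c(2, 4))$cv, sqrt(2) / 3, tolerance = 1e-12)
  traces <- lapply(1:5, function(i) make_trace(rep(1.2, 10), id = paste0("c", i)))
  ps <- population_summary(traces)
  expect_equal(ps$cv[ps$quantity == "ratio"], 0)
  # wider mixture has strictly larger CV than a tight one
  set.seed(3)
  wide <- population_summary(rnorm(200, 1, 0.3))
  tight <- population_summary(rnorm(200, 1, 0.02))
  expect_gt(wide$cv, tight$cv)
  expect_true(is.na(population_summary(c(-1, 1))$cv))
})
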