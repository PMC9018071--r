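# Prominence-based focus detection and the RMSD statistic.

test_that("find_maxima handles degenerate and single-spot images", {
  expect_identical(nrow(find_maxima(matrix(5, 10, 10), 100)), 0L)
  img <- paint_spot(matrix(0, 21, 21), 11, 11, 10000)
  fx <- find_maxima(img, 4000)
  expect_identical(nrow(fx), 1L)
  expect_identical(c(fx$row, fx$col), c(11L, 11L))
  expect_error(find_maxima(array(0, c(3, 3, 3)), 10), "2-D")
  expect_error(find_maxima(matrix(0, 3, 3), 0), "positive")
})

test_that("two spots resolve or merge according to the tolerance", {
  img <- matrix(0, 40, 40)
  img <- paint_spot(img, 10, 10, 10000)
  img <- paint_spot(img, 30, 30, 5000)
  expect_identical(nrow(find_maxima(img, 4000)), 2L)
  expect_identical(nrow(find_maxima(img, 6000)), 1L)
  # the survivor at the high tolerance is the brighter spot
  fx <- find_maxima(img, 6000)
  expect_identical(c(fx$row, fx$col), c(10L, 10L))
})

test_that("find_maxima equals the brute-force prominence oracle", {
  set.seed(101)
  for (i in 1:60) {
    img <- matrix(sample(0:12, 32 * 32, replace = TRUE), 32, 32)
    tol <- sample(1:6, 1)
    got <- find_maxima(img, tol)
    want <- oracle_prominence_maxima(img, tol)
    n_want <- if (is.null(want)) 0L else nrow(want)
    expect_identical(nrow(got), n_want)
    if (n_want > 0) {
      got <- got[order(got$row, got$col), ]
      want <- want[order(want$row, want$col), ]
      expect_equal(got$row, want$row)
      expect_equal(got$col, want$col)
      expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
    }
  }
})

test_that("find_maxima is offset-invariant and translation-equivariant", {
  set.seed(7)
  img <- matrix(sample(0:9, 24 * 24, replace = TRUE), 24, 24)
  a <- find_maxima(img, 3)
  b <- find_maxima(img + 1000, 3)
  expect_equal(a[c("row", "col", "prominence")], b[c("row", "col", "prominence")])
  # translate by (2, 3) with a constant pad; interior maxima move along
  big <- matrix(min(img), 30, 30)
  big[3:26, 4:27] <- img
  shifted <- find_maxima(big, 3)
  inner <- a[a$row > 1 & a$row < 24 & a$col > 1 & a$col < 24, ]
  for (j in seq_len(nrow(inner))) {
    expect_true(any(shifted$row == inner$row[j] + 2 & shifted$col == inner$col[j] + 3))
  }
})

test_that("the 3-px-diameter circle is centre plus 4-neighbours", {
  img <- matrix(7, 9, 9)
  expect_equal(focus_mean_intensity(img, 5, 5)$mean, 7)
  img2 <- matrix(0, 9, 9)
  img2[5, 5] <- 100
  img2[4, 5] <- img2[6, 5] <- img2[5, 4] <- img2[5, 6] <- 50
  img2[4, 4] <- img2[4, 6] <- img2[6, 4] <- img2[6, 6] <- 999  # diagonals excluded
  m <- focus_mean_intensity(img2, 5, 5)
  expect_equal(m$mean, (100 + 4 * 50) / 5)
  expect_false(m$edge)
  # corner focus: in-bounds subset, edge flag
  img3 <- matrix(0, 9, 9); img3[1, 1] <- 30; img3[2, 1] <- 60; img3[1, 2] <- 90
  mc <- focus_mean_intensity(img3, 1, 1)
  expect_equal(mc$mean, (30 + 60 + 90) / 3)
  expect_true(mc$edge)
})

test_that("per-field foci fractions count cells with a detected focus", {
  cfg <- synthetic_config(image_size = 96, cell_radius = 7)
  st <- gen_cell_image_stack(cfg, seed = 31, n_cells_img = 10, n_frames_img = 1,
                             noise = FALSE,
                             foci_per_cell = c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0))
  ff <- foci_fraction(st$reporter[[1]], st$mask, tolerance = 4000)
  expect_equal(ff$n_cells, 10)
  expect_equal(ff$percent, 70)
  # no foci planted -> 0%
  st0 <- gen_cell_image_stack(cfg, seed = 32, n_cells_img = 5, n_frames_img = 1,
                              noise = FALSE, foci_per_cell = 0)
  expect_equal(foci_fraction(st0$reporter[[1]], st0$mask, 4000)$percent, 0)
  # pooled mean equals the cell-weighted mean of the two fields
  both <- foci_fraction(list(st$reporter[[1]], st0$reporter[[1]]),
                        list(st$mask, st0$mask), 4000)
  pooled <- 100 * sum(both$n_cells_with_foci) / sum(both$n_cells)
  expect_equal(pooled, weighted.mean(both$percent, both$n_cells))
})

test_that("pre-dip regression recovers exact lines and refuses short windows", {
  t_ <- (0:59) * 4
  agg <- aggregation_trace(2 * t_ + 5, 4)
  fit <- fit_pre_dip_regression(agg)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 5, tolerance = 1e-12)
  expect_equal(fit$pearson_r, 1)
  # decreasing line: r = -1
  fit2 <- fit_pre_dip_regression(aggregation_trace(rev(2 * t_ + 5), 4))
  expect_equal(fit2$pearson_r, -1)
  # window shorter than the minimum pre-dip span is refused
  expect_error(fit_pre_dip_regression(agg, dip_onset = 10), "min")
})

test_that("rmsd equals its one-line oracle on random inputs", {
  t_ <- (0:199) * 4
  set.seed(5)
  for (i in 1:50) {
    slope <- runif(1, -2, 2); intercept <- runif(1, -50, 50)
    y <- intercept + slope * t_ + rnorm(200, 0, runif(1, 0.1, 20))
    agg <- aggregation_trace(y, 4)
    fit <- list(slope = slope, intercept = intercept)
    w <- sort(sample(200, sample(5:200, 1)))
    expect_equal(rmsd(agg, fit, w), oracle_rmsd(y, t_, slope, intercept, w),
                 tolerance = 1e-12)
  }
  # exact line -> 0; residuals (+1,-1,+1,-1) -> 1
  agg0 <- aggregation_trace(3 * t_ + 1, 4)
  expect_equal(rmsd(agg0, list(slope = 3, intercept = 1), 1:200), 0)
  agg1 <- aggregation_trace(c(1, -1, 1, -1), 4)
  expect_equal(rmsd(agg1, list(slope = 0, intercept = 0), 1:4), 1)
  # chi-interval: iid noise sd 10 about the true line, 500 frames
  ok <- vapply(1:100, function(s) {
    set.seed(400 + s)
    y <- 5 + 0.5 * (0:499) + rnorm(500, 0, 10)
    r <- rmsd(aggregation_trace(y, 1), list(slope = 0.5, intercept = 5), 1:500)
    r >= 9 && r <= 11
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("rmsd is offset-invariant, gain-linear, and folds are gain-invariant", {
  set.seed(6)
  t_ <- (0:149) * 4
  y <- 100 + 1.2 * t_ + rnorm(150, 0, 8)
  y[t_ > 300] <- y[t_ > 300] + 0.9 * (t_[t_ > 300] - 300)
  onset <- which(t_ == 300)
  run <- function(yy) {
    agg <- aggregation_trace(yy, 4)
    fit <- fit_pre_dip_regression(agg, onset)
    suppressWarnings(rmsd_timecourse(agg, fit, onset))
  }
  base <- run(y)
  shifted <- run(y + 1234)
  expect_equal(shifted$rmsd_before, base$rmsd_before, tolerance = 1e-9)
  expect_equal(shifted$fold_changes, base$fold_changes, tolerance = 1e-9)
  gained <- run(y * 7)
  expect_equal(gained$rmsd_before, 7 * base$rmsd_before, tolerance = 1e-9)
  expect_equal(gained$fold_changes, base$fold_changes, tolerance = 1e-9)
})

test_that("rmsd time course exposes injected post-onset deviations", {
  t_ <- (0:149) * 4
  onset <- 60L
  # null: no injected deviation -> folds near 1
  set.seed(9)
  folds <- replicate(30, {
    y <- 50 + 2 * t_ + rnorm(150, 0, 10)
    agg <- aggregation_trace(y, 4)
    fit <- fit_pre_dip_regression(agg, onset)
    rmsd_timecourse(agg, fit, onset)$fold_changes
  })
  expect_lt(abs(mean(folds) - 1), 0.15)
  # residual SD tripled after onset by construction -> max fold >= 3 on average
  set.seed(10)
  maxf <- replicate(30, {
    e <- rnorm(150, 0, 10); e[t_ > t_[onset]] <- 3 * e[t_ > t_[onset]]
    agg <- aggregation_trace(50 + 2 * t_ + e, 4)
    fit <- fit_pre_dip_regression(agg, onset)
    rmsd_timecourse(agg, fit, onset)$max_fold
  })
  expect_gte(mean(maxf), 3)
  # trace ending before the horizon gives a flagged partial result
  agg_short <- aggregation_trace(50 + 2 * t_[1:80] + rnorm(80, 0, 10), 4)
  fit <- fit_pre_dip_regression(agg_short, onset)
  expect_warning(rc <- rmsd_timecourse(agg_short, fit, onset), "horizon")
  expect_true(rc$partial)
})

test_that("the cohort RMSD report partitions dip and stable cells", {
  cfg <- synthetic_config(n_cells = 30)
  co <- gen_cohort(cfg, seed = 41,
                   proportions = c(stable = 0.4, dip = 0.6))
  cells <- lapply(seq_len(30), function(i)
    list(agg = co$agg[[i]], dip_onset = co$truth$cells$onset[i]))
  rep_ <- cohort_rmsd_report(cells)
  expect_identical(rep_$summary$n_dip + rep_$summary$n_stable, 30L)
  expect_identical(nrow(rep_$dip), sum(co$truth$cells$class == "dip"))
  # permuting cell order leaves the summary unchanged
  rep2 <- cohort_rmsd_report(cells[rev(seq_len(30))])
  expect_equal(rep2$summary$mean_max_fold, rep_$summary$mean_max_fold)
  expect_equal(rep2$summary$mean_stable_rmsd, rep_$summary$mean_stable_rmsd)
  # all-stable cohort: no dip entries, full-span RMSD reported
  cells0 <- lapply(co$agg[co$truth$cells$class != "dip"], function(a)
    list(agg = a, dip_onset = NA))
  rep0 <- cohort_rmsd_report(cells0)
  expect_identical(rep0$summary$n_dip, 0L)
  expect_true(all(rep0$stable$rmsd_full > 0))
})
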