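# Aggregate-foci detection and the pre-dip-regression RMSD statistic.
#
# Foci of the Hsp104 reporter are detected as local intensity maxima whose
# topographic prominence -- height above the highest saddle connecting them
# to any higher maximum -- exceeds a noise tolerance (default 4000, the
# value used with EMCCD counts in this assay). Per-cell reporter intensity
# rises linearly in cells with stable ATP; deviations from the line fitted
# before an ATP dip, summarized as an RMSD per time window, quantify the
# post-dip acceleration of aggregate accumulation.

#' Prominence-based local maxima (focus candidates) in an image
#'
#' Finds all local-maximum plateaus (8-connectivity) and keeps those whose
#' prominence exceeds `noise_tolerance`. Prominence is defined by the
#' flood-fill rule: descend an intensity threshold from the peak; the first
#' level at which the peak's connected super-level region touches a strictly
#' higher pixel is its saddle, and prominence = peak - saddle. The global
#' maximum's prominence is peak - min(image). Plateau maxima are reduced to
#' the (rounded) centroid of the plateau.
#'
#' @param image numeric matrix.
#' @param noise_tolerance minimum prominence, > 0.
#' @return data.frame of class `foci` with columns row, col, peak_value,
#'   prominence, mean_intensity_3px, edge (TRUE when the 3-px-diameter
#'   circle was clipped at the border). Zero rows when no maximum stands
#'   out (e.g. a constant image).
#' @export
find_maxima <- function(image, noise_tolerance) {
  check_that(is.matrix(image) && is.numeric(image), "image", "must be a 2-D numeric matrix")
  check_that(is.numeric(noise_tolerance) && noise_tolerance > 0,
             "noise_tolerance", "must be a positive number")
  n <- nrow(image); m <- ncol(image); npix <- n * m
  v <- as.numeric(image)

  # 8-neighbourhood lookup, NA outside the border
  rr <- rep.int(seq_len(n), m)
  cc <- rep(seq_len(m), each = n)
  nbr <- matrix(NA_integer_, npix, 8)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    if (dr == 0 && dc == 0) next
    k <- k + 1L
    ok <- rr + dr >= 1L & rr + dr <= n & cc + dc >= 1L & cc + dc <= m
    nbr[ok, k] <- which(ok) + dr + dc * n
  }

  comp <- integer(npix)                 # 0 = not yet flooded
  parent <- integer(0)                  # union-find over component ids
  peak <- numeric(0)                    # component peak value
  saddle <- numeric(0)                  # per-candidate: NA while still open
  plateau_of <- list()                  # birth plateau pixels per candidate
  open_cands <- list()                  # per-root: candidate ids not yet closed

  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  lev <- split(seq_len(npix), factor(-v))   # pixel groups, descending value
  for (grp in lev) {
    vt <- v[grp[1]]
    in_level <- logical(npix); in_level[grp] <- TRUE
    seen <- logical(npix)
    for (p0 in grp) {
      if (seen[p0]) next
      # flood the equal-value plateau containing p0
      plate <- integer(0); queue <- p0; seen[p0] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        plate <- c(plate, p)
        for (q in nbr[p, ]) {
          if (!is.na(q) && in_level[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
        }
      }
      nb <- nbr[plate, , drop = FALSE]
      nb <- nb[!is.na(nb)]
      roots <- unique(vapply(unique(comp[nb][comp[nb] > 0L]), find_root, integer(1)))
      if (length(roots) == 0L) {
        # no higher neighbour anywhere: a new local-maximum plateau is born
        cid <- length(parent) + 1L
        parent[cid] <- cid; peak[cid] <- vt; saddle[cid] <- NA_real_
        plateau_of[[cid]] <- plate
        open_cands[[cid]] <- cid
        comp[plate] <- cid
      } else {
        # plateau touches flooded ground: merge all touched components here.
        # Candidates whose component loses to a strictly higher peak close
        # with their saddle at this level; equal-peak candidates stay open
        # (an equal peak provides no saddle to higher terrain).
        survivor <- roots[order(-peak[roots], roots)][1]
        for (r2 in setdiff(roots, survivor)) {
          if (peak[r2] < peak[survivor]) {
            saddle[open_cands[[r2]]] <- vt
          } else {
            open_cands[[survivor]] <- c(open_cands[[survivor]], open_cands[[r2]])
          }
          open_cands[r2] <- list(NULL)
          parent[r2] <- survivor
        }
        comp[plate] <- survivor
      }
    }
  }
  # candidates still open connect to no higher maximum: saddle at the image floor
  saddle[is.na(saddle)] <- min(v)

  prom <- peak - saddle
  keep <- which(prom > noise_tolerance)
  out <- do.call(rbind, lapply(keep, function(cid) {
    pl <- plateau_of[[cid]]
    # round-half-up keeps centroids translation-equivariant
    row <- as.integer(floor(mean((pl - 1L) %% n + 1L) + 0.5))
    col <- as.integer(floor(mean((pl - 1L) %/% n + 1L) + 0.5))
    mi <- focus_mean_intensity(image, row, col)
    data.frame(row = row, col = col, peak_value = peak[cid],
               prominence = prom[cid],
               mean_intensity_3px = mi$mean, edge = mi$edge)
  }))
  if (is.null(out)) {
    out <- data.frame(row = integer(0), col = integer(0), peak_value = numeric(0),
                      prominence = numeric(0), mean_intensity_3px = numeric(0),
                      edge = logical(0))
  }
  out <- out[order(-out$peak_value, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("foci", "data.frame")
  out
}

#' Mean intensity in a 3-pixel-diameter circle around a focus
#'
#' The circle is rasterized as the centre pixel plus its 4-neighbours (the
#' pixel-centre-in-disk rule for a 3-px diameter). Foci at the border use
#' the in-bounds subset and are flagged.
#'
#' @param image numeric matrix.
#' @param row,col focus position (pixels).
#' @return List with `mean` and `edge` (TRUE if clipped at the border).
#' @export
focus_mean_intensity <- function(image, row, col) {
  n <- nrow(image); m <- ncol(image)
  check_that(row >= 1 && row <= n && col >= 1 && col <= m, "row",
             "focus must lie inside the image")
  pts <- cbind(row + c(0L, -1L, 1L, 0L, 0L), col + c(0L, 0L, 0L, -1L, 1L))
  ok <- pts[, 1] >= 1 & pts[, 1] <= n & pts[, 2] >= 1 & pts[, 2] <= m
  list(mean = mean(image[pts[ok, , drop = FALSE]]), edge = any(!ok))
}

#' Percentage of cells with at least one aggregate focus, per field
#'
#' Foci are detected with [find_maxima()] and assigned to cells by mask
#' membership at the focus position; foci falling outside every cell are
#' excluded (with a message).
#'
#' @param images a matrix (one field) or list of matrices (several fields).
#' @param masks matching integer label mask(s).
#' @param tolerance prominence tolerance for [find_maxima()].
#' @return data.frame with one row per field: n_cells, n_cells_with_foci,
#'   percent.
#' @export
foci_fraction <- function(images, masks, tolerance = 4000) {
  if (is.matrix(images)) { images <- list(images); masks <- list(masks) }
  check_that(length(images) == length(masks), "masks", "one mask per field required")
  rows <- lapply(seq_along(images), function(f) {
    im <- images[[f]]; mk <- masks[[f]]
    cells <- setdiff(sort(unique(as.integer(mk))), 0L)
    fx <- find_maxima(im, tolerance)
    owner <- if (nrow(fx)) mk[cbind(fx$row, fx$col)] else integer(0)
    if (any(owner == 0L)) {
      message(sprintf("field %d: %d focus(-i) outside all cells excluded", f, sum(owner == 0L)))
    }
    with_foci <- length(intersect(cells, owner[owner > 0L]))
    data.frame(field = f, n_cells = length(cells), n_cells_with_foci = with_foci,
               percent = 100 * with_foci / max(1L, length(cells)))
  })
  do.call(rbind, rows)
}

#' Construct a per-cell aggregate-reporter intensity trace
#'
#' @param intensity numeric vector of per-frame mean reporter intensities.
#' @param frame_interval minutes per frame.
#' @param cell_id identifier.
#' @param foci_count optional per-frame focus counts.
#' @return Object of class `aggregation_trace`: list with `cell_id`, `time`
#'   (minutes), `intensity`, `foci_count`, `frame_interval`.
#' @export
aggregation_trace <- function(intensity, frame_interval, cell_id = "cell_1",
                              foci_count = NULL) {
  check_that(is.numeric(intensity) && length(intensity) >= 3, "intensity",
             "must be a numeric vector of at least 3 frames")
  check_that(all(is.finite(intensity)), "intensity", "must be finite")
  check_that(frame_interval > 0, "frame_interval", "must be positive")
  structure(list(cell_id = cell_id,
                 time = (seq_along(intensity) - 1) * frame_interval,
                 intensity = as.numeric(intensity),
                 foci_count = foci_count,
                 frame_interval = frame_interval),
            class = "aggregation_trace")
}

#' Per-cell mean reporter intensity over time
#'
#' @param reporter_stack list of image matrices, one per frame (use
#'   [max_project()] upstream when frames are z-stacks).
#' @param mask integer label mask.
#' @param cell_id cell label to extract.
#' @param frame_interval minutes per frame.
#' @return An [aggregation_trace()].
#' @export
cell_mean_intensity_trace <- function(reporter_stack, mask, cell_id,
                                      frame_interval = 4) {
  sel <- mask == cell_id
  check_that(any(sel), "cell_id",
             sprintf("label %s has no pixels in the mask", format(cell_id)))
  y <- vapply(reporter_stack, function(im) {
    check_that(identical(dim(im), dim(mask)), "mask", "mask shape must match frames")
    mean(im[sel])
  }, numeric(1))
  aggregation_trace(y, frame_interval, cell_id = cell_id)
}

#' Linear regression of reporter intensity over the pre-dip window
#'
#' Fits intensity ~ time by ordinary least squares over `[start, dip_onset)`
#' (the full trace when no onset is given). The window must span at least
#' `min_span` minutes; shorter pre-dip periods do not constrain the
#' baseline accumulation rate well enough for the RMSD statistic.
#'
#' @param agg an [aggregation_trace()].
#' @param dip_onset onset frame of the ATP dip, or NULL.
#' @param min_span minimum window span in minutes (default 92, the shortest
#'   pre-dip period retained in the reference analysis).
#' @return List of class `linear_fit`: slope (intensity/min), intercept,
#'   pearson_r, fit_window (frame indices).
#' @export
fit_pre_dip_regression <- function(agg, dip_onset = NULL, min_span = 92) {
  stopifnot(inherits(agg, "aggregation_trace"))
  n <- length(agg$intensity)
  win <- if (is.null(dip_onset)) seq_len(n) else {
    check_that(dip_onset > 1 && dip_onset <= n, "dip_onset", "must lie inside the trace")
    seq_len(dip_onset - 1L)
  }
  span <- agg$time[win[length(win)]] - agg$time[win[1]]
  check_that(span >= min_span, "dip_onset",
             sprintf("pre-dip window spans %g min, below the %g min minimum", span, min_span))
  t_ <- agg$time[win]; y <- agg$intensity[win]
  fit <- stats::lm.fit(cbind(1, t_), y)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 pearson_r = stats::cor(t_, y),
                 fit_window = win),
            class = "linear_fit")
}

#' Root mean square deviation from a linear fit over a window
#'
#' Deviations are measured intensity minus the value predicted by the
#' regression line; the RMSD is the positive square root of their mean
#' square over the window.
#'
#' @param agg an [aggregation_trace()].
#' @param fit a [fit_pre_dip_regression()] result (or list with slope,
#'   intercept).
#' @param window integer frame indices.
#' @return Nonnegative scalar.
#' @export
rmsd <- function(agg, fit, window = fit$fit_window) {
  stopifnot(inherits(agg, "aggregation_trace"))
  check_that(length(window) >= 1, "window", "must be nonempty")
  check_that(all(window >= 1 & window <= length(agg$intensity)), "window",
             "must lie within the trace")
  dev <- agg$intensity[window] - (fit$intercept + fit$slope * agg$time[window])
  sqrt(mean(dev^2))
}

#' RMSD time course around an ATP dip and its fold changes
#'
#' `rmsd_before` is computed over `[start, onset)` against the pre-dip fit;
#' `rmsd_after` over cumulative windows `(onset, onset + k*step]` minutes,
#' `k = 1 .. horizon/step`. Fold changes are after/before and
#' `max_fold` is the largest fold within the horizon.
#'
#' @param agg an [aggregation_trace()].
#' @param fit pre-dip [fit_pre_dip_regression()] of the same trace.
#' @param dip_onset onset frame of the dip.
#' @param step window step in minutes (default 30).
#' @param horizon post-dip horizon in minutes (default 180).
#' @return List of class `rmsd_result`: rmsd_before, rmsd_after (named by
#'   window end in minutes), fold_changes, max_fold, pre_dip_span
#'   (minutes), partial (TRUE when the trace ends before the horizon).
#' @export
rmsd_timecourse <- function(agg, fit, dip_onset, step = 30, horizon = 180) {
  stopifnot(inherits(agg, "aggregation_trace"))
  check_that(horizon > 0 && step > 0 && abs(horizon / step - round(horizon / step)) < 1e-9,
             "horizon", "must be a positive multiple of `step`")
  n <- length(agg$intensity)
  check_that(dip_onset > 1 && dip_onset < n, "dip_onset", "must be an interior frame")
  before <- seq_len(dip_onset - 1L)
  rmsd_before <- rmsd(agg, fit, before)
  t_on <- agg$time[dip_onset]
  ks <- seq_len(round(horizon / step))
  after <- lapply(ks, function(k) which(agg$time > t_on & agg$time <= t_on + k * step))
  have <- vapply(after, length, integer(1)) > 0
  rmsd_after <- vapply(after[have], function(w) rmsd(agg, fit, w), numeric(1))
  names(rmsd_after) <- sprintf("after_%g_min", (ks * step)[have])
  folds <- if (rmsd_before > 0) rmsd_after / rmsd_before else rep(NA_real_, length(rmsd_after))
  partial <- agg$time[n] < t_on + horizon
  if (partial) warning(sprintf("trace ends %g min after onset, before the %g min horizon",
                               agg$time[n] - t_on, horizon))
  structure(list(rmsd_before = rmsd_before, rmsd_after = rmsd_after,
                 fold_changes = folds,
                 max_fold = if (length(folds)) max(folds) else NA_real_,
                 pre_dip_span = t_on - agg$time[1], partial = partial),
            class = "rmsd_result")
}

#' Cohort RMSD report: dip cells before/after, stable cells full-span
#'
#' @param cells list, one element per cell: `list(agg = <aggregation_trace>,
#'   dip_onset = <frame or NA>)`. Cells with an onset get the pre-dip fit
#'   and fold time course; cells without get a full-span fit and RMSD.
#' @param step,horizon passed to [rmsd_timecourse()].
#' @param min_span passed to [fit_pre_dip_regression()].
#' @return List with `dip` (data.frame cell_id, pre_dip_span, rmsd_before,
#'   max_fold and per-window folds), `stable` (cell_id, rmsd_full,
#'   pearson_r), and `summary` (mean/median max fold, fraction of dip cells
#'   with fold > 3, mean stable RMSD).
#' @export
cohort_rmsd_report <- function(cells, step = 30, horizon = 180, min_span = 92) {
  dip_rows <- list(); stable_rows <- list()
  for (cell in cells) {
    agg <- cell$agg
    onset <- cell$dip_onset
    if (!is.null(onset) && !is.na(onset)) {
      fit <- fit_pre_dip_regression(agg, onset, min_span)
      rc <- suppressWarnings(rmsd_timecourse(agg, fit, onset, step, horizon))
      row <- data.frame(cell_id = agg$cell_id, pre_dip_span = rc$pre_dip_span,
                        rmsd_before = rc$rmsd_before, max_fold = rc$max_fold)
      for (nm in names(rc$fold_changes)) row[[paste0("fold_", nm)]] <- rc$fold_changes[[nm]]
      dip_rows[[length(dip_rows) + 1L]] <- row
    } else {
      fit <- fit_pre_dip_regression(agg, NULL, min_span)
      stable_rows[[length(stable_rows) + 1L]] <- data.frame(
        cell_id = agg$cell_id, rmsd_full = rmsd(agg, fit), pearson_r = fit$pearson_r)
    }
  }
  rbind_fill <- function(rows) {
    if (!length(rows)) return(NULL)
    cols <- unique(unlist(lapply(rows, names)))
    do.call(rbind, lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] }))
  }
  dip <- rbind_fill(dip_rows)
  stable <- rbind_fill(stable_rows)
  list(dip = dip, stable = stable,
       summary = list(
         n_dip = if (is.null(dip)) 0L else nrow(dip),
         n_stable = if (is.null(stable)) 0L else nrow(stable),
         mean_max_fold = if (is.null(dip)) NA_real_ else mean(dip$max_fold),
         median_max_fold = if (is.null(dip)) NA_real_ else stats::median(dip$max_fold),
         frac_fold_gt3 = if (is.null(dip)) NA_real_ else mean(dip$max_fold > 3),
         mean_stable_rmsd = if (is.null(stable)) NA_real_ else mean(stable$rmsd_full)))
}
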