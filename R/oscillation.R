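# Period estimation for oscillatory ATP traces via the autocorrelation
# function: the apparent period is the lag of the first positive-lag ACF
# peak (the "second peak", the lag-0 peak being the first) that stands
# outside the no-correlation confidence band.

#' Sample autocorrelation of a ratio trace
#'
#' @param trace a [ratio_trace()].
#' @param max_lag largest lag in frames (default `floor(T/2)`).
#' @param detrend remove a linear trend before the ACF (default FALSE for
#'   QUEEN traces; recommended for anything with a drift, e.g. reporter
#'   traces).
#' @return List of class `acf_result`: `lags` (0..max_lag, frames),
#'   `coefficients`, `ci_halfwidth` (pointwise 95% band `1.96/sqrt(T)`),
#'   `n_effective` (T), `zero_variance` flag, `frame_interval`.
#' @export
autocorrelation <- function(trace, max_lag = NULL, detrend = FALSE) {
  stopifnot(inherits(trace, "ratio_trace"))
  x <- trace$ratio
  T_ <- length(x)
  if (is.null(max_lag)) max_lag <- floor(T_ / 2)
  check_that(max_lag >= 1 && max_lag < T_, "max_lag",
             sprintf("must satisfy 1 <= max_lag < %d", T_))
  if (detrend) x <- stats::residuals(stats::lm(x ~ seq_along(x)))
  zero_var <- stats::sd(x) == 0
  co <- if (zero_var) c(1, rep(NA_real_, max_lag)) else
    as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  structure(list(lags = 0:max_lag, coefficients = co,
                 ci_halfwidth = 1.96 / sqrt(T_), n_effective = T_,
                 zero_variance = zero_var,
                 frame_interval = trace$frame_interval),
            class = "acf_result")
}

#' Estimate the oscillation period from an ACF
#'
#' Locates the first strict local maximum at positive lag whose coefficient
#' is positive and exceeds the significance band, and converts its lag to
#' minutes. With `adjust = "bonferroni"` (default) the band is widened to
#' `qnorm(1 - alpha/2/L)/sqrt(T)` over the `L` candidate lags so the
#' family-wise false-positive rate on a white-noise trace is `alpha`;
#' `adjust = "none"` applies the pointwise 95% band at every lag. Absence
#' of a qualifying peak is a valid result (`period = NA`).
#'
#' @param acf_result an [autocorrelation()] result.
#' @param frame_interval minutes per frame (defaults to the trace's).
#' @param adjust multiplicity handling, `"bonferroni"` or `"none"`.
#' @param alpha significance level (default 0.05).
#' @return List of class `period_estimate`: `period` (minutes or NA),
#'   `peak_lag` (frames), `peak_coefficient`, `significant`,
#'   `zero_variance`.
#' @export
estimate_period <- function(acf_result, frame_interval = acf_result$frame_interval,
                            adjust = c("bonferroni", "none"), alpha = 0.05) {
  stopifnot(inherits(acf_result, "acf_result"))
  adjust <- match.arg(adjust)
  none <- structure(list(period = NA_real_, peak_lag = NA_integer_,
                         peak_coefficient = NA_real_, significant = FALSE,
                         zero_variance = isTRUE(acf_result$zero_variance)),
                    class = "period_estimate")
  if (isTRUE(acf_result$zero_variance)) return(none)
  co <- acf_result$coefficients
  L <- length(co) - 1L          # candidate positive lags
  band <- if (adjust == "bonferroni") {
    stats::qnorm(1 - alpha / 2 / L) / sqrt(acf_result$n_effective)
  } else {
    stats::qnorm(1 - alpha / 2) / sqrt(acf_result$n_effective)
  }
  # strict local maxima over +/- 1 lag among positive lags (ties -> smaller lag)
  for (k in seq_len(L - 1L)) {          # lag k, index k + 1
    ck <- co[k + 1L]
    if (ck > co[k] && ck > co[k + 2L] && ck > 0 && ck > band) {
      return(structure(list(period = k * frame_interval, peak_lag = k,
                            peak_coefficient = ck, significant = TRUE,
                            zero_variance = FALSE),
                       class = "period_estimate"))
    }
  }
  none
}

#' Per-cell period table for a cohort
#'
#' @param traces list of [ratio_trace()] objects.
#' @param max_lag,detrend,adjust,alpha passed through.
#' @return data.frame: cell_id, period_min, peak_lag, peak_r, significant.
#' @export
cohort_periods <- function(traces, max_lag = NULL, detrend = FALSE,
                           adjust = "bonferroni", alpha = 0.05) {
  do.call(rbind, lapply(traces, function(tr) {
    pe <- estimate_period(autocorrelation(tr, max_lag, detrend),
                          adjust = adjust, alpha = alpha)
    data.frame(cell_id = tr$cell_id, period_min = pe$period,
               peak_lag = pe$peak_lag, peak_r = pe$peak_coefficient,
               significant = pe$significant)
  }))
}
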