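#' Time-domain HRV: SDNN
#'
#' Sample standard deviation (n-1 denominator) of the valid R-R intervals.
#'
#' @param rr Numeric vector of R-R intervals in ms.
#' @param valid Optional logical vector of per-interval validity flags.
#' @return SDNN in ms.
#' @export
sdnn <- function(rr, valid = NULL) {
  if (!is.null(valid)) rr <- rr[valid]
  if (length(rr) < 2L)
    stop("insufficient data: need at least 2 valid intervals", call. = FALSE)
  stats::sd(rr)
}

#' Time-domain HRV: RMSSD
#'
#' Root mean square of successive R-R differences. A difference
#' `rr[i+1] - rr[i]` contributes only when both intervals are valid, so
#' differences spanning an artifact gap are excluded.
#'
#' @inheritParams sdnn
#' @return RMSSD in ms.
#' @export
rmssd <- function(rr, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(rr))
  ok <- valid[-length(valid)] & valid[-1]
  d <- diff(rr)[ok]
  if (length(d) < 1L)
    stop("insufficient data: no admissible consecutive interval pair",
         call. = FALSE)
  sqrt(mean(d^2))
}

#' Non-linear HRV: Poincare SD1/SD2
#'
#' Short- and long-term Poincare-plot descriptors. SD1 is computed from the
#' second moment of successive differences, `sqrt(mean(d^2)/2)`, so the
#' identity `SD1 = RMSSD / sqrt(2)` holds exactly; SD2 uses the population
#' variance of the intervals, `sqrt(2 * varp(rr) - mean(d^2)/2)`, floored
#' at zero.
#'
#' @inheritParams sdnn
#' @return A list with elements `sd1` and `sd2` (ms).
#' @export
poincare <- function(rr, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(rr))
  if (sum(valid) < 3L)
    stop("insufficient data: need at least 3 valid intervals", call. = FALSE)
  ok <- valid[-length(valid)] & valid[-1]
  d <- diff(rr)[ok]
  if (length(d) < 1L)
    stop("insufficient data: no admissible consecutive interval pair",
         call. = FALSE)
  msd <- mean(d^2)
  v <- rr[valid]
  varp <- mean((v - mean(v))^2)
  list(sd1 = sqrt(msd / 2), sd2 = sqrt(max(0, 2 * varp - msd / 2)))
}

#' Lomb-Scargle periodogram of an R-R tachogram
#'
#' Classical Lomb-Scargle ordinates (tau-shifted form) of the
#' mean-subtracted tachogram, evaluated on an explicit frequency grid. The
#' tachogram is unevenly sampled by nature, which this estimator handles
#' without resampling or interpolation; invalid beats are simply omitted.
#' Each raw ordinate equals half the sum-of-squares reduction of a
#' least-squares sine + cosine fit at that frequency; ordinates are scaled
#' by `2 * T / n` (T = observation span) to a one-sided spectral density in
#' ms^2/Hz, so that integrating the density across a band returns the
#' variance contributed by that band (amplitude^2 / 2 for a sinusoid).
#'
#' @param t Numeric vector of sample times in seconds (times of the beats
#'   the intervals are attached to).
#' @param rr Numeric vector of R-R intervals in ms, same length as `t`.
#' @param freq Optional frequency grid in Hz; by default
#'   `seq(0.02, 5, by = 1/(ofac * T))`.
#' @param ofac Oversampling factor of the default grid.
#' @return An object of class `"periodogram"`: list with `freq`, `power`
#'   (density, ms^2/Hz) and `normalization = "density"`.
#' @export
lomb_scargle <- function(t, rr, freq = NULL, ofac = 4) {
  stopifnot(length(t) == length(rr))
  if (length(t) < 10L)
    stop("insufficient data: need at least 10 beats", call. = FALSE)
  tspan <- max(t) - min(t)
  if (is.null(freq)) {
    freq <- seq(0.02, 5.0, by = 1 / (ofac * tspan))
    if (max(freq) < 5.0) freq <- c(freq, 5.0)
  }
  y <- rr - mean(rr)
  n <- length(y)
  p <- numeric(length(freq))
  if (stats::var(rr) > 0) {
    for (k in seq_along(freq)) {
      w <- 2 * pi * freq[k]
      tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
      ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
      p[k] <- 0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
    }
  }
  structure(list(freq = freq, power = p * 2 * tspan / n,
                 normalization = "density"),
            class = "periodogram")
}

#' Integrate spectral density over a band
#'
#' Trapezoidal integral of the periodogram density over the closed band,
#' with linear interpolation at the exact band edges.
#'
#' @param p A `"periodogram"` from [lomb_scargle()].
#' @param band Two-element numeric vector of band edges in Hz.
#' @return Band power in ms^2.
#' @export
band_power <- function(p, band) {
  stopifnot(inherits(p, "periodogram"), length(band) == 2L, band[1] < band[2])
  f <- p$freq; s <- p$power
  if (band[1] < min(f) - 1e-9 || band[2] > max(f) + 1e-9)
    stop("configuration error: band outside periodogram grid", call. = FALSE)
  inside <- f > band[1] & f < band[2]
  fe <- c(band[1], f[inside], band[2])
  se <- c(stats::approx(f, s, xout = band[1])$y, s[inside],
          stats::approx(f, s, xout = band[2])$y)
  sum(diff(fe) * (se[-1] + se[-length(se)]) / 2)
}

#' LF/HF band powers
#'
#' @param p A `"periodogram"`.
#' @param cfg An [analysis_config()] supplying the band edges.
#' @return List of class `"band_power"` with `lf`, `hf` (ms^2) and the
#'   dimensionless ratio `lf_hf`.
#' @export
band_powers <- function(p, cfg = analysis_config()) {
  lf <- band_power(p, cfg$lf_band)
  hf <- band_power(p, cfg$hf_band)
  structure(list(lf = lf, hf = hf,
                 lf_hf = if (hf > 0) lf / hf else NA_real_),
            class = "band_power")
}

#' Full HRV analysis of a beat series
#'
#' Selects the most stable segment of the configured HRV length, then
#' computes SDNN, RMSSD, Poincare SD1/SD2 and Lomb-Scargle LF/HF powers on
#' the valid beats of that segment.
#'
#' @param bs A screened [beat_series()].
#' @param cfg An [analysis_config()].
#' @return Object of class `"hrv_analysis"`: time/non-linear indices, band
#'   powers, the periodogram and the segment selection.
#' @export
hrv <- function(bs, cfg = analysis_config()) {
  seg <- select_segment(bs, cfg$hrv_segment_s, cfg$reject_ceiling)
  sub <- subset_beats(bs, seg$idx)
  int_valid <- sub$valid[-length(sub$valid)] & sub$valid[-1]
  pc <- poincare(sub$rr, int_valid)
  tv <- sub$t[-1][int_valid]          # interval attached to its ending beat
  pg <- lomb_scargle(tv, sub$rr[int_valid])
  bp <- band_powers(pg, cfg)
  structure(list(
    sdnn = sdnn(sub$rr, int_valid),
    rmssd = rmssd(sub$rr, int_valid),
    sd1 = pc$sd1, sd2 = pc$sd2,
    lf = bp$lf, hf = bp$hf, lf_hf = bp$lf_hf,
    n_beats = seg$n_beats,
    periodogram = pg, segment = seg
  ), class = "hrv_analysis")
}

#' @export
print.hrv_analysis <- function(x, ...) {
  cat("Heart rate variability\n")
  cat(sprintf("  segment: %.0f-%.0f s, %d beats\n",
              x$segment$start_s, x$segment$end_s, x$n_beats))
  cat(sprintf("  SDNN %.2f ms   RMSSD %.2f ms   SD1 %.2f ms   SD2 %.2f ms\n",
              x$sdnn, x$rmssd, x$sd1, x$sd2))
  cat(sprintf("  LF %.2f ms^2   HF %.2f ms^2   LF/HF %.3f\n",
              x$lf, x$hf, x$lf_hf))
  invisible(x)
}

#' @export
plot.periodogram <- function(x, ...) {
  graphics::plot(x$freq, x$power, type = "l", xlab = "frequency (Hz)",
                 ylab = expression(density ~ (ms^2 / Hz)),
                 main = "Lomb-Scargle periodogram", ...)
  invisible(x)
}
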