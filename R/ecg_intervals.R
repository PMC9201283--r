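#' Ensemble-averaged beat
#'
#' Aligns fixed windows around each R peak and averages them pointwise,
#' which suppresses zero-mean noise by roughly `sqrt(n)`. Beats are skipped
#' when the beat itself is invalid, when another beat falling inside the
#' window is invalid, or when the window crosses a recording edge.
#'
#' @param rec A `waveform_recording`.
#' @param peaks Beat times in seconds (from [detect_r_peaks()]).
#' @param window_ms Two-element window around the R peak in ms
#'   (default `c(-30, 80)`).
#' @param valid Optional per-beat validity flags (default all valid).
#' @param min_beats Minimum number of beats that must enter the average.
#' @return Object of class `"averaged_beat"`: `waveform` (mV), `rate` (Hz),
#'   `window_ms`, `r_offset` (sample index of the R peak within the
#'   window) and `n_beats_averaged`.
#' @export
average_beat <- function(rec, peaks, window_ms = c(-30, 80), valid = NULL,
                         min_beats = 30L) {
  stopifnot(inherits(rec, "waveform_recording"), length(window_ms) == 2L,
            window_ms[1] < 0, window_ms[2] > 0)
  fs <- rec$sampling_rate
  if (is.null(valid)) valid <- rep(TRUE, length(peaks))
  ridx <- as.integer(round((peaks - rec$start_time) * fs)) + 1L
  w0 <- as.integer(round(window_ms[1] / 1000 * fs))
  w1 <- as.integer(round(window_ms[2] / 1000 * fs))
  use <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    if (!valid[k]) next
    a <- ridx[k] + w0; b <- ridx[k] + w1
    if (a < 1L || b > length(rec$ecg)) next
    inside <- which(ridx >= a & ridx <= b)
    if (any(!valid[inside])) next
    use[k] <- TRUE
  }
  if (sum(use) < min_beats)
    stop(sprintf("insufficient data: only %d usable beats (need %d)",
                 sum(use), min_beats), call. = FALSE)
  mat <- vapply(which(use), function(k) rec$ecg[(ridx[k] + w0):(ridx[k] + w1)],
                numeric(w1 - w0 + 1L))
  structure(list(waveform = rowMeans(mat), rate = fs, window_ms = window_ms,
                 r_offset = 1L - w0, n_beats_averaged = sum(use)),
            class = "averaged_beat")
}

#' Measure the QT interval on an averaged beat
#'
#' The isoelectric baseline is the median of the pre-Q window
#' (`baseline_ms`, default -30 to -20 ms before R, the murine PR segment).
#' Q onset is found by scanning backwards from the R peak for the first
#' sample at which the derivative re-enters a band of +/-2% of the maximum
#' QRS slope around the baseline slope, sustained for at least 0.5 ms (the
#' sustain requirement keeps the momentary zero slope at the Q nadir from
#' being mistaken for onset). T end is the first sample after the T apex
#' where the waveform stays within 5% of the T amplitude of baseline for at
#' least 2 ms. Both rules are invariant to DC offset and global gain.
#'
#' @param ab An `"averaged_beat"`.
#' @param baseline_ms Pre-R window defining the isoelectric baseline (ms).
#' @param q_search_ms Pre-R window searched for Q onset (ms).
#' @param t_search_ms Post-R window searched for the T apex (ms).
#' @return List of class `"qt_measurement"`: `qt` (ms), `q_onset_ms` and
#'   `t_end_ms` (relative to the R peak), `baseline` (mV).
#' @export
measure_qt <- function(ab, baseline_ms = c(-30, -20),
                       q_search_ms = c(-30, -2), t_search_ms = c(6, Inf)) {
  stopifnot(inherits(ab, "averaged_beat"))
  fs <- ab$rate
  w <- ab$waveform
  ms2i <- function(ms) ab$r_offset + as.integer(round(ms / 1000 * fs))
  nb <- length(w)

  bwin <- max(1L, ms2i(baseline_ms[1])):min(nb, ms2i(baseline_ms[2]))
  baseline <- stats::median(w[bwin])
  noise_sd <- stats::mad(w[bwin])

  # --- T apex and T end ---------------------------------------------------
  t0 <- max(ab$r_offset + 1L, ms2i(t_search_ms[1]))
  t1 <- if (is.finite(t_search_ms[2])) min(nb, ms2i(t_search_ms[2])) else nb
  apex <- t0 - 1L + which.max(w[t0:t1] - baseline)
  t_amp <- w[apex] - baseline
  if (t_amp <= 3 * noise_sd)
    stop("unmeasurable QT: no T deflection above baseline noise",
         call. = FALSE)
  sustain_t <- max(2L, as.integer(round(0.002 * fs)))
  near <- abs(w - baseline) < 0.05 * t_amp
  t_end <- NA_integer_
  for (i in (apex + 1L):(nb - sustain_t + 1L)) {
    if (all(near[i:(i + sustain_t - 1L)])) { t_end <- i; break }
  }
  if (is.na(t_end))
    stop("unmeasurable QT: T wave does not return to the isoelectric line",
         call. = FALSE)

  # --- Q onset ------------------------------------------------------------
  d <- c(diff(w), 0) * fs / 1000                 # mV per ms
  base_slope <- stats::median(d[bwin])
  q0 <- max(1L, ms2i(q_search_ms[1]))
  q1 <- min(ab$r_offset - 1L, ms2i(q_search_ms[2]))
  band <- 0.02 * max(abs(d[q0:ab$r_offset] - base_slope))
  inband <- abs(d - base_slope) <= band
  sustain_q <- max(2L, as.integer(round(0.0005 * fs)))
  q_onset <- NA_integer_
  for (i in q1:q0) {                             # scan backwards from R
    lo <- i - sustain_q + 1L
    if (lo >= q0 && all(inband[lo:i])) { q_onset <- i; break }
  }
  if (is.na(q_onset))
    stop("unmeasurable QT: no quiescent pre-QRS baseline found",
         call. = FALSE)

  structure(list(
    qt = (t_end - q_onset) / fs * 1000,
    q_onset_ms = (q_onset - ab$r_offset) / fs * 1000,
    t_end_ms = (t_end - ab$r_offset) / fs * 1000,
    baseline = baseline
  ), class = "qt_measurement")
}

#' Mitchell's murine rate-corrected QT
#'
#' `QTc = QT / sqrt(RR / 100)` with QT and the mean R-R interval both in
#' ms; at RR = 100 ms the correction is the identity.
#'
#' @param qt QT interval in ms (> 0).
#' @param rr_mean Mean R-R interval of the same section in ms (> 0).
#' @return Object of class `"qtc_result"` with `qt`, `rr_mean` and `qtc`
#'   (all ms).
#' @examples
#' qtc(50, 121)$qtc   # 45.4545...
#' @export
qtc <- function(qt, rr_mean) {
  if (!is.numeric(qt) || !is.numeric(rr_mean) || qt <= 0 || rr_mean <= 0)
    stop("domain error: qt and rr_mean must be positive", call. = FALSE)
  structure(list(qt = qt, rr_mean = rr_mean, qtc = qt / sqrt(rr_mean / 100)),
            class = "qtc_result")
}

#' @export
print.qt_measurement <- function(x, ...) {
  cat(sprintf("QT %.2f ms (Q onset %.2f ms, T end %.2f ms relative to R)\n",
              x$qt, x$q_onset_ms, x$t_end_ms))
  invisible(x)
}

#' @export
print.qtc_result <- function(x, ...) {
  cat(sprintf("QT %.2f ms at mean RR %.1f ms -> QTc %.2f ms\n",
              x$qt, x$rr_mean, x$qtc))
  invisible(x)
}

#' @export
plot.averaged_beat <- function(x, ...) {
  ms <- ((seq_along(x$waveform)) - x$r_offset) / x$rate * 1000
  graphics::plot(ms, x$waveform, type = "l", xlab = "time from R (ms)",
                 ylab = "ECG (mV)",
                 main = sprintf("Averaged beat (n = %d)", x$n_beats_averaged),
                 ...)
  invisible(x)
}
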