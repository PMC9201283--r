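#' Detect R peaks in an ECG channel
#'
#' Pan-Tompkins-style detector: band-pass filtering to emphasise the QRS
#' complex, squaring, short moving-window integration, an adaptive amplitude
#' threshold, and refinement of each candidate to the local maximum of the
#' raw signal. The refractory period suppresses double detections; the
#' default of 40 ms suits murine heart rates (R-R around 80--150 ms).
#'
#' @param rec A `waveform_recording` (see [read_recording()] or [sim_ecg()]).
#' @param refractory_ms Minimum separation between detected peaks in ms.
#' @return Numeric vector of peak times in seconds (strictly increasing);
#'   empty, with a warning, when no plausible QRS is found.
#' @export
detect_r_peaks <- function(rec, refractory_ms = 40) {
  stopifnot(inherits(rec, "waveform_recording"))
  fs <- rec$sampling_rate
  x <- rec$ecg
  if (length(x) < 2 * fs)
    stop("insufficient data: need at least 2 s of ECG", call. = FALSE)

  if (stats::sd(x) == 0) {
    warning("flat ECG signal: no peaks detected")
    return(numeric(0))
  }

  # band-pass 10 Hz .. min(150, 0.45 fs) Hz, zero-phase
  hi <- min(150, 0.45 * fs)
  bf <- signal::butter(2, c(10, hi) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))

  # energy envelope: squared signal smoothed over ~10 ms
  w <- max(3L, as.integer(round(0.010 * fs)))
  env <- as.numeric(stats::filter(xf^2, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0

  # adaptive threshold: robust against isolated artifacts by using the
  # median of per-second envelope maxima
  nsec <- max(1L, floor(length(x) / fs))
  secmax <- vapply(seq_len(nsec), function(k) {
    i0 <- (k - 1L) * as.integer(fs) + 1L
    max(env[i0:min(length(env), i0 + as.integer(fs) - 1L)])
  }, numeric(1))
  thr <- 0.25 * stats::median(secmax)
  if (!is.finite(thr) || thr <= 0) {
    warning("no QRS energy above threshold: no peaks detected")
    return(numeric(0))
  }

  above <- env > thr
  if (!any(above)) {
    warning("no QRS energy above threshold: no peaks detected")
    return(numeric(0))
  }

  # candidate = envelope maximum of each supra-threshold region
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- mapply(function(s, e) s - 1L + which.max(env[s:e]),
                 starts[r$values], ends[r$values])

  # refine to raw-ECG local maximum within +/- 10 ms
  half <- as.integer(round(0.010 * fs))
  peaks <- vapply(cand, function(i) {
    a <- max(1L, i - half); b <- min(length(x), i + half)
    a - 1L + which.max(x[a:b])
  }, numeric(1))
  peaks <- sort(unique(peaks))

  # refractory: greedy scan keeping the larger peak of conflicting pairs
  refr <- refractory_ms / 1000 * fs
  keep <- logical(length(peaks))
  last <- -Inf
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= refr) {
      keep[i] <- TRUE
      last <- peaks[i]
    } else if (x[peaks[i]] > x[peaks[which(keep)[sum(keep)]]]) {
      keep[which(keep)[sum(keep)]] <- FALSE
      keep[i] <- TRUE
      last <- peaks[i]
    }
  }
  rec$start_time + (peaks[keep] - 1) / fs
}

#' Build a beat series from R-peak times
#'
#' Derives the R-R tachogram from successive peaks and, when an arterial
#' pressure channel is available, assigns each beat its systolic pressure as
#' the maximum of the pressure waveform over the half-open cycle
#' `[t[i], t[i+1])` anchored at the R peak. The last beat uses the samples
#' remaining to the end of the recording (NA if fewer than two).
#'
#' @param peaks Numeric vector of beat times in seconds (>= 2).
#' @param abp Optional numeric vector of arterial pressure samples (mmHg).
#' @param rate Sampling rate of `abp` in Hz (required with `abp`).
#' @param start_time Time of the first `abp` sample in seconds.
#' @param meta Optional [subject_meta()].
#' @return A [beat_series()].
#' @export
build_beat_series <- function(peaks, abp = NULL, rate = NULL, start_time = 0,
                              meta = NULL) {
  if (length(peaks) < 2L)
    stop("insufficient data: need at least 2 peaks", call. = FALSE)
  sbp <- NULL
  if (!is.null(abp)) {
    if (is.null(rate)) stop("rate required when abp is supplied", call. = FALSE)
    n <- length(peaks)
    idx <- as.integer(round((peaks - start_time) * rate)) + 1L
    bounds <- c(idx, length(abp) + 1L)
    sbp <- vapply(seq_len(n), function(i) {
      a <- max(1L, bounds[i]); b <- min(length(abp), bounds[i + 1L] - 1L)
      if (b - a < 1L) return(NA_real_)
      max(abp[a:b])
    }, numeric(1))
  }
  beat_series(peaks, sbp = sbp, meta = meta)
}

#' Screen a beat series for artifacts
#'
#' Flags as invalid every beat bounding an R-R interval outside the
#' physiological range, and the beat shared by two successive intervals
#' whose relative change exceeds the ectopy threshold. Screening only ever
#' adds invalid flags (it never rehabilitates a beat) and is idempotent.
#'
#' @param bs A [beat_series()].
#' @param cfg An [analysis_config()]; `rr_physiologic_ms` and `ectopy_frac`
#'   are used.
#' @return `bs` with updated `valid` flags; the number of newly flagged
#'   beats is attached as attribute `"n_flagged"`.
#' @export
screen_artifacts <- function(bs, cfg = analysis_config()) {
  stopifnot(inherits(bs, "beat_series"))
  n <- length(bs$t)
  rr <- bs$rr
  bad <- rep(FALSE, n)

  out <- rr < cfg$rr_physiologic_ms[1] | rr > cfg$rr_physiologic_ms[2]
  # interval i spans beats i and i+1
  bad[which(out)] <- TRUE
  bad[which(out) + 1L] <- TRUE

  if (length(rr) >= 2L) {
    jump <- abs(diff(rr)) / rr[-length(rr)] > cfg$ectopy_frac
    # transition between intervals i and i+1 shares beat i+1
    bad[which(jump) + 1L] <- TRUE
  }

  newly <- bad & bs$valid
  bs$valid <- bs$valid & !bad
  attr(bs, "n_flagged") <- sum(newly)
  bs
}

#' Select the most stable analysis segment
#'
#' Slides a window of the requested duration across the series in steps of
#' one beat and returns the window with the smallest fraction of invalid
#' beats; ties are broken by the earliest start. This automates the manual
#' selection of a stable, artifact-free section.
#'
#' @param bs A screened [beat_series()].
#' @param duration_s Segment length in seconds.
#' @param reject_ceiling Maximum tolerated invalid fraction in the best
#'   window; exceeding it is an error.
#' @return A list of class `"segment_selection"` with `start_s`, `end_s`,
#'   `n_beats`, `rejected_fraction` and the selected beat indices `idx`.
#' @export
select_segment <- function(bs, duration_s, reject_ceiling = 0.05) {
  stopifnot(inherits(bs, "beat_series"))
  t <- bs$t
  n <- length(t)
  if (t[n] - t[1] < duration_s)
    stop("insufficient data: recording shorter than requested segment",
         call. = FALSE)
  starts <- which(t + duration_s <= t[n] + 1e-9)
  best <- NULL
  for (i in starts) {
    j <- which(t >= t[i] & t < t[i] + duration_s)
    frac <- mean(!bs$valid[j])
    if (is.null(best) || frac < best$rejected_fraction - 1e-12) {
      best <- list(start_s = t[i], end_s = t[i] + duration_s,
                   n_beats = length(j), rejected_fraction = frac, idx = j)
      if (frac == 0) break  # cannot improve; earliest zero-rejection window
    }
  }
  if (best$rejected_fraction > reject_ceiling)
    stop(sprintf(
      "no admissible segment: best window rejects %.1f%% of beats (ceiling %.1f%%)",
      100 * best$rejected_fraction, 100 * reject_ceiling), call. = FALSE)
  class(best) <- "segment_selection"
  best
}

#' @export
print.segment_selection <- function(x, ...) {
  cat(sprintf("Segment %.1f-%.1f s: %d beats, %.2f%% rejected\n",
              x$start_s, x$end_s, x$n_beats, 100 * x$rejected_fraction))
  invisible(x)
}
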