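#' Find spontaneous baroreflex sequences
#'
#' Scans the beat series for maximal runs of `min_beats` or more
#' consecutive beats in which systolic pressure and the R-R interval change
#' concordantly beat over beat: SBP rising with RR lengthening (`up`) or
#' SBP falling with RR shortening (`down`). Following the study convention,
#' no magnitude thresholds are applied to SBP changes, R-R changes or the
#' correlation coefficient. A zero beat-to-beat change in either signal
#' breaks a run; two runs of opposite direction may share a pivot beat.
#' Beat `i`'s interval is the cycle starting at that beat
#' (`rr[i] = 1000*(t[i+1]-t[i])`); with `lag > 0`, `sbp[i]` is paired with
#' `rr[i + lag]`. Runs containing an invalid beat are not used.
#'
#' @param bs A [beat_series()] with systolic pressures.
#' @param min_beats Minimum beats per sequence (>= 3).
#' @param lag Beat lag between SBP and RR (0--2).
#' @return A data.frame of class `"baro_sequences"` with one row per
#'   sequence: `start` (first beat index), `length` (beats), `direction`,
#'   `slope` (ms/mmHg) and `r`. Degenerate regressions (constant SBP cannot
#'   occur inside a run) would be dropped with a message.
#' @export
find_sequences <- function(bs, min_beats = 3L, lag = 0L) {
  stopifnot(inherits(bs, "beat_series"))
  if (is.null(bs$sbp))
    stop("missing channel: beat series carries no systolic pressure",
         call. = FALSE)
  if (min_beats < 3L) stop("min_beats must be >= 3", call. = FALSE)
  n <- length(bs$t)
  # beat i usable if sbp[i], rr[i+lag] and the beats involved are valid
  usable <- function(i) {
    i >= 1L && i + lag + 1L <= n &&
      all(bs$valid[c(i, i + lag, i + lag + 1L)]) && !is.na(bs$sbp[i])
  }
  rrb <- function(i) bs$rr[i + lag]

  res <- list()
  i <- 1L
  while (i < n) {
    if (!usable(i) || !usable(i + 1L)) { i <- i + 1L; next }
    ds <- bs$sbp[i + 1L] - bs$sbp[i]
    dr <- rrb(i + 1L) - rrb(i)
    sgn <- if (ds > 0 && dr > 0) 1L else if (ds < 0 && dr < 0) -1L else 0L
    if (sgn == 0L) { i <- i + 1L; next }
    # extend the run as far as deltas keep the same concordant sign
    j <- i + 1L
    while (j < n && usable(j + 1L)) {
      ds <- bs$sbp[j + 1L] - bs$sbp[j]
      dr <- rrb(j + 1L) - rrb(j)
      s2 <- if (ds > 0 && dr > 0) 1L else if (ds < 0 && dr < 0) -1L else 0L
      if (s2 != sgn) break
      j <- j + 1L
    }
    len <- j - i + 1L
    if (len >= min_beats) {
      beats <- i:j
      fit <- sequence_slope(bs$sbp[beats], bs$rr[beats + lag])
      res[[length(res) + 1L]] <- data.frame(
        start = i, length = len,
        direction = if (sgn > 0) "up" else "down",
        slope = fit$slope, r = fit$r)
    }
    i <- j  # runs of opposite direction may share the pivot beat j
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(0), length = integer(0),
               direction = character(0), slope = numeric(0), r = numeric(0))
  class(out) <- c("baro_sequences", "data.frame")
  out
}

#' Regression slope of one baroreflex sequence
#'
#' Ordinary least-squares slope of R-R on SBP and the Pearson correlation.
#'
#' @param sbp Systolic pressures (mmHg), >= 3 values.
#' @param rr R-R intervals (ms), same length.
#' @return List with `slope` (ms/mmHg) and `r`.
#' @export
sequence_slope <- function(sbp, rr) {
  stopifnot(length(sbp) == length(rr))
  if (length(sbp) < 3L)
    stop("insufficient data: need at least 3 points", call. = FALSE)
  if (stats::var(sbp) == 0)
    stop("degenerate regressor: SBP constant within sequence", call. = FALSE)
  slope <- stats::cov(sbp, rr) / stats::var(sbp)
  r <- if (stats::var(rr) == 0) NA_real_ else stats::cor(sbp, rr)
  list(slope = slope, r = r)
}

#' Aggregate baroreflex sequences into a gain estimate
#'
#' The overall gain is the unweighted mean of all sequence slopes; up and
#' down sequences are pooled, with per-direction means also reported.
#'
#' @param seqs A `"baro_sequences"` data.frame from [find_sequences()].
#' @return Object of class `"brs_summary"`: `gain` (ms/mmHg, `NA` when no
#'   sequence was found), `n_sequences`, `n_up`, `n_down`,
#'   `gain_up`, `gain_down`.
#' @export
brs_summary <- function(seqs) {
  up <- seqs$direction == "up"
  structure(list(
    gain = if (nrow(seqs)) mean(seqs$slope) else NA_real_,
    n_sequences = nrow(seqs),
    n_up = sum(up), n_down = sum(!up),
    gain_up = if (any(up)) mean(seqs$slope[up]) else NA_real_,
    gain_down = if (any(!up)) mean(seqs$slope[!up]) else NA_real_
  ), class = "brs_summary")
}

#' Sequence-method baroreflex sensitivity of a beat series
#'
#' Selects the most stable segment of the configured BRS length, detects
#' spontaneous sequences among its valid beats and aggregates their slopes.
#'
#' @param bs A screened [beat_series()] with systolic pressures.
#' @param cfg An [analysis_config()].
#' @return Object of class `"brs_estimate"` wrapping the `"brs_summary"`,
#'   the per-sequence table and the segment selection.
#' @export
brs <- function(bs, cfg = analysis_config()) {
  seg <- select_segment(bs, cfg$brs_segment_s, cfg$reject_ceiling)
  sub <- subset_beats(bs, seg$idx)
  seqs <- find_sequences(sub, cfg$min_sequence_beats, cfg$sequence_lag_beats)
  structure(list(summary = brs_summary(seqs), sequences = seqs,
                 segment = seg),
            class = "brs_estimate")
}

#' @export
print.brs_summary <- function(x, ...) {
  if (x$n_sequences == 0L) {
    cat("Baroreflex sensitivity: no sequences found\n")
  } else {
    cat(sprintf(
      "Baroreflex sensitivity: gain %.3f ms/mmHg over %d sequences (%d up / %d down)\n",
      x$gain, x$n_sequences, x$n_up, x$n_down))
  }
  invisible(x)
}

#' @export
print.brs_estimate <- function(x, ...) {
  print(x$summary)
  cat(sprintf("  segment %.0f-%.0f s\n", x$segment$start_s, x$segment$end_s))
  invisible(x)
}

#' @export
coef.brs_estimate <- function(object, ...) c(gain = object$summary$gain)

#' @export
plot.brs_estimate <- function(x, ...) {
  if (nrow(x$sequences) == 0L) {
    graphics::plot.new(); graphics::title("No baroreflex sequences")
    return(invisible(x))
  }
  graphics::hist(x$sequences$slope, breaks = "FD",
                 xlab = "sequence slope (ms/mmHg)",
                 main = "Baroreflex sequence slopes", ...)
  graphics::abline(v = x$summary$gain, col = 2, lwd = 2)
  invisible(x)
}
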