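#' Beat series: the pipeline's central currency
#'
#' A `beat_series` holds per-beat R-peak times (s, strictly increasing), the
#' derived R-R tachogram (ms), optional beat-wise systolic pressure (mmHg)
#' and per-beat validity flags. The interval convention is
#' `rr[i] = 1000 * (t[i + 1] - t[i])`, i.e. `rr[i]` is the cycle *starting*
#' at beat `i`, so `rr` has one element fewer than `t`.
#'
#' @param t Numeric vector of beat times in seconds, strictly increasing.
#' @param sbp Optional numeric vector of per-beat systolic pressures in
#'   mmHg, one value per beat.
#' @param valid Optional logical vector of per-beat validity flags
#'   (default all `TRUE`).
#' @param meta Optional [subject_meta()] attached to the series.
#'
#' @return An object of class `"beat_series"` with elements `t`, `rr`,
#'   `sbp` (or `NULL`), `valid` and `meta`.
#' @examples
#' bs <- beat_series(c(0, 0.12, 0.24))
#' bs$rr   # 120 120
#' @export
beat_series <- function(t, sbp = NULL, valid = NULL, meta = NULL) {
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2L) stop("insufficient data: need at least 2 beats", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("integrity error: beat times must be strictly increasing", call. = FALSE)
  if (!is.null(sbp)) {
    sbp <- as.numeric(sbp)
    if (length(sbp) != n)
      stop("integrity error: sbp must hold one value per beat", call. = FALSE)
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n)
    stop("integrity error: valid must hold one flag per beat", call. = FALSE)
  structure(list(t = t, rr = 1000 * diff(t), sbp = sbp,
                 valid = as.logical(valid), meta = meta),
            class = "beat_series")
}

#' Number of beats in a series
#' @param bs A [beat_series()].
#' @return Integer beat count.
#' @export
n_beats <- function(bs) length(bs$t)

# internal consistency check used by tests and after mutating operations
check_beat_series <- function(bs) {
  stopifnot(inherits(bs, "beat_series"))
  if (any(abs(bs$rr - 1000 * diff(bs$t)) > 1e-6))  # 1e-9 s in ms
    stop("integrity error: rr inconsistent with beat times", call. = FALSE)
  invisible(TRUE)
}

# restrict a beat series to beats idx (contiguous, increasing)
subset_beats <- function(bs, idx) {
  beat_series(bs$t[idx],
              sbp = if (!is.null(bs$sbp)) bs$sbp[idx],
              valid = bs$valid[idx], meta = bs$meta)
}

#' @export
print.beat_series <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("Beat series: %d beats over %.1f s\n", n, x$t[n] - x$t[1]))
  cat(sprintf("  mean RR %.1f ms (HR %.0f bpm), %d beat(s) flagged invalid\n",
              mean(x$rr), 60000 / mean(x$rr), sum(!x$valid)))
  if (!is.null(x$sbp))
    cat(sprintf("  SBP %.1f +/- %.1f mmHg\n", mean(x$sbp), stats::sd(x$sbp)))
  if (!is.null(x$meta))
    cat(sprintf("  subject %s (%s %s, %d mo)\n", x$meta$subject_id,
                x$meta$genotype, x$meta$sex, x$meta$age_group))
  invisible(x)
}

#' @export
plot.beat_series <- function(x, ...) {
  graphics::plot(x$t[-length(x$t)], x$rr, type = "l", xlab = "time (s)",
                 ylab = "R-R interval (ms)", main = "Tachogram", ...)
  bad <- !x$valid[-length(x$valid)]
  if (any(bad))
    graphics::points(x$t[-length(x$t)][bad], x$rr[bad], col = 2, pch = 4)
  invisible(x)
}

#' @export
as.data.frame.beat_series <- function(x, ...) {
  n <- length(x$t)
  data.frame(t_s = x$t,
             rr_ms = c(x$rr, NA_real_),
             sbp_mmHg = if (is.null(x$sbp)) NA_real_ else x$sbp,
             valid = x$valid)
}
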