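# Generators for ground-truth murine cardiovascular data. Each generator is
# a pure function of its parameters and seed, and attaches a "truth" record
# sufficient to predict every downstream statistic.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  expr
}

#' Simulate a modulated murine R-R tachogram
#'
#' Beat times are built iteratively (integral-pulse style):
#' `t[k+1] = t[k] + rr(t[k]) / 1000` with
#' `rr(t) = mean_rr + lf_amp*sin(2*pi*lf_freq*t) + hf_amp*sin(2*pi*hf_freq*t) + noise`,
#' so the tachogram is natively unevenly sampled. Defaults sit at murine
#' physiology: mean RR 120 ms with LF modulation at 0.4 Hz and HF
#' modulation at 2.5 Hz, inside the study's LF and HF bands. The analytic
#' band power of each sinusoid is `amp^2 / 2`.
#'
#' @param duration_s Recording length in seconds.
#' @param mean_rr Mean R-R interval in ms.
#' @param lf_freq,lf_amp LF modulation frequency (Hz) and amplitude (ms).
#' @param hf_freq,hf_amp HF modulation frequency (Hz) and amplitude (ms).
#' @param rr_noise_sd Additive Gaussian R-R noise SD in ms.
#' @param seed Optional integer seed (the generator is deterministic given
#'   the seed).
#' @param meta Optional [subject_meta()].
#' @return A [beat_series()] with attribute `"truth"` (parameters plus
#'   analytic `lf_power` and `hf_power` in ms^2).
#' @export
sim_rr_series <- function(duration_s = 180, mean_rr = 120,
                          lf_freq = 0.4, lf_amp = 4,
                          hf_freq = 2.5, hf_amp = 5,
                          rr_noise_sd = 1, seed = NULL, meta = NULL) {
  stopifnot(duration_s > 0, mean_rr > 0, lf_amp >= 0, hf_amp >= 0,
            rr_noise_sd >= 0)
  nyq <- 1000 / (2 * mean_rr)
  if (lf_freq <= 0 || hf_freq <= 0 || lf_freq >= nyq || hf_freq >= nyq)
    stop("parameter error: modulation frequencies must lie in (0, Nyquist)",
         call. = FALSE)
  if (lf_amp + hf_amp + 5 * rr_noise_sd >= mean_rr)
    stop("parameter error: modulation would yield non-positive intervals",
         call. = FALSE)
  with_seed(seed, {
    nmax <- ceiling(duration_s * 1000 / (mean_rr - lf_amp - hf_amp)) + 2L
    noise <- if (rr_noise_sd > 0) stats::rnorm(nmax, 0, rr_noise_sd) else
      numeric(nmax)
    t <- numeric(nmax)
    k <- 1L
    while (t[k] <= duration_s) {
      rrk <- mean_rr + lf_amp * sin(2 * pi * lf_freq * t[k]) +
        hf_amp * sin(2 * pi * hf_freq * t[k]) + noise[k]
      t[k + 1L] <- t[k] + rrk / 1000
      k <- k + 1L
    }
    bs <- beat_series(t[seq_len(k)], meta = meta)
    attr(bs, "truth") <- list(
      mean_rr = mean_rr, lf_freq = lf_freq, lf_amp = lf_amp,
      hf_freq = hf_freq, hf_amp = hf_amp, rr_noise_sd = rr_noise_sd,
      lf_power = lf_amp^2 / 2, hf_power = hf_amp^2 / 2, seed = seed)
    bs
  })
}

default_ramp_spec <- function() {
  list(c(6, 1, 2), c(3, 0, 0), c(6, -1, 2), c(3, 0, 0))
}

#' Couple systolic pressure to a beat series with known baroreflex gain
#'
#' Writes a systolic-pressure profile over the beats following
#' `ramp_spec` (repeated cyclically, re-centred on `mean_sbp`), then
#' rewrites the R-R intervals as the linear baroreflex response
#' `rr[k] = brs_gain * sbp[k] + intercept + noise`, with the intercept
#' chosen to preserve the series' mean R-R interval, and rebuilds beat
#' times from the new intervals. Each programmed ramp is annotated with its
#' beat range, so sequence detection can be checked against ground truth.
#' The default ramp pattern is a 6-beat rise of 2 mmHg per beat and a
#' matching 6-beat fall, separated by 3-beat plateaus (plateaus break
#' sequence runs, keeping programmed ramps and detected sequences aligned).
#'
#' @param bs A [beat_series()] (typically from [sim_rr_series()]).
#' @param brs_gain Programmed baroreflex gain in ms/mmHg.
#' @param mean_sbp Mean systolic pressure in mmHg.
#' @param ramp_spec List of `c(length_beats, direction, step_mmHg)` triples;
#'   direction is +1 (rise), -1 (fall) or 0 (plateau).
#' @param sbp_noise_sd Additive SBP noise SD in mmHg.
#' @param rr_noise_sd Additive R-R noise SD in ms around the linear
#'   coupling.
#' @param seed Optional integer seed.
#' @return A [beat_series()] with `sbp`, and attribute `"truth"` holding
#'   the gain and a data.frame `ramps` (`start`, `end`, `direction`).
#' @export
sim_coupled_sbp <- function(bs, brs_gain = 2, mean_sbp = 110,
                            ramp_spec = default_ramp_spec(),
                            sbp_noise_sd = 0, rr_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(bs, "beat_series"), brs_gain > 0, mean_sbp > 0)
  n <- length(bs$t)
  lens <- vapply(ramp_spec, `[`, numeric(1), 1)
  if (any(lens < 1)) stop("parameter error: ramp lengths must be >= 1",
                          call. = FALSE)
  if (lens[1] > n)
    stop("parameter error: ramp spec longer than series", call. = FALSE)
  with_seed(seed, {
    sbp <- numeric(0)
    ramps <- list()
    level <- 0
    done <- FALSE
    while (!done) {
      for (item in ramp_spec) {
        L <- as.integer(item[1]); dir <- item[2]; step <- item[3]
        start <- length(sbp) + 1L
        # a ramp that cannot complete within the drivable beats (1..n-1,
        # the beats that carry an interval) is rendered as a plateau so
        # that annotated ramps and detectable runs coincide exactly
        if (dir != 0 && start + L - 1L > n - 1L) dir <- 0
        seg <- if (dir == 0) rep(level, L) else level + dir * step * seq_len(L)
        sbp <- c(sbp, seg)
        level <- sbp[length(sbp)]
        if (dir != 0)
          # the annotated range is the concordant run the ramp induces: the
          # preceding beat (plateau level or previous ramp's end) anchors
          # the first beat-to-beat change and belongs to the run
          ramps[[length(ramps) + 1L]] <- data.frame(
            start = max(1L, start - 1L), end = start + L - 1L,
            direction = if (dir > 0) "up" else "down")
        if (length(sbp) >= n) { done <- TRUE; break }
      }
    }
    sbp <- sbp[seq_len(n)] - mean(sbp[seq_len(n)]) + mean_sbp
    if (sbp_noise_sd > 0) sbp <- sbp + stats::rnorm(n, 0, sbp_noise_sd)

    intercept <- mean(bs$rr) - brs_gain * mean(sbp[-n])
    rr_new <- brs_gain * sbp[-n] + intercept
    if (rr_noise_sd > 0) rr_new <- rr_new + stats::rnorm(n - 1L, 0, rr_noise_sd)
    if (any(rr_new <= 0))
      stop("parameter error: coupling yields non-positive intervals",
           call. = FALSE)
    t_new <- bs$t[1] + c(0, cumsum(rr_new)) / 1000

    out <- beat_series(t_new, sbp = sbp, meta = bs$meta)
    ramps <- do.call(rbind, ramps)
    ramps <- ramps[ramps$end <= n, , drop = FALSE]
    attr(out, "truth") <- list(brs_gain = brs_gain, mean_sbp = mean_sbp,
                               intercept = intercept, ramps = ramps,
                               sbp_noise_sd = sbp_noise_sd,
                               rr_noise_sd = rr_noise_sd, seed = seed)
    out
  })
}

# Gaussian bump helper: amplitude amp, centre c_ms, width sd_ms, on time
# axis ms (vectorised over ms)
.gauss <- function(ms, c_ms, sd_ms, amp) amp * exp(-0.5 * ((ms - c_ms) / sd_ms)^2)

# analytic PQRST template on a ms axis relative to the R peak; Q onset is
# fixed at -q_offset_ms and the T centre placed so that the 5%-amplitude
# return crossing lands at (qt_true - q_offset_ms) after R
ecg_template <- function(ms, qt_true, q_offset_ms = 8) {
  t_sd <- 6
  t_centre <- (qt_true - q_offset_ms) - t_sd * sqrt(2 * log(20))
  .gauss(ms, -36, 2.0, 0.08) +          # P
    .gauss(ms, -5, 1.2, -0.12) +        # Q
    .gauss(ms, 0, 1.3, 1.00) +          # R
    .gauss(ms, 4, 1.2, -0.25) +         # S
    .gauss(ms, t_centre, t_sd, 0.30)    # T
}

#' Synthesise an ECG (and optional pressure) waveform from a beat series
#'
#' Renders one PQRST complex per beat from Gaussian kernels (R amplitude
#' 1 mV) with the Q onset and T end placed so the template's true QT equals
#' `qt_true`, plus optional additive Gaussian noise. When the beat series
#' carries systolic pressures, an arterial-pressure channel is rendered
#' whose per-cycle maximum equals the programmed SBP.
#'
#' @param bs A [beat_series()].
#' @param qt_true Programmed QT interval in ms.
#' @param sampling_rate Sampling rate in Hz (study convention 4000).
#' @param ecg_noise_sd Additive ECG noise SD in mV.
#' @param seed Optional integer seed.
#' @return A `waveform_recording` with attribute `"truth"` (`qt_true`,
#'   `q_offset_ms`, per-beat R times, programmed SBP).
#' @export
sim_ecg <- function(bs, qt_true = 45, sampling_rate = 4000,
                    ecg_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(bs, "beat_series"), qt_true > 0, sampling_rate > 0)
  if (length(bs$t) < 1L) stop("empty beat series", call. = FALSE)
  if (qt_true >= mean(bs$rr))
    stop("parameter error: qt_true must be below the mean R-R interval",
         call. = FALSE)
  with_seed(seed, {
    fs <- sampling_rate
    t_end <- bs$t[length(bs$t)] + 0.1
    ns <- as.integer(ceiling((t_end - bs$t[1]) * fs)) + 1L
    tt <- bs$t[1] + (seq_len(ns) - 1) / fs
    ecg <- numeric(ns)
    for (tk in bs$t) {
      lo <- max(1L, as.integer(floor((tk - bs$t[1] - 0.05) * fs)))
      hi <- min(ns, as.integer(ceiling((tk - bs$t[1] + 0.09) * fs)) + 1L)
      idx <- lo:hi
      ecg[idx] <- ecg[idx] + ecg_template((tt[idx] - tk) * 1000, qt_true)
    }
    if (ecg_noise_sd > 0) ecg <- ecg + stats::rnorm(ns, 0, ecg_noise_sd)

    abp <- NULL
    if (!is.null(bs$sbp)) {
      abp <- numeric(ns)
      bounds <- c(bs$t, t_end)
      for (k in seq_along(bs$t)) {
        lo <- as.integer(floor((bounds[k] - bs$t[1]) * fs)) + 1L
        hi <- min(ns, as.integer(ceiling((bounds[k + 1L] - bs$t[1]) * fs)))
        idx <- lo:hi
        phase <- (tt[idx] - bounds[k]) / (bounds[k + 1L] - bounds[k])
        dbp <- bs$sbp[k] - 30
        abp[idx] <- dbp + (bs$sbp[k] - dbp) *
          exp(-0.5 * ((phase - 0.3) / 0.12)^2)
      }
    }
    rec <- waveform_recording(sampling_rate = fs, ecg = ecg, abp = abp,
                              start_time = bs$t[1], meta = bs$meta)
    attr(rec, "truth") <- list(qt_true = qt_true, q_offset_ms = 8,
                               r_times = bs$t, sbp = bs$sbp, seed = seed)
    rec
  })
}

#' Simulate a 2x2x2 group-structured outcome table
#'
#' Cell means follow a fully crossed factorial model on +/-1 codes
#' (`WT`/`M`/`6 mo` coded -1): effect coefficients are specified as the
#' *difference* between the two levels of each factor (and analogously for
#' interactions), with Gaussian residuals. Default cell sizes mirror the
#' study's group sizes (8, 15, 12, 10, 11, 23, 12, 17 in the order
#' WT/M/6, WT/M/12, WT/F/6, WT/F/12, TG/M/6, TG/M/12, TG/F/6, TG/F/12).
#'
#' @param grand_mean Grand mean of the outcome.
#' @param genotype_eff,sex_eff,age_eff Main-effect level differences.
#' @param gs_int,ga_int,sa_int,gsa_int Interaction coefficients (same
#'   difference scale).
#' @param residual_sd Residual SD (> 0).
#' @param n_per_cell Cell sizes: one integer or eight (order above).
#' @param outcome Name of the outcome column.
#' @param seed Optional integer seed.
#' @return Data frame (`genotype`, `sex`, `age_group`, outcome) with
#'   attribute `"truth"` holding programmed cell means and effects.
#' @export
sim_group_data <- function(grand_mean = 10, genotype_eff = 0, sex_eff = 0,
                           age_eff = 0, gs_int = 0, ga_int = 0, sa_int = 0,
                           gsa_int = 0, residual_sd = 1,
                           n_per_cell = c(8, 15, 12, 10, 11, 23, 12, 17),
                           outcome = "outcome", seed = NULL) {
  stopifnot(residual_sd > 0)
  if (length(n_per_cell) == 1L) n_per_cell <- rep(n_per_cell, 8L)
  stopifnot(length(n_per_cell) == 8L, all(n_per_cell >= 2))
  grid <- expand.grid(age_group = c("6", "12"), sex = c("M", "F"),
                      genotype = c("WT", "TG"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "sex", "age_group")]
  g <- ifelse(grid$genotype == "TG", 1, -1)
  s <- ifelse(grid$sex == "F", 1, -1)
  a <- ifelse(grid$age_group == "12", 1, -1)
  cell_mean <- grand_mean + (genotype_eff * g + sex_eff * s + age_eff * a +
    gs_int * g * s + ga_int * g * a + sa_int * s * a +
    gsa_int * g * s * a) / 2
  with_seed(seed, {
    rows <- lapply(seq_len(8L), function(i) {
      data.frame(genotype = grid$genotype[i], sex = grid$sex[i],
                 age_group = grid$age_group[i],
                 y = cell_mean[i] + stats::rnorm(n_per_cell[i], 0, residual_sd))
    })
    out <- do.call(rbind, rows)
    names(out)[4] <- outcome
    attr(out, "truth") <- list(cell_means = cbind(grid, mean = cell_mean),
                               grand_mean = grand_mean,
                               effects = c(genotype = genotype_eff,
                                           sex = sex_eff, age = age_eff,
                                           gs = gs_int, ga = ga_int,
                                           sa = sa_int, gsa = gsa_int),
                               residual_sd = residual_sd,
                               n_per_cell = n_per_cell, seed = seed)
    out
  })
}
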