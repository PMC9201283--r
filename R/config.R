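#' Analysis configuration
#'
#' Bundles every tunable of the pipeline: segment lengths, murine spectral
#' bands, sequence-method settings and artifact-screening bounds. Defaults
#' reproduce the study conventions: 3-min heart-rate-variability / ECG
#' sections and 5-min baroreflex sections taken from a 15-min recording,
#' LF 0.10--1.00 Hz and HF 1.00--5.00 Hz.
#'
#' @param hrv_segment_s Length of the HRV/ECG analysis section in seconds.
#' @param brs_segment_s Length of the baroreflex analysis section in seconds.
#' @param lf_band,hf_band Two-element numeric vectors, band edges in Hz.
#'   The LF upper edge must not exceed the HF lower edge.
#' @param min_sequence_beats Minimum beats in a baroreflex sequence (>= 3).
#' @param sequence_lag_beats Beat lag between SBP and the R-R interval it is
#'   paired with (0--2; 0 pairs each systolic value with the interval that
#'   starts at the same beat).
#' @param rr_physiologic_ms Two-element vector, admissible murine R-R range
#'   in ms; beats bounding intervals outside it are flagged as artifacts.
#' @param ectopy_frac Maximum admissible relative beat-to-beat R-R change
#'   before the shared beat is flagged ectopic.
#' @param reject_ceiling Maximum fraction of flagged beats tolerated in a
#'   selected analysis segment.
#' @param refractory_ms R-peak detector refractory period in ms.
#' @param seed Optional integer seed recorded in the configuration (used by
#'   pipeline-level simulation helpers).
#'
#' @return An object of class `"analysis_config"` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$lf_band
#' @export
analysis_config <- function(hrv_segment_s = 180,
                            brs_segment_s = 300,
                            lf_band = c(0.10, 1.00),
                            hf_band = c(1.00, 5.00),
                            min_sequence_beats = 3L,
                            sequence_lag_beats = 0L,
                            rr_physiologic_ms = c(50, 250),
                            ectopy_frac = 0.30,
                            reject_ceiling = 0.05,
                            refractory_ms = 40,
                            seed = NULL) {
  stopifnot(hrv_segment_s > 0, brs_segment_s > 0,
            length(lf_band) == 2L, length(hf_band) == 2L,
            length(rr_physiologic_ms) == 2L)
  if (lf_band[1] >= lf_band[2] || hf_band[1] >= hf_band[2])
    stop("band lower edge must be below its upper edge", call. = FALSE)
  if (lf_band[2] > hf_band[1])
    stop("LF upper edge must not exceed HF lower edge", call. = FALSE)
  if (min_sequence_beats < 3L)
    stop("min_sequence_beats must be >= 3", call. = FALSE)
  if (sequence_lag_beats < 0L || sequence_lag_beats > 2L)
    stop("sequence_lag_beats must be in 0..2", call. = FALSE)
  if (rr_physiologic_ms[1] <= 0 || rr_physiologic_ms[1] >= rr_physiologic_ms[2])
    stop("rr_physiologic_ms must be an increasing positive pair", call. = FALSE)
  if (ectopy_frac <= 0 || reject_ceiling <= 0 || reject_ceiling >= 1)
    stop("ectopy_frac must be > 0 and reject_ceiling in (0, 1)", call. = FALSE)
  structure(list(
    hrv_segment_s = hrv_segment_s,
    brs_segment_s = brs_segment_s,
    lf_band = as.numeric(lf_band),
    hf_band = as.numeric(hf_band),
    min_sequence_beats = as.integer(min_sequence_beats),
    sequence_lag_beats = as.integer(sequence_lag_beats),
    rr_physiologic_ms = as.numeric(rr_physiologic_ms),
    ectopy_frac = ectopy_frac,
    reject_ceiling = reject_ceiling,
    refractory_ms = refractory_ms,
    seed = seed
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  HRV/ECG section : %g s   BRS section: %g s\n",
              x$hrv_segment_s, x$brs_segment_s))
  cat(sprintf("  LF band         : %.2f-%.2f Hz   HF band: %.2f-%.2f Hz\n",
              x$lf_band[1], x$lf_band[2], x$hf_band[1], x$hf_band[2]))
  cat(sprintf("  Sequences       : >= %d beats, lag %d\n",
              x$min_sequence_beats, x$sequence_lag_beats))
  cat(sprintf("  RR bounds       : %g-%g ms, ectopy > %.0f%%, reject ceiling %.0f%%\n",
              x$rr_physiologic_ms[1], x$rr_physiologic_ms[2],
              100 * x$ectopy_frac, 100 * x$reject_ceiling))
  invisible(x)
}

#' Subject metadata for the factorial design
#'
#' @param subject_id Opaque subject label.
#' @param genotype `"WT"` or `"TG"` (transgenic).
#' @param sex `"M"` or `"F"`.
#' @param age_group `6` or `12` (months).
#' @return A list of class `"subject_meta"`.
#' @export
subject_meta <- function(subject_id, genotype, sex, age_group) {
  genotype <- match.arg(as.character(genotype), c("WT", "TG"))
  sex <- match.arg(as.character(sex), c("M", "F"))
  age_group <- as.integer(age_group)
  if (!age_group %in% c(6L, 12L))
    stop("age_group must be 6 or 12 (months)", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), genotype = genotype,
                 sex = sex, age_group = age_group),
            class = "subject_meta")
}
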