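#' Two-channel waveform recording
#'
#' Container for sampled ECG (mV) and optional arterial blood pressure
#' (mmHg) sharing one clock. All channels must have the same length;
#' `duration = n_samples / sampling_rate`.
#'
#' @param sampling_rate Sampling rate in Hz (> 0; study convention 4000).
#' @param ecg Numeric vector of ECG samples in mV.
#' @param abp Optional numeric vector of pressure samples in mmHg, same
#'   length as `ecg`.
#' @param start_time Time of the first sample in seconds.
#' @param meta Optional [subject_meta()].
#' @return Object of class `"waveform_recording"`.
#' @export
waveform_recording <- function(sampling_rate, ecg, abp = NULL,
                               start_time = 0, meta = NULL) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("format error: sampling_rate must be positive", call. = FALSE)
  ecg <- as.numeric(ecg)
  if (!is.null(abp)) {
    abp <- as.numeric(abp)
    if (length(abp) != length(ecg))
      stop("integrity error: channel length mismatch", call. = FALSE)
  }
  structure(list(sampling_rate = sampling_rate, ecg = ecg, abp = abp,
                 start_time = start_time, meta = meta),
            class = "waveform_recording")
}

#' @export
print.waveform_recording <- function(x, ...) {
  cat(sprintf("Waveform recording: %.1f s at %g Hz (%d samples)\n",
              length(x$ecg) / x$sampling_rate, x$sampling_rate,
              length(x$ecg)))
  cat(sprintf("  channels: ecg (mV)%s\n",
              if (is.null(x$abp)) "" else ", abp (mmHg)"))
  if (!is.null(x$meta))
    cat(sprintf("  subject %s (%s %s, %d mo)\n", x$meta$subject_id,
                x$meta$genotype, x$meta$sex, x$meta$age_group))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `waveform_recording`.
#' @return Numeric duration.
#' @export
duration <- function(rec) length(rec$ecg) / rec$sampling_rate

#' Write a recording as delimited text
#'
#' Native interchange format: a one-line JSON header carrying the sampling
#' rate, start time, units, channel names and subject metadata, followed by
#' tab-separated sample rows in physical units.
#'
#' @param rec A `waveform_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "waveform_recording"))
  channels <- c("ecg", if (!is.null(rec$abp)) "abp")
  header <- jsonlite::toJSON(list(
    sampling_rate = rec$sampling_rate,
    start_time = rec$start_time,
    channels = channels,
    units = list(ecg = "mV", abp = "mmHg")[channels],
    subject = if (!is.null(rec$meta)) unclass(rec$meta)
  ), auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", header), con)
  dat <- if (is.null(rec$abp)) cbind(ecg = rec$ecg) else
    cbind(ecg = rec$ecg, abp = rec$abp)
  utils::write.table(format(dat, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_recording_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop("format error: missing JSON header line (sampling rate unknown)",
         call. = FALSE)
  hd <- jsonlite::fromJSON(sub("^#", "", first))
  if (is.null(hd$sampling_rate))
    stop("format error: header declares no sampling rate", call. = FALSE)
  dat <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!"ecg" %in% names(dat))
    stop("format error: no ecg channel", call. = FALSE)
  meta <- if (!is.null(hd$subject))
    subject_meta(hd$subject$subject_id, hd$subject$genotype, hd$subject$sex,
                 hd$subject$age_group)
  waveform_recording(hd$sampling_rate, dat$ecg,
                     abp = if ("abp" %in% names(dat)) dat$abp,
                     start_time = if (is.null(hd$start_time)) 0 else hd$start_time,
                     meta = meta)
}

# waveform-database-style paired header/sample files (read-only, text
# samples). Header line 1: "<record> <nsig> <fs> <nsamp>"; then one line
# per signal: "<samples-file> <units> <label>". Sample file: whitespace-
# separated matrix, one column per signal, physical units.
read_recording_wfdb <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 3L || is.na(suppressWarnings(as.numeric(hdr[3]))))
    stop("format error: header declares no sampling rate", call. = FALSE)
  nsig <- as.integer(hdr[2]); fs <- as.numeric(hdr[3])
  sig <- do.call(rbind, lapply(lines[1L + seq_len(nsig)], function(l)
    strsplit(trimws(l), "\\s+")[[1]][1:3]))
  datafile <- file.path(dirname(path), sig[1, 1])
  dat <- as.matrix(utils::read.table(datafile, header = FALSE))
  if (ncol(dat) != nsig)
    stop("integrity error: sample columns do not match declared signals",
         call. = FALSE)
  labels <- tolower(sig[, 3])
  if (!"ecg" %in% labels) stop("format error: no ecg channel", call. = FALSE)
  waveform_recording(fs, dat[, match("ecg", labels)],
                     abp = if ("abp" %in% labels) dat[, match("abp", labels)])
}

#' Read a recording from disk
#'
#' @param path File path: the native delimited-text format (JSON header
#'   line + sample table) or a waveform-database-style text header naming
#'   a samples file.
#' @param format `"csv"` (native) or `"wfdb"`; guessed from the file when
#'   omitted.
#' @return A `waveform_recording`.
#' @export
read_recording <- function(path, format = c("auto", "csv", "wfdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.hea$", path)) "wfdb" else "csv"
  switch(format, csv = read_recording_csv(path),
         wfdb = read_recording_wfdb(path))
}

#' Write a beat table as delimited text
#'
#' Tab-separated columns `t_s`, `rr_ms` (interval starting at the beat; NA
#' on the last row), `sbp_mmHg` and `valid`.
#'
#' @param bs A [beat_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beat_table <- function(bs, path) {
  stopifnot(inherits(bs, "beat_series"))
  df <- as.data.frame(bs)
  df$t_s <- sprintf("%.15g", df$t_s)
  df$rr_ms <- ifelse(is.na(df$rr_ms), "NA", sprintf("%.15g", df$rr_ms))
  df$sbp_mmHg <- ifelse(is.na(df$sbp_mmHg), "NA", sprintf("%.15g", df$sbp_mmHg))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beat table
#'
#' @param path Path to a tab-separated table with columns `t_s`, `rr_ms`
#'   and optionally `sbp_mmHg` and `valid`. Beat times must be strictly
#'   increasing; intervals are rebuilt from the times.
#' @return A [beat_series()].
#' @export
read_beat_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("t_s", "rr_ms") %in% names(df)))
    stop("format error: beat table needs t_s and rr_ms columns", call. = FALSE)
  if (any(diff(df$t_s) <= 0))
    stop("integrity error: beat times must be strictly increasing",
         call. = FALSE)
  sbp <- if ("sbp_mmHg" %in% names(df) && !all(is.na(df$sbp_mmHg)))
    df$sbp_mmHg
  valid <- if ("valid" %in% names(df)) as.logical(df$valid)
  beat_series(df$t_s, sbp = sbp, valid = valid)
}
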