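#' Analyse one subject
#'
#' Runs the full per-subject chain: for a waveform recording, R-peak
#' detection and beat-series construction (with beat-wise systolic
#' pressures when a pressure channel is present); then artifact screening,
#' HRV on the most stable HRV-length segment, sequence-method BRS on the
#' most stable BRS-length segment, and QT/QTc from the ensemble-averaged
#' beat of the HRV segment (waveform inputs only). Stages that cannot run
#' (missing pressure channel, too little data) yield `NA` columns and a log
#' entry rather than an error.
#'
#' @param input A `waveform_recording` or [beat_series()].
#' @param cfg An [analysis_config()].
#' @return List of class `"subject_result"` with `row` (one-row
#'   data.frame: SDNN, RMSSD, SD1, SD2, LF, HF, LF/HF, BRS, QT, QTc),
#'   component objects and a character `log`.
#' @export
analyze_subject <- function(input, cfg = analysis_config()) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  meta <- input$meta

  if (inherits(input, "waveform_recording")) {
    peaks <- detect_r_peaks(input, cfg$refractory_ms)
    note("detected %d R peaks", length(peaks))
    bs <- build_beat_series(peaks, abp = input$abp,
                            rate = input$sampling_rate,
                            start_time = input$start_time, meta = meta)
    rec <- input
  } else if (inherits(input, "beat_series")) {
    bs <- input
    rec <- NULL
    note("beat-table input: %d beats", length(bs$t))
  } else stop("input must be a waveform_recording or beat_series",
              call. = FALSE)

  bs <- screen_artifacts(bs, cfg)
  note("artifact screening flagged %d beat(s)", attr(bs, "n_flagged"))

  hr <- tryCatch(hrv(bs, cfg), error = function(e) {
    note("HRV failed: %s", conditionMessage(e)); NULL
  })
  if (!is.null(hr))
    note("HRV segment %.1f-%.1f s (%.2f%% rejected)", hr$segment$start_s,
         hr$segment$end_s, 100 * hr$segment$rejected_fraction)

  br <- NULL
  if (is.null(bs$sbp)) {
    note("no pressure channel: BRS flagged absent")
  } else {
    br <- tryCatch(brs(bs, cfg), error = function(e) {
      note("BRS failed: %s", conditionMessage(e)); NULL
    })
    if (!is.null(br))
      note("BRS segment %.1f-%.1f s: %d sequences", br$segment$start_s,
           br$segment$end_s, br$summary$n_sequences)
  }

  qt <- NULL
  if (!is.null(rec) && !is.null(hr)) {
    qt <- tryCatch({
      idx <- hr$segment$idx
      ab <- average_beat(rec, bs$t[idx], valid = bs$valid[idx])
      m <- measure_qt(ab)
      int_valid <- bs$valid[idx][-length(idx)] & bs$valid[idx][-1]
      qtc(m$qt, mean(bs$rr[idx[-length(idx)]][int_valid]))
    }, error = function(e) {
      note("QT failed: %s", conditionMessage(e)); NULL
    })
    if (!is.null(qt)) note("QT %.2f ms, QTc %.2f ms", qt$qt, qt$qtc)
  } else if (is.null(rec)) {
    note("no waveform: QT flagged absent")
  }

  row <- data.frame(
    subject_id = if (!is.null(meta)) meta$subject_id else NA_character_,
    genotype = if (!is.null(meta)) meta$genotype else NA_character_,
    sex = if (!is.null(meta)) meta$sex else NA_character_,
    age_group = if (!is.null(meta)) meta$age_group else NA_integer_,
    sdnn = if (!is.null(hr)) hr$sdnn else NA_real_,
    rmssd = if (!is.null(hr)) hr$rmssd else NA_real_,
    sd1 = if (!is.null(hr)) hr$sd1 else NA_real_,
    sd2 = if (!is.null(hr)) hr$sd2 else NA_real_,
    lf = if (!is.null(hr)) hr$lf else NA_real_,
    hf = if (!is.null(hr)) hr$hf else NA_real_,
    lf_hf = if (!is.null(hr)) hr$lf_hf else NA_real_,
    brs = if (!is.null(br)) br$summary$gain else NA_real_,
    qt = if (!is.null(qt)) qt$qt else NA_real_,
    qtc = if (!is.null(qt)) qt$qtc else NA_real_)

  structure(list(row = row, beats = bs, hrv = hr, brs = br, qtc = qt,
                 log = log),
            class = "subject_result")
}

#' Run the full cohort pipeline
#'
#' Analyses every input subject, assembles the per-subject results table
#' and, when all eight genotype x sex x age cells hold at least two
#' subjects, fits the three-way ANOVA with Sidak one-factor contrasts for
#' each outcome. Per-subject outputs are always produced; a group-stats
#' failure (e.g. an empty cell) is recorded in the log instead of
#' aborting.
#'
#' @param inputs List of `waveform_recording` / [beat_series()] objects,
#'   each carrying [subject_meta()].
#' @param cfg An [analysis_config()].
#' @param out_dir Optional directory: writes `subjects.csv`, `stats.csv`
#'   and `pipeline.log`.
#' @return Object of class `"cv_pipeline"`: `subjects` (one row each),
#'   `stats` (named list of `"cv_anova"` per outcome, or `NULL`), `log`.
#' @export
run_pipeline <- function(inputs, cfg = analysis_config(), out_dir = NULL) {
  stopifnot(length(inputs) >= 1L)
  log <- character(0)
  results <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    res <- analyze_subject(inputs[[i]], cfg)
    results[[i]] <- res
    log <- c(log, paste0("[", res$row$subject_id, "] ", res$log))
  }
  subjects <- do.call(rbind, lapply(results, `[[`, "row"))

  outcomes <- c("sdnn", "rmssd", "sd1", "sd2", "lf", "hf", "lf_hf",
                "brs", "qt", "qtc")
  stats <- list()
  for (oc in outcomes) {
    tbl <- subjects[!is.na(subjects[[oc]]),
                    c("genotype", "sex", "age_group", oc)]
    fit <- tryCatch(three_way_anova(tbl, oc),
                    error = function(e) {
                      log <<- c(log, sprintf("group stats (%s) skipped: %s",
                                             oc, conditionMessage(e)))
                      NULL
                    })
    if (!is.null(fit)) stats[[oc]] <- fit
  }
  if (length(stats) == 0L) stats <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(subjects, file.path(out_dir, "subjects.csv"),
                     row.names = FALSE)
    if (!is.null(stats)) {
      blocks <- lapply(names(stats), function(oc) {
        e <- stats[[oc]]$effects
        cbind(outcome = oc, type = "effect", term = e$effect,
              estimate = e$F, p = e$p,
              p_adj = NA_real_)
      })
      cblocks <- lapply(names(stats), function(oc) {
        ct <- stats[[oc]]$contrasts
        cbind(outcome = oc, type = "contrast",
              term = paste(ct$cell_a, "vs", ct$cell_b),
              estimate = ct$diff, p = ct$p_raw, p_adj = ct$p_sidak)
      })
      utils::write.csv(do.call(rbind, c(blocks, cblocks)),
                       file.path(out_dir, "stats.csv"), row.names = FALSE)
    }
    writeLines(log, file.path(out_dir, "pipeline.log"))
  }

  structure(list(subjects = subjects, stats = stats, log = log,
                 config = cfg),
            class = "cv_pipeline")
}

#' @export
print.subject_result <- function(x, ...) {
  cat("Subject analysis\n")
  print(x$row, row.names = FALSE)
  invisible(x)
}

#' @export
print.cv_pipeline <- function(x, ...) {
  cat(sprintf("Cardiovascular autonomic pipeline: %d subject(s)\n",
              nrow(x$subjects)))
  print(x$subjects, row.names = FALSE, digits = 4)
  if (is.null(x$stats)) {
    cat("Group statistics: not computed (see log)\n")
  } else {
    cat(sprintf("Group statistics computed for: %s\n",
                paste(names(x$stats), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.cv_pipeline <- function(object, ...) {
  print(object)
  if (!is.null(object$stats)) for (fit in object$stats) print(fit)
  invisible(object)
}
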