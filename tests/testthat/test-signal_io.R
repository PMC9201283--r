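test_that("native recordings carry rate/duration arithmetic and round-trip", {
  set.seed(42)
  rec <- waveform_recording(4000, rnorm(8000))
  expect_equal(duration(rec), 2.0)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_equal(back$sampling_rate, 4000)
  expect_equal(back$ecg, rec$ecg, tolerance = 1e-12)

  # headerless file: the sampling rate is unrecoverable
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ecg", "0.1", "0.2"), f2)
  expect_error(read_recording(f2), "header")

  expect_error(waveform_recording(4000, rnorm(100), abp = rnorm(99)),
               "length mismatch")
  expect_error(waveform_recording(-1, rnorm(100)), "sampling_rate")
})

test_that("a written synthetic recording re-reads to identical beat detection", {
  bs <- sim_rr_series(duration_s = 6, lf_amp = 2, hf_amp = 2,
                      rr_noise_sd = 0.5, seed = 7)
  rec <- sim_ecg(bs, qt_true = 45, sampling_rate = 1000)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_identical(detect_r_peaks(back), detect_r_peaks(rec))
})

test_that("wfdb-style paired header/sample files are read", {
  bs <- sim_rr_series(duration_s = 4, lf_amp = 0, hf_amp = 0,
                      rr_noise_sd = 0, seed = 1)
  bsc <- sim_coupled_sbp(bs, brs_gain = 2)
  rec <- sim_ecg(bsc, qt_true = 45, sampling_rate = 500)
  d <- withr::local_tempdir()
  writeLines(c(sprintf("rec 2 %g %d", 500, length(rec$ecg)),
               "rec.sig mV ECG", "rec.sig mmHg ABP"),
             file.path(d, "rec.hea"))
  write.table(format(cbind(rec$ecg, rec$abp), digits = 15),
              file.path(d, "rec.sig"), row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  back <- read_recording(file.path(d, "rec.hea"))
  expect_equal(back$sampling_rate, 500)
  expect_equal(back$ecg, rec$ecg, tolerance = 1e-12)
  expect_equal(back$abp, rec$abp, tolerance = 1e-12)

  writeLines(c("rec 2 notarate 100", "rec.sig mV ECG", "rec.sig mmHg ABP"),
             file.path(d, "bad.hea"))
  expect_error(read_recording(file.path(d, "bad.hea")), "sampling rate")
})

test_that("beat tables validate monotone times and round-trip losslessly", {
  bs3 <- beat_series(c(0, 0.12, 0.24))
  expect_equal(bs3$rr, c(120, 120))

  d <- withr::local_tempdir()
  f <- file.path(d, "beats.tsv")

  # shuffled rows violate monotonicity
  write_beat_table(bs3, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  write.table(tab[c(2, 1, 3), ], f, sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(read_beat_table(f), "strictly increasing")

  # pipeline-emitted table round-trips
  bs <- sim_rr_series(duration_s = 10, seed = 3)
  bsc <- sim_coupled_sbp(bs, brs_gain = 2, rr_noise_sd = 0.3, seed = 4)
  bsc <- screen_artifacts(bsc)
  write_beat_table(bsc, f)
  back <- read_beat_table(f)
  expect_equal(back$t, bsc$t, tolerance = 1e-12)
  expect_equal(back$rr, bsc$rr, tolerance = 1e-9)
  expect_equal(back$sbp, bsc$sbp, tolerance = 1e-12)
  expect_identical(back$valid, bsc$valid)
})

test_that("pipeline produces per-subject rows, flags absences, and is deterministic", {
  cfg <- analysis_config(hrv_segment_s = 20, brs_segment_s = 20)
  cells <- cell_labels()
  inputs <- lapply(1:8, function(i) {
    b <- sim_rr_series(duration_s = 25, seed = 300 + i,
                       meta = subject_meta(paste0("s", i), cells$genotype[i],
                                           cells$sex[i], cells$age_group[i]))
    sim_coupled_sbp(b, brs_gain = 2, rr_noise_sd = 0.3, seed = 400 + i)
  })
  d <- withr::local_tempdir()
  pl <- run_pipeline(inputs, cfg, out_dir = d)
  expect_equal(nrow(pl$subjects), 8L)
  expect_true(all(is.finite(pl$subjects$sdnn)))
  expect_true(all(is.finite(pl$subjects$brs)))
  # one subject per cell: group stats cannot estimate error, logged not fatal
  expect_null(pl$stats)
  expect_true(any(grepl("group stats", pl$log)))
  expect_true(all(file.exists(file.path(d, c("subjects.csv", "pipeline.log")))))

  # inputs without a pressure channel yield NA BRS but full HRV
  noabp <- sim_rr_series(duration_s = 25, seed = 300 + 1,
                         meta = subject_meta("x", "WT", "M", 6))
  r1 <- analyze_subject(noabp, cfg)
  expect_true(is.na(r1$row$brs))
  expect_true(is.finite(r1$row$sdnn))
  expect_true(any(grepl("no pressure channel", r1$log)))

  # duplicated input gives identical duplicated rows
  pl2 <- run_pipeline(list(inputs[[1]], inputs[[1]]), cfg)
  expect_identical(as.list(pl2$subjects[1, -1]), as.list(pl2$subjects[2, -1]))
})
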