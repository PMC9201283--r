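# beat-wise rr here means the interval *starting* at each beat; an extra
# trailing beat supplies the last interval
bs_with_sbp <- function(sbp, rr_beat, valid = NULL) {
  bs_from_rr(c(rr_beat, 120), sbp = c(sbp, 100, 100),
             valid = if (!is.null(valid)) c(valid, TRUE, TRUE))
}

test_that("the 8-beat worked example yields one up and one down sequence", {
  bs <- bs_with_sbp(sbp = c(100, 102, 104, 106, 100, 98, 96, 100),
                    rr_beat = c(100, 101, 102, 103, 100, 99, 98, 100))
  sq <- find_sequences(bs)
  expect_equal(nrow(sq), 2L)
  expect_equal(sq$direction, c("up", "down"))
  expect_equal(sq$start, c(1L, 4L))               # share the pivot beat
  expect_equal(sq$length, c(4L, 4L))
  expect_equal(sq$slope, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sq$r, c(1, 1), tolerance = 1e-12)

  sm <- brs_summary(sq)
  expect_equal(sm$gain, 0.5, tolerance = 1e-12)
  expect_equal(c(sm$n_sequences, sm$n_up, sm$n_down), c(2L, 1L, 1L))
})

test_that("anti-concordant changes and ties produce no sequences", {
  anti <- bs_with_sbp(sbp = c(100, 102, 104, 106, 108, 110),
                      rr_beat = c(110, 108, 106, 104, 102, 100))
  expect_equal(nrow(find_sequences(anti)), 0L)

  tied <- bs_with_sbp(sbp = c(100, 102, 102, 104, 106),
                      rr_beat = c(100, 101, 102, 103, 104))
  # the zero SBP step breaks the run; neither half reaches 3 beats... the
  # second half (102,104,106) does
  sq <- find_sequences(tied)
  expect_true(all(sq$length >= 3L))
  expect_true(all(sq$start >= 3L))

  empty <- brs_summary(find_sequences(anti))
  expect_true(is.na(empty$gain))
  expect_equal(empty$n_sequences, 0L)

  expect_error(find_sequences(bs_from_rr(rep(120, 10))), "missing channel")
})

test_that("sequence regression is exact on collinear points, both directions", {
  up <- sequence_slope(c(100, 102, 104, 106), c(100, 101, 102, 103))
  expect_equal(up$slope, 0.5, tolerance = 1e-12)
  expect_equal(up$r, 1, tolerance = 1e-12)
  down <- sequence_slope(c(106, 100, 98, 96), c(103, 100, 99, 98))
  expect_equal(down$slope, 0.5, tolerance = 1e-12)
  expect_equal(down$r, 1, tolerance = 1e-12)

  # permutation invariance
  set.seed(4)
  sbp <- c(100, 103, 101, 105); rr <- c(98, 104, 99, 107)
  perm <- sample(4)
  expect_equal(sequence_slope(sbp[perm], rr[perm])$slope,
               sequence_slope(sbp, rr)$slope, tolerance = 1e-12)

  expect_error(sequence_slope(c(100, 100, 100), c(1, 2, 3)), "degenerate")
  expect_error(sequence_slope(c(1, 2), c(1, 2)), "insufficient data")
})

test_that("noiseless linear coupling returns the programmed gain exactly", {
  for (G in c(1, 2, 4)) {
    base <- sim_rr_series(duration_s = 40, lf_amp = 0, hf_amp = 0,
                          rr_noise_sd = 0, seed = 50 + G)
    cp <- sim_coupled_sbp(base, brs_gain = G)
    sq <- find_sequences(cp)
    expect_gt(nrow(sq), 10)
    expect_equal(sq$slope, rep(G, nrow(sq)), tolerance = 1e-9)
    expect_equal(brs_summary(sq)$gain, G, tolerance = 1e-9)
  }
})

test_that("sequences are maximal and output is shift-invariant", {
  base <- sim_rr_series(duration_s = 60, lf_amp = 0, hf_amp = 0,
                        rr_noise_sd = 0, seed = 61)
  cp <- sim_coupled_sbp(base, brs_gain = 2, rr_noise_sd = 0.5,
                        sbp_noise_sd = 1, seed = 62)
  sq <- find_sequences(cp)
  expect_gt(nrow(sq), 5)
  n <- n_beats(cp)
  rrb <- cp$rr
  for (k in seq_len(nrow(sq))) {
    i0 <- sq$start[k]; i1 <- sq$start[k] + sq$length[k] - 1L
    sgn <- if (sq$direction[k] == "up") 1 else -1
    d_in <- sgn * diff(cp$sbp[i0:i1]) > 0 & sgn * diff(rrb[i0:i1]) > 0
    expect_true(all(d_in))                        # concordant inside
    if (i0 > 1L)                                   # not extendable left
      expect_false(sgn * (cp$sbp[i0] - cp$sbp[i0 - 1L]) > 0 &&
                     sgn * (rrb[i0] - rrb[i0 - 1L]) > 0)
    if (i1 < n - 1L)                               # not extendable right
      expect_false(sgn * (cp$sbp[i1 + 1L] - cp$sbp[i1]) > 0 &&
                     sgn * (rrb[i1 + 1L] - rrb[i1]) > 0)
  }

  # adding constants to all SBP or all RR leaves everything unchanged
  shifted <- cp
  shifted$sbp <- cp$sbp + 25
  sq2 <- find_sequences(shifted)
  expect_equal(sq2$slope, sq$slope, tolerance = 1e-9)
  expect_equal(sq2$start, sq$start)
})

test_that("brs() estimates the gain on the most stable segment", {
  base <- sim_rr_series(duration_s = 70, lf_amp = 0, hf_amp = 0,
                        rr_noise_sd = 0, seed = 71)
  cp <- screen_artifacts(sim_coupled_sbp(base, brs_gain = 2,
                                         rr_noise_sd = 0.5, seed = 72))
  est <- brs(cp, analysis_config(brs_segment_s = 60))
  expect_lt(abs(coef(est)[["gain"]] - 2) / 2, 0.1)
  expect_gt(est$summary$n_up, 0)
  expect_gt(est$summary$n_down, 0)
})
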