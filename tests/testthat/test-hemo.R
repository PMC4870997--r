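make_const_recording <- function(value = 1000, dur_s = 100, fs = 4,
                                 nopt = 1) {
  n <- dur_s * fs
  labs <- c(t(outer(seq_len(nopt), c(730, 850), function(o, w)
    sprintf("optode%d_%d", o, w))))
  I <- matrix(value, n, nopt * 2, dimnames = list(NULL, labs))
  amb <- matrix(0, n, nopt,
                dimnames = list(NULL, sprintf("optode%d_ambient",
                                              seq_len(nopt))))
  new_recording((0:(n - 1)) / fs, I, amb, fs = fs, adc_max = 1e9,
                subject = "S01")
}

mk <- function(onset, offset, task = "oneback", block = 1) {
  data.frame(subject = "S01", task = task, block = block, onset = onset,
             offset = offset, condition = "ARWD", accuracy = "correct")
}

test_that("block extraction follows the markers and validates durations", {
  rec <- make_const_recording(dur_s = 120)
  segs <- extract_blocks(rec, mk(10, 70))
  expect_length(segs, 1L)
  expect_equal(nrow(segs[[1]]$I), 240L) # 60 s at 4 Hz
  expect_equal(segs[[1]]$baseline_idx, 1:40) # first 10 s
  expect_equal(segs[[1]]$idx, c(41L, 280L))

  expect_error(extract_blocks(rec, mk(10, 130)), "beyond the end")
  expect_error(extract_blocks(rec, mk(10, 19)), "shorter than")
})

test_that("MBLL conversion is zero at baseline and inverts the forward model", {
  rec <- make_const_recording()
  seg <- extract_blocks(rec, mk(0, 60))[[1]]
  hb <- mbll_convert(seg)
  expect_true(all(abs(hb$hbo) < 1e-12))
  expect_true(all(abs(hb$hbr) < 1e-12))

  # forward intensities from known concentrations, then invert
  optics <- optical_constants()
  truth <- c(hbo = 1.0, hbr = -0.2) # uM
  n <- 240
  I <- matrix(NA_real_, n, 2,
              dimnames = list(NULL, c("optode1_730", "optode1_850")))
  conc_t <- c(rep(0, 40), rep(1, n - 40)) # flat baseline, then the step
  for (w in 1:2) {
    dod <- (optics$epsilon[w, 1] * truth["hbo"] / 1000 +
              optics$epsilon[w, 2] * truth["hbr"] / 1000) *
      optics$d * optics$dpf[w] * conc_t
    I[, w] <- 1000 * 10^(-dod)
  }
  amb <- matrix(0, n, 1, dimnames = list(NULL, "optode1_ambient"))
  rec2 <- new_recording((0:(n - 1)) / 4, I, amb, 4, 1e9, "S01")
  hb2 <- mbll_convert(extract_blocks(rec2, mk(0, 60))[[1]], optics)
  expect_lt(max(abs(hb2$hbo[41:n, 1] - 1.0)), 1e-9)
  expect_lt(max(abs(hb2$hbr[41:n, 1] + 0.2)), 1e-9)

  # doubling the concentrations doubles the recovery (linearity)
  I4 <- 1000 * (I / 1000)^2 # squares the transmittance = doubles dOD
  rec4 <- new_recording((0:(n - 1)) / 4, I4, amb, 4, 1e9, "S01")
  hb4 <- mbll_convert(extract_blocks(rec4, mk(0, 60))[[1]], optics)
  expect_lt(max(abs(hb4$hbo - 2 * hb2$hbo)), 1e-9)
  expect_lt(max(abs(hb4$hbr - 2 * hb2$hbr)), 1e-9)

  expect_error(mbll_convert(
    extract_blocks(make_const_recording(value = 0.0), mk(0, 60))[[1]]),
    "non-positive")
})

test_that("halved intensity gives dOD = log10(2) and the 2x2 solve matches the inversion oracle", {
  optics <- optical_constants()
  n <- 80
  I <- matrix(1000, n, 2,
              dimnames = list(NULL, c("optode1_730", "optode1_850")))
  I[41:80, ] <- 500
  amb <- matrix(0, n, 1, dimnames = list(NULL, "optode1_ambient"))
  rec <- new_recording((0:(n - 1)) / 4, I, amb, 4, 1e9, "S01")
  hb <- mbll_convert(extract_blocks(rec, mk(0, 20))[[1]], optics)
  expect_equal(unname(hb$dod[41, 1]), log10(2), tolerance = 1e-12)
  expect_equal(unname(hb$dod[41, 2]), log10(2), tolerance = 1e-12)
  expected <- oracle_solve2x2(optics$epsilon,
                              c(log10(2) / (optics$d * optics$dpf[1]),
                                log10(2) / (optics$d * optics$dpf[2]))) * 1000
  expect_equal(hb$hbo[41, 1], expected[1], tolerance = 1e-9)
  expect_equal(hb$hbr[41, 1], expected[2], tolerance = 1e-9)
})

test_that("per-sample 2x2 solver agrees with brute-force inversion on 1000 random dOD vectors", {
  optics <- optical_constants()
  set.seed(99)
  dods <- matrix(runif(2000, -0.5, 0.5), ncol = 2)
  n <- nrow(dods) + 40
  base <- 1000
  I <- matrix(base, n, 2,
              dimnames = list(NULL, c("optode1_730", "optode1_850")))
  I[41:n, 1] <- base * 10^(-dods[, 1])
  I[41:n, 2] <- base * 10^(-dods[, 2])
  amb <- matrix(0, n, 1, dimnames = list(NULL, "optode1_ambient"))
  rec <- new_recording((0:(n - 1)) / 4, I, amb, 4, 1e12, "S01")
  hb <- mbll_convert(extract_blocks(rec, mk(0, n / 4))[[1]], optics)
  for (i in seq_len(nrow(dods))) {
    expected <- oracle_solve2x2(
      optics$epsilon, dods[i, ] / (optics$d * optics$dpf)) * 1000
    expect_lt(abs(hb$hbo[40 + i, 1] - expected[1]), 1e-12 * max(1, abs(expected[1])))
    expect_lt(abs(hb$hbr[40 + i, 1] - expected[2]), 1e-12 * max(1, abs(expected[2])))
  }
})

test_that("sub-block binning averages correctly and drops the trailing partial bin", {
  # a bare hb_series carrying a pure sample ramp: binning is arithmetic
  n <- 250 # 62.5 s: the trailing 10 samples don't fill a 40-sample bin
  ramp <- as.numeric(0:(n - 1))
  hb <- structure(list(
    hbo = matrix(ramp, n, 1), hbr = matrix(7, n, 1),
    dod = NULL, t = (0:(n - 1)) / 4, fs = 4,
    subject = "S01", task = "oneback", block = 1,
    condition = "ARWD", accuracy = "correct",
    idx = c(1L, n), baseline_idx = 1:40), class = "hb_series")
  bs <- bin_block_series(hb, bin_s = 10)
  sub1 <- bs$subblocks[bs$subblocks$optode == 1, ]
  expect_equal(nrow(sub1), 6L) # 240 usable samples / 40
  expect_equal(sub1$HbO, c(19.5, 59.5, 99.5, 139.5, 179.5, 219.5),
               tolerance = 1e-12)
  expect_equal(bs$blocks$n_subblocks[1], 6L)
  expect_true(all(sub1$HbR == 7)) # constant series: every mean = the value
  expect_true(all(bs$blocks$HbR == 7))
  expect_error(bin_block_series(hb, bin_s = 100), "duration")

  # constant intensities end-to-end: all summaries identically zero
  recc <- make_const_recording(value = 800, dur_s = 60)
  hbc <- mbll_convert(extract_blocks(recc, mk(0, 60))[[1]])
  bsc <- bin_block_series(hbc, bin_s = 10)
  expect_true(all(abs(bsc$subblocks$HbO) < 1e-12))
  expect_true(all(abs(bsc$blocks$HbO) < 1e-12))
})

test_that("every non-excluded marker yields exactly one block summary per optode", {
  ex <- make_roundtrip_experiment(seed = 5, n_subjects = 2, n_blocks = 4,
                                  n_probes = 2)
  rec <- ex$recordings[[1]]
  sm <- summarize_blocks(rec, ex$markers)
  mks <- ex$markers[ex$markers$subject == rec$subject, ]
  expect_equal(nrow(sm$blocks), nrow(mks) * rec$n_optodes)
  got <- unique(sm$blocks[c("task", "block")])
  expect_equal(nrow(got), nrow(mks))
})
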