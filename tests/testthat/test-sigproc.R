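test_that("FIR design has symmetric unit-DC taps with the required band behavior", {
  f <- design_lowpass_fir(20, 0.1, 4)
  expect_length(f$taps, 21L)
  expect_equal(f$taps, rev(f$taps), tolerance = 1e-12)
  expect_lt(abs(sum(f$taps) - 1), 1e-12)

  # independent frequency-response oracle
  expect_lt(abs(oracle_fir_gain(f$taps, 0, 4) - 1), 1e-9)
  pass <- oracle_fir_gain(f$taps, seq(0, 0.05, by = 0.005), 4)
  expect_true(all(pass >= 0.99 & pass <= 1.01))
  stopb <- oracle_fir_gain(f$taps, seq(1.0, 2.0, by = 0.02), 4)
  expect_true(all(stopb <= 0.01))
  # package gain agrees with the oracle
  expect_equal(fir_gain(f, c(0.03, 0.5, 1.5)),
               oracle_fir_gain(f$taps, c(0.03, 0.5, 1.5), 4),
               tolerance = 1e-12)

  expect_error(design_lowpass_fir(21, 0.1, 4), "even")
  expect_error(design_lowpass_fir(20, 2.0, 4), "Nyquist")
})

test_that("zero-lag filtering preserves constants, centers the impulse response, and keeps passband amplitude", {
  f <- design_lowpass_fir(20, 0.1, 4)
  expect_equal(filter_series(rep(3.7, 100), f), rep(3.7, 100),
               tolerance = 1e-12)

  x <- numeric(201); x[101] <- 1
  y <- filter_series(x, f)
  expect_equal(y[91:111], f$taps, tolerance = 1e-12)

  t <- seq(0, 600 - 0.25, by = 0.25)
  s <- sin(2 * pi * 0.02 * t)
  ys <- filter_series(s, f)
  inner <- 100:(length(t) - 100)
  g <- oracle_fir_gain(f$taps, 0.02, 4)
  expect_lt(max(abs(ys[inner] - g * s[inner])), 0.01)
  expect_gt(g, 0.99)

  expect_error(filter_series(rep(1, 10), f), "length")
})

test_that("filtering is linear away from the edges", {
  f <- design_lowpass_fir(20, 0.1, 4)
  set.seed(42)
  x <- rnorm(300); y <- rnorm(300)
  lhs <- filter_series(2.5 * x - 1.3 * y, f)
  rhs <- 2.5 * filter_series(x, f) - 1.3 * filter_series(y, f)
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("saturation detection flags exactly the at-or-above-ceiling samples", {
  n <- 50
  I <- matrix(100, n, 2,
              dimnames = list(NULL, c("optode1_730", "optode1_850")))
  amb <- matrix(0, n, 1, dimnames = list(NULL, "optode1_ambient"))
  t <- (0:(n - 1)) / 4
  rec <- new_recording(t, I, amb, fs = 4, adc_max = 4096)
  expect_false(any(detect_saturation(rec)))

  I2 <- I; I2[17, 1] <- 4096
  rec2 <- new_recording(t, I2, amb, fs = 4, adc_max = 4096)
  flags <- detect_saturation(rec2)
  expect_identical(which(flags), 17L)
})

test_that("saturation flags agree with the generator's event log", {
  d <- make_design(n_subjects = 1, n_oneback_blocks = 2, n_probe_trials = 0)
  params <- hemo_params(saturation_prob = 1)
  tr <- simulate_hemodynamics(d, params, seed = 21)
  raw <- simulate_raw_recording(tr, seed = 21)
  flags <- detect_saturation(raw$recordings[[1]])
  ev <- raw$events[raw$events$type == "saturation", ]
  expect_gt(nrow(ev), 0)
  for (i in seq_len(nrow(ev)))
    expect_true(all(flags[ev$start_sample[i]:ev$end_sample[i],
                          ev$channel[i]]))
})

test_that("CoV scan matches brute-force recomputation and reacts only to real artifacts", {
  set.seed(8)
  n <- 400
  x <- 1000 + rnorm(n, 0, 2)  # very quiet channel: CoV ~ 0.2%
  I <- cbind(optode1_730 = x, optode1_850 = 1000 + rnorm(n, 0, 2))
  amb <- matrix(0, n, 1, dimnames = list(NULL, "optode1_ambient"))
  rec <- new_recording((0:(n - 1)) / 4, I, amb, fs = 4, adc_max = 1e5)

  rep1 <- cov_artifact_scan(rec, window_s = 20, step_s = 5,
                            threshold_pct = 10)
  brute <- oracle_cov_windows(x, 80, 20)
  ch1 <- rep1[rep1$channel == "optode1_730", ]
  expect_equal(ch1$start_sample, as.integer(brute[, "start"]))
  expect_equal(ch1$cov_pct, unname(brute[, "cov"]), tolerance = 1e-12)
  expect_false(any(rep1$flagged)) # clean low-noise signal

  # constant positive signal: CoV identically zero
  recc <- new_recording((0:(n - 1)) / 4,
                        matrix(500, n, 2, dimnames = dimnames(I)),
                        amb, fs = 4, adc_max = 1e5)
  repc <- cov_artifact_scan(recc)
  expect_true(all(repc$cov_pct == 0))
  expect_false(any(repc$flagged))

  # a window with mean 100 and sd 20 has CoV exactly 20%
  w <- rep(100, 80)
  w <- w + c(rep(-20, 40), rep(20, 40)) * sqrt(79 / 80)
  expect_equal(100 * sd(w) / mean(w), 20, tolerance = 1e-12)
  recw <- new_recording((0:79) / 4,
                        cbind(optode1_730 = w, optode1_850 = w),
                        matrix(0, 80, 1,
                               dimnames = list(NULL, "optode1_ambient")),
                        fs = 4, adc_max = 1e5)
  repw <- cov_artifact_scan(recw, window_s = 20, step_s = 20,
                            threshold_pct = 10)
  expect_equal(repw$cov_pct[1], 20, tolerance = 1e-12)
  expect_true(repw$flagged[1])

  # a 10-SD spike on a mobile-grade (7% CoV) channel is flagged, and only
  # in windows containing it
  set.seed(15)
  xm <- 1000 + rnorm(n, 0, 70)
  sdx <- sd(xm)
  xs <- xm
  xs[200:201] <- xs[200:201] + 10 * sdx
  recs <- new_recording((0:(n - 1)) / 4,
                        cbind(optode1_730 = xs, optode1_850 = I[, 2]),
                        amb, fs = 4, adc_max = 1e5)
  reps <- cov_artifact_scan(recs)
  fl <- reps[reps$flagged, ]
  expect_gt(nrow(fl), 0)
  expect_true(all(fl$channel == "optode1_730"))
  expect_true(all(fl$start_sample <= 201 & fl$end_sample >= 200))

  recn <- new_recording((0:(n - 1)) / 4, cbind(optode1_730 = x * 0,
                                               optode1_850 = I[, 2]),
                        amb, fs = 4, adc_max = 1e5)
  expect_error(cov_artifact_scan(recn), "non-positive")
})

test_that("injected 10-SD spikes are detected at default settings at >= 95% sensitivity", {
  d <- make_design(n_subjects = 2, n_oneback_blocks = 6, n_probe_trials = 0)
  params <- hemo_params(spike_rate_per_min = 2, spike_amp_sd = 10)
  ex <- simulate_experiment(design = d, params = params, seed = 31)
  hits <- 0L; total <- 0L
  for (s in names(ex$recordings)) {
    rep_s <- cov_artifact_scan(ex$recordings[[s]])
    ev <- ex$events[ex$events$subject == s & ex$events$type == "spike", ]
    total <- total + nrow(ev)
    for (i in seq_len(nrow(ev))) {
      fl <- rep_s[rep_s$flagged & rep_s$channel == ev$channel[i], ]
      if (nrow(fl) && any(fl$start_sample <= ev$end_sample[i] &
                          fl$end_sample >= ev$start_sample[i]))
        hits <- hits + 1L
    }
  }
  expect_gt(total, 10)
  expect_gte(hits / total, 0.95)
})

test_that("ambient screen flags only meaningful stray-light levels", {
  n <- 100
  I <- matrix(1000, n, 2,
              dimnames = list(NULL, c("optode1_730", "optode1_850")))
  t <- (0:(n - 1)) / 4
  mk_amb <- function(level) matrix(level, n, 1,
                                   dimnames = list(NULL, "optode1_ambient"))
  expect_false(ambient_check(
    new_recording(t, I, mk_amb(0), 4, 4096), 0.1)[["optode1"]])
  expect_true(ambient_check(
    new_recording(t, I, mk_amb(1000), 4, 4096), 0.99)[["optode1"]])
  rec10 <- new_recording(t, I, mk_amb(100), 4, 4096)
  expect_true(ambient_check(rec10, 0.05)[["optode1"]])
  expect_false(ambient_check(rec10, 0.2)[["optode1"]])
})
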