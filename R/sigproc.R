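#' Raw fNIRS recording container
#'
#' One subject's uniformly sampled light-intensity recording: a matrix of
#' detector intensities per optode x wavelength channel, an ambient-light
#' channel per optode, the sampling rate and the ADC ceiling.
#'
#' @param t time grid, seconds (strictly increasing, uniform at `fs`).
#' @param I numeric matrix, samples x channels, columns named
#'   `optode<N>_<wavelength>`.
#' @param ambient numeric matrix, samples x optodes, columns
#'   `optode<N>_ambient`.
#' @param fs sampling rate, Hz.
#' @param adc_max analog-to-digital converter ceiling (intensity units).
#' @param subject subject label.
#' @param wavelengths the wavelength pair, nm.
#' @return an object of class `fnirs_recording`.
#' @export
new_recording <- function(t, I, ambient, fs, adc_max, subject = "S01",
                          wavelengths = c(730, 850)) {
  if (length(t) != nrow(I) || length(t) != nrow(ambient))
    stop("time grid and intensity matrices disagree in length", call. = FALSE)
  dtt <- diff(t)
  if (length(dtt) && (any(dtt <= 0) ||
                      max(abs(dtt - 1 / fs)) > 1e-6 / fs))
    stop("time grid must be strictly increasing and uniform at fs",
         call. = FALSE)
  if (any(I < 0)) stop("intensities must be >= 0", call. = FALSE)
  stopifnot_scalar_num(adc_max, "adc_max", 0, strict_lower = TRUE)
  structure(list(t = t, I = I, ambient = ambient, fs = fs,
                 adc_max = adc_max, subject = subject,
                 wavelengths = wavelengths,
                 n_optodes = ncol(ambient)),
            class = "fnirs_recording")
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("fNIRS recording %s: %d samples @ %g Hz (%.1f s), %d channels + %d ambient, ADC max %g\n",
              x$subject, length(x$t), x$fs, length(x$t) / x$fs,
              ncol(x$I), ncol(x$ambient), x$adc_max))
  invisible(x)
}

#' Design a linear-phase low-pass FIR filter
#'
#' Windowed-sinc design (Hamming window by default) with even order (type-I
#' linear phase) and taps normalized to exactly unit DC gain, so a constant
#' baseline intensity is invariant under filtering. `cutoff_hz` is the
#' passband edge: the ideal sinc cutoff is placed at
#' `cutoff_hz + transition/2`, where `transition = 3.3 * fs / order` is the
#' Hamming main-lobe transition width — so the response stays flat through
#' the passband and reaches the stopband floor well before the cardiac band.
#' The default experiment filter (order 20, passband edge 0.1 Hz at fs = 4 Hz)
#' passes the hemodynamic band essentially untouched (gain > 0.998 below
#' 0.05 Hz) and attenuates frequencies above 1 Hz by more than 40 dB.
#'
#' @param order filter order (even; `order + 1` taps).
#' @param cutoff_hz passband edge, Hz.
#' @param fs sampling rate, Hz.
#' @param window `"hamming"` or `"hann"`.
#' @return an object of class `fir_filter`: list with `taps`, `order`,
#'   `cutoff_hz`, `fs`, `window`.
#' @examples
#' f <- design_lowpass_fir(20, 0.1, 4)
#' sum(f$taps) # exactly 1
#' fir_gain(f, c(0, 0.05, 1.0))
#' @export
design_lowpass_fir <- function(order = 20L, cutoff_hz = 0.1, fs = 4,
                               window = c("hamming", "hann")) {
  window <- match.arg(window)
  stopifnot_scalar_num(order, "order", 2)
  stopifnot_scalar_num(cutoff_hz, "cutoff_hz", 0, strict_lower = TRUE)
  if (order %% 2 != 0)
    stop("'order' must be even: an odd order has a half-sample group delay that cannot be compensated on the sample grid",
         call. = FALSE)
  if (cutoff_hz >= fs / 2)
    stop(sprintf("'cutoff_hz' (%g) must be below the Nyquist frequency %g Hz",
                 cutoff_hz, fs / 2), call. = FALSE)
  transition <- 3.3 * fs / order
  fc <- min(cutoff_hz + transition / 2, fs / 2 * 0.999)
  m <- (0:order) - order / 2
  x <- 2 * fc / fs * m
  s <- ifelse(m == 0, 1, sin(pi * x) / (pi * x)) * (2 * fc / fs)
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:order) / order),
    hann = 0.5 - 0.5 * cos(2 * pi * (0:order) / order))
  taps <- s * w
  taps <- taps / sum(taps)
  structure(list(taps = taps, order = as.integer(order),
                 cutoff_hz = cutoff_hz, fs = fs, window = window),
            class = "fir_filter")
}

#' FIR magnitude response
#'
#' Evaluates `|sum_k taps[k] exp(-i 2 pi f k / fs)|` at the given
#' frequencies.
#'
#' @param filt a [design_lowpass_fir()] object.
#' @param f_hz frequencies, Hz.
#' @return numeric vector of gains.
#' @export
fir_gain <- function(filt, f_hz) {
  k <- seq_along(filt$taps) - 1
  vapply(f_hz, function(f)
    Mod(sum(filt$taps * exp(-2i * pi * f * k / filt$fs))), numeric(1))
}

#' Zero-lag FIR filtering of a sample series
#'
#' Convolves the series with the filter taps, compensating the `order/2`
#' sample group delay of the linear-phase design and reflect-padding the
#' edges, so filtered samples stay aligned with the task markers and a
#' constant input is returned unchanged.
#'
#' @param x numeric series.
#' @param filt a [design_lowpass_fir()] object.
#' @return filtered series, same length as `x`.
#' @export
filter_series <- function(x, filt) {
  stopifnot(inherits(filt, "fir_filter"))
  n <- length(x)
  L <- filt$order / 2
  if (n <= filt$order)
    stop(sprintf("series length (%d) must exceed the filter order (%d)",
                 n, filt$order), call. = FALSE)
  # mirror-reflect about the end samples (edge sample not repeated)
  xp <- c(x[(L + 1):2], x, x[(n - 1):(n - L)])
  y <- stats::filter(xp, filt$taps, method = "convolution", sides = 2)
  as.numeric(y[(L + 1):(L + n)])
}

#' Filter every channel of a recording
#'
#' Applies [filter_series()] to each optode x wavelength channel (ambient
#' channels are left untouched — they serve raw-signal QC).
#'
#' @param rec an `fnirs_recording`.
#' @param filt a [design_lowpass_fir()] object.
#' @return a new `fnirs_recording` with filtered `I`.
#' @export
filter_recording <- function(rec, filt) {
  stopifnot(inherits(rec, "fnirs_recording"))
  I <- apply(rec$I, 2, filter_series, filt = filt)
  dimnames(I) <- dimnames(rec$I)
  out <- rec
  out$I <- I
  out$filtered <- TRUE
  out
}

#' Detect detector saturation
#'
#' Flags every sample whose intensity reaches or exceeds the ADC ceiling, per
#' optode x wavelength channel.
#'
#' @param rec an `fnirs_recording` (use the raw, unfiltered recording).
#' @return logical matrix, samples x channels.
#' @export
detect_saturation <- function(rec) {
  stopifnot(inherits(rec, "fnirs_recording"))
  flags <- rec$I >= rec$adc_max
  dimnames(flags) <- dimnames(rec$I)
  flags
}

#' Coefficient-of-variation motion-artifact scan
#'
#' Slides a window along each channel and computes the coefficient of
#' variation `CoV = 100 * sd / mean` (percent). Motion artifacts — spikes and
#' baseline shifts — inflate the within-window SD relative to the mean
#' intensity, so windows with `CoV > threshold_pct` are flagged.
#'
#' @param rec an `fnirs_recording` (raw intensities).
#' @param window_s window length, seconds (must span at least 2 samples).
#' @param step_s window step, seconds.
#' @param threshold_pct flagging threshold, percent.
#' @return a `data.frame` of class `cov_report`: one row per channel x
#'   window with `channel`, `start_sample`, `end_sample` (1-based, inclusive),
#'   `cov_pct`, `flagged`; scan parameters in attributes.
#' @export
cov_artifact_scan <- function(rec, window_s = 20, step_s = 5,
                              threshold_pct = 10) {
  stopifnot(inherits(rec, "fnirs_recording"))
  fs <- rec$fs
  wlen <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  if (wlen < 2L)
    stop("'window_s' must span at least 2 samples", call. = FALSE)
  n <- nrow(rec$I)
  if (wlen > n)
    stop("'window_s' exceeds the recording length", call. = FALSE)
  starts <- seq(1L, max(1L, n - wlen + 1L), by = step)
  out <- vector("list", ncol(rec$I))
  for (ci in seq_len(ncol(rec$I))) {
    x <- rec$I[, ci]
    mu <- vapply(starts, function(s) mean(x[s:(s + wlen - 1L)]), numeric(1))
    if (any(mu <= 0))
      stop(sprintf("channel %s: non-positive window mean, CoV undefined",
                   colnames(rec$I)[ci]), call. = FALSE)
    sdv <- vapply(starts, function(s) stats::sd(x[s:(s + wlen - 1L)]),
                  numeric(1))
    cov <- 100 * sdv / mu
    out[[ci]] <- data.frame(channel = colnames(rec$I)[ci],
                            start_sample = starts,
                            end_sample = starts + wlen - 1L,
                            cov_pct = cov,
                            flagged = cov > threshold_pct)
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  attr(rep, "window_s") <- window_s
  attr(rep, "step_s") <- step_s
  attr(rep, "threshold_pct") <- threshold_pct
  class(rep) <- c("cov_report", "data.frame")
  rep
}

#' Ambient-light contamination check
#'
#' Flags an optode when the median of its ambient channel exceeds
#' `max_ratio` times the median of its detector intensities (both
#' wavelengths pooled) — i.e. when stray light is a non-negligible fraction
#' of the measured signal.
#'
#' @param rec an `fnirs_recording`.
#' @param max_ratio tolerated ambient / detector median ratio, in (0, 1).
#' @return named logical vector, one flag per optode.
#' @export
ambient_check <- function(rec, max_ratio = 0.1) {
  stopifnot(inherits(rec, "fnirs_recording"))
  stopifnot_scalar_num(max_ratio, "max_ratio", 0, 1, strict_lower = TRUE)
  nopt <- rec$n_optodes
  flags <- logical(nopt)
  for (o in seq_len(nopt)) {
    det_cols <- grep(sprintf("^optode%d_", o), colnames(rec$I))
    med_det <- stats::median(rec$I[, det_cols])
    med_amb <- stats::median(rec$ambient[, o])
    flags[o] <- med_amb > max_ratio * med_det
  }
  names(flags) <- sprintf("optode%d", seq_len(nopt))
  flags
}

#' Full quality screen of a recording
#'
#' Bundles [detect_saturation()], [cov_artifact_scan()] and
#' [ambient_check()] into one quality-flag object used by the block
#' exclusion policy downstream.
#'
#' @param rec the raw (unfiltered) `fnirs_recording`.
#' @param cov_window_s,cov_step_s,cov_threshold_pct CoV scan settings.
#' @param ambient_max_ratio ambient check setting.
#' @return an object of class `quality_flags`: list with `saturated`
#'   (samples x channels logical), `artifacts` (CoV report), `ambient`
#'   (per-optode logical).
#' @export
screen_recording <- function(rec, cov_window_s = 20, cov_step_s = 5,
                             cov_threshold_pct = 10,
                             ambient_max_ratio = 0.1) {
  structure(list(
    saturated = detect_saturation(rec),
    artifacts = cov_artifact_scan(rec, cov_window_s, cov_step_s,
                                  cov_threshold_pct),
    ambient = ambient_check(rec, ambient_max_ratio)
  ), class = "quality_flags")
}
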