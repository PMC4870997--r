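#' Hemodynamic and noise parameters for the synthetic-data generator
#'
#' Collects the ground-truth response amplitudes and the physiological /
#' instrumental noise model used when simulating raw fNIRS intensities.
#' Response amplitudes are specified per (condition x accuracy) cell in uM of
#' oxygenated hemoglobin (HbO); the deoxygenated (HbR) amplitude defaults to
#' -1/3 of the HbO amplitude, the typical activation ratio (functional
#' activation: dHbO > 0, dHbR < 0).
#'
#' Noise components are sinusoids with random phase at cardiac (~1.1 Hz),
#' respiratory (~0.25 Hz) and Mayer-wave (~0.10 Hz) frequencies, plus linear
#' drift and white noise, all expressed in uM-equivalent units and injected
#' through the forward optical model. Motion artifacts are short spikes (1-3
#' samples) and step shifts in the intensity domain; detector saturation is
#' hard clipping at the ADC ceiling.
#'
#' @param amp_hbo named numeric: HbO response amplitude (uM) per
#'   `condition.accuracy` cell (`ARWD.correct`, `ARWD.incorrect`,
#'   `HHD.correct`, `HHD.incorrect`).
#' @param amp_hbr named numeric of HbR amplitudes; default `-amp_hbo / 3`.
#' @param hrf `"double_gamma"` (canonical hemodynamic response, peak 6 s,
#'   undershoot 16 s, ratio 1:6) or `"boxcar"` (no convolution; piecewise-
#'   constant truth, used for exact round-trip checks).
#' @param hrf_peak_s,hrf_undershoot_s,undershoot_ratio double-gamma shape.
#' @param response_delay_s onset delay of the neural boxcar within each block,
#'   seconds. With `hrf = "boxcar"` a 10 s delay makes the truth zero in the
#'   local-baseline window and exactly `amp` afterwards.
#' @param cardiac_amp,cardiac_hz,resp_amp,resp_hz,mayer_amp,mayer_hz
#'   sinusoidal physiological components (uM-equivalent amplitude, Hz).
#' @param drift_uM_per_min linear drift slope, uM-equivalent per minute.
#' @param white_sd white-noise standard deviation, uM-equivalent.
#' @param detector_noise_rel multiplicative detector noise: per-sample
#'   relative SD of the measured intensity (dimensionless). Mobile outdoor
#'   recordings carry percent-level broadband intensity noise (detector shot
#'   noise, stray-light and coupling fluctuations); the default of 0.075
#'   puts the raw-intensity coefficient of variation near 7.5%, the scale at
#'   which the CoV artifact screen operates.
#' @param hbr_noise_ratio scale of the HbR noise relative to HbO noise.
#' @param spike_rate_per_min expected motion spikes per minute per channel.
#' @param spike_amp_sd spike amplitude in multiples of the channel SD.
#' @param shift_rate_per_min expected baseline step shifts per minute.
#' @param shift_amp_sd step-shift amplitude in multiples of the channel SD.
#' @param saturation_prob probability that an optode suffers one saturation
#'   event (a ~1 s run clipped at the ADC ceiling) during the session.
#' @return an object of class `hemo_params`.
#' @export
hemo_params <- function(amp_hbo = c(ARWD.correct = 0.4, ARWD.incorrect = 0.7,
                                    HHD.correct = 0.6, HHD.incorrect = 0.9),
                        amp_hbr = NULL,
                        hrf = c("double_gamma", "boxcar"),
                        hrf_peak_s = 6, hrf_undershoot_s = 16,
                        undershoot_ratio = 1 / 6,
                        response_delay_s = 0,
                        cardiac_amp = 0.08, cardiac_hz = 1.1,
                        resp_amp = 0.05, resp_hz = 0.25,
                        mayer_amp = 0.04, mayer_hz = 0.10,
                        drift_uM_per_min = 0.02,
                        white_sd = 0.05,
                        detector_noise_rel = 0.075,
                        hbr_noise_ratio = 1 / 3,
                        spike_rate_per_min = 0,
                        spike_amp_sd = 10,
                        shift_rate_per_min = 0,
                        shift_amp_sd = 3,
                        saturation_prob = 0) {
  hrf <- match.arg(hrf)
  cells <- c("ARWD.correct", "ARWD.incorrect", "HHD.correct", "HHD.incorrect")
  if (!all(cells %in% names(amp_hbo)))
    stop("'amp_hbo' must name all four condition.accuracy cells", call. = FALSE)
  if (is.null(amp_hbr)) amp_hbr <- -amp_hbo / 3
  if (!all(cells %in% names(amp_hbr)))
    stop("'amp_hbr' must name all four condition.accuracy cells", call. = FALSE)
  amps <- c(amp_hbo, amp_hbr, cardiac_amp, resp_amp, mayer_amp,
            drift_uM_per_min, white_sd, spike_amp_sd, shift_amp_sd)
  if (any(!is.finite(amps)))
    stop("all amplitudes must be finite", call. = FALSE)
  stopifnot_scalar_num(saturation_prob, "saturation_prob", 0, 1)
  structure(list(
    amp_hbo = amp_hbo[cells], amp_hbr = amp_hbr[cells], hrf = hrf,
    hrf_peak_s = hrf_peak_s, hrf_undershoot_s = hrf_undershoot_s,
    undershoot_ratio = undershoot_ratio, response_delay_s = response_delay_s,
    cardiac_amp = cardiac_amp, cardiac_hz = cardiac_hz,
    resp_amp = resp_amp, resp_hz = resp_hz,
    mayer_amp = mayer_amp, mayer_hz = mayer_hz,
    drift_uM_per_min = drift_uM_per_min, white_sd = white_sd,
    detector_noise_rel = detector_noise_rel,
    hbr_noise_ratio = hbr_noise_ratio,
    spike_rate_per_min = spike_rate_per_min, spike_amp_sd = spike_amp_sd,
    shift_rate_per_min = shift_rate_per_min, shift_amp_sd = shift_amp_sd,
    saturation_prob = saturation_prob
  ), class = "hemo_params")
}

#' Noise-free generator parameters
#'
#' Convenience wrapper: [hemo_params()] with every noise, drift, artifact and
#' saturation component set to zero, for forward-inverse round-trip checks.
#' @param ... passed to [hemo_params()].
#' @export
hemo_params_noiseless <- function(...) {
  args <- list(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
               drift_uM_per_min = 0, white_sd = 0, detector_noise_rel = 0,
               spike_rate_per_min = 0, shift_rate_per_min = 0,
               saturation_prob = 0)
  user <- list(...)
  args[names(user)] <- user
  do.call(hemo_params, args)
}

#' Behavioral effect parameters (log-odds scale)
#'
#' Fixed and random effects of the logistic model generating per-trial binary
#' accuracy: `logit(p) = intercept + group_effect * 1[ARWD] +
#' trial_slope * trial + u_subject + s_subject * trial`, with
#' `u ~ N(0, subject_intercept_sd^2)` and `s ~ N(0, subject_trial_slope_sd^2)`
#' (uncorrelated). Default fixed effects for the 1-back task are the reported
#' log-odds estimates b = 0.528 (reference-group intercept, HHD) and b = 0.551
#' (ARWD - HHD); for the scenery probe, b = 0.914 and b = -0.155.
#'
#' @param intercept_logodds log-odds of a correct response in the reference
#'   (HHD) group.
#' @param group_effect_logodds ARWD - HHD difference, log-odds.
#' @param trial_slope_logodds per-trial change in log-odds.
#' @param subject_intercept_sd SD of subject random intercepts (log-odds).
#' @param subject_trial_slope_sd SD of subject random trial slopes.
#' @return an object of class `behavioral_effects`.
#' @export
behavioral_effects <- function(intercept_logodds = 0.528,
                               group_effect_logodds = 0.551,
                               trial_slope_logodds = 0,
                               subject_intercept_sd = 0.5,
                               subject_trial_slope_sd = 0) {
  if (subject_intercept_sd < 0 || subject_trial_slope_sd < 0)
    stop("random-effect SDs must be >= 0", call. = FALSE)
  structure(list(
    intercept_logodds = intercept_logodds,
    group_effect_logodds = group_effect_logodds,
    trial_slope_logodds = trial_slope_logodds,
    subject_intercept_sd = subject_intercept_sd,
    subject_trial_slope_sd = subject_trial_slope_sd
  ), class = "behavioral_effects")
}

# Default per-task effects: 1-back and scenery probe use their respective
# reported log-odds estimates.
default_behavioral_effects <- function() {
  list(
    oneback = behavioral_effects(0.528, 0.551, 0, 0.5, 0),
    probe = behavioral_effects(0.914, -0.155, 0, 0.5, 0)
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (peak at `peak_s`, undershoot at
#' `undershoot_s`, undershoot amplitude `ratio` of the peak), sampled on a
#' grid of spacing `dt` and normalized to unit area so that convolution with
#' a sustained boxcar of height A plateaus at A.
#'
#' @param dt sample spacing, seconds.
#' @param duration_s support length, seconds.
#' @param peak_s,undershoot_s,ratio shape parameters.
#' @return numeric vector of HRF samples.
#' @export
canonical_hrf <- function(dt = 0.25, duration_s = 40,
                          peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  t <- seq(0, duration_s, by = dt)
  # gamma density parameterized by its mode: shape a, scale b with (a-1)b=mode
  g <- function(t, mode, disp = 1) {
    a <- mode / disp + 1
    stats::dgamma(t, shape = a, scale = disp)
  }
  h <- g(t, peak_s) - ratio * g(t, undershoot_s)
  h / (sum(h) * dt) * dt # unit discrete sum => unit steady-state gain
}

#' Simulate ground-truth hemodynamics for a design
#'
#' Builds the true per-subject, per-optode dHbO/dHbR time series (uM): a
#' block-locked boxcar per secondary-task event, scaled by the
#' (condition x accuracy) cell amplitude and convolved with the canonical
#' double-gamma HRF (or left as a boxcar). Per-block accuracy labels are taken
#' from `responses` (one row per subject x task x trial); if omitted, they are
#' drawn from the default behavioral model under the same master seed.
#'
#' @param design an [make_design()] object.
#' @param params a [hemo_params()] object.
#' @param seed master integer seed; the output is a pure function of
#'   (design, params, seed, responses).
#' @param responses optional response table from [simulate_behavior()].
#' @return an object of class `ground_truth`: list with `t` (time grid), per
#'   subject matrices `hbo[[s]]`, `hbr[[s]]` (samples x optodes, uM), the
#'   per-subject `markers` table (onset, offset, task, block, condition,
#'   accuracy), and `block_truth` — per subject x task x block x optode
#'   baseline-referenced true block means (`true_hbo`, `true_hbr`), i.e. the
#'   block mean of the truth minus its mean over the first `baseline_s`
#'   seconds, the estimand the local-baseline pipeline recovers.
#' @export
simulate_hemodynamics <- function(design, params = hemo_params(), seed,
                                  responses = NULL) {
  stopifnot(inherits(design, "fnirs_design"), inherits(params, "hemo_params"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (is.null(responses))
    responses <- simulate_behavior(design, default_behavioral_effects(), seed)

  fs <- design$fs
  dt <- 1 / fs
  n <- round(design$duration_s * fs)
  t <- (seq_len(n) - 1) * dt
  sched <- design$schedule

  hrf <- if (params$hrf == "double_gamma")
    canonical_hrf(dt = dt, peak_s = params$hrf_peak_s,
                  undershoot_s = params$hrf_undershoot_s,
                  ratio = params$undershoot_ratio)
  else 1 # boxcar: identity kernel

  hbo <- hbr <- vector("list", design$n_subjects)
  names(hbo) <- names(hbr) <- design$subjects
  markers_list <- vector("list", design$n_subjects)
  truth_rows <- vector("list", design$n_subjects)

  for (si in seq_len(design$n_subjects)) {
    subj <- design$subjects[si]
    cond <- unname(design$groups[subj])
    resp_s <- responses[responses$subject == subj, , drop = FALSE]
    acc <- character(nrow(sched))
    for (ev in seq_len(nrow(sched))) {
      row <- resp_s[resp_s$task == sched$task[ev] &
                      resp_s$trial == sched$block[ev], , drop = FALSE]
      acc[ev] <- if (nrow(row) == 1L && row$correct == 1L) "correct"
      else "incorrect"
    }

    boxcar_o <- numeric(n)
    boxcar_r <- numeric(n)
    for (ev in seq_len(nrow(sched))) {
      cell <- paste(cond, acc[ev], sep = ".")
      i0 <- round((sched$onset[ev] + params$response_delay_s) * fs) + 1L
      i1 <- round(sched$offset[ev] * fs)
      if (i0 <= i1) {
        idx <- i0:min(i1, n)
        boxcar_o[idx] <- boxcar_o[idx] + params$amp_hbo[[cell]]
        boxcar_r[idx] <- boxcar_r[idx] + params$amp_hbr[[cell]]
      }
    }
    sig_o <- convolve_causal(boxcar_o, hrf)
    sig_r <- convolve_causal(boxcar_r, hrf)
    hbo[[si]] <- matrix(sig_o, n, design$n_optodes)
    hbr[[si]] <- matrix(sig_r, n, design$n_optodes)

    markers_list[[si]] <- data.frame(
      subject = subj, task = sched$task, block = sched$block,
      onset = sched$onset, offset = sched$offset,
      condition = cond, accuracy = acc)

    # baseline-referenced true block means per optode (identical optodes here)
    bl <- design$baseline_s
    tb <- lapply(seq_len(nrow(sched)), function(ev) {
      i0 <- round(sched$onset[ev] * fs) + 1L
      i1 <- round(sched$offset[ev] * fs)
      ib <- i0:(i0 + round(bl * fs) - 1L)
      data.frame(subject = subj, task = sched$task[ev],
                 block = sched$block[ev], optode = seq_len(design$n_optodes),
                 condition = cond, accuracy = acc[ev],
                 true_hbo = mean(sig_o[i0:i1]) - mean(sig_o[ib]),
                 true_hbr = mean(sig_r[i0:i1]) - mean(sig_r[ib]))
    })
    truth_rows[[si]] <- do.call(rbind, tb)
  }

  structure(list(
    design = design, params = params, seed = seed, t = t,
    hbo = hbo, hbr = hbr,
    markers = do.call(rbind, markers_list),
    block_truth = do.call(rbind, truth_rows),
    responses = responses
  ), class = "ground_truth")
}

# causal FIR convolution truncated to the input length
convolve_causal <- function(x, h) {
  if (length(h) == 1L) return(x * h)
  stats::filter(x, h, method = "convolution", sides = 1) -> y
  y <- as.numeric(y)
  # stats::filter(sides=1) leaves the first length(h)-1 samples NA; fill by
  # direct partial sums (signal assumed zero before t = 0)
  for (i in seq_len(min(length(h) - 1L, length(x)))) {
    y[i] <- sum(h[seq_len(i)] * x[i:1])
  }
  y
}

#' Simulate behavioral responses
#'
#' Draws per-subject, per-trial binary accuracy from the logistic mixed model
#' in [behavioral_effects()], for both secondary tasks. Each subject uses an
#' RNG stream derived from the master seed, so subject subsets reproduce.
#'
#' @param design an [make_design()] object.
#' @param effects a single [behavioral_effects()] object (applied to both
#'   tasks) or a named list with elements `oneback` and `probe`.
#' @param seed master integer seed.
#' @return a `data.frame` (the response table): `subject`, `group`, `task`,
#'   `trial`, `correct` (0/1).
#' @export
simulate_behavior <- function(design, effects = default_behavioral_effects(),
                              seed) {
  stopifnot(inherits(design, "fnirs_design"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (inherits(effects, "behavioral_effects"))
    effects <- list(oneback = effects, probe = effects)
  stopifnot(all(c("oneback", "probe") %in% names(effects)))

  n_trials <- c(oneback = design$n_oneback_blocks,
                probe = design$n_probe_trials)
  rows <- vector("list", design$n_subjects)
  for (si in seq_len(design$n_subjects)) {
    subj <- design$subjects[si]
    grp <- unname(design$groups[subj])
    set.seed(derive_seed(seed, si, salt = 1L))
    per_task <- lapply(c("oneback", "probe"), function(task) {
      ef <- effects[[task]]
      nt <- n_trials[[task]]
      if (nt == 0L) return(NULL)
      u <- stats::rnorm(1, 0, ef$subject_intercept_sd)
      s <- stats::rnorm(1, 0, ef$subject_trial_slope_sd)
      trial <- seq_len(nt)
      eta <- ef$intercept_logodds +
        ef$group_effect_logodds * (grp == "ARWD") +
        (ef$trial_slope_logodds + s) * trial + u
      data.frame(subject = subj, group = grp, task = task, trial = trial,
                 correct = stats::rbinom(nt, 1, stats::plogis(eta)))
    })
    rows[[si]] <- do.call(rbind, per_task)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forward-model raw fNIRS intensities from ground truth
#'
#' Inverts the Modified Beer-Lambert Law: for each optode and wavelength,
#' `I(t) = I0 * 10^(-dOD(t))` with
#' `dOD = (eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF` (concentrations in mM).
#' Physiological noise (cardiac / respiratory / Mayer sinusoids with random
#' phase, linear drift, white noise) is added in uM-equivalent units before
#' the optical forward step; motion spikes (1-3 samples) and step shifts are
#' injected in the intensity domain; saturation events and the ADC ceiling
#' clip intensities at `adc_max`. An ambient-light channel per optode is
#' generated at `ambient_level`.
#'
#' @param truth a [simulate_hemodynamics()] result.
#' @param optics an [optical_constants()] object.
#' @param baseline_intensity detector intensity at zero concentration change
#'   (arbitrary units); scalar or per-channel matrix `optodes x wavelengths`.
#' @param seed master integer seed for the noise/artifact streams.
#' @param adc_max ADC ceiling, same units as the intensities.
#' @param ambient_level mean ambient-channel intensity.
#' @return list with `recordings` (named list of `fnirs_recording`, one per
#'   subject), `markers` (data.frame across subjects), and `events` — the
#'   injected artifact/saturation log (`subject`, `channel`, `type`,
#'   `start_sample`, `end_sample`).
#' @export
simulate_raw_recording <- function(truth, optics = optical_constants(),
                                   baseline_intensity = 1000, seed,
                                   adc_max = 4096, ambient_level = 2) {
  stopifnot(inherits(truth, "ground_truth"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  design <- truth$design
  params <- truth$params
  if (any(baseline_intensity <= 0))
    stop("baseline intensities must be > 0", call. = FALSE)
  eps <- optics$epsilon
  if (abs(det(eps)) < 1e-8)
    stop("extinction-coefficient matrix is near-singular", call. = FALSE)

  fs <- design$fs
  n <- length(truth$t)
  wl <- design$wavelengths
  nopt <- design$n_optodes
  I0 <- if (length(baseline_intensity) == 1L)
    matrix(baseline_intensity, nopt, 2) else baseline_intensity

  recs <- vector("list", design$n_subjects)
  names(recs) <- design$subjects
  events <- list()

  for (si in seq_len(design$n_subjects)) {
    subj <- design$subjects[si]
    set.seed(derive_seed(seed, si, salt = 3L))
    I <- matrix(NA_real_, n, nopt * 2)
    labs <- character(nopt * 2)
    amb <- matrix(NA_real_, n, nopt)

    for (o in seq_len(nopt)) {
      # physiological noise in uM-equivalent, shared across wavelengths of an
      # optode (a common superficial source), independent across optodes
      noise_o <- physio_noise(truth$t, params)
      noise_r <- params$hbr_noise_ratio * physio_noise(truth$t, params)
      hbo_mM <- (truth$hbo[[si]][, o] + noise_o) / 1000
      hbr_mM <- (truth$hbr[[si]][, o] + noise_r) / 1000
      for (w in 1:2) {
        dod <- (eps[w, 1] * hbo_mM + eps[w, 2] * hbr_mM) *
          optics$d * optics$dpf[w]
        intens <- I0[o, w] * 10^(-dod)
        if (any(intens <= 0) || any(!is.finite(intens)))
          stop("computed intensity <= 0: amplitudes too large for the chosen baseline intensity",
               call. = FALSE)
        if (params$detector_noise_rel > 0)
          intens <- intens *
            (1 + stats::rnorm(n, 0, params$detector_noise_rel))
        ci <- (o - 1L) * 2L + w
        labs[ci] <- sprintf("optode%d_%d", o, wl[w])
        sdI <- max(stats::sd(intens), 1e-6)

        # motion spikes: 1-3 sample excursions
        n_spikes <- stats::rpois(1, params$spike_rate_per_min *
                                   design$duration_s / 60)
        if (n_spikes > 0) {
          for (k in seq_len(n_spikes)) {
            at <- sample.int(n - 3L, 1)
            len <- sample(1:3, 1)
            sgn <- sample(c(-1, 1), 1)
            intens[at:(at + len - 1L)] <-
              intens[at:(at + len - 1L)] + sgn * params$spike_amp_sd * sdI
            events[[length(events) + 1L]] <- data.frame(
              subject = subj, channel = labs[ci], type = "spike",
              start_sample = at, end_sample = at + len - 1L)
          }
        }
        # step shifts
        n_shift <- stats::rpois(1, params$shift_rate_per_min *
                                  design$duration_s / 60)
        if (n_shift > 0) {
          for (k in seq_len(n_shift)) {
            at <- sample.int(n - 1L, 1)
            sgn <- sample(c(-1, 1), 1)
            intens[at:n] <- intens[at:n] + sgn * params$shift_amp_sd * sdI
            events[[length(events) + 1L]] <- data.frame(
              subject = subj, channel = labs[ci], type = "shift",
              start_sample = at, end_sample = n)
          }
        }
        intens <- pmax(intens, .Machine$double.eps)
        I[, ci] <- intens
      }
      # saturation event: clip a ~1 s run of both wavelengths at the ceiling
      if (stats::runif(1) < params$saturation_prob) {
        at <- sample.int(n - round(fs), 1)
        run <- at:(at + round(fs) - 1L)
        for (w in 1:2) {
          ci <- (o - 1L) * 2L + w
          I[run, ci] <- adc_max
          events[[length(events) + 1L]] <- data.frame(
            subject = subj, channel = labs[ci], type = "saturation",
            start_sample = min(run), end_sample = max(run))
        }
      }
      amb[, o] <- pmax(ambient_level +
                         stats::rnorm(n, 0, ambient_level / 10), 0)
    }
    I <- pmin(I, adc_max)
    colnames(I) <- labs
    colnames(amb) <- sprintf("optode%d_ambient", seq_len(nopt))
    recs[[si]] <- new_recording(t = truth$t, I = I, ambient = amb, fs = fs,
                                adc_max = adc_max, subject = subj,
                                wavelengths = wl)
  }

  list(recordings = recs,
       markers = truth$markers,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(subject = character(), channel = character(),
                    type = character(), start_sample = integer(),
                    end_sample = integer()))
}

# cardiac + respiratory + Mayer sinusoids (random phase) + drift + white noise
physio_noise <- function(t, params) {
  ph <- stats::runif(3, 0, 2 * pi)
  params$cardiac_amp * sin(2 * pi * params$cardiac_hz * t + ph[1]) +
    params$resp_amp * sin(2 * pi * params$resp_hz * t + ph[2]) +
    params$mayer_amp * sin(2 * pi * params$mayer_hz * t + ph[3]) +
    params$drift_uM_per_min * t / 60 +
    stats::rnorm(length(t), 0, params$white_sd)
}

#' Simulate a complete experiment
#'
#' Convenience wrapper chaining [simulate_behavior()],
#' [simulate_hemodynamics()] and [simulate_raw_recording()] under one master
#' seed.
#'
#' @inheritParams simulate_hemodynamics
#' @inheritParams simulate_raw_recording
#' @param effects behavioral effects (see [simulate_behavior()]).
#' @return list: `design`, `truth`, `responses`, `recordings`, `markers`,
#'   `events`.
#' @export
simulate_experiment <- function(design = make_design(),
                                params = hemo_params(),
                                effects = default_behavioral_effects(),
                                optics = optical_constants(),
                                baseline_intensity = 1000,
                                adc_max = 4096, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  responses <- simulate_behavior(design, effects, seed)
  truth <- simulate_hemodynamics(design, params, seed, responses)
  raw <- simulate_raw_recording(truth, optics, baseline_intensity, seed,
                                adc_max = adc_max)
  list(design = design, truth = truth, responses = responses,
       recordings = raw$recordings, markers = raw$markers,
       events = raw$events)
}
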