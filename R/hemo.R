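#' Optical constants for the Modified Beer-Lambert Law
#'
#' Extinction coefficients, source-detector separation and differential
#' pathlength factors used to convert optical-density changes into
#' hemoglobin concentration changes. The packaged default extinction table
#' is the widely used compilation of hemoglobin spectra distributed by the
#' Oregon Medical Laser Center (Prahl), at 730 and 850 nm, converted to
#' 1/(mM*cm). Defaults `d = 2.5 cm` and `DPF = 6.0` at both wavelengths are
#' typical adult-forehead values; every conversion property of the pipeline
#' is a forward-inverse round trip, so results hold for any nonsingular
#' table.
#'
#' @param epsilon 2x2 matrix of extinction coefficients, rows = wavelengths
#'   (730, 850 nm), columns = chromophores (HbO, HbR), units 1/(mM*cm).
#' @param d source-detector separation, cm.
#' @param dpf differential pathlength factor per wavelength (length 2).
#' @param source free-text provenance label for the epsilon table.
#' @return an object of class `optical_constants`.
#' @export
optical_constants <- function(epsilon = matrix(c(0.3900, 1.1022,
                                                 1.0580, 0.6913),
                                               nrow = 2, byrow = TRUE,
                                               dimnames = list(
                                                 c("730", "850"),
                                                 c("HbO", "HbR"))),
                              d = 2.5,
                              dpf = c(6.0, 6.0),
                              source = "OMLC hemoglobin spectra compilation (Prahl), 1/(mM cm)") {
  if (!is.matrix(epsilon) || any(dim(epsilon) != 2))
    stop("'epsilon' must be a 2x2 matrix (wavelength x chromophore)",
         call. = FALSE)
  if (abs(det(epsilon)) < 1e-6)
    stop("'epsilon' is near-singular: the two wavelengths cannot separate HbO from HbR",
         call. = FALSE)
  stopifnot_scalar_num(d, "d", 0, strict_lower = TRUE)
  if (length(dpf) == 1L) dpf <- rep(dpf, 2)
  if (length(dpf) != 2L || any(dpf <= 0))
    stop("'dpf' must be one or two positive values", call. = FALSE)
  structure(list(epsilon = epsilon, d = d, dpf = dpf, source = source),
            class = "optical_constants")
}

#' Extract task blocks from a recording
#'
#' Slices the recording at the time-synchronization markers of task onset and
#' end. Sample indices use the half-open window
#' `[round(onset * fs), round(offset * fs))` (0-based), i.e. R rows
#' `(round(onset * fs) + 1) : round(offset * fs)`; the local-baseline window
#' is the first `baseline_s` seconds of each block.
#'
#' @param rec an `fnirs_recording` (typically filtered).
#' @param markers data.frame with columns `subject`, `task`, `block`,
#'   `onset`, `offset`, `condition`, `accuracy` (seconds); only rows matching
#'   `rec$subject` are used.
#' @param baseline_s local-baseline length, seconds.
#' @return list of `block_segment` objects: each holds the intensity slice
#'   (`I`), its sample index range (`idx`), the baseline rows
#'   (`baseline_idx`, relative to the slice), and the marker metadata.
#' @export
extract_blocks <- function(rec, markers, baseline_s = 10) {
  stopifnot(inherits(rec, "fnirs_recording"))
  mk <- markers[markers$subject == rec$subject, , drop = FALSE]
  if (nrow(mk) == 0L)
    stop(sprintf("no markers for subject %s", rec$subject), call. = FALSE)
  fs <- rec$fs
  n <- nrow(rec$I)
  nb <- round(baseline_s * fs)
  lapply(seq_len(nrow(mk)), function(i) {
    onset <- mk$onset[i]; offset <- mk$offset[i]
    if (onset >= offset)
      stop(sprintf("block %s/%s %d: onset >= offset", rec$subject,
                   mk$task[i], mk$block[i]), call. = FALSE)
    i0 <- round(onset * fs) + 1L
    i1 <- round(offset * fs)
    if (i1 > n)
      stop(sprintf("block %s/%s %d: marker offset (%g s) lies beyond the end of the recording (%g s)",
                   rec$subject, mk$task[i], mk$block[i], offset, n / fs),
           call. = FALSE)
    if (i1 - i0 + 1L < nb)
      stop(sprintf("block %s/%s %d: duration %g s is shorter than the %g s baseline",
                   rec$subject, mk$task[i], mk$block[i], offset - onset,
                   baseline_s), call. = FALSE)
    structure(list(
      I = rec$I[i0:i1, , drop = FALSE],
      t = rec$t[i0:i1],
      idx = c(i0, i1),
      baseline_idx = seq_len(nb),
      fs = fs,
      subject = rec$subject,
      task = mk$task[i], block = mk$block[i],
      condition = mk$condition[i], accuracy = mk$accuracy[i],
      n_optodes = rec$n_optodes, wavelengths = rec$wavelengths
    ), class = "block_segment")
  })
}

#' Modified Beer-Lambert conversion of a block segment
#'
#' Computes optical-density changes against the block's local baseline and
#' solves the two-wavelength system for chromophore concentration changes:
#' \deqn{\Delta OD(\lambda, t) = -\log_{10}\!\frac{I_\lambda(t)}{\bar I_{\lambda,\mathrm{baseline}}}}
#' \deqn{\varepsilon \begin{bmatrix}\Delta HbO\\ \Delta HbR\end{bmatrix} =
#'   \begin{bmatrix}\Delta OD(730)/(d\,DPF_{730})\\
#'                  \Delta OD(850)/(d\,DPF_{850})\end{bmatrix}}
#' With epsilon in 1/(mM*cm) and d in cm, the solution is in mM and is scaled
#' by 1000 to uM.
#'
#' @param seg a `block_segment` from [extract_blocks()].
#' @param optics an [optical_constants()] object.
#' @return an object of class `hb_series`: list with `hbo`, `hbr`
#'   (samples x optodes, uM), `dod` (samples x channels), time grid and the
#'   block metadata.
#' @export
mbll_convert <- function(seg, optics = optical_constants()) {
  stopifnot(inherits(seg, "block_segment"),
            inherits(optics, "optical_constants"))
  if (any(seg$I <= 0))
    stop("non-positive intensity inside block: cannot form optical density",
         call. = FALSE)
  base_mean <- colMeans(seg$I[seg$baseline_idx, , drop = FALSE])
  if (any(base_mean <= 0))
    stop("non-positive baseline mean intensity", call. = FALSE)
  dod <- -log10(sweep(seg$I, 2, base_mean, "/"))

  nopt <- seg$n_optodes
  n <- nrow(seg$I)
  hbo <- hbr <- matrix(NA_real_, n, nopt)
  einv <- solve(optics$epsilon) # 2x2; validated nonsingular at construction
  for (o in seq_len(nopt)) {
    c730 <- grep(sprintf("^optode%d_%d$", o, seg$wavelengths[1]),
                 colnames(seg$I))
    c850 <- grep(sprintf("^optode%d_%d$", o, seg$wavelengths[2]),
                 colnames(seg$I))
    if (length(c730) != 1L || length(c850) != 1L)
      stop(sprintf("optode %d: missing wavelength channel", o), call. = FALSE)
    rhs <- rbind(dod[, c730] / (optics$d * optics$dpf[1]),
                 dod[, c850] / (optics$d * optics$dpf[2]))
    hb_mM <- einv %*% rhs
    hbo[, o] <- hb_mM[1, ] * 1000
    hbr[, o] <- hb_mM[2, ] * 1000
  }
  structure(list(
    hbo = hbo, hbr = hbr, dod = dod, t = seg$t, fs = seg$fs,
    subject = seg$subject, task = seg$task, block = seg$block,
    condition = seg$condition, accuracy = seg$accuracy,
    idx = seg$idx, baseline_idx = seg$baseline_idx
  ), class = "hb_series")
}

#' Sub-block binning and block summary
#'
#' Divides a block's hemoglobin series into consecutive `bin_s`-second
#' sub-blocks, averages each across time (trailing partial bin dropped), and
#' computes the block means of dHbO and dHbR per optode. If quality flags are
#' supplied, blocks overlapping a saturated sample or a flagged CoV window on
#' any of their channels — or sitting on an ambient-contaminated optode — are
#' marked; under `policy = "exclude"` (default) such blocks carry
#' `excluded = TRUE` with a reason, under `"warn"` they are annotated only.
#'
#' @param hb an `hb_series` from [mbll_convert()].
#' @param bin_s sub-block length, seconds.
#' @param flags optional `quality_flags` from [screen_recording()].
#' @param policy `"exclude"` or `"warn"`.
#' @return list of class `block_summary`: `blocks` — one row per optode with
#'   block-mean `HbO`, `HbR`, `excluded`, `reason`; `subblocks` — one row per
#'   optode x sub-block with its mean `HbO`, `HbR`.
#' @export
bin_block_series <- function(hb, bin_s = 10, flags = NULL,
                             policy = c("exclude", "warn")) {
  stopifnot(inherits(hb, "hb_series"))
  policy <- match.arg(policy)
  n <- nrow(hb$hbo)
  blen <- round(bin_s * hb$fs)
  if (blen > n)
    stop("'bin_s' exceeds the block duration", call. = FALSE)
  nbins <- n %/% blen
  nopt <- ncol(hb$hbo)

  reason <- qc_reason(hb, flags)
  excluded <- policy == "exclude" & nzchar(reason)

  sub <- do.call(rbind, lapply(seq_len(nopt), function(o) {
    means_o <- vapply(seq_len(nbins), function(b)
      mean(hb$hbo[((b - 1) * blen + 1):(b * blen), o]), numeric(1))
    means_r <- vapply(seq_len(nbins), function(b)
      mean(hb$hbr[((b - 1) * blen + 1):(b * blen), o]), numeric(1))
    data.frame(subject = hb$subject, task = hb$task, block = hb$block,
               optode = o, condition = hb$condition, accuracy = hb$accuracy,
               subblock = seq_len(nbins), HbO = means_o, HbR = means_r,
               excluded = excluded[o], reason = reason[o])
  }))
  blocks <- data.frame(
    subject = hb$subject, task = hb$task, block = hb$block,
    optode = seq_len(nopt), condition = hb$condition, accuracy = hb$accuracy,
    n_subblocks = nbins,
    HbO = colMeans(hb$hbo), HbR = colMeans(hb$hbr),
    excluded = excluded, reason = reason)
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, subblocks = sub), class = "block_summary")
}

# per-optode QC reason string ("" = clean) for the samples a block spans
qc_reason <- function(hb, flags) {
  nopt <- ncol(hb$hbo)
  reason <- character(nopt)
  if (is.null(flags)) return(reason)
  span <- hb$idx[1]:hb$idx[2]
  for (o in seq_len(nopt)) {
    r <- character(0)
    ch_pat <- sprintf("^optode%d_", o)
    sat_cols <- grep(ch_pat, colnames(flags$saturated))
    if (length(sat_cols) && any(flags$saturated[span, sat_cols]))
      r <- c(r, "saturation")
    art <- flags$artifacts
    art <- art[grepl(ch_pat, art$channel) & art$flagged, , drop = FALSE]
    if (nrow(art) &&
        any(art$start_sample <= hb$idx[2] & art$end_sample >= hb$idx[1]))
      r <- c(r, "motion_artifact")
    if (isTRUE(unname(flags$ambient[o]))) r <- c(r, "ambient_light")
    reason[o] <- paste(r, collapse = "+")
  }
  reason
}

#' Convert a whole recording into tidy block summaries
#'
#' Orchestrates [extract_blocks()], [mbll_convert()] and
#' [bin_block_series()] for every marker of one subject, returning tidy
#' tables at both the block-mean and sub-block grain — the input contract of
#' the statistical module.
#'
#' @param rec an `fnirs_recording` (typically filtered).
#' @param markers the marker table (see [extract_blocks()]).
#' @param optics an [optical_constants()] object.
#' @param flags optional `quality_flags` computed on the raw recording.
#' @param baseline_s,bin_s baseline and sub-block lengths, seconds.
#' @param policy block exclusion policy, see [bin_block_series()].
#' @return list with `blocks` and `subblocks` data.frames (all optodes, all
#'   markers of this subject).
#' @export
summarize_blocks <- function(rec, markers, optics = optical_constants(),
                             flags = NULL, baseline_s = 10, bin_s = 10,
                             policy = c("exclude", "warn")) {
  policy <- match.arg(policy)
  segs <- extract_blocks(rec, markers, baseline_s)
  res <- lapply(segs, function(seg)
    bin_block_series(mbll_convert(seg, optics), bin_s, flags, policy))
  list(blocks = do.call(rbind, lapply(res, `[[`, "blocks")),
       subblocks = do.call(rbind, lapply(res, `[[`, "subblocks")))
}
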