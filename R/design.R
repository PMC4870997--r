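#' Define a dual-task fNIRS experiment design
#'
#' Builds the fixed layout of a mobile dual-task session: a between-subject
#' device manipulation (augmented-reality wearable display, `ARWD`, vs.
#' hand-held display, `HHD`), repeated auditory 1-back blocks and scenery-probe
#' trials performed while navigating, and the optical sampling parameters of a
#' four-optode prefrontal fNIRS montage. Defaults reproduce the reference
#' design: 20 subjects split 10/10 between devices, 37 one-back blocks of 60 s,
#' 10 probe trials of 30 s, at least 15 s of pure navigation between secondary
#' tasks, sampling at 4 Hz with wavelengths 730/850 nm.
#'
#' The construction is fully deterministic: the block/probe schedule (probes
#' interleaved evenly among the 1-back blocks) is part of the design, mirroring
#' preplanned task positions along the navigation routes.
#'
#' @param n_subjects total number of subjects (split as evenly as possible
#'   between the two groups, first half `ARWD`).
#' @param group_assignment optional character vector of length `n_subjects`
#'   with entries in `c("ARWD", "HHD")`; overrides the default split.
#' @param n_oneback_blocks number of auditory 1-back blocks per subject.
#' @param oneback_block_s duration of each 1-back block, seconds.
#' @param n_probe_trials number of scenery-probe trials per subject.
#' @param probe_trial_s duration of each probe trial, seconds.
#' @param inter_block_gap_s navigation-only gap between secondary tasks,
#'   seconds (the reference design guarantees at least 15 s).
#' @param fs optical sampling rate, Hz.
#' @param n_optodes number of optodes (source-detector sites).
#' @param wavelengths the two laser wavelengths, nm.
#' @param baseline_s local-baseline length used downstream; blocks must be at
#'   least this long.
#' @return an object of class `fnirs_design`: a list with the fields above
#'   plus `subjects` (labels), `groups` (named assignment) and `schedule`
#'   (data.frame of task, block index, onset and offset in seconds, common to
#'   all subjects).
#' @examples
#' d <- make_design()
#' d$n_subjects
#' head(d$schedule)
#' # a miniature design for quick experimentation
#' make_design(n_subjects = 4, n_oneback_blocks = 3, n_probe_trials = 2)
#' @export
make_design <- function(n_subjects = 20L,
                        group_assignment = NULL,
                        n_oneback_blocks = 37L,
                        oneback_block_s = 60,
                        n_probe_trials = 10L,
                        probe_trial_s = 30,
                        inter_block_gap_s = 15,
                        fs = 4,
                        n_optodes = 4L,
                        wavelengths = c(730, 850),
                        baseline_s = 10) {
  stopifnot_scalar_num(n_subjects, "n_subjects", lower = 1)
  stopifnot_scalar_num(n_oneback_blocks, "n_oneback_blocks", lower = 0)
  stopifnot_scalar_num(n_probe_trials, "n_probe_trials", lower = 0)
  stopifnot_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_num(n_optodes, "n_optodes", lower = 1)
  stopifnot_scalar_num(inter_block_gap_s, "inter_block_gap_s", lower = 0)
  stopifnot_scalar_num(baseline_s, "baseline_s", lower = 0,
                       strict_lower = TRUE)
  if (length(wavelengths) != 2L || any(!is.finite(wavelengths)))
    stop("'wavelengths' must be a pair of finite values (nm)", call. = FALSE)
  if (oneback_block_s < baseline_s)
    stop(sprintf(
      "invalid design: 'oneback_block_s' (%g s) is shorter than the %g s local baseline",
      oneback_block_s, baseline_s), call. = FALSE)
  if (probe_trial_s < baseline_s)
    stop(sprintf(
      "invalid design: 'probe_trial_s' (%g s) is shorter than the %g s local baseline",
      probe_trial_s, baseline_s), call. = FALSE)

  n_subjects <- as.integer(n_subjects)
  subjects <- subject_labels(n_subjects)
  if (is.null(group_assignment)) {
    n_arwd <- ceiling(n_subjects / 2)
    group_assignment <- rep(c("ARWD", "HHD"),
                            c(n_arwd, n_subjects - n_arwd))
  }
  if (length(group_assignment) != n_subjects ||
      !all(group_assignment %in% c("ARWD", "HHD")))
    stop("'group_assignment' must give 'ARWD' or 'HHD' for every subject",
         call. = FALSE)
  groups <- stats::setNames(group_assignment, subjects)

  design <- structure(list(
    n_subjects = n_subjects,
    subjects = subjects,
    groups = groups,
    n_oneback_blocks = as.integer(n_oneback_blocks),
    oneback_block_s = oneback_block_s,
    n_probe_trials = as.integer(n_probe_trials),
    probe_trial_s = probe_trial_s,
    inter_block_gap_s = inter_block_gap_s,
    fs = fs,
    n_optodes = as.integer(n_optodes),
    wavelengths = wavelengths,
    baseline_s = baseline_s
  ), class = "fnirs_design")
  design$schedule <- design_schedule(design)
  design$duration_s <- max(design$schedule$offset) + inter_block_gap_s
  design
}

# Deterministic event schedule: probes spread evenly among 1-back blocks,
# every event preceded by a navigation-only gap.
design_schedule <- function(design) {
  n1 <- design$n_oneback_blocks
  n2 <- design$n_probe_trials
  tasks <- rep("oneback", n1)
  if (n2 > 0L) {
    # insert probe j after a proportional share of the 1-back blocks
    pos <- floor(seq_len(n2) * n1 / (n2 + 1))
    seqs <- character(0)
    prev <- 0L
    for (j in seq_len(n2)) {
      seqs <- c(seqs, rep("oneback", pos[j] - prev), "probe")
      prev <- pos[j]
    }
    tasks <- c(seqs, rep("oneback", n1 - prev))
  }
  dur <- ifelse(tasks == "oneback", design$oneback_block_s,
                design$probe_trial_s)
  gap <- design$inter_block_gap_s
  onset <- gap + cumsum(c(0, (dur + gap)[-length(dur)]))
  block <- stats::ave(seq_along(tasks), tasks, FUN = seq_along)
  data.frame(task = tasks, block = block,
             onset = onset, offset = onset + dur)
}

#' @export
print.fnirs_design <- function(x, ...) {
  cat(sprintf(
    "fNIRS dual-task design: %d subjects (%d ARWD / %d HHD)\n",
    x$n_subjects, sum(x$groups == "ARWD"), sum(x$groups == "HHD")))
  cat(sprintf("  %d one-back blocks x %g s, %d probe trials x %g s, gaps %g s\n",
              x$n_oneback_blocks, x$oneback_block_s, x$n_probe_trials,
              x$probe_trial_s, x$inter_block_gap_s))
  cat(sprintf("  fs = %g Hz, %d optodes, wavelengths %g/%g nm, session %g s\n",
              x$fs, x$n_optodes, x$wavelengths[1], x$wavelengths[2],
              x$duration_s))
  invisible(x)
}
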