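# CSV + JSON-sidecar I/O for recordings, markers and responses. The dialect
# is deliberately plain: one recording CSV per subject with columns
# time, optode<N>_730, optode<N>_850, optode<N>_ambient, plus a JSON sidecar
# carrying fs, adc_max, subject and wavelengths. Vendor formats (e.g. SNIRF)
# can be adapted to this surface by an import shim.

#' Write / read a recording
#'
#' `write_recording()` writes the intensity CSV and its JSON sidecar
#' (`<path>.json`); `read_recording()` validates and reconstructs the
#' `fnirs_recording` so that write-then-read is the identity on values.
#'
#' @param rec an `fnirs_recording`.
#' @param path CSV file path.
#' @return `read_recording()` returns an `fnirs_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fnirs_recording"))
  df <- data.frame(time = rec$t, rec$I, rec$ambient, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, adc_max = rec$adc_max, subject = rec$subject,
         wavelengths = rec$wavelengths, n_optodes = rec$n_optodes),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param sidecar path of the JSON sidecar (default `<path>.json`).
#' @param n_optodes expected number of optodes; a missing channel is an
#'   error naming it.
#' @export
read_recording <- function(path, sidecar = paste0(path, ".json"),
                           n_optodes = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar: %s", sidecar), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("recording CSV lacks a 'time' column", call. = FALSE)
  nopt <- n_optodes %||% meta$n_optodes
  wl <- meta$wavelengths
  want <- c(t(outer(seq_len(nopt), c(wl, "ambient"),
                    function(o, w) sprintf("optode%d_%s", o, w))))
  missing_ch <- setdiff(want, names(df))
  if (length(missing_ch))
    stop(sprintf("recording CSV lacks channel(s): %s",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  t <- df$time
  dtt <- diff(t)
  if (any(dtt <= 0) || max(abs(dtt - 1 / meta$fs)) > 1e-6 / meta$fs) {
    bad <- which(abs(dtt - 1 / meta$fs) > 1e-6 / meta$fs)[1]
    stop(sprintf("non-uniform time grid at line %d (data row %d)",
                 bad + 2L, bad + 1L), call. = FALSE)
  }
  det_cols <- sprintf("optode%d_%s", rep(seq_len(nopt), each = 2),
                      rep(wl, nopt))
  I <- as.matrix(df[det_cols])
  if (any(I < 0)) {
    bad <- which(rowSums(I < 0) > 0)[1]
    stop(sprintf("negative intensity at line %d (data row %d)",
                 bad + 1L, bad), call. = FALSE)
  }
  amb <- as.matrix(df[sprintf("optode%d_ambient", seq_len(nopt))])
  new_recording(t = t, I = I, ambient = amb, fs = meta$fs,
                adc_max = meta$adc_max, subject = meta$subject,
                wavelengths = wl)
}

#' Write / read marker tables
#'
#' Markers carry one row per secondary-task block: `subject`, `task`
#' (`oneback`/`probe`), `block`, `onset`, `offset` (seconds), `condition`
#' (`ARWD`/`HHD`) and per-block `accuracy`. Reading validates onsets against
#' offsets and rejects overlapping blocks within a subject — the two
#' secondary tasks never occur simultaneously.
#'
#' @param markers marker data.frame.
#' @param path CSV file path.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(markers, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  mk <- utils::read.csv(path)
  need <- c("subject", "task", "block", "onset", "offset", "condition",
            "accuracy")
  miss <- setdiff(need, names(mk))
  if (length(miss))
    stop(sprintf("marker CSV lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(mk$onset >= mk$offset))
    stop("marker with onset >= offset", call. = FALSE)
  for (s in unique(mk$subject)) {
    ms <- mk[mk$subject == s, ]
    ms <- ms[order(ms$onset), ]
    if (nrow(ms) > 1L && any(ms$onset[-1] < ms$offset[-nrow(ms)]))
      stop(sprintf(
        "subject %s has overlapping secondary-task blocks: the tasks never occur simultaneously",
        s), call. = FALSE)
  }
  mk
}

#' Write / read behavioral response tables
#'
#' One row per subject x task x trial with the binary outcome `correct`.
#'
#' @param responses response data.frame.
#' @param path CSV file path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  rs <- utils::read.csv(path)
  need <- c("subject", "group", "task", "trial", "correct")
  miss <- setdiff(need, names(rs))
  if (length(miss))
    stop(sprintf("response CSV lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!all(rs$correct %in% c(0, 1)))
    stop("'correct' must be 0/1", call. = FALSE)
  if (any(stats::aggregate(group ~ subject, rs,
                           function(g) length(unique(g)))$group != 1L))
    stop("group assignment must be constant within subject", call. = FALSE)
  dup <- duplicated(rs[c("subject", "task", "trial")])
  if (any(dup))
    stop("duplicate subject x task x trial row in responses", call. = FALSE)
  rs
}

#' Write a simulated experiment to disk
#'
#' Emits the pipeline's input files: one recording CSV (+ JSON sidecar) per
#' subject, a marker CSV, a response CSV, and a ground-truth JSON sidecar
#' (true block means and the injected artifact/saturation event log) for
#' validation against the analysis output.
#'
#' @param exper a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of file paths.
#' @export
write_experiment <- function(exper, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(markers = file.path(dir, "markers.csv"),
                responses = file.path(dir, "responses.csv"),
                truth = file.path(dir, "ground_truth.json"),
                recordings = character(0))
  write_markers(exper$markers, paths$markers)
  write_responses(exper$responses, paths$responses)
  for (s in names(exper$recordings)) {
    p <- file.path(dir, sprintf("recording_%s.csv", s))
    write_recording(exper$recordings[[s]], p)
    paths$recordings <- c(paths$recordings, p)
  }
  jsonlite::write_json(
    list(block_truth = exper$truth$block_truth, events = exper$events),
    paths$truth, digits = NA, dataframe = "columns")
  invisible(paths)
}

#' Export filter taps for audit
#'
#' @param filt a [design_lowpass_fir()] object.
#' @param path JSON file path.
#' @export
write_filter_taps <- function(filt, path) {
  jsonlite::write_json(
    list(taps = filt$taps, order = filt$order, cutoff_hz = filt$cutoff_hz,
         fs = filt$fs, window = filt$window),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
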