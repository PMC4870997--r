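#' Assemble a run configuration
#'
#' Collects every tunable of the pipeline — input paths, signal-processing
#' settings, optical constants, binning, model ladders and the FDR level —
#' with defaults matching the reference analysis. The configuration is
#' echoed into every report for provenance.
#'
#' @param recording_paths character vector of recording CSVs (sidecars
#'   assumed at `<path>.json`); may be `NULL` when an in-memory experiment
#'   is passed to [run_analysis()].
#' @param marker_path,response_path input CSVs (ignored for in-memory runs).
#' @param out_dir default output directory for [write_report()].
#' @param filter_order,filter_cutoff_hz FIR design (see
#'   [design_lowpass_fir()]).
#' @param cov_window_s,cov_step_s,cov_threshold_pct CoV artifact scan.
#' @param ambient_max_ratio ambient-light screen.
#' @param policy `"exclude"` (drop flagged blocks) or `"warn"`.
#' @param optics an [optical_constants()] object.
#' @param baseline_s,bin_s local-baseline and sub-block lengths, seconds.
#' @param grain `"subblock"` (default; one model row per 10 s sub-block,
#'   supporting a random block slope) or `"block"` (block means).
#' @param hemo_fixed,hemo_random candidate ladders for the hemodynamic
#'   models (fixed-term strings x random structures).
#' @param behavior_fixed,behavior_random ladders for the behavioral models.
#' @param alpha FDR level.
#' @param fdr_rows contrast rows entering the FDR families (`NULL` = every
#'   row with a test except the descriptive grand-mean `"Mean"` row, which
#'   is not a device/accuracy hypothesis).
#' @param seed integer seed echoed into outputs (the analysis itself is
#'   deterministic given its inputs).
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(recording_paths = NULL, marker_path = NULL,
                       response_path = NULL, out_dir = "fnirsdual_report",
                       filter_order = 20L, filter_cutoff_hz = 0.1,
                       cov_window_s = 20, cov_step_s = 5,
                       cov_threshold_pct = 10, ambient_max_ratio = 0.1,
                       policy = c("exclude", "warn"),
                       optics = optical_constants(),
                       baseline_s = 10, bin_s = 10,
                       grain = c("subblock", "block"),
                       hemo_fixed = c("1", "condition",
                                      "condition + accuracy",
                                      "condition * accuracy"),
                       hemo_random = c("intercept", "intercept_slope",
                                       "slope"),
                       behavior_fixed = c("1", "group", "group + trial_c",
                                          "group * trial_c"),
                       behavior_random = c("intercept", "intercept_slope"),
                       alpha = 0.05, fdr_rows = NULL, seed = 1L) {
  structure(list(
    recording_paths = recording_paths, marker_path = marker_path,
    response_path = response_path, out_dir = out_dir,
    filter_order = filter_order, filter_cutoff_hz = filter_cutoff_hz,
    cov_window_s = cov_window_s, cov_step_s = cov_step_s,
    cov_threshold_pct = cov_threshold_pct,
    ambient_max_ratio = ambient_max_ratio,
    policy = match.arg(policy), optics = optics,
    baseline_s = baseline_s, bin_s = bin_s, grain = match.arg(grain),
    hemo_fixed = hemo_fixed, hemo_random = hemo_random,
    behavior_fixed = behavior_fixed, behavior_random = behavior_random,
    alpha = alpha, fdr_rows = fdr_rows, seed = seed
  ), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes screen -> filter -> block extraction -> Modified Beer-Lambert
#' conversion -> sub-block binning -> mixed-model selection -> contrasts ->
#' FDR correction -> behavioral models, from files named in the config or
#' from an in-memory [simulate_experiment()] result. The run is
#' deterministic given its inputs and configuration.
#'
#' @param config a [run_config()].
#' @param experiment optional in-memory experiment (list with `recordings`,
#'   `markers`, `responses`); when given, file paths in the config are
#'   ignored.
#' @return an object of class `report_bundle`: `contrasts` (per task x
#'   chromophore x optode contrast rows with FDR decisions), `selection`
#'   (BIC ledger), `behavioral` (log-odds tables per task), `families`
#'   (the `fdr_family` objects), `qc` (per-subject counts and exclusion
#'   reasons), `varcomp` (variance components of the chosen models),
#'   `config`.
#' @export
run_analysis <- function(config = run_config(), experiment = NULL) {
  stopifnot(inherits(config, "run_config"))

  inputs <- stage("read", {
    if (!is.null(experiment)) {
      list(recordings = experiment$recordings,
           markers = experiment$markers,
           responses = experiment$responses)
    } else {
      if (is.null(config$recording_paths))
        stop("no recordings: supply 'experiment' or config paths")
      list(recordings = stats::setNames(
        lapply(config$recording_paths, read_recording),
        vapply(config$recording_paths, function(p)
          jsonlite::read_json(paste0(p, ".json"))$subject, character(1))),
        markers = read_markers(config$marker_path),
        responses = read_responses(config$response_path))
    }
  })

  filt <- design_lowpass_fir(config$filter_order, config$filter_cutoff_hz,
                             inputs$recordings[[1]]$fs)

  conv <- stage("signal_processing", {
    per_subj <- lapply(inputs$recordings, function(rec) {
      flags <- screen_recording(rec, config$cov_window_s, config$cov_step_s,
                                config$cov_threshold_pct,
                                config$ambient_max_ratio)
      frec <- filter_recording(rec, filt)
      sm <- summarize_blocks(frec, inputs$markers, config$optics, flags,
                             config$baseline_s, config$bin_s, config$policy)
      sm
    })
    list(blocks = do.call(rbind, lapply(per_subj, `[[`, "blocks")),
         subblocks = do.call(rbind, lapply(per_subj, `[[`, "subblocks")))
  })

  model_data <- stage("assemble", {
    dat <- if (config$grain == "subblock") conv$subblocks else conv$blocks
    dat$condition <- factor(dat$condition, levels = c("HHD", "ARWD"))
    dat$accuracy <- factor(dat$accuracy, levels = c("correct", "incorrect"))
    # center the block index within task so contrasts sit at the mid-session
    dat$block_c <- stats::ave(dat$block, dat$task, FUN = function(b)
      b - mean(b))
    rownames(dat) <- NULL
    dat
  })

  hemo_res <- stage("hemodynamic_models", {
    rows <- list(); sel_rows <- list(); vc_rows <- list()
    dat_ok <- model_data[!model_data$excluded, , drop = FALSE]
    for (task in sort(unique(dat_ok$task))) {
      for (chrom in c("HbO", "HbR")) {
        for (opt in sort(unique(dat_ok$optode))) {
          d <- dat_ok[dat_ok$task == task & dat_ok$optode == opt, ,
                      drop = FALSE]
          if (nrow(d) == 0L) next # whole optode excluded by QC
          cands <- list()
          for (r in config$hemo_random) for (f in config$hemo_fixed)
            cands[[length(cands) + 1L]] <-
              model_spec(chrom, f, r, "block_c", "gaussian", "ML")
          sel <- select_by_bic(cands, d, refit = "REML")
          ct <- cell_contrasts(sel$fit)
          ct$task <- task; ct$chromophore <- chrom; ct$optode <- opt
          rows[[length(rows) + 1L]] <- ct
          st <- sel$table
          st$task <- task; st$chromophore <- chrom; st$optode <- opt
          st$chosen <- st$label == sel$chosen_label
          sel_rows[[length(sel_rows) + 1L]] <- st
          vc <- sel$fit$varcomp
          if (nrow(vc)) {
            vc$task <- task; vc$chromophore <- chrom; vc$optode <- opt
            vc_rows[[length(vc_rows) + 1L]] <- vc
          }
        }
      }
    }
    list(contrasts = do.call(rbind, rows),
         selection = do.call(rbind, sel_rows),
         varcomp = do.call(rbind, vc_rows))
  })

  fam_res <- stage("fdr", {
    ct <- hemo_res$contrasts
    fams <- list()
    for (task in sort(unique(ct$task))) for (chrom in c("HbO", "HbR")) {
      sub <- ct[ct$task == task & ct$chromophore == chrom &
                  is.finite(ct$p), , drop = FALSE]
      # the grand-mean row is descriptive, not a device/accuracy hypothesis
      sub <- if (!is.null(config$fdr_rows))
        sub[sub$row %in% config$fdr_rows, , drop = FALSE]
      else sub[sub$row != "Mean", , drop = FALSE]
      fams[[paste(task, chrom, sep = ".")]] <-
        fdr_family(task, chrom, sub$p,
                   sprintf("optode%d:%s", sub$optode, sub$row))
    }
    bh_fdr(fams, config$alpha)
  })

  contrasts <- stage("annotate", {
    ct <- hemo_res$contrasts
    ct$fdr_reject <- FALSE
    for (fam in fam_res) {
      sub_idx <- which(ct$task == fam$task & ct$chromophore ==
                         fam$chromophore & is.finite(ct$p))
      sub_idx <- if (!is.null(config$fdr_rows))
        sub_idx[ct$row[sub_idx] %in% config$fdr_rows]
      else sub_idx[ct$row[sub_idx] != "Mean"]
      ct$fdr_reject[sub_idx] <- fam$reject
    }
    ct$sig <- ifelse(ct$fdr_reject, "*", "")
    ct[c("task", "chromophore", "optode", "row", "estimate", "se", "df",
         "stat", "p", "fdr_reject", "sig")]
  })

  behav <- stage("behavioral_models", {
    out <- list(); sel_out <- list()
    rs <- inputs$responses
    rs$group <- factor(rs$group, levels = c("HHD", "ARWD"))
    for (task in sort(unique(rs$task))) {
      d <- rs[rs$task == task, , drop = FALSE]
      d$trial_c <- d$trial - mean(d$trial)
      cands <- list()
      for (r in config$behavior_random) for (f in config$behavior_fixed)
        cands[[length(cands) + 1L]] <-
          model_spec("correct", f, r, "trial_c", "binomial", "ML")
      sel <- select_by_bic(cands, d, refit = "ML")
      tab <- sel$fit$coef
      tab$task <- task
      out[[task]] <- tab
      st <- sel$table; st$task <- task
      st$chosen <- st$label == sel$chosen_label
      sel_out[[task]] <- st
    }
    list(tables = do.call(rbind, out), selection = do.call(rbind, sel_out))
  })

  qc <- stage("qc_summary", {
    bl <- conv$blocks
    agg <- do.call(rbind, lapply(split(bl, bl$subject), function(b) {
      data.frame(subject = b$subject[1],
                 n_markers = length(unique(paste(b$task, b$block))),
                 n_block_optode = nrow(b),
                 n_analyzed = sum(!b$excluded),
                 n_excluded = sum(b$excluded),
                 reasons = paste(sort(unique(b$reason[nzchar(b$reason)])),
                                 collapse = ";"))
    }))
    rownames(agg) <- NULL
    agg
  })

  structure(list(
    contrasts = contrasts,
    selection = rbind_fill(hemo_res$selection),
    varcomp = hemo_res$varcomp,
    families = fam_res,
    behavioral = behav$tables,
    behavioral_selection = behav$selection,
    qc = qc,
    blocks = conv$blocks,
    filter = filt,
    config = config
  ), class = "report_bundle")
}

rbind_fill <- function(x) x # selection tables share columns; kept for clarity

#' Write a report bundle to disk
#'
#' One CSV per contrast table (task x chromophore x optode), the behavioral
#' tables, the BIC selection ledger, variance components and the QC summary,
#' plus a JSON manifest (file list + configuration echo) and a plain-text
#' summary whose significance markers (`*`) are keyed to the FDR decisions.
#' An empty or partial bundle yields a manifest flagged incomplete.
#'
#' @param bundle a [run_analysis()] result (possibly partial).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  complete <- TRUE
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }

  if (!is.null(bundle$contrasts) && nrow(bundle$contrasts)) {
    ct <- bundle$contrasts
    for (task in unique(ct$task)) for (chrom in unique(ct$chromophore))
      for (opt in unique(ct$optode)) {
        sub <- ct[ct$task == task & ct$chromophore == chrom &
                    ct$optode == opt, , drop = FALSE]
        if (nrow(sub))
          emit(sub, sprintf("contrasts_%s_%s_optode%d.csv", task, chrom,
                            opt))
      }
  } else complete <- FALSE
  if (!is.null(bundle$behavioral) && nrow(bundle$behavioral)) {
    for (task in unique(bundle$behavioral$task))
      emit(bundle$behavioral[bundle$behavioral$task == task, ],
           sprintf("behavioral_%s.csv", task))
  } else complete <- FALSE
  if (!is.null(bundle$selection)) emit(bundle$selection, "selection.csv")
  if (!is.null(bundle$behavioral_selection))
    emit(bundle$behavioral_selection, "behavioral_selection.csv")
  if (!is.null(bundle$varcomp)) emit(bundle$varcomp, "varcomp.csv")
  if (!is.null(bundle$qc)) emit(bundle$qc, "qc_summary.csv")
  if (!is.null(bundle$filter)) {
    write_filter_taps(bundle$filter, file.path(dir, "filter_taps.json"))
    files <- c(files, "filter_taps.json")
  }

  # human-readable summary with FDR-keyed significance markers
  sump <- file.path(dir, "summary.txt")
  con <- file(sump, "w")
  on.exit(close(con))
  writeLines("fnirsdual analysis summary", con)
  writeLines(sprintf("generated: deterministic run, seed %s",
                     bundle$config$seed %||% "NA"), con)
  if (!is.null(bundle$contrasts) && nrow(bundle$contrasts)) {
    writeLines("\nHemodynamic contrasts ('*' = significant after BH-FDR within task x chromophore):",
               con)
    ct <- bundle$contrasts
    for (i in seq_len(nrow(ct))) {
      if (nzchar(ct$sig[i]))
        writeLines(sprintf("  %s %s optode%d  %-32s %8.3f (SE %.3f, p=%.4f) %s",
                           ct$task[i], ct$chromophore[i], ct$optode[i],
                           ct$row[i], ct$estimate[i], ct$se[i], ct$p[i],
                           ct$sig[i]), con)
    }
    writeLines(sprintf("  (%d of %d rows significant)",
                       sum(ct$fdr_reject), nrow(ct)), con)
  }
  if (!is.null(bundle$qc)) {
    writeLines("\nQC: per-subject block x optode counts (analyzed + excluded = total):",
               con)
    for (i in seq_len(nrow(bundle$qc)))
      writeLines(sprintf("  %s: %d analyzed, %d excluded%s",
                         bundle$qc$subject[i], bundle$qc$n_analyzed[i],
                         bundle$qc$n_excluded[i],
                         ifelse(nzchar(bundle$qc$reasons[i]),
                                paste0(" (", bundle$qc$reasons[i], ")"),
                                "")), con)
  }
  files <- c(files, "summary.txt")

  manifest <- list(files = files, complete = complete,
                   config = config_echo(bundle$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

config_echo <- function(config) {
  if (is.null(config)) return(NULL)
  out <- unclass(config)
  out$optics <- list(epsilon = config$optics$epsilon, d = config$optics$d,
                     dpf = config$optics$dpf, source = config$optics$source)
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("fnirsdual report bundle\n")
  if (!is.null(x$contrasts))
    cat(sprintf("  %d contrast rows (%d FDR-significant) over %d task x chromophore x optode tables\n",
                nrow(x$contrasts), sum(x$contrasts$fdr_reject),
                nrow(unique(x$contrasts[c("task", "chromophore",
                                          "optode")]))))
  if (!is.null(x$behavioral))
    cat(sprintf("  behavioral tables: %s\n",
                paste(unique(x$behavioral$task), collapse = ", ")))
  if (!is.null(x$qc))
    cat(sprintf("  QC: %d subjects, %d block x optode units excluded\n",
                nrow(x$qc), sum(x$qc$n_excluded)))
  invisible(x)
}
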