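#' Default candidate model ladders
#'
#' The fixed-by-random grids of candidate models submitted to the BIC
#' strength-of-evidence selection. For hemodynamic responses the fixed
#' ladder grows from the null model (no fixed effects) through device
#' condition, accuracy, their interaction and a block ("trial") slope;
#' the random ladder covers subject intercepts, uncorrelated block slopes
#' and a slope-only structure. For behavioral responses the fixed ladder is
#' condition, trial and their interaction with subject intercepts and
#' optional uncorrelated trial slopes. Every ladder contains the null model:
#' no fixed effects with a subject random intercept.
#'
#' @param response response column name.
#' @param slope_var within-subject slope column (centered block or trial
#'   index).
#' @return list of [model_spec()] objects.
#' @export
candidate_ladder_hemo <- function(response = "HbO", slope_var = "block_c") {
  fixed <- c("1", "condition", "condition + accuracy",
             "condition * accuracy",
             paste0("condition * accuracy + ", slope_var),
             paste0("condition * accuracy + condition * ", slope_var))
  random <- c("intercept", "intercept_slope", "slope")
  specs <- list()
  for (r in random) for (f in fixed)
    specs[[length(specs) + 1L]] <-
      model_spec(response, f, r, slope_var, "gaussian", "ML")
  specs
}

#' @rdname candidate_ladder_hemo
#' @export
candidate_ladder_behavior <- function(response = "correct",
                                      slope_var = "trial_c") {
  fixed <- c("1", "group", paste0("group + ", slope_var),
             paste0("group * ", slope_var))
  specs <- list()
  for (r in c("intercept", "intercept_slope")) for (f in fixed)
    specs[[length(specs) + 1L]] <-
      model_spec(response, f, r, slope_var, "binomial", "ML")
  specs
}

#' Select fixed and random effects by BIC
#'
#' Fits every candidate by maximum likelihood, ranks them by
#' `BIC = -2 logLik + k log n`, and applies the strength-of-evidence rule:
#' a BIC difference greater than 2 is treated as meaningful. The selected
#' model has the lowest BIC, except that when a simpler model (fewer
#' parameters) lies within 2 BIC of the minimum, the simpler model is
#' retained and the comparison is flagged "not meaningful". Gaussian winners
#' are refitted with REML for coefficient reporting; binomial winners keep
#' their ML fit. Candidates that fail to converge are excluded and logged,
#' never silently dropped.
#'
#' @param candidates list of [model_spec()] objects; must include the null
#'   spec (no fixed effects, subject random intercept).
#' @param data the model data.
#' @param refit `"REML"` (default, gaussian only) or `"ML"`: criterion for
#'   the final reported fit.
#' @return an object of class `bic_selection`: `table` (one row per
#'   candidate: label, k, BIC, delta_bic vs. the minimum,
#'   delta_vs_chosen, meaningful flag, converged, singular), `chosen_label`,
#'   `chosen_spec`, `fit` (the refitted chosen model), `excluded`
#'   (labels + error messages of non-converging candidates), and `note`
#'   recording any within-2 tie resolution.
#' @export
select_by_bic <- function(candidates, data, refit = c("REML", "ML")) {
  refit <- match.arg(refit)
  if (inherits(candidates, "model_spec")) candidates <- list(candidates)
  stopifnot(length(candidates) >= 1L,
            all(vapply(candidates, inherits, logical(1), "model_spec")))
  has_null <- any(vapply(candidates, function(s)
    s$fixed == "1" && s$random == "intercept", logical(1)))
  if (!has_null)
    stop("candidate set must include the null model (no fixed effects, subject random intercept)",
         call. = FALSE)

  fits <- vector("list", length(candidates))
  errs <- character(length(candidates))
  for (i in seq_along(candidates)) {
    spec <- candidates[[i]]
    spec$estimation <- "ML" # selection is always on the ML criterion
    res <- tryCatch({
      if (spec$family == "binomial") fit_glmm_binomial(spec, data)
      else fit_lmm(spec, data)
    }, error = function(e) {
      errs[i] <<- conditionMessage(e)
      NULL
    })
    # a separated binomial fit has no comparable likelihood
    if (!is.null(res) && isTRUE(res$separation)) {
      errs[i] <- "separation: estimates diverge, fit excluded from selection"
      res <- NULL
    }
    fits[i] <- list(res)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate model converged", call. = FALSE)

  labels <- vapply(candidates, spec_label, character(1))
  k <- vapply(seq_along(fits), function(i)
    if (ok[i]) fits[[i]]$k else NA_integer_, numeric(1))
  bic <- vapply(seq_along(fits), function(i)
    if (ok[i]) fits[[i]]$BIC else NA_real_, numeric(1))
  singular <- vapply(seq_along(fits), function(i)
    if (ok[i]) fits[[i]]$singular else NA, logical(1))

  best_bic <- min(bic[ok])
  delta <- bic - best_bic
  # strength-of-evidence tie-break: within 2 BIC of the minimum, prefer the
  # most parsimonious model
  cand_idx <- which(ok & delta <= 2)
  chosen_idx <- cand_idx[order(k[cand_idx], delta[cand_idx])][1]
  note <- if (delta[chosen_idx] > 0)
    sprintf("within-2 BIC tie resolved toward fewer parameters: '%s' (dBIC = %.2f) over the minimum-BIC model",
            labels[chosen_idx], delta[chosen_idx]) else ""

  delta_chosen <- bic - bic[chosen_idx]
  tab <- data.frame(
    label = labels, k = k, BIC = bic,
    delta_bic = delta, delta_vs_chosen = delta_chosen,
    meaningful = delta_chosen > 2,
    converged = ok, singular = singular)
  rownames(tab) <- NULL

  chosen_spec <- candidates[[chosen_idx]]
  final <- if (chosen_spec$family == "gaussian" && refit == "REML") {
    sp <- chosen_spec
    sp$estimation <- if (sp$random == "none") "ML" else "REML"
    fit_lmm(sp, data)
  } else fits[[chosen_idx]]

  structure(list(
    table = tab,
    chosen_label = labels[chosen_idx],
    chosen_spec = chosen_spec,
    fit = final,
    excluded = data.frame(label = labels[!ok], error = errs[!ok]),
    note = note
  ), class = "bic_selection")
}

#' @export
print.bic_selection <- function(x, ...) {
  cat("BIC strength-of-evidence selection\n")
  tab <- x$table[order(x$table$BIC), ]
  print(tab, row.names = FALSE, digits = 5)
  cat(sprintf("chosen: %s\n", x$chosen_label))
  if (nzchar(x$note)) cat(" ", x$note, "\n")
  if (nrow(x$excluded))
    cat(sprintf("excluded (non-convergence): %s\n",
                paste(x$excluded$label, collapse = "; ")))
  invisible(x)
}
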