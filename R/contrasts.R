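#' Cell-mean and difference contrasts in the report vocabulary
#'
#' Translates a reference-coded fit into the report table rows: estimated
#' cell means for each device (ARWD, HHD) by accuracy (correct, incorrect)
#' combination, marginal means, and their differences
#' (`Incorrect-Correct`, `HHD-ARWD`, within-device accuracy differences and
#' between-device differences at fixed accuracy). Because every row is a
#' linear contrast `c'b` of the same coefficient vector, cells and
#' differences are exactly mutually consistent. Standard errors are
#' `sqrt(c'Vc)` from the fit's coefficient covariance; gaussian fits get
#' Satterthwaite degrees of freedom and t-tests, binomial fits Wald z.
#' Covariates other than the condition/accuracy factors (e.g. a centered
#' block index) are evaluated at 0, i.e. at their center.
#'
#' When the fit lacks the accuracy factor the scheme degrades to
#' device-only rows; a null fit yields the overall mean only. Custom rows
#' can be supplied as named numeric contrast vectors over the coefficient
#' names; referencing a coefficient absent from the model is an error naming
#' the term.
#'
#' @param fit an `fnirs_fit` with reference-coded `condition` and/or
#'   `accuracy` fixed effects.
#' @param custom optional named list of contrast vectors (each of length
#'   `nrow(fit$coef)`, or named by coefficient).
#' @return a `data.frame` of class `contrast_table`: `row`, `estimate`,
#'   `se`, `df`, `stat`, `p`.
#' @export
cell_contrasts <- function(fit, custom = NULL) {
  stopifnot(inherits(fit, "fnirs_fit"))
  if (isTRUE(fit$separation))
    stop("cannot form contrasts from a separated fit", call. = FALSE)
  coefs <- fit$coef$term

  cond_var <- if (any(grepl("^condition", coefs))) "condition"
  else if (any(grepl("^group", coefs))) "group" else NA
  cond_levels <- cell_levels(fit, cond_var, c("HHD", "ARWD"))
  acc_levels <- cell_levels(fit, "accuracy", c("correct", "incorrect"))
  has_cond <- !is.na(cond_var) &&
    any(grepl(paste0("^", cond_var), coefs))
  has_acc <- any(grepl("^accuracy", coefs))

  cellvec <- function(cond = NA, acc = NA) {
    vapply(coefs, function(nm)
      coef_indicator(nm, cond_var, cond, acc), numeric(1))
  }

  rows <- list()
  if (has_cond && has_acc) {
    cells <- list()
    for (cn in cond_levels) for (ac in acc_levels)
      cells[[paste0(cn, ":", ac)]] <- cellvec(cn, ac)
    avg <- function(a, b) (a + b) / 2
    A <- cond_levels[cond_levels != "HHD"][1] # non-reference device
    rows <- list(
      "Correct" = avg(cells[[paste0(A, ":correct")]],
                      cells[["HHD:correct"]]),
      "Incorrect" = avg(cells[[paste0(A, ":incorrect")]],
                        cells[["HHD:incorrect"]]),
      "ARWD" = avg(cells[[paste0(A, ":correct")]],
                   cells[[paste0(A, ":incorrect")]]),
      "HHD" = avg(cells[["HHD:correct"]], cells[["HHD:incorrect"]])
    )
    rows[["Incorrect-Correct"]] <- rows[["Incorrect"]] - rows[["Correct"]]
    rows[["HHD-ARWD"]] <- rows[["HHD"]] - rows[["ARWD"]]
    rows[["ARWD: Correct"]] <- cells[[paste0(A, ":correct")]]
    rows[["ARWD: Incorrect"]] <- cells[[paste0(A, ":incorrect")]]
    rows[["ARWD: Incorrect-Correct"]] <-
      cells[[paste0(A, ":incorrect")]] - cells[[paste0(A, ":correct")]]
    rows[["HHD: Correct"]] <- cells[["HHD:correct"]]
    rows[["HHD: Incorrect"]] <- cells[["HHD:incorrect"]]
    rows[["HHD: Incorrect-Correct"]] <-
      cells[["HHD:incorrect"]] - cells[["HHD:correct"]]
    rows[["HHD: Correct-ARWD: Correct"]] <-
      cells[["HHD:correct"]] - cells[[paste0(A, ":correct")]]
    rows[["HHD: Incorrect-ARWD: Incorrect"]] <-
      cells[["HHD:incorrect"]] - cells[[paste0(A, ":incorrect")]]
    ord <- c("Correct", "Incorrect", "Incorrect-Correct", "ARWD", "HHD",
             "HHD-ARWD", "ARWD: Correct", "ARWD: Incorrect",
             "ARWD: Incorrect-Correct", "HHD: Correct", "HHD: Incorrect",
             "HHD: Incorrect-Correct", "HHD: Correct-ARWD: Correct",
             "HHD: Incorrect-ARWD: Incorrect")
    rows <- rows[ord]
  } else if (has_cond) {
    A <- cond_levels[cond_levels != "HHD"][1]
    rows[["ARWD"]] <- cellvec(cond = A)
    rows[["HHD"]] <- cellvec(cond = "HHD")
    rows[["HHD-ARWD"]] <- rows[["HHD"]] - rows[["ARWD"]]
  } else {
    rows[["Mean"]] <- cellvec()
  }

  if (!is.null(custom)) {
    for (nm in names(custom)) {
      cv <- custom[[nm]]
      if (!is.null(names(cv))) {
        absent <- setdiff(names(cv), coefs)
        if (length(absent))
          stop(sprintf("contrast '%s' requests absent term(s): %s", nm,
                       paste(absent, collapse = ", ")), call. = FALSE)
        full <- stats::setNames(numeric(length(coefs)), coefs)
        full[names(cv)] <- cv
        cv <- unname(full)
      }
      if (length(cv) != length(coefs))
        stop(sprintf("contrast '%s' must have %d entries", nm,
                     length(coefs)), call. = FALSE)
      rows[[nm]] <- cv
    }
  }

  out <- do.call(rbind, lapply(names(rows), function(nm)
    eval_contrast(fit, rows[[nm]], nm)))
  rownames(out) <- NULL
  class(out) <- c("contrast_table", "data.frame")
  attr(out, "contrasts") <- rows
  out
}

cell_levels <- function(fit, var, fallback) {
  if (is.na(var)) return(fallback)
  lv <- fit$xlevels[[var]]
  if (is.null(lv)) fallback else lv
}

# value of one reference-coded coefficient at a (condition, accuracy) cell
coef_indicator <- function(nm, cond_var, cond, acc) {
  if (nm == "(Intercept)") return(1)
  parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
  val <- 1
  for (p in parts) {
    if (!is.na(cond_var) && startsWith(p, cond_var)) {
      lvl <- substring(p, nchar(cond_var) + 1)
      val <- val * as.numeric(!is.na(cond) && cond == lvl)
    } else if (startsWith(p, "accuracy")) {
      lvl <- substring(p, nchar("accuracy") + 1)
      val <- val * as.numeric(!is.na(acc) && acc == lvl)
    } else {
      val <- 0 # other covariates evaluated at 0 (their center)
    }
  }
  val
}

eval_contrast <- function(fit, cvec, name) {
  est <- sum(cvec * fit$coef$estimate)
  if (all(cvec == 0))
    return(data.frame(row = name, estimate = 0, se = 0, df = NA_real_,
                      stat = NA_real_, p = NA_real_))
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  if (fit$family == "gaussian") {
    df <- suppressWarnings(satterthwaite_df(fit, cvec))
    stat <- est / se
    p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df) else NA_real_
  } else {
    df <- NA_real_
    stat <- est / se
    p <- 2 * stats::pnorm(-abs(stat))
  }
  data.frame(row = name, estimate = est, se = se, df = as.numeric(df),
             stat = stat, p = p)
}
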