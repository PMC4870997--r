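#' Specify a mixed-effects model
#'
#' A compact declaration of one candidate model: the response, the
#' fixed-effect structure (an R formula right-hand side such as
#' `"condition * accuracy"`), the subject-level random structure, the family
#' and the estimation criterion. Random slopes are always uncorrelated with
#' the random intercept (fitted as `(1|subject) + (0 + slope|subject)`),
#' matching the uncorrelated-slopes parameterization used for the behavioral
#' models.
#'
#' @param response response column: one of the hemoglobin summaries (`HbO`,
#'   `HbR`) or the binary `correct`.
#' @param fixed right-hand-side string of fixed terms (`"1"` = none).
#' @param random `"intercept"`, `"intercept_slope"`, `"slope"` (slope only,
#'   no intercept) or `"none"`.
#' @param slope_var data column carrying the within-subject slope variable
#'   (block or trial index, typically centered).
#' @param family `"gaussian"` or `"binomial"`.
#' @param estimation `"ML"` or `"REML"` (gaussian only; binomial models are
#'   always ML).
#' @return an object of class `model_spec`.
#' @examples
#' model_spec("HbO", "condition * accuracy", "intercept_slope",
#'            slope_var = "block_c")
#' @export
model_spec <- function(response, fixed = "1",
                       random = c("intercept", "intercept_slope", "slope",
                                  "none"),
                       slope_var = "block_c",
                       family = c("gaussian", "binomial"),
                       estimation = c("ML", "REML")) {
  random <- match.arg(random)
  family <- match.arg(family)
  estimation <- match.arg(estimation)
  if (family == "binomial" && estimation == "REML")
    stop("binomial models cannot be fitted by REML", call. = FALSE)
  if (random %in% c("intercept_slope", "slope") && !nzchar(slope_var))
    stop("'slope_var' required for a random-slope structure", call. = FALSE)
  structure(list(response = response, fixed = fixed, random = random,
                 slope_var = slope_var, family = family,
                 estimation = estimation),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rand <- switch(spec$random,
    none = NULL,
    intercept = "(1 | subject)",
    slope = sprintf("(0 + %s | subject)", spec$slope_var),
    intercept_slope = sprintf("(1 | subject) + (0 + %s | subject)",
                              spec$slope_var))
  rhs <- paste(c(spec$fixed, rand), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", rhs))
}

spec_label <- function(spec) {
  sprintf("%s ~ %s | %s", spec$response, spec$fixed, spec$random)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %s  [%s, %s]\n", spec_label(x), x$family,
              x$estimation))
  invisible(x)
}

# shared guts: assemble the fnirs_fit object from a fitted model
build_fit <- function(spec, fit, data, singular, messages) {
  # mer summaries may warn while inverting the Hessian; keep the message on
  # the fit record instead of the console
  caught <- character(0)
  out <- withCallingHandlers(
    build_fit_(spec, fit, data, singular, messages),
    warning = function(w) {
      caught <<- c(caught, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  out$messages <- unique(c(out$messages, caught))
  out
}

build_fit_ <- function(spec, fit, data, singular, messages) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  bic <- -2 * as.numeric(ll) + k * log(n)
  is_mer <- inherits(fit, "merMod")
  cf <- as.data.frame(stats::coef(summary(fit)))
  if (is_mer && spec$family == "gaussian" && ncol(cf) >= 5) {
    coef_tab <- data.frame(term = rownames(cf), estimate = cf[[1]],
                           se = cf[[2]], df = cf[[3]], stat = cf[[4]],
                           p = cf[[5]])
  } else if (is_mer) { # binomial: Wald z
    coef_tab <- data.frame(term = rownames(cf), estimate = cf[[1]],
                           se = cf[[2]], df = NA_real_, stat = cf[[3]],
                           p = cf[[4]])
  } else if (inherits(fit, "glm")) {
    coef_tab <- data.frame(term = rownames(cf), estimate = cf[[1]],
                           se = cf[[2]], df = NA_real_, stat = cf[[3]],
                           p = cf[[4]])
  } else { # lm
    coef_tab <- data.frame(term = rownames(cf), estimate = cf[[1]],
                           se = cf[[2]], df = stats::df.residual(fit),
                           stat = cf[[3]], p = cf[[4]])
  }
  rownames(coef_tab) <- NULL

  if (is_mer) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- data.frame(group = vc$grp,
                          term = ifelse(is.na(vc$var1), "", vc$var1),
                          var = vc$vcov, sd = vc$sdcor)
  } else if (inherits(fit, "lm") && !inherits(fit, "glm")) {
    s2 <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
    varcomp <- data.frame(group = "Residual", term = "", var = s2,
                          sd = sqrt(s2))
  } else {
    varcomp <- data.frame(group = character(), term = character(),
                          var = numeric(), sd = numeric())
  }

  mf <- stats::model.frame(fit)
  xlev <- lapply(Filter(is.factor, mf), levels)

  structure(list(
    spec = spec, fit = fit, family = spec$family,
    estimation = spec$estimation,
    coef = coef_tab, vcov = as.matrix(stats::vcov(fit)),
    logLik = as.numeric(ll), BIC = bic, n = n, k = k,
    varcomp = varcomp, singular = singular, separation = FALSE,
    messages = messages, xlevels = xlev
  ), class = "fnirs_fit")
}

check_fixed_rank <- function(spec, data) {
  X <- stats::model.matrix(stats::reformulate(spec$fixed), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient fixed-effect design: term(s) %s aliased",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
}

#' Fit a gaussian linear mixed model
#'
#' Fits the declared model with `lmerTest::lmer` (so Satterthwaite degrees of
#' freedom and p-values are available) by the requested criterion, or with
#' `lm` when the random structure is `"none"`. Singular (boundary) variance
#' fits are returned with `singular = TRUE`, never silently simplified;
#' rank-deficient fixed designs raise an error naming the aliased term.
#'
#' @param spec a gaussian [model_spec()].
#' @param data tidy block/sub-block table with the referenced columns and a
#'   `subject` column.
#' @return an object of class `fnirs_fit`: coefficient table (`estimate`,
#'   `se`, `df`, `stat`, `p`), `logLik`, `BIC` (`-2 logLik + k log n`),
#'   variance components (`var = sd^2`), covariance of the fixed effects,
#'   and fit diagnostics.
#' @export
fit_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "gaussian")
    stop("fit_lmm() is for gaussian responses; use fit_glmm_binomial()",
         call. = FALSE)
  vars <- all.vars(spec_formula(spec))
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop(sprintf("data lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (spec$random != "none" && length(unique(data$subject)) < 2L)
    stop("at least 2 subjects required for a mixed model", call. = FALSE)
  check_fixed_rank(spec, data)

  msgs <- character(0)
  if (spec$random == "none") {
    fit <- stats::lm(spec_formula(spec), data = data)
    return(build_fit(spec, fit, data, singular = FALSE, messages = msgs))
  }
  fit <- withCallingHandlers(
    lmerTest::lmer(spec_formula(spec), data = data,
                   REML = spec$estimation == "REML"),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  build_fit(spec, fit, data, singular = lme4::isSingular(fit),
            messages = msgs)
}

#' Fit a binomial generalized linear mixed model
#'
#' Fits the declared logistic model with `lme4::glmer` (Laplace
#' approximation; the method is recorded in the fit) and reports log-odds
#' coefficients with Wald standard errors, z statistics and p-values.
#' Complete separation — a response with no variation overall or explosive
#' estimates — is flagged, with non-finite estimates for the degenerate case
#' rather than a misleading finite fit.
#'
#' @param spec a binomial [model_spec()] (`estimation = "ML"`).
#' @param data response table with a binary response column and `subject`.
#' @return an `fnirs_fit`; `$separation` is `TRUE` when separation was
#'   detected and `$method` records the integral approximation.
#' @export
fit_glmm_binomial <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "binomial")
    stop("spec family must be 'binomial'", call. = FALSE)
  y <- data[[spec$response]]
  if (!all(y %in% c(0, 1)))
    stop("response must be binary 0/1", call. = FALSE)
  check_fixed_rank(spec, data)

  if (length(unique(y)) < 2L) {
    # degenerate: no response variation => intercept diverges
    est <- if (y[1] == 1) Inf else -Inf
    out <- structure(list(
      spec = spec, fit = NULL, family = "binomial", estimation = "ML",
      coef = data.frame(term = "(Intercept)", estimate = est, se = NA_real_,
                        df = NA_real_, stat = NA_real_, p = NA_real_),
      vcov = matrix(NA_real_, 1, 1), logLik = 0,
      BIC = NA_real_, n = length(y), k = 1L,
      varcomp = data.frame(group = character(), term = character(),
                           var = numeric(), sd = numeric()),
      singular = FALSE, separation = TRUE,
      messages = "complete separation: response has no variation",
      xlevels = list(), method = "none"
    ), class = "fnirs_fit")
    return(out)
  }

  msgs <- character(0)
  if (spec$random == "none") {
    fit <- stats::glm(spec_formula(spec), data = data,
                      family = stats::binomial())
    out <- build_fit(spec, fit, data, singular = FALSE, messages = msgs)
    out$method <- "glm"
  } else {
    fit <- withCallingHandlers(
      lme4::glmer(spec_formula(spec), data = data,
                  family = stats::binomial()),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    out <- build_fit(spec, fit, data, singular = lme4::isSingular(fit),
                     messages = msgs)
    out$method <- "Laplace"
  }
  if (any(abs(out$coef$estimate) > 10 | out$coef$se > 25, na.rm = TRUE)) {
    out$separation <- TRUE
    out$messages <- c(out$messages,
                      "possible separation: extreme log-odds estimate")
  }
  out
}

#' @export
print.fnirs_fit <- function(x, ...) {
  cat(sprintf("%s mixed-model fit (%s): %s\n", x$family, x$estimation,
              spec_label(x$spec)))
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, BIC = %.3f%s%s\n",
              x$n, x$k, x$logLik, x$BIC,
              if (x$singular) " [singular]" else "",
              if (x$separation) " [separation]" else ""))
  print(x$coef, row.names = FALSE, digits = 4)
  if (nrow(x$varcomp)) {
    cat("  random effects:\n")
    print(x$varcomp, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Satterthwaite denominator degrees of freedom for a contrast
#'
#' For a gaussian mixed-model fit, approximates the denominator degrees of
#' freedom of the t-statistic for the linear contrast `c'b` as
#' `df = 2 (c'Vc)^2 / Var(c'Vc)`, where the variance of the quadratic form
#' is obtained by the delta method over the estimated variance components
#' (computed via the `lmerTest` machinery). For a fixed-effects-only fit the
#' formula reduces to the residual degrees of freedom `n - k`. The result is
#' invariant under scaling of the contrast vector.
#'
#' @param fit an `fnirs_fit` (gaussian).
#' @param contrast numeric contrast vector, one entry per fixed coefficient.
#' @return degrees of freedom (scalar); `NA` with a `"diagnostic"` attribute
#'   when the variance approximation fails.
#' @export
satterthwaite_df <- function(fit, contrast) {
  stopifnot(inherits(fit, "fnirs_fit"))
  if (fit$family != "gaussian")
    stop("Satterthwaite df require a gaussian fit (binomial models use Wald z)",
         call. = FALSE)
  p <- nrow(fit$coef)
  if (length(contrast) != p)
    stop(sprintf("contrast must have %d entries (one per coefficient)", p),
         call. = FALSE)
  if (inherits(fit$fit, "lm")) {
    return(stats::df.residual(fit$fit))
  }
  res <- tryCatch(
    lmerTest::contest1D(fit$fit, contrast, ddf = "Satterthwaite"),
    error = function(e) e)
  if (inherits(res, "error") || !is.finite(res$df) || res$df <= 0) {
    out <- NA_real_
    attr(out, "diagnostic") <-
      "non-positive or unavailable variance estimate in Satterthwaite approximation"
    return(out)
  }
  res$df
}
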