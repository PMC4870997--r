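#' Benjamini-Hochberg step-up decisions for one set of p-values
#'
#' Orders the m p-values, finds the largest rank k with
#' `p_(k) <= (k/m) * alpha`, and rejects every hypothesis with
#' `p <= p_(k)` (none when no rank qualifies). This is the adaptive
#' false-discovery-rate threshold: the cutoff grows with the rank of the
#' p-value and shrinks with the number of hypotheses tested.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha target false-discovery rate.
#' @return list: `reject` (logical, in input order), `k` (largest rejected
#'   rank, 0 if none), `threshold` (the rejection cutoff `p_(k)`, 0 if
#'   none), `alpha`, `m`.
#' @examples
#' bh_reject(c(0.001, 0.02, 0.04, 0.30), alpha = 0.05) # rejects the 2 smallest
#' @export
bh_reject <- function(p, alpha = 0.05) {
  if (length(p) == 0L)
    return(list(reject = logical(0), k = 0L, threshold = 0,
                alpha = alpha, m = 0L))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stopifnot_scalar_num(alpha, "alpha", 0, 1)
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) / m * alpha)
  if (length(ok) == 0L)
    return(list(reject = rep(FALSE, m), k = 0L, threshold = 0,
                alpha = alpha, m = m))
  k <- max(ok)
  thr <- ps[k]
  list(reject = p <= thr, k = k, threshold = thr, alpha = alpha, m = m)
}

#' Construct an FDR family
#'
#' A family groups the p-values corrected together: here one secondary task
#' crossed with one chromophore, pooling hypotheses across optodes and
#' contrast rows.
#'
#' @param task secondary task label (e.g. `"oneback"`).
#' @param chromophore `"HbO"` or `"HbR"`.
#' @param p p-values of the family's hypotheses.
#' @param labels optional hypothesis labels (same length as `p`).
#' @return an object of class `fdr_family`.
#' @export
fdr_family <- function(task, chromophore, p, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("h%d", seq_along(p))
  if (length(labels) != length(p))
    stop("'labels' must match 'p' in length", call. = FALSE)
  if (length(p) && (any(!is.finite(p)) || any(p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  structure(list(task = task, chromophore = chromophore,
                 p = p, labels = labels),
            class = "fdr_family")
}

#' Apply Benjamini-Hochberg FDR control within families
#'
#' Runs the step-up rule independently within each family (one secondary
#' task by one chromophore, hypotheses pooled across optodes), recording the
#' rejection mask, the largest rejected rank and the rejection threshold.
#'
#' @param families an `fdr_family` or list of them.
#' @param alpha target false-discovery rate (default 0.05).
#' @return the families, each augmented with `reject`, `k`, `threshold`,
#'   `alpha`; a single family input returns a single family.
#' @export
bh_fdr <- function(families, alpha = 0.05) {
  single <- inherits(families, "fdr_family")
  if (single) families <- list(families)
  out <- lapply(families, function(fam) {
    stopifnot(inherits(fam, "fdr_family"))
    dec <- bh_reject(fam$p, alpha)
    fam$reject <- dec$reject
    fam$k <- dec$k
    fam$threshold <- dec$threshold
    fam$alpha <- alpha
    fam
  })
  if (single) out[[1]] else out
}

#' @export
print.fdr_family <- function(x, ...) {
  cat(sprintf("FDR family (%s, %s): %d hypotheses", x$task, x$chromophore,
              length(x$p)))
  if (!is.null(x$reject))
    cat(sprintf(", %d rejected at alpha = %g (threshold %.4g)",
                sum(x$reject), x$alpha, x$threshold))
  cat("\n")
  invisible(x)
}
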