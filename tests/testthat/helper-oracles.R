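# Independent oracles used across tests. Each is a deliberately naive
# implementation kept separate from the package code paths it checks.

# discrete-time Fourier transform magnitude of a tap vector
oracle_fir_gain <- function(taps, f_hz, fs) {
  vapply(f_hz, function(f) {
    k <- seq_along(taps) - 1
    re <- sum(taps * cos(2 * pi * f * k / fs))
    im <- -sum(taps * sin(2 * pi * f * k / fs))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# 2x2 linear solve by the explicit inverse formula
oracle_solve2x2 <- function(A, b) {
  dt <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  c(A[2, 2] * b[1] - A[1, 2] * b[2],
    -A[2, 1] * b[1] + A[1, 1] * b[2]) / dt
}

# per-window coefficient of variation, recomputed from scratch
oracle_cov_windows <- function(x, wlen, step) {
  starts <- seq(1L, max(1L, length(x) - wlen + 1L), by = step)
  t(vapply(starts, function(s) {
    w <- x[s:(s + wlen - 1L)]
    c(start = s, cov = 100 * stats::sd(w) / mean(w))
  }, numeric(2)))
}

# BH step-up by hand enumeration over all ranks
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * alpha) k <- i
  if (k == 0) rep(FALSE, m) else p <= ps[k]
}

# Profiled ML log-likelihood of the random-intercept model on a dense grid:
# y = X b + u_subject + e, V = s2 * (I + g Z Z'). For each grid value of g,
# beta and s2 have closed GLS forms; the grid is zoomed twice for precision.
oracle_ri_varcomp <- function(y, X, subject, g_hi = 50) {
  Z <- stats::model.matrix(~ 0 + factor(subject))
  n <- length(y)
  prof <- function(g) {
    V <- diag(n) + g * tcrossprod(Z)
    ev <- eigen(V, symmetric = TRUE)
    Vi <- ev$vectors %*% diag(1 / ev$values) %*% t(ev$vectors)
    XtVi <- t(X) %*% Vi
    b <- solve(XtVi %*% X, XtVi %*% y)
    r <- y - X %*% b
    s2 <- drop(t(r) %*% Vi %*% r) / n
    -0.5 * (n * log(2 * pi * s2) + sum(log(ev$values)) + n)
  }
  grid <- seq(0, g_hi, length.out = 201)
  for (zoom in 1:3) {
    ll <- vapply(grid, prof, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    grid <- seq(lo, hi, length.out = 201)
  }
  g <- grid[which.max(vapply(grid, prof, numeric(1)))]
  V <- diag(n) + g * tcrossprod(Z)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  b <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% b
  s2 <- drop(t(r) %*% Vi %*% r) / n
  c(var_subject = g * s2, var_residual = s2)
}

# miniature noise-free experiment used by several round-trip tests:
# piecewise-constant truth (boxcar, 10 s onset delay) so the local-baseline
# window is flat and true block means are exact
make_roundtrip_experiment <- function(seed = 11, n_subjects = 2,
                                      n_blocks = 3, n_probes = 1) {
  design <- make_design(n_subjects = n_subjects,
                        n_oneback_blocks = n_blocks,
                        n_probe_trials = n_probes)
  params <- hemo_params_noiseless(hrf = "boxcar", response_delay_s = 10)
  simulate_experiment(design = design, params = params, seed = seed)
}

# gaussian random-intercept test data with a 2x2 condition/accuracy design
make_lmm_data <- function(n_subjects = 10, n_blocks = 8, effect = 0,
                          interaction = 0, subj_sd = 0.5, resid_sd = 1,
                          seed = 1) {
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  cond <- rep(c("HHD", "ARWD"), length.out = n_subjects)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    u <- rnorm(1, 0, subj_sd)
    acc <- rep(c("correct", "incorrect"), length.out = n_blocks)
    mu <- effect * (cond[i] == "ARWD") +
      0.3 * (acc == "incorrect") +
      interaction * (cond[i] == "ARWD") * (acc == "incorrect")
    rows[[i]] <- data.frame(
      subject = subjects[i],
      condition = factor(cond[i], levels = c("HHD", "ARWD")),
      accuracy = factor(acc, levels = c("correct", "incorrect")),
      block = seq_len(n_blocks),
      HbO = mu + u + rnorm(n_blocks, 0, resid_sd))
  }
  d <- do.call(rbind, rows)
  d$block_c <- d$block - mean(d$block)
  d
}
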