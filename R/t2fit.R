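#' Unbiased power signal
#'
#' Converts magnitude echoes to the noise-unbiased power signal
#' `P_i = M_i^2 - 2 sigma^2`. Under Rician noise `E[M^2] = nu^2 + 2 sigma^2`,
#' so subtracting `2 sigma^2` removes the noise-floor bias in the squared
#' domain. Negative values are preserved: clipping them would re-introduce
#' bias at low SNR.
#'
#' @param m numeric magnitudes (vector or array), >= 0.
#' @param sigma Rician noise scale, >= 0.
#' @return Power values, same shape as `m` (may be negative).
#' @examples
#' unbias_power(c(10, 8, 6, 5, 4), sigma = 2)  # 92 56 28 17 8
#' @export
unbias_power <- function(m, sigma) {
  if (sigma < 0) stopf("sigma must be >= 0")
  m^2 - 2 * sigma^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weighted power-domain fit with inverse Rician-power-variance weights.
# Var(M^2) = 4 sigma^2 (nu^2 + sigma^2), so the natural weights are
# w_i = 1 / (4 sigma^2 (P_hat_i + sigma^2)). Evaluating them at the MEASURED
# power would correlate the weights with the noise (an echo that fluctuates
# low gets a large weight, dragging T2 down), so the weights are taken from
# the model: a uniform-weight pass fixes P_hat, a second pass reweights.
# mode "uniform" (or sigma = 0, where all power variances coincide) stops
# after the first pass. Returns the engine result plus the weights used.
fit_power_irls <- function(p, te, sigma, mode = "ricepower",
                           t2_bounds = c(1, 1000)) {
  p <- as.matrix(p)
  E <- nrow(p)
  w <- matrix(1, E, ncol(p))
  eng <- fit_t2_engine(p, w, te, t2_bounds = t2_bounds)
  if (mode == "ricepower" && sigma > 0) {
    p_hat <- exp(-2 * outer(te, 1 / eng$t2)) * rep(eng$a0^2, each = E)
    w <- 1 / (4 * sigma^2 * (p_hat + sigma^2))
    eng <- fit_t2_engine(p, w, te, t2_bounds = t2_bounds)
  }
  c(eng, list(w = w))
}

# Profile weighted least squares for the power-decay model
# P_i ~ B * exp(-2 TE_i / T2), B = A0^2 >= 0. For fixed T2 the optimal B is
# closed-form, so the 2-D fit reduces to a 1-D search over T2: a coarse
# log-spaced grid bracket followed by vectorised golden-section refinement.
# p, w: E x N matrices; returns per-voxel a0, t2 and objective value.
fit_t2_engine <- function(p, w, te, t2_bounds = c(1, 1000),
                          n_grid = 160L, tol = 1e-7) {
  p <- as.matrix(p); w <- as.matrix(w)
  E <- length(te); N <- ncol(p)
  stopifnot(nrow(p) == E, identical(dim(p), dim(w)))

  obj_at <- function(t2) {
    # t2: length-N vector; returns list(obj, b) at per-voxel T2 values
    g <- exp(-2 * outer(te, 1 / t2))          # E x N
    wg <- w * g
    b <- colSums(wg * p) / colSums(wg * g)
    b[!is.finite(b) | b < 0] <- 0
    r <- p - g * rep(b, each = E)
    list(obj = colSums(w * r * r), b = b)
  }

  grid <- exp(seq(log(t2_bounds[1]), log(t2_bounds[2]), length.out = n_grid))
  best <- rep(1L, N); best_obj <- rep(Inf, N)
  for (k in seq_len(n_grid)) {
    g <- exp(-2 * te / grid[k])              # shared across voxels
    wg <- w * g
    b <- colSums(wg * p) / colSums(wg * g)
    b[!is.finite(b) | b < 0] <- 0
    r <- p - g * rep(b, each = E)
    ok <- colSums(w * r * r)
    upd <- ok < best_obj
    best[upd] <- k; best_obj[upd] <- ok[upd]
  }
  lo <- grid[pmax(best - 1L, 1L)]
  hi <- grid[pmin(best + 1L, n_grid)]

  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- obj_at(x1)$obj; f2 <- obj_at(x2)$obj
  it <- ceiling(log(tol / max(hi - lo)) / log(gr))
  for (k in seq_len(max(it, 1L))) {
    sel <- f1 > f2
    lo[sel] <- x1[sel]; x1[sel] <- x2[sel]; f1[sel] <- f2[sel]
    x2[sel] <- lo[sel] + gr * (hi[sel] - lo[sel])
    if (any(sel)) f2[sel] <- obj_at_subset(p, w, te, x2, sel)
    nsel <- !sel
    hi[nsel] <- x2[nsel]; x2[nsel] <- x1[nsel]; f2[nsel] <- f1[nsel]
    x1[nsel] <- hi[nsel] - gr * (hi[nsel] - lo[nsel])
    if (any(nsel)) f1[nsel] <- obj_at_subset(p, w, te, x1, nsel)
    if (max(hi - lo) < tol) break
  }
  t2 <- (lo + hi) / 2
  fin <- obj_at(t2)
  # guard: refinement must never lose to its own starting grid point
  worse <- fin$obj > best_obj
  if (any(worse)) {
    t2[worse] <- grid[best[worse]]
    fx <- obj_at(t2)
    fin$obj[worse] <- fx$obj[worse]; fin$b[worse] <- fx$b[worse]
  }
  list(a0 = sqrt(fin$b), t2 = t2, objective = fin$obj)
}

obj_at_subset <- function(p, w, te, x, sel) {
  E <- length(te)
  ps <- p[, sel, drop = FALSE]; ws <- w[, sel, drop = FALSE]
  g <- exp(-2 * outer(te, 1 / x[sel]))
  wg <- ws * g
  b <- colSums(wg * ps) / colSums(wg * g)
  b[!is.finite(b) | b < 0] <- 0
  r <- ps - g * rep(b, each = E)
  colSums(ws * r * r)
}

# Fit-quality metrics from magnitudes, reconstruction and noise scale.
fit_metrics <- function(m, m_hat, sigma, E = nrow(as.matrix(m))) {
  m <- as.matrix(m); m_hat <- as.matrix(m_hat)
  ss_res <- colSums((m - m_hat)^2)
  mbar <- colMeans(m)
  ss_tot <- colSums((m - rep(mbar, each = nrow(m)))^2)
  if (sigma > 0) {
    snr <- colSums(m^2) / (E * sigma^2)
    chi2 <- ss_res / ((E - 2) * sigma^2)
  } else {
    snr <- rep(Inf, ncol(m))
    chi2 <- rep(0, ncol(m))
  }
  r2 <- 1 - ss_res / ss_tot
  r2[ss_tot == 0] <- ifelse(ss_res[ss_tot == 0] == 0, 1, -Inf)
  list(snr = snr, r2 = r2, chi2_red = chi2)
}

#' Default voxel-exclusion thresholds
#'
#' Quality-control and tissue-plausibility gates applied to every voxel fit:
#' SNR, coefficient of determination and reduced chi-squared gates; the
#' articular-tissue T2 window; a first-echo reconstructed-intensity floor
#' (`m1_min`) flagging low-signal voxels; and a long-TE extrapolated-signal
#' ceiling (`A0 * exp(-long_te / T2) > long_te_max`) flagging bone-like
#' voxels. The intensity-scale filters are scanner-normalisation specific
#' and configurable.
#'
#' @param snr_min minimum SNR (default 5).
#' @param r2_min minimum R^2 (default 0.5).
#' @param chi2_max maximum reduced chi-squared (default 10).
#' @param t2_range accepted T2 window in msec (default 5-100).
#' @param m1_min minimum reconstructed first-echo magnitude (default 200).
#' @param long_te extrapolation echo time in msec (default 80).
#' @param long_te_max maximum extrapolated signal at `long_te` (default 300).
#' @return A named list of thresholds.
#' @export
exclusion_thresholds <- function(snr_min = 5, r2_min = 0.5, chi2_max = 10,
                                 t2_range = c(5, 100), m1_min = 200,
                                 long_te = 80, long_te_max = 300) {
  stopifnot(snr_min > 0, chi2_max > 0, length(t2_range) == 2,
            t2_range[1] < t2_range[2])
  list(snr_min = snr_min, r2_min = r2_min, chi2_max = chi2_max,
       t2_range = t2_range, m1_min = m1_min, long_te = long_te,
       long_te_max = long_te_max)
}

FLAG_NAMES <- c("qc_snr", "qc_r2", "qc_chi2", "t2_range", "low_signal",
                "bone_like")

# Vectorised flag computation; returns an N x 6 logical matrix.
exclusion_flags <- function(a0, t2, snr, r2, chi2_red, m_hat1,
                            thr = exclusion_thresholds()) {
  cbind(
    qc_snr     = snr < thr$snr_min,
    qc_r2      = r2 < thr$r2_min,
    qc_chi2    = chi2_red > thr$chi2_max,
    t2_range   = t2 < thr$t2_range[1] | t2 > thr$t2_range[2],
    low_signal = m_hat1 < thr$m1_min,
    bone_like  = a0 * exp(-thr$long_te / t2) > thr$long_te_max
  )
}

#' Rician-bias-corrected mono-exponential T2 fit for one voxel
#'
#' Fits the power-decay model `P_i = A0^2 * exp(-2 TE_i / T2)` to the
#' noise-unbiased power signal `P_i = M_i^2 - 2 sigma^2` by weighted least
#' squares (A0 >= 0, T2 in `t2_bounds`), reconstructs the biased echo signal
#' `M_hat_i = sqrt(P_hat_i + 2 sigma^2)` and computes the fit-quality gates:
#' `SNR = sum(M_i^2) / (E sigma^2)`, R^2 of the reconstruction against the
#' echo mean, and reduced chi-squared
#' `sum((M_i - M_hat_i)^2) / ((E - 2) sigma^2)`.
#'
#' @param m numeric magnitudes, one per echo.
#' @param te echo times in msec, strictly increasing (>= 3 echoes).
#' @param sigma Rician noise scale (from [estimate_sigma()]); `sigma = 0`
#'   gives SNR = Inf and reduced chi-squared = 0.
#' @param weights `"ricepower"` (default): two-pass fit with weights equal
#'   to the inverse Rician power variance `1 / (4 sigma^2 (P_hat + sigma^2))`
#'   evaluated at the first-pass reconstruction; or `"uniform"`.
#' @param thresholds exclusion gates from [exclusion_thresholds()].
#' @param t2_bounds optimisation bounds in msec, deliberately wider than the
#'   5-100 msec acceptance window so the range filter, not the optimiser
#'   bound, rejects voxels.
#' @return A `t2fit` object with `coefficients` (A0, T2), stored echoes,
#'   reconstruction, metrics and exclusion `flags` (character subset of
#'   `qc_snr, qc_r2, qc_chi2, t2_range, low_signal, bone_like`; the voxel is
#'   valid iff empty).
#' @examples
#' te <- c(13.8, 27.6, 41.4, 55.2, 69)
#' fit <- t2fit(1000 * exp(-te / 40), te, sigma = 0)
#' coef(fit)          # A0 = 1000, T2 = 40
#' @export
t2fit <- function(m, te, sigma, weights = c("ricepower", "uniform"),
                  thresholds = exclusion_thresholds(),
                  t2_bounds = c(1, 1000)) {
  weights <- match.arg(weights)
  m <- as.numeric(m); te <- as.numeric(te)
  if (length(m) != length(te)) stopf("m and te lengths differ")
  if (length(te) < 3L) stopf("need at least 3 echoes")
  if (any(diff(te) <= 0)) stopf("te must be strictly increasing")
  if (sigma < 0) stopf("sigma must be >= 0")
  E <- length(te)
  p <- unbias_power(m, sigma)
  eng <- fit_power_irls(matrix(p), te, sigma, weights, t2_bounds = t2_bounds)
  a0 <- eng$a0; t2 <- eng$t2
  p_hat <- a0^2 * exp(-2 * te / t2)
  m_hat <- sqrt(p_hat + 2 * sigma^2)
  met <- fit_metrics(matrix(m), matrix(m_hat), sigma, E)
  fl <- exclusion_flags(a0, t2, met$snr, met$r2, met$chi2_red, m_hat[1],
                        thresholds)
  structure(
    list(coefficients = c(A0 = a0, T2 = t2), m = m, te = te, sigma = sigma,
         p = p, p_hat = p_hat, m_hat = m_hat, weights_mode = weights,
         w = eng$w[, 1],
         snr = met$snr, r2 = met$r2, chi2_red = met$chi2_red,
         objective = eng$objective, thresholds = thresholds,
         flags = FLAG_NAMES[fl[1, ]]),
    class = "t2fit")
}

#' @export
coef.t2fit <- function(object, ...) object$coefficients

#' @export
fitted.t2fit <- function(object, ...) object$m_hat

#' @export
residuals.t2fit <- function(object, ...) object$m - object$m_hat

#' Predict echo magnitudes from a voxel fit
#'
#' @param object a [t2fit()] object.
#' @param te echo times (msec) at which to predict; defaults to the fitted
#'   ones.
#' @param type `"magnitude"` for the noise-floor-biased reconstruction
#'   `sqrt(A0^2 exp(-2 TE / T2) + 2 sigma^2)` (comparable to measured
#'   magnitudes), `"signal"` for the noiseless decay `A0 exp(-TE / T2)`.
#' @param ... unused.
#' @export
predict.t2fit <- function(object, te = object$te,
                          type = c("magnitude", "signal"), ...) {
  type <- match.arg(type)
  a0 <- object$coefficients[["A0"]]; t2 <- object$coefficients[["T2"]]
  if (type == "signal") a0 * exp(-te / t2)
  else sqrt(a0^2 * exp(-2 * te / t2) + 2 * object$sigma^2)
}

#' Simulate Rician-noisy echo vectors from a fitted voxel
#'
#' @param object a [t2fit()] object.
#' @param nsim number of simulated echo vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return `nsim x E` matrix of magnitudes.
#' @export
simulate.t2fit <- function(object, nsim = 1, seed = NULL, ...) {
  s <- predict(object, type = "signal")
  E <- length(s)
  with_seed(seed, {
    n1 <- matrix(rnorm(nsim * E, 0, object$sigma), nsim)
    n2 <- matrix(rnorm(nsim * E, 0, object$sigma), nsim)
    sqrt((rep(s, each = nsim) + n1)^2 + n2^2)
  })
}

#' @export
print.t2fit <- function(x, ...) {
  cat(sprintf("T2 fit: A0 = %.4g, T2 = %.4g msec (%s weights)\n",
              x$coefficients[["A0"]], x$coefficients[["T2"]], x$weights_mode))
  cat(sprintf("  SNR = %.3g, R^2 = %.4f, reduced chi^2 = %.3g\n",
              x$snr, x$r2, x$chi2_red))
  if (length(x$flags)) cat("  excluded:", paste(x$flags, collapse = ", "), "\n")
  else cat("  voxel valid\n")
  invisible(x)
}

#' @export
summary.t2fit <- function(object, ...) {
  out <- data.frame(te = object$te, m = object$m, p = object$p,
                    m_hat = object$m_hat, residual = object$m - object$m_hat)
  structure(list(fit = object, table = out), class = "summary.t2fit")
}

#' @export
print.summary.t2fit <- function(x, ...) {
  print(x$fit)
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.t2fit <- function(x, ...) {
  te_fine <- seq(0, max(x$te) * 1.1, length.out = 200)
  plot(x$te, x$m, xlab = "TE (msec)", ylab = "magnitude",
       ylim = range(0, x$m, x$m_hat), pch = 19, ...)
  lines(te_fine, predict(x, te_fine, type = "magnitude"))
  lines(te_fine, predict(x, te_fine, type = "signal"), lty = 2)
  legend("topright", bty = "n",
         legend = c("measured", "reconstruction", "noiseless decay"),
         pch = c(19, NA, NA), lty = c(NA, 1, 2))
  invisible(x)
}

#' Naive log-linear T2 fit (reference estimator)
#'
#' Ordinary least squares of `log(M_i)` on `TE_i`, ignoring the Rician noise
#' floor; `T2 = -1 / slope`. Provided as the uncorrected baseline against
#' which the power-domain correction is evaluated.
#'
#' @param m magnitudes (> 0 required; non-positive echoes are dropped).
#' @param te echo times in msec.
#' @return `c(A0, T2)`; `T2 = NA` if fewer than 2 usable echoes or a
#'   non-negative slope.
#' @export
loglinear_t2 <- function(m, te) {
  keep <- m > 0
  if (sum(keep) < 2) return(c(A0 = NA_real_, T2 = NA_real_))
  fit <- stats::lm.fit(cbind(1, te[keep]), log(m[keep]))
  sl <- fit$coefficients[2]
  t2 <- if (is.na(sl) || sl >= 0) NA_real_ else -1 / sl
  c(A0 = unname(exp(fit$coefficients[1])), T2 = unname(t2))
}
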