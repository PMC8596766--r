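# Validity class codes for the T2 map volume.
VALID_OK <- 1L; VALID_QC <- 2L; VALID_SIGNAL <- 3L; VALID_RANGE <- 4L

#' Fit a T2 map over a whole multi-echo volume
#'
#' Applies the Rician-bias-corrected power-domain fit (see [t2fit()]) to every
#' voxel of a multi-echo series and applies the voxel-exclusion rules. The
#' fit is fully vectorised: for each voxel the weighted least-squares
#' amplitude is profiled out analytically and T2 found by a grid-bracketed
#' golden-section search, so a whole stack is fitted in one pass.
#'
#' @param series an [echo_series()].
#' @param noise a `noise_estimate` from [estimate_sigma()], or a numeric
#'   sigma.
#' @param weights `"ricepower"` or `"uniform"` (see [t2fit()]).
#' @param thresholds exclusion gates from [exclusion_thresholds()].
#' @param t2_bounds optimisation bounds in msec.
#' @param audit if `TRUE`, per-voxel A0/SNR/R^2/chi^2 volumes are stored on
#'   the returned object (memory permitting); flags are always stored.
#' @return A `t2map` object: `t2` (msec volume, `NA` where not valid),
#'   `validity` (integer volume: 1 valid, 2 excluded by quality control,
#'   3 excluded low-signal or bone-like, 4 excluded by the T2 range),
#'   `flags` (N x 6 logical matrix), `flag_counts`, `sigma`, geometry.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 1), sigma_rice = 0,
#'                                     seed = 1))
#' map <- t2map(ph$series, noise = 0)
#' summary(map)
#' @export
t2map <- function(series, noise, weights = c("ricepower", "uniform"),
                  thresholds = exclusion_thresholds(),
                  t2_bounds = c(1, 1000), audit = TRUE) {
  stopifnot(inherits(series, "echo_series"))
  weights <- match.arg(weights)
  sigma <- if (inherits(noise, "noise_estimate")) noise$sigma else as.numeric(noise)
  if (sigma < 0) stopf("sigma must be >= 0")
  d <- dim(series$data); E <- d[4]
  if (E < 3L) stopf("need at least 3 echoes")

  m <- echo_matrix(series)                    # E x N
  p <- unbias_power(m, sigma)
  eng <- fit_power_irls(p, series$te, sigma, weights, t2_bounds = t2_bounds)

  g1 <- exp(-2 * outer(series$te, 1 / eng$t2))
  m_hat <- sqrt(g1 * rep(eng$a0^2, each = E) + 2 * sigma^2)
  met <- fit_metrics(m, m_hat, sigma, E)
  fl <- exclusion_flags(eng$a0, eng$t2, met$snr, met$r2, met$chi2_red,
                        m_hat[1, ], thresholds)

  qc <- fl[, "qc_snr"] | fl[, "qc_r2"] | fl[, "qc_chi2"]
  sigflag <- fl[, "low_signal"] | fl[, "bone_like"]
  validity <- ifelse(qc, VALID_QC,
                     ifelse(sigflag, VALID_SIGNAL,
                            ifelse(fl[, "t2_range"], VALID_RANGE, VALID_OK)))
  t2vol <- eng$t2
  t2vol[validity != VALID_OK] <- NA_real_

  out <- list(
    t2 = array(t2vol, dim = d[1:3]),
    validity = array(as.integer(validity), dim = d[1:3]),
    flags = fl,
    flag_counts = colSums(fl),
    sigma = sigma, te = series$te,
    spacing = series$spacing, thickness = series$thickness,
    weights_mode = weights, thresholds = thresholds
  )
  if (isTRUE(audit)) {
    out$a0 <- array(eng$a0, dim = d[1:3])
    out$snr <- array(met$snr, dim = d[1:3])
    out$r2 <- array(met$r2, dim = d[1:3])
    out$chi2_red <- array(met$chi2_red, dim = d[1:3])
  }
  structure(out, class = "t2map")
}

#' @export
dim.t2map <- function(x) dim(x$t2)

#' @export
print.t2map <- function(x, ...) {
  d <- dim(x$t2); n <- prod(d)
  nv <- sum(x$validity == VALID_OK)
  cat(sprintf("T2 map: %d x %d x %d voxels, sigma = %.4g\n",
              d[1], d[2], d[3], x$sigma))
  cat(sprintf("  valid: %d (%.1f%%); QC-excluded: %d; low-signal/bone: %d; out of range: %d\n",
              nv, 100 * nv / n, sum(x$validity == VALID_QC),
              sum(x$validity == VALID_SIGNAL), sum(x$validity == VALID_RANGE)))
  invisible(x)
}

#' @export
summary.t2map <- function(object, ...) {
  v <- object$t2[object$validity == VALID_OK]
  q <- if (length(v)) quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
       else rep(NA_real_, 3)
  structure(list(map = object, n_valid = length(v),
                 q1 = q[1], median = q[2], q3 = q[3],
                 flag_counts = object$flag_counts),
            class = "summary.t2map")
}

#' @export
print.summary.t2map <- function(x, ...) {
  print(x$map)
  cat(sprintf("  valid-voxel T2 (msec): median %.1f (q1-q3 %.1f-%.1f)\n",
              x$median, x$q1, x$q3))
  cat("  exclusion flag counts:\n")
  for (nm in names(x$flag_counts))
    cat(sprintf("    %-10s %d\n", nm, x$flag_counts[[nm]]))
  invisible(x)
}

#' Display one slice of a T2 map
#'
#' Valid voxels are coloured by T2; excluded voxels are black (quality
#' control / low signal / out of range) or dark grey (bone-like long-TE
#' signal). No colour interpolation between voxels.
#'
#' @param x a `t2map`.
#' @param slice slice index.
#' @param zlim T2 colour range in msec.
#' @param ... passed to [graphics::image()].
#' @export
plot.t2map <- function(x, slice = ceiling(dim(x$t2)[3] / 2),
                       zlim = c(0, 100), ...) {
  sl <- x$t2[, , slice]
  vl <- x$validity[, , slice]
  bg <- matrix(0, nrow(sl), ncol(sl))
  bg[vl == VALID_SIGNAL] <- 1
  image(t(bg[nrow(bg):1, ]), col = c("black", gray(0.3)), axes = FALSE,
        useRaster = TRUE)
  disp <- pmin(pmax(sl, zlim[1]), zlim[2])
  image(t(disp[nrow(disp):1, ]), col = hcl.colors(64, "viridis"),
        zlim = zlim, add = TRUE, useRaster = TRUE, ...)
  invisible(x)
}
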