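test_that("unbias_power subtracts exactly 2 sigma^2 and keeps negatives", {
  expect_equal(unbias_power(c(10, 8, 6, 5, 4), 2), c(92, 56, 28, 17, 8))
  m <- c(12.5, 3.1, 0.7)
  expect_equal(unbias_power(m, 0), m^2)
  expect_equal(unbias_power(rep(1, 5), 1), rep(-1, 5))
  expect_error(unbias_power(m, -1), ">= 0")
})

test_that("noiseless model data is recovered exactly", {
  fit <- t2fit(1000 * exp(-TE5 / 40), TE5, sigma = 0)
  expect_equal(coef(fit)[["T2"]], 40, tolerance = 1e-6 / 40)
  expect_equal(coef(fit)[["A0"]], 1000, tolerance = 1e-3 / 1000)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$snr, Inf)
  expect_equal(fit$chi2_red, 0)
  expect_length(fit$flags, 0)
})

test_that("noiseless recovery across the articular window is exact and monotone", {
  t2_true <- seq(5, 100, length.out = 1000)
  p <- sapply(t2_true, function(t2) (800 * exp(-TE5 / t2))^2)
  eng <- qt2map:::fit_t2_engine(p, matrix(1, 5, 1000), TE5)
  expect_lt(max(abs(eng$t2 - t2_true)), 1e-4)
  expect_true(all(diff(eng$t2) > 0))
  expect_equal(eng$a0, rep(800, 1000), tolerance = 1e-6)
})

test_that("the optimiser beats a brute-force grid on noisy voxels", {
  set.seed(42)
  n <- 50
  a0 <- runif(n, 200, 2000); t2 <- runif(n, 10, 90); sigma <- 15
  m <- sapply(seq_len(n), function(j)
    sqrt((a0[j] * exp(-TE5 / t2[j]) + rnorm(5, 0, sigma))^2 +
           rnorm(5, 0, sigma)^2))
  t2_grid <- seq(5, 150, by = 0.05)
  b_grid <- seq(100, 2500, by = 5)^2
  for (j in seq_len(n)) {
    fit <- t2fit(m[, j], TE5, sigma)
    w <- fit$w
    p <- fit$p
    obj <- function(b, t2) sum(w * (p - b * exp(-2 * TE5 / t2))^2)
    # independent oracle: exhaustive 2-D evaluation
    grid_best <- min(vapply(t2_grid, function(tt) {
      g <- exp(-2 * TE5 / tt)
      min(colSums(w * (p - outer(g, b_grid))^2))
    }, numeric(1)))
    expect_lte(fit$objective, grid_best * (1 + 1e-9) + 1e-9)
    # stored objective is consistent with the stored coefficients
    expect_equal(fit$objective,
                 obj(coef(fit)[["A0"]]^2, coef(fit)[["T2"]]),
                 tolerance = 1e-9)
  }
})

test_that("power-domain correction beats naive log-linear fitting at low SNR", {
  sigma <- 50; t2_true <- 35
  g <- sum(exp(-2 * TE5 / t2_true))
  for (snr in c(5, 8, 12)) {
    a0 <- sqrt(snr * 5 * sigma^2 / g)
    m <- rician_voxels(800, a0, t2_true, sigma, seed = 1000 + snr)
    p <- unbias_power(m, sigma)
    eng <- qt2map:::fit_power_irls(p, TE5, sigma)
    naive <- apply(m, 2, function(mm) loglinear_t2(mm, TE5)[["T2"]])
    bias_corr <- median(eng$t2) - t2_true
    bias_naive <- median(naive, na.rm = TRUE) - t2_true
    expect_lt(abs(bias_corr), abs(bias_naive))
  }
})

test_that("stored SNR, R2 and reduced chi2 match their defining formulas", {
  set.seed(8)
  for (k in 1:20) {
    sigma <- runif(1, 5, 80)
    m <- rician_voxels(1, runif(1, 300, 1500), runif(1, 10, 80), sigma,
                       seed = k)[, 1]
    fit <- t2fit(m, TE5, sigma)
    m_hat <- fitted(fit)
    expect_equal(fit$snr, sum(m^2) / (5 * sigma^2), tolerance = 1e-12)
    expect_equal(fit$r2, 1 - sum((m - m_hat)^2) / sum((m - mean(m))^2),
                 tolerance = 1e-12)
    expect_equal(fit$chi2_red, sum((m - m_hat)^2) / (3 * sigma^2),
                 tolerance = 1e-12)
    # reconstruction identity M_hat = sqrt(P_hat + 2 sigma^2)
    expect_equal(m_hat, sqrt(fit$p_hat + 2 * sigma^2), tolerance = 1e-12)
  }
})

test_that("each exclusion rule fires exactly at its printed threshold", {
  thr <- exclusion_thresholds()
  # amplitude kept low enough that the long-TE rule stays silent as T2 varies
  base <- list(a0 = 400, t2 = 35, snr = 20, r2 = 0.95, chi2 = 1, m1 = 600)
  flags_of <- function(l) {
    fl <- qt2map:::exclusion_flags(l$a0, l$t2, l$snr, l$r2, l$chi2, l$m1, thr)
    qt2map:::FLAG_NAMES[fl[1, ]]
  }
  expect_length(flags_of(base), 0)
  expect_equal(flags_of(modifyList(base, list(snr = 4.9))), "qc_snr")
  expect_length(flags_of(modifyList(base, list(snr = 5))), 0)
  expect_equal(flags_of(modifyList(base, list(r2 = 0.49))), "qc_r2")
  expect_equal(flags_of(modifyList(base, list(chi2 = 10.1))), "qc_chi2")
  expect_length(flags_of(modifyList(base, list(chi2 = 10))), 0)
  expect_equal(flags_of(modifyList(base, list(t2 = 120))), "t2_range")
  expect_equal(flags_of(modifyList(base, list(t2 = 4.9))), "t2_range")
  expect_length(flags_of(modifyList(base, list(t2 = 5))), 0)
  expect_equal(flags_of(modifyList(base, list(m1 = 199))), "low_signal")
  # A0 = 2000, T2 = 60: 2000 * exp(-80/60) = 527 > 300
  expect_equal(flags_of(modifyList(base, list(a0 = 2000, t2 = 60))),
               "bone_like")
  expect_equal(2000 * exp(-80 / 60), 527, tolerance = 0.01)
  # long-TE rule just below threshold does not fire
  expect_length(flags_of(modifyList(base, list(a0 = 300 / exp(-80 / 35)))), 0)
})

test_that("t2fit methods are mutually consistent", {
  m <- rician_voxels(1, 900, 45, 25, seed = 3)[, 1]
  fit <- t2fit(m, TE5, 25)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  expect_equal(residuals(fit), m - fitted(fit), tolerance = 1e-12)
  expect_equal(predict(fit, te = 0, type = "signal"), coef(fit)[["A0"]],
               tolerance = 1e-12)
  sim1 <- simulate(fit, nsim = 5, seed = 11)
  sim2 <- simulate(fit, nsim = 5, seed = 11)
  expect_identical(sim1, sim2)
  expect_equal(dim(sim1), c(5L, 5L))
  expect_output(print(fit), "T2 fit")
  expect_output(print(summary(fit)), "residual")
})

test_that("input validation rejects malformed echo vectors", {
  expect_error(t2fit(c(1, 2), c(10, 20), 0), "3 echoes")
  expect_error(t2fit(1:5, c(10, 20, 30, 30, 40), 0), "increasing")
  expect_error(t2fit(1:5, TE5, -1), ">= 0")
})
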