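make_fitted_phantom <- function(sigma = 30, shape = c(64, 64, 2), seed = 7,
                                ...) {
  ph <- small_phantom(sigma = sigma, shape = shape, seed = seed, ...)
  ne <- estimate_sigma(ph$series)
  list(ph = ph, map = t2map(ph$series, ne))
}

test_that("a VOI inside valid cartilage keeps its full size", {
  fp <- make_fitted_phantom()
  voi <- load_voi(fp$ph$truth$voi_tx, fp$map, label = "TX")
  expect_equal(voi$n, sum(fp$ph$truth$voi_tx))
  expect_gt(voi$n_valid / voi$n, 0.8)
})

test_that("an integer shift recovers a deliberately offset mask", {
  fp <- make_fitted_phantom()
  mask <- fp$ph$truth$voi_tx
  shifted <- array(FALSE, dim = dim(mask))
  shifted[, 3:dim(mask)[2], ] <- mask[, 1:(dim(mask)[2] - 2), ]  # +2 columns
  ref <- load_voi(mask, fp$map, label = "TX")
  rec <- load_voi(shifted, fp$map, shift = c(0, -2, 0), label = "TX")
  expect_identical(sort(rec$idx), sort(ref$idx))
})

test_that("a VOI with no valid voxels errors with a flag breakdown", {
  fp <- make_fitted_phantom()
  fluid_mask <- fp$ph$truth$region_labels == 2L
  expect_error(load_voi(fluid_mask, fp$map, label = "FLUID"),
               "bone_like|t2_range")
  expect_error(load_voi(array(FALSE, dim = dim(fp$map$t2)), fp$map), "empty")
})

test_that("pooled quartiles are inverse-CDF order statistics with integer rounding", {
  thr <- pooled_quartiles(1:100)
  expect_equal(thr$ta, 25)
  expect_equal(thr$tb, 75)
  # independent order-statistics route: x_(ceil(p * n))
  set.seed(14)
  v <- rexp(257, 1 / 40)
  sv <- sort(v)
  thr2 <- pooled_quartiles(v, round = FALSE)
  expect_equal(thr2$ta, sv[ceiling(0.25 * 257)])
  expect_equal(thr2$tb, sv[ceiling(0.75 * 257)])

  deg <- pooled_quartiles(rep(35, 10))
  expect_equal(deg$ta, 35)
  expect_equal(deg$tb, 35)
  expect_error(pooled_quartiles(c(1, 2, 3)), "at least 4")
})

test_that("control-cartilage quartiles are recovered from a fitted phantom", {
  fp <- make_fitted_phantom(sigma = 20, shape = c(96, 96, 4), seed = 13)
  voi <- load_voi(fp$ph$truth$voi_ctrl, fp$map, label = "CTRL")
  thr <- pooled_quartiles(qt2map:::voi_values(voi, fp$map))
  expect_lte(abs(thr$ta - 25), 1)
  expect_lte(abs(thr$tb - 45), 1)
  med <- median(qt2map:::voi_values(voi, fp$map))
  expect_lt(abs(med - 35), 2)
})

test_that("T2 distributions are unit-area with the expected support", {
  d1 <- t2_distribution(35)
  expect_equal(sum(d1$smoothed), 1, tolerance = 1e-9)
  nz <- d1$mids[d1$smoothed > 0]
  expect_true(all(nz >= 30 & nz <= 40))

  set.seed(2)
  u <- runif(1e5, 5, 100)
  du <- t2_distribution(u)
  interior <- du$smoothed[du$mids > 12 & du$mids < 93]
  expect_lt(stats::sd(interior) / mean(interior), 0.05)

  for (k in 1:50) {
    vals <- runif(sample(1:500, 1), 5, 100)
    expect_equal(sum(t2_distribution(vals)$smoothed), 1, tolerance = 1e-9)
  }
})

test_that("composition classifies the printed intervals with inclusive boundaries", {
  thr <- tissue_thresholds(25, 45)
  comp <- composition(c(20, 35, 50), thr = thr, voxel_volume = 1)
  expect_equal(c(comp$frac_fibro, comp$frac_hyaline, comp$frac_remodel),
               rep(1 / 3, 3))
  # boundary values are hyaline-like on both sides
  cb <- composition(c(25, 45), thr = thr, voxel_volume = 1)
  expect_equal(cb$frac_hyaline, 1)

  set.seed(5)
  v <- runif(1e5, 5, 100)
  # interval lengths over the support: 20, 20 and 55 msec out of 95
  cu <- composition(v, thr = thr, voxel_volume = 1)
  expect_lt(abs(cu$frac_fibro - 20 / 95), 0.01)
  expect_lt(abs(cu$frac_hyaline - 20 / 95), 0.01)
  expect_lt(abs(cu$frac_remodel - 55 / 95), 0.01)
  expect_equal(cu$frac_fibro + cu$frac_hyaline + cu$frac_remodel, 1,
               tolerance = 1e-12)
})

test_that("composition is permutation-invariant and monotone in thresholds", {
  set.seed(6)
  v <- runif(500, 5, 100)
  thr <- tissue_thresholds(25, 45)
  c1 <- composition(v, thr = thr, voxel_volume = 1)
  c2 <- composition(sample(v), thr = thr, voxel_volume = 1)
  expect_equal(c1$frac_fibro, c2$frac_fibro)
  expect_equal(pooled_quartiles(v, round = FALSE)$ta,
               pooled_quartiles(sample(v), round = FALSE)$ta)
  for (ta in c(20, 30, 40)) {
    lo <- composition(v, thr = tissue_thresholds(ta, 60), voxel_volume = 1)
    hi <- composition(v, thr = tissue_thresholds(ta + 5, 60), voxel_volume = 1)
    expect_gte(hi$frac_fibro, lo$frac_fibro)
  }
  for (tb in c(40, 50, 60)) {
    lo <- composition(v, thr = tissue_thresholds(20, tb), voxel_volume = 1)
    hi <- composition(v, thr = tissue_thresholds(20, tb + 5), voxel_volume = 1)
    expect_gte(hi$frac_hyaline, lo$frac_hyaline)
  }
})

test_that("tissue volume bookkeeping uses the acquisition geometry", {
  vv <- voxel_volume(0.664, 2)
  expect_equal(round(193 * vv), 170)
  fp <- make_fitted_phantom(shape = c(32, 32, 2))
  voi <- load_voi(fp$ph$truth$voi_tx, fp$map, label = "TX")
  comp <- composition(voi, fp$map, tissue_thresholds(25, 45))
  expect_equal(comp$tissue_volume, comp$n_valid * vv, tolerance = 1e-12)
})

test_that("composition fractions recover generating weights at high SNR", {
  base <- phantom_spec(shape = c(64, 64, 2), sigma_rice = 20)
  coh <- generate_cohort(n_per_arm = c(BMDCT = 1L, MFS = 1L),
                         concentration = Inf, base_spec = base, seed = 3)
  thr <- tissue_thresholds(25, 45)
  for (p in coh) {
    map <- t2map(p$series, estimate_sigma(p$series))
    voi <- load_voi(p$truth$voi_tx, map, label = "TX")
    comp <- composition(voi, map, thr)
    est <- c(comp$frac_fibro, comp$frac_hyaline, comp$frac_remodel)
    expect_lt(max(abs(est - p$weights)), 0.05)
  }
})
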