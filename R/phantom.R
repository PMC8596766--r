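#' Tissue T2/amplitude specification for the synthetic phantom
#'
#' Describes one tissue compartment by a distribution over T2 (msec) and a
#' signal amplitude with voxel-to-voxel variability.
#'
#' @param name tissue label.
#' @param t2 a T2 distribution created by [t2_point()], [t2_uniform()] or
#'   [t2_truncnorm()].
#' @param a0_mean mean signal amplitude (arbitrary intensity units), >= 0.
#' @param a0_cv coefficient of variation of the amplitude, >= 0.
#' @return A `tissue_spec` object.
#' @examples
#' tissue_spec("hyaline", t2_truncnorm(35, 6, 25, 45), a0_mean = 1000)
#' @export
tissue_spec <- function(name, t2, a0_mean, a0_cv = 0.1) {
  stopifnot(inherits(t2, "t2_dist"))
  if (a0_mean < 0 || a0_cv < 0) stopf("a0_mean and a0_cv must be >= 0")
  structure(list(name = name, t2 = t2, a0_mean = a0_mean, a0_cv = a0_cv),
            class = "tissue_spec")
}

#' T2 distributions for tissue specifications
#'
#' Point mass, uniform on an interval, or normal truncated to an interval;
#' all values in msec and the support must be positive.
#'
#' @param value,min,max,mean,sd,lower,upper distribution parameters in msec.
#' @return A `t2_dist` object.
#' @export
t2_point <- function(value) {
  if (value <= 0) stopf("T2 must be positive")
  structure(list(kind = "point", value = value), class = "t2_dist")
}

#' @rdname t2_point
#' @export
t2_uniform <- function(min, max) {
  if (min <= 0 || max < min) stopf("need 0 < min <= max")
  structure(list(kind = "uniform", min = min, max = max), class = "t2_dist")
}

#' @rdname t2_point
#' @export
t2_truncnorm <- function(mean, sd, lower, upper) {
  if (lower <= 0 || upper < lower || sd < 0) stopf("need 0 < lower <= upper, sd >= 0")
  structure(list(kind = "truncnorm", mean = mean, sd = sd,
                 lower = lower, upper = upper), class = "t2_dist")
}

sample_t2 <- function(dist, n) {
  switch(dist$kind,
    point     = rep(dist$value, n),
    uniform   = runif(n, dist$min, dist$max),
    truncnorm = rtnorm(n, dist$mean, dist$sd, dist$lower, dist$upper),
    stopf("unknown T2 distribution kind '%s'", dist$kind)
  )
}

# Default tissue palette. The three cartilage classes partition T2 at the
# 25/45 msec class boundaries; bone has weak signal (fires the first-echo
# intensity filter), synovial fluid has long T2 and strong signal (fires the
# long-TE filter).
default_tissues <- function() {
  list(
    bone      = tissue_spec("bone", t2_uniform(5, 20), a0_mean = 80, a0_cv = 0.2),
    fluid     = tissue_spec("fluid", t2_truncnorm(200, 20, 120, 300),
                            a0_mean = 1600, a0_cv = 0.05),
    soft      = tissue_spec("soft tissue", t2_truncnorm(35, 8, 15, 80),
                            a0_mean = 600, a0_cv = 0.15),
    # cartilage amplitude sits clear of both intensity-scale filters: the
    # first-echo floor (M1 < 200) only reaches T2 < 10 msec and the long-TE
    # ceiling (A0 exp(-80/T2) > 300) only T2 > 82 msec, so the filters
    # target bone/fluid rather than articular tissue
    fibro     = tissue_spec("fibrocartilage", t2_truncnorm(20, 4, 5, 25),
                            a0_mean = 800, a0_cv = 0.1),
    hyaline   = tissue_spec("hyaline", t2_truncnorm(35, 6, 25, 45),
                            a0_mean = 800, a0_cv = 0.1),
    remodel   = tissue_spec("remodeling", t2_truncnorm(55, 8, 45, 100),
                            a0_mean = 800, a0_cv = 0.1)
  )
}

#' Synthetic multi-echo ankle phantom specification
#'
#' Defines the grid, acquisition, noise level and region layout of a
#' simplified stacked-slab ankle-like phantom: air background surrounding a
#' central object composed (top to bottom, in-plane) of a synovial-fluid
#' layer, a cartilage shell carrying an embedded treated-lesion patch, and a
#' bone slab. Default geometry matches a coronal 5-echo T2-mapping
#' acquisition on a 256 x 256 matrix with 0.664 mm pixels and 2 mm slices,
#' echo times evenly spaced from 13.8 to 69 msec.
#'
#' @param shape integer grid `c(rows, cols, slices)`.
#' @param spacing in-plane pixel spacing in mm.
#' @param thickness slice thickness in mm.
#' @param te echo times in msec, strictly increasing.
#' @param sigma_rice Rician noise scale in intensity units (>= 0).
#' @param tissues named list of [tissue_spec()]s for `bone`, `fluid`,
#'   `fibro`, `hyaline`, `remodel`.
#' @param lesion_weights,ctrl_weights length-3 non-negative composition
#'   weights (fibrocartilage, hyaline-like, remodeling), each summing to 1,
#'   for the treated-lesion patch and the healthy control cartilage.
#' @param layout named list of fractional region boundaries (see Details).
#' @param quantize if `TRUE`, intensities are rounded to 12-bit integers
#'   (0-4095) to mimic scanner output; default keeps floating point.
#' @param seed integer RNG seed; generation is reproducible given the seed.
#'
#' @details `layout` gives fractional positions on the in-plane grid. The
#' object (`object_rows` x `object_cols`) is filled with soft tissue; inside
#' it, slabs spanning `slab_cols` hold the synovial-fluid layer
#' (`fluid_rows`), the cartilage shell (`cartilage_rows`) and the bone slab
#' (`bone_rows`), so bone and cartilage are enclosed by soft tissue and the
#' air background is strictly outside the object. `lesion_cols` and
#' `ctrl_cols` give the column ranges of the treated-lesion patch and the
#' control-cartilage block inside the cartilage shell.
#'
#' @return A `phantom_spec` object.
#' @examples
#' spec <- phantom_spec(shape = c(48, 48, 2), sigma_rice = 20, seed = 7)
#' ph <- generate_phantom(spec)
#' ph$series
#' @export
phantom_spec <- function(shape = c(256, 256, 26),
                         spacing = 0.664, thickness = 2,
                         te = c(13.8, 27.6, 41.4, 55.2, 69.0),
                         sigma_rice = 60,
                         tissues = default_tissues(),
                         lesion_weights = c(0.18, 0.56, 0.27) / 1.01,
                         ctrl_weights = c(0.25, 0.50, 0.25),
                         layout = list(
                           object_rows    = c(0.24, 0.95),
                           object_cols    = c(0.10, 0.90),
                           slab_cols      = c(0.16, 0.84),
                           fluid_rows     = c(0.30, 0.42),
                           cartilage_rows = c(0.42, 0.60),
                           bone_rows      = c(0.60, 0.85),
                           lesion_cols    = c(0.22, 0.42),
                           ctrl_cols      = c(0.55, 0.78)
                         ),
                         quantize = FALSE, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape[1:2] < 16L) || shape[3] < 1L)
    stopf("`shape` must be c(rows, cols, slices), in-plane dims >= 16")
  te <- as.numeric(te)
  if (length(te) < 2L || any(diff(te) <= 0))
    stopf("`te` must be >= 2 strictly increasing msec values")
  if (sigma_rice < 0) stopf("sigma_rice must be >= 0")
  for (w in list(lesion_weights, ctrl_weights)) {
    if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stopf("composition weights must be 3 non-negative values summing to 1")
  }
  need <- c("bone", "fluid", "soft", "fibro", "hyaline", "remodel")
  if (!all(need %in% names(tissues)))
    stopf("`tissues` must name: %s", paste(need, collapse = ", "))
  structure(list(shape = shape, spacing = spacing, thickness = thickness,
                 te = te, sigma_rice = sigma_rice, tissues = tissues,
                 lesion_weights = lesion_weights, ctrl_weights = ctrl_weights,
                 layout = layout, quantize = quantize, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Region label codes used in ground-truth volumes.
REGION_AIR <- 0L; REGION_BONE <- 1L; REGION_FLUID <- 2L
REGION_CARTILAGE <- 3L; REGION_LESION <- 4L; REGION_SOFT <- 5L
CLASS_NONE <- 0L; CLASS_FIBRO <- 1L; CLASS_HYALINE <- 2L; CLASS_REMODEL <- 3L

frac_range <- function(frac, n) {
  lo <- max(1L, 1L + floor(frac[1] * n))
  hi <- min(n, floor(frac[2] * n))
  if (hi < lo) integer(0) else lo:hi
}

# Build the integer region-label volume from the fractional layout.
phantom_labels <- function(spec) {
  d <- spec$shape
  lab <- array(REGION_AIR, dim = d)
  ly <- spec$layout
  or_ <- frac_range(ly$object_rows, d[1])
  oc <- frac_range(ly$object_cols, d[2])
  sc <- intersect(frac_range(ly$slab_cols, d[2]), oc)
  fr <- intersect(frac_range(ly$fluid_rows, d[1]), or_)
  cr <- intersect(frac_range(ly$cartilage_rows, d[1]), or_)
  br <- intersect(frac_range(ly$bone_rows, d[1]), or_)
  lab[or_, oc, ] <- REGION_SOFT
  lab[fr, sc, ] <- REGION_FLUID
  lab[cr, sc, ] <- REGION_CARTILAGE
  lab[br, sc, ] <- REGION_BONE
  lc <- intersect(frac_range(ly$lesion_cols, d[2]), sc)
  lab[cr, lc, ] <- REGION_LESION
  cc <- intersect(frac_range(ly$ctrl_cols, d[2]), sc)
  if (length(cr) == 0L || length(lc) == 0L)
    stopf("layout leaves the TX (lesion) VOI empty")
  if (length(cc) == 0L)
    stopf("layout leaves the CTRL VOI empty")
  attr(lab, "ctrl_cols") <- cc
  attr(lab, "cartilage_rows") <- cr
  lab
}

# Assign cartilage classes to a voxel index set with exact largest-remainder
# counts matching `weights`, in a seeded random spatial arrangement.
assign_classes <- function(idx, weights) {
  n <- length(idx)
  counts <- floor(weights * n)
  rem <- weights * n - counts
  short <- n - sum(counts)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1L
  }
  cls <- rep.int(c(CLASS_FIBRO, CLASS_HYALINE, CLASS_REMODEL), counts)
  cls[sample.int(n)]
}

#' Generate a synthetic multi-echo phantom
#'
#' Draws per-voxel (A0, T2) from the tissue specifications, evaluates the
#' noiseless mono-exponential decay `S_i = A0 * exp(-TE_i / T2)` at each echo
#' time, and corrupts each echo independently with Rician noise: the observed
#' magnitude is `|S_i + n1 + i*n2|` with `n1, n2 ~ N(0, sigma_rice)`. Air has
#' `S_i = 0` and therefore pure Rayleigh noise.
#'
#' @param spec a [phantom_spec()].
#' @return A list with components `series` (an [echo_series()]) and `truth`,
#'   a `ground_truth` list with `true_t2`, `true_a0`, `region_labels`,
#'   `class_labels` (fibro/hyaline/remodel codes 1-3 for cartilage voxels),
#'   logical VOI masks `voi_tx`, `voi_ctrl`, and the realised composition
#'   weights.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$shape
  lab <- phantom_labels(spec)
  n <- prod(d)
  true_t2 <- array(NA_real_, dim = d)
  true_a0 <- array(0, dim = d)
  cls <- array(CLASS_NONE, dim = d)

  draw_region <- function(idx, tissue) {
    true_t2[idx] <<- sample_t2(tissue$t2, length(idx))
    a0 <- rnorm(length(idx), tissue$a0_mean, tissue$a0_cv * tissue$a0_mean)
    true_a0[idx] <<- pmax(a0, 0)
  }
  draw_cartilage <- function(idx, weights) {
    ci <- assign_classes(idx, weights)
    cls[idx] <<- ci
    tis <- spec$tissues
    for (k in seq_len(3)) {
      sel <- idx[ci == k]
      if (length(sel))
        draw_region(sel, tis[[c("fibro", "hyaline", "remodel")[k]]])
    }
  }

  draw_region(which(lab == REGION_BONE), spec$tissues$bone)
  draw_region(which(lab == REGION_FLUID), spec$tissues$fluid)
  draw_region(which(lab == REGION_SOFT), spec$tissues$soft)

  lesion_idx <- which(lab == REGION_LESION)
  draw_cartilage(lesion_idx, spec$lesion_weights)

  # CTRL VOI: the control-cartilage block; remaining healthy cartilage gets
  # the same composition so the shell is homogeneous.
  cart_idx <- which(lab == REGION_CARTILAGE)
  ctrl_mask <- array(FALSE, dim = d)
  ctrl_mask[attr(lab, "cartilage_rows"), attr(lab, "ctrl_cols"), ] <- TRUE
  ctrl_idx <- intersect(which(ctrl_mask), cart_idx)
  if (length(ctrl_idx) == 0L) stopf("layout leaves the CTRL VOI empty")
  other_idx <- setdiff(cart_idx, ctrl_idx)
  draw_cartilage(ctrl_idx, spec$ctrl_weights)
  if (length(other_idx)) draw_cartilage(other_idx, spec$ctrl_weights)

  voi_tx <- array(FALSE, dim = d); voi_tx[lesion_idx] <- TRUE
  voi_ctrl <- array(FALSE, dim = d); voi_ctrl[ctrl_idx] <- TRUE

  # Noiseless decay, then independent complex Gaussian noise per echo.
  E <- length(spec$te)
  dat <- array(0, dim = c(d, E))
  obj <- which(!is.na(true_t2))
  sig <- spec$sigma_rice
  for (i in seq_len(E)) {
    s <- array(0, dim = d)
    s[obj] <- true_a0[obj] * exp(-spec$te[i] / true_t2[obj])
    if (sig > 0) {
      m <- sqrt((s + array(rnorm(n, 0, sig), dim = d))^2 +
                  array(rnorm(n, 0, sig), dim = d)^2)
    } else m <- s
    dat[, , , i] <- m
  }
  if (isTRUE(spec$quantize)) dat <- pmin(pmax(round(dat), 0), 4095)

  series <- echo_series(dat, spec$te, spec$spacing, spec$thickness)
  truth <- structure(
    list(true_t2 = true_t2, true_a0 = true_a0, region_labels = lab,
         class_labels = cls, voi_tx = voi_tx, voi_ctrl = voi_ctrl,
         lesion_weights = spec$lesion_weights, ctrl_weights = spec$ctrl_weights),
    class = "ground_truth")
  list(series = series, truth = truth)
}

#' Generate a two-arm synthetic cohort
#'
#' Produces per-patient phantoms for two treatment arms whose treated-lesion
#' compositions are sampled from a Dirichlet distribution centred on the arm
#' mean fractions, while control cartilage composition is identical across
#' arms (cohort homogeneity holds by construction). Arm defaults emulate a
#' regenerative (BMDCT-like) versus reparative (MFS-like) comparison.
#'
#' @param n_per_arm named integer vector of patients per arm.
#' @param arm_means named list of length-3 mean lesion compositions
#'   (fibrocartilage, hyaline-like, remodeling), each summing to 1 after
#'   normalisation.
#' @param concentration Dirichlet concentration; larger is tighter.
#'   `Inf` gives zero dispersion (every patient at the arm mean).
#' @param base_spec a [phantom_spec()] supplying geometry, noise and control
#'   composition for every patient.
#' @param seed integer seed; per-patient seeds are derived from it.
#' @return A list of patients, each a list with `id`, `arm`, `weights`
#'   (sampled lesion composition), `series` and `truth`.
#' @export
generate_cohort <- function(n_per_arm = c(BMDCT = 9L, MFS = 6L),
                            arm_means = list(
                              BMDCT = c(0.18, 0.56, 0.27) / 1.01,
                              MFS   = c(0.46, 0.41, 0.18) / 1.05),
                            concentration = 50,
                            base_spec = phantom_spec(),
                            seed = 1L) {
  if (any(n_per_arm < 1L)) stopf("need at least 1 patient per arm")
  if (!all(names(n_per_arm) %in% names(arm_means)))
    stopf("every arm in `n_per_arm` needs a mean composition in `arm_means`")
  out <- list(); pid <- 0L
  for (arm in names(n_per_arm)) {
    mu <- arm_means[[arm]] / sum(arm_means[[arm]])
    w <- with_seed(seed + match(arm, names(n_per_arm)) * 10000L,
                   rdirichlet_mean(n_per_arm[[arm]], mu, concentration))
    for (j in seq_len(n_per_arm[[arm]])) {
      pid <- pid + 1L
      pspec <- base_spec
      pspec$lesion_weights <- w[j, ]
      pspec$seed <- as.integer((seed + 1000L * pid) %% .Machine$integer.max)
      ph <- generate_phantom(pspec)
      out[[pid]] <- list(id = sprintf("P%02d", pid), arm = arm,
                         weights = w[j, ], series = ph$series,
                         truth = ph$truth)
    }
  }
  out
}
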