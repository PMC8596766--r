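# Shared fixtures: the 5-echo protocol and small phantom builders.

TE5 <- c(13.8, 27.6, 41.4, 55.2, 69.0)

# Single-tissue noiseless phantom: every compartment is the same point-mass
# tissue, so every object voxel decays identically.
uniform_tissue_spec <- function(t2 = 40, a0 = 1000, shape = c(32, 32, 2),
                                sigma = 0, seed = 1) {
  one <- tissue_spec("uniform", t2_point(t2), a0_mean = a0, a0_cv = 0)
  phantom_spec(shape = shape, sigma_rice = sigma, seed = seed,
               tissues = list(bone = one, fluid = one, soft = one,
                              fibro = one, hyaline = one, remodel = one),
               lesion_weights = c(1, 0, 0), ctrl_weights = c(1, 0, 0))
}

# Pure-noise series: no object anywhere, so all echoes are Rayleigh.
rayleigh_series <- function(sigma, shape = c(50, 50, 4), te = TE5, seed = 1) {
  n <- prod(shape) * length(te)
  dat <- withr::with_seed(seed, {
    array(sqrt(rnorm(n, 0, sigma)^2 + rnorm(n, 0, sigma)^2),
          dim = c(shape, length(te)))
  })
  echo_series(dat, te)
}

# Rician echo-vector matrix (E x n) for a single (A0, T2) ground truth.
rician_voxels <- function(n, a0, t2, sigma, te = TE5, seed = 1) {
  E <- length(te)
  s <- a0 * exp(-te / t2)
  withr::with_seed(seed, {
    sqrt((matrix(s, E, n) + matrix(rnorm(E * n, 0, sigma), E))^2 +
           matrix(rnorm(E * n, 0, sigma), E)^2)
  })
}

small_phantom <- function(sigma = 60, shape = c(64, 64, 2), seed = 7, ...) {
  generate_phantom(phantom_spec(shape = shape, sigma_rice = sigma,
                                seed = seed, ...))
}
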