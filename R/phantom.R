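#' @title Synthetic brain phantoms with known lesions
#' @name synthetic_phantom
#' @description
#' Phantoms emulate the structure the pipeline relies on in real scans: an
#' ellipsoidal brain support with exactly-zero background (skull-stripped),
#' a smooth low-frequency tissue intensity field (a sum of Gaussian bumps,
#' so in-plane and across-third normalizations genuinely differ), a single
#' connected ellipsoidal lesion whose centre lies in the left hemisphere,
#' a second pseudo-modality with a different lesion contrast (emulating T1
#' vs FLAIR), and additive Gaussian noise. They do not emulate MRI physics,
#' bias fields, or multi-lesion anatomy.
NULL

#' Phantom specification
#'
#' @param shape grid dims (IS, PA, LR), each divisible by 16.
#' @param spacing voxel size in mm per axis.
#' @param lesion_center voxel coordinates of the lesion centre, or `NULL`
#'   to sample one in the left hemisphere.
#' @param lesion_radii lesion ellipsoid semi-axes in mm per axis.
#' @param lesion_offset_a,lesion_offset_b additive lesion contrast in
#'   modality A (T1-like, hypointense) and B (FLAIR-like, hyperintense).
#' @param n_bumps,bump_amp number and amplitude of the smooth intensity
#'   bumps forming the tissue field (baseline intensity 1).
#' @param noise_sd additive Gaussian noise level inside the brain support.
#' @param seed integer seed; the phantom is a deterministic function of the
#'   spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 64L, 48L), spacing = c(1, 1, 1),
                         lesion_center = NULL, lesion_radii = c(5, 6, 5),
                         lesion_offset_a = -0.5, lesion_offset_b = 0.7,
                         n_bumps = 4L, bump_amp = 0.25, noise_sd = 0.08,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape %% 16L != 0L))
    stopf("phantom_spec: shape (%s) must be divisible by 16",
          paste(shape, collapse = ","))
  if (any(lesion_radii <= 0)) stopf("phantom_spec: radii must be positive")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 lesion_center = lesion_center,
                 lesion_radii = as.numeric(lesion_radii),
                 lesion_offset_a = lesion_offset_a,
                 lesion_offset_b = lesion_offset_b,
                 n_bumps = as.integer(n_bumps), bump_amp = bump_amp,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

.ellipsoid_mask <- function(shape, center, semi) {
  g <- lapply(1:3, function(a) ((seq_len(shape[a]) - center[a]) / semi[a])^2)
  o <- outer(outer(g[[1]], g[[2]], `+`), g[[3]], `+`)
  o <= 1
}

#' Generate one phantom case
#'
#' Deterministic given the spec's seed. The returned mask is exactly the
#' voxelized lesion ellipsoid; the background outside the brain support is
#' exactly zero in both modalities.
#'
#' @param spec a [phantom_spec].
#' @return List with `t1`, `flair` ([brain_volume]s), `mask`
#'   ([lesion_mask]) and the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  sh <- spec$shape
  center <- (sh + 1) / 2
  brain_semi <- 0.45 * sh
  support <- .ellipsoid_mask(sh, center, brain_semi)
  # smooth low-frequency tissue field: baseline + Gaussian bumps
  field <- array(1, sh)
  ax <- lapply(sh, seq_len)
  for (k in seq_len(spec$n_bumps)) {
    bc <- center + (runif(3) - 0.5) * 0.8 * brain_semi
    bw <- (0.25 + 0.25 * runif(3)) * sh
    amp <- spec$bump_amp * (2 * runif(1) - 1)
    g <- lapply(1:3, function(a) exp(-((ax[[a]] - bc[a])^2) / (2 * bw[a]^2)))
    field <- field + amp * outer(outer(g[[1]], g[[2]], `*`), g[[3]], `*`)
  }
  rad_vox <- spec$lesion_radii / spec$spacing
  lc <- spec$lesion_center
  if (is.null(lc)) {
    # centre in the left hemisphere (lower LR index); rejection-sample a
    # placement whose voxelized lesion lies fully inside the support
    for (try in 1:200) {
      lc <- c(center[1] + (runif(1) - 0.5) * 0.7 * brain_semi[1],
              center[2] + (runif(1) - 0.5) * 0.7 * brain_semi[2],
              center[3] - runif(1) * 0.55 * brain_semi[3])
      les <- .ellipsoid_mask(sh, lc, rad_vox)
      if (all(support[les])) break
      lc <- NULL
    }
    if (is.null(lc))
      stopf("generate_phantom: could not place lesion inside the support")
  } else {
    les <- .ellipsoid_mask(sh, lc, rad_vox)
    if (!all(support[les]))
      stopf("generate_phantom: lesion extends outside the brain support")
  }
  noise_a <- array(rnorm(prod(sh), sd = spec$noise_sd), sh)
  noise_b <- array(rnorm(prod(sh), sd = spec$noise_sd), sh)
  a <- (field + spec$lesion_offset_a * les + noise_a) * support
  b <- (field + spec$lesion_offset_b * les + noise_b) * support
  list(t1 = brain_volume(a, spacing = spec$spacing),
       flair = brain_volume(b, spacing = spec$spacing),
       mask = lesion_mask(les * 1, spacing = spec$spacing),
       spec = spec)
}

#' Generate a phantom dataset with a small/large lesion mix
#'
#' Lesion placement, size and contrast are randomized per case from seeds
#' derived deterministically from the master seed. `round(size_mix * n)`
#' cases receive small lesions (all bounding-box extents strictly under
#' 20 x 20 x 25 mm) and the remainder large ones.
#'
#' @param n number of cases.
#' @param base_spec a [phantom_spec] providing shape, noise and contrast
#'   ranges.
#' @param size_mix fraction of small lesions in `[0, 1]`.
#' @param seed master seed.
#' @param id_prefix prefix for case identifiers.
#' @return List of cases, each with `id`, `t1`, `flair`, `mask`,
#'   `size_class` (intended class) and `seed`.
#' @export
generate_dataset <- function(n, base_spec = phantom_spec(), size_mix = 0.5,
                             seed = 1L, id_prefix = "case") {
  if (n < 1L) stopf("generate_dataset: n must be >= 1")
  if (size_mix < 0 || size_mix > 1)
    stopf("generate_dataset: size_mix must lie in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_small <- round(size_mix * n)
  small <- sample(rep(c(TRUE, FALSE), c(n_small, n - n_small)))
  lapply(seq_len(n), function(i) {
    set.seed(case_seeds[i])
    radii <- if (small[i]) {
      2.5 + runif(3) * 4.5              # extents <= ~16 mm: small
    } else {
      c(4.5 + runif(1) * 2.5,           # IS
        10.5 + runif(1) * 2,            # PA extent >= 22 mm: large
        5 + runif(1) * 2.5)             # LR
    }
    sp <- phantom_spec(shape = base_spec$shape, spacing = base_spec$spacing,
                       lesion_radii = radii,
                       lesion_offset_a = -(0.35 + runif(1) * 0.25),
                       lesion_offset_b = 0.5 + runif(1) * 0.3,
                       n_bumps = base_spec$n_bumps,
                       bump_amp = base_spec$bump_amp,
                       noise_sd = base_spec$noise_sd,
                       seed = case_seeds[i])
    ph <- generate_phantom(sp)
    c(list(id = sprintf("%s%03d", id_prefix, i),
           size_class = if (small[i]) "small" else "large",
           seed = case_seeds[i]),
      ph[c("t1", "flair", "mask")])
  })
}
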