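# Programmatic test fixtures: textured ellipsoid nucleus prototypes, toy
# spheroid scenes and paired volumes with known distributional differences.
# These are first-class generators (used by the CLI too), not canned data.

#' Textured ellipsoid nucleus prototype
#'
#' A stand-in for a manually annotated nucleus: a binary ellipsoid mask with
#' a smoothly varying multiplicative texture,
#' `intensity = base_level * (1 + texture_amplitude * field)`, zero outside
#' the mask and clipped at zero. With zero amplitude the intensity is
#' constant and independent of the seed.
#'
#' @param semi_axes ellipsoid semi-axes `(z, y, x)` in voxels, each >= 1.
#' @param texture_amplitude relative amplitude of the smooth texture field.
#' @param seed integer seed.
#' @param base_level mean interior intensity.
#' @param voxel_size voxel size `(z, y, x)` um.
#' @return A [nucleus_prototype()].
#' @export
make_ellipsoid_prototype <- function(semi_axes = c(3, 6, 6),
                                     texture_amplitude = 0.3,
                                     seed = 1L,
                                     base_level = 100,
                                     voxel_size = c(1, 1, 1)) {
  semi_axes <- as.numeric(semi_axes)
  if (any(semi_axes < 1)) stop("semi_axes must be >= 1", call. = FALSE)
  half <- ceiling(semi_axes)
  dims <- 2L * half + 1L
  zz <- (seq_len(dims[1]) - half[1] - 1L) / semi_axes[1]
  yy <- (seq_len(dims[2]) - half[2] - 1L) / semi_axes[2]
  xx <- (seq_len(dims[3]) - half[3] - 1L) / semi_axes[3]
  rho2 <- outer(outer(zz^2, yy^2, "+"), xx^2, "+")
  mask <- rho2 <= 1
  intens <- array(base_level, dims)
  if (texture_amplitude > 0) {
    field <- with_seed_or_current(substream_seed(seed, "texture"),
      smooth_field3d(dims, spacing = 3))
    intens <- intens * (1 + texture_amplitude * field)
    intens[intens < 0] <- 0
  }
  intens[!mask] <- 0
  nucleus_prototype(intens, mask, voxel_size,
    provenance = sprintf("ellipsoid_%s", paste(semi_axes, collapse = "x")))
}

#' Small synthetic nuclei database
#'
#' Convenience wrapper: a few textured ellipsoid prototypes of varied
#' shapes, expanded by offline augmentation.
#'
#' @param n_prototypes number of base ellipsoids.
#' @param cfg an [augmentation_config()].
#' @param seed integer seed.
#' @param base_semi_axes semi-axes of the first prototype; subsequent ones
#'   are mildly varied.
#' @return A `nuclei_database`.
#' @export
make_fixture_database <- function(n_prototypes = 3,
                                  cfg = augmentation_config(
                                    variants_per_prototype = 4),
                                  seed = 1L,
                                  base_semi_axes = c(2.5, 5, 5)) {
  protos <- lapply(seq_len(n_prototypes), function(i) {
    jitter <- 0.85 + 0.3 * ((i - 1) %% 3) / 2
    make_ellipsoid_prototype(
      semi_axes = pmax(1, base_semi_axes * jitter),
      texture_amplitude = 0.25,
      seed = substream_seed(seed, paste0("proto_", i)),
      base_level = 90 + 10 * i
    )
  })
  build_database(protos, cfg, seed = substream_seed(seed, "db"))
}

#' Toy spheroid scene
#'
#' Shape mask plus a placed (pre-imaging) scene at test scale.
#'
#' @param shape volume extents `(z, y, x)`.
#' @param radii mask semi-axes in voxels; default fills most of the volume.
#' @param db nuclei database; default [make_fixture_database()].
#' @param max_consecutive_failures placement stopping criterion.
#' @param seed integer seed.
#' @return List with `mask`, `placement` (a `placement_result`) and `db`.
#' @export
make_toy_spheroid <- function(shape = c(32, 96, 96), radii = NULL,
                              db = NULL, max_consecutive_failures = 200,
                              seed = 1L) {
  if (is.null(radii)) radii <- floor(shape / 2 * 0.85)
  if (is.null(db)) db <- make_fixture_database(seed = seed)
  mask <- generate_spheroid_mask(shape, radii, perturb_amplitude = 0.05,
    seed = substream_seed(seed, "mask"))
  placement <- place_nuclei(mask, db, placement_config(
    max_consecutive_failures = max_consecutive_failures,
    seed = substream_seed(seed, "placement")))
  list(mask = mask, placement = placement, db = db)
}

#' Paired reference / degraded volumes with known differences
#'
#' Emulates a matched real-like / simulation-like image pair over identical
#' labels: both volumes share the placed scene, brightness decay and PSF;
#' the degraded one receives `extra_blur_sigma` of additional in-plane blur
#' and *less* noise inside the culture (noise gain multiplied by
#' `inside_noise_factor` > 1 there), mimicking a simulation whose in-culture
#' noise is too clean. By construction the quality metrics must rank the
#' reference above the degraded volume: the edge profile of the degraded
#' volume peaks lower, and its intensity distributions deviate inside the
#' culture but not outside.
#'
#' @param shape volume extents `(z, y, x)`.
#' @param extra_blur_sigma additional `(y, x)` Gaussian sigma (px) applied
#'   to the degraded volume; 0 disables.
#' @param inside_noise_factor factor (>= 1) by which the Poisson gain is
#'   increased inside the mask for the degraded volume (less noise);
#'   1 disables.
#' @param background_level constant background offset added before noise so
#'   background regions carry a distribution.
#' @param gain base Poisson gain.
#' @param p brightness decay parameter.
#' @param seed integer seed.
#' @return List with `reference`, `degraded` (both [volume3d()]), `mask`,
#'   `labels`.
#' @export
make_degraded_pair <- function(shape = c(32, 100, 100),
                               extra_blur_sigma = 2,
                               inside_noise_factor = 16,
                               background_level = 20,
                               gain = 0.5,
                               p = 150,
                               seed = 1L) {
  scene <- make_toy_spheroid(shape, seed = substream_seed(seed, "scene"))
  mask <- scene$mask
  labels <- scene$placement$labels
  base <- scene$placement$image
  occ <- occlusion_depth(mask)
  base <- brightness_reduction(base, occ, p = p)
  psf <- gaussian_psf(c(1.5, 0.8, 0.8), voxel_size(base))
  base <- psf_convolve(base, psf)
  base_arr <- as_plain_array(base) + background_level

  deg_arr <- base_arr
  if (extra_blur_sigma > 0) {
    deg_arr <- gaussian_smooth(deg_arr,
      c(0, extra_blur_sigma, extra_blur_sigma))
  }
  inside <- as.vector(as_plain_array(mask))
  # one shared noise substream: with identity degradation parameters the
  # two volumes are drawn identically, hence exactly equal
  noisy <- function(v, gains) {
    with_seed_or_current(substream_seed(seed, "pair_noise"),
      stats::rpois(length(v), lambda = gains * v) / gains)
  }
  ref_v <- noisy(as.vector(base_arr), gain)
  deg_gain <- ifelse(inside, gain * inside_noise_factor, gain)
  deg_v <- noisy(as.vector(deg_arr), deg_gain)
  list(
    reference = volume3d(array(ref_v, dim(base_arr)), voxel_size(base)),
    degraded = volume3d(array(deg_v, dim(base_arr)), voxel_size(base)),
    mask = mask,
    labels = labels
  )
}
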