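#' Occlusion depth map
#'
#' For every voxel, the number of shape-mask foreground voxels strictly above
#' it (towards `z = 1`, the top optical section) in its own `(y, x)` column.
#' The count is exclusive, so the top slice is always 0 and an uncovered
#' surface voxel keeps full brightness. This map drives the content-dependent
#' brightness attenuation: deeper voxels with more occluding structure above
#' them receive less light.
#'
#' @param mask a [shape_mask()].
#' @return Integer 3D array of the same shape.
#' @export
occlusion_depth <- function(mask) {
  m <- array(as.integer(mask), dim(mask))
  nz <- dim(m)[1]
  # inclusive cumulative count down each column, then shift to exclusive
  cs <- apply(m, c(2, 3), cumsum)        # dims (z, y, x)
  if (nz == 1L) dim(cs) <- dim(m)
  occ <- array(0L, dim(m))
  if (nz > 1L) occ[2:nz, , ] <- cs[1:(nz - 1L), , ]
  storage.mode(occ) <- "integer"
  occ
}

#' Occlusion-dependent brightness factor
#'
#' The attenuation factor applied per voxel:
#' `b = clamp((i / p + 1)^(-6), 0, 1)`, where `i` is the occlusion depth and
#' `p > 0` tunes the decay. Larger `p` (a well-cleared sample) means a slower
#' decay; `i = 0` gives `b = 1` exactly. For `i >= 0` the raw power already
#' lies in `(0, 1]`, so the clamps are inert — they are retained as written
#' for defensive robustness.
#'
#' @param i occlusion depth(s), nonnegative.
#' @param p decay parameter, positive (paper-scale default 150).
#' @return Brightness factor(s) in `[0, 1]`, same shape as `i`.
#' @export
brightness_factor <- function(i, p = 150) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0) {
    stop("brightness parameter p must be a positive number", call. = FALSE)
  }
  pmax(pmin((i / p + 1)^(-6), 1), 0)
}

#' Apply brightness reduction to a volume
#'
#' Multiplies each voxel by its [brightness_factor()] computed from the
#' occlusion map.
#'
#' @param image a [volume3d()].
#' @param occ occlusion map from [occlusion_depth()], same shape.
#' @param p decay parameter (> 0).
#' @return A [volume3d()].
#' @export
brightness_reduction <- function(image, occ, p = 150) {
  if (!identical(dim(image), dim(occ))) {
    stop("image and occlusion map shapes differ", call. = FALSE)
  }
  b <- brightness_factor(as_plain_array(occ), p)
  volume3d(as_plain_array(image) * b, voxel_size(image))
}

#' PSF convolution of an intensity volume
#'
#' Models the optical blur of the microscope. In `"global"` mode the volume
#' is convolved once with the single kernel. In `"depth_varying"` mode the
#' volume is convolved with every anchored kernel and each z slice is
#' linearly interpolated between the two convolution results whose anchors
#' bracket that slice (clamped at the ends) — reproducing the increasing
#' blur of deeper optical sections. Boundaries are reflect-padded to avoid
#' dark halos at the volume faces.
#'
#' @param image a [volume3d()].
#' @param psfs a [psf_stack()].
#' @param mode `"global"` (single kernel) or `"depth_varying"` (>= 2 anchored
#'   kernels).
#' @return A [volume3d()].
#' @export
psf_convolve <- function(image, psfs, mode = c("global", "depth_varying")) {
  mode <- match.arg(mode)
  stopifnot(inherits(psfs, "psf_stack"))
  a <- as_plain_array(image)
  vs <- voxel_size(image)
  if (mode == "global") {
    if (length(psfs$kernels) != 1L) {
      stop("global mode needs exactly one kernel", call. = FALSE)
    }
    out <- conv3d_fft(a, psfs$kernels[[1]])
  } else {
    if (identical(psfs$depth_anchors, "global") || length(psfs$kernels) < 2L) {
      stop("depth_varying mode needs >= 2 kernels with depth anchors",
        call. = FALSE)
    }
    convs <- lapply(psfs$kernels, function(k) conv3d_fft(a, k))
    anchors <- psfs$depth_anchors            # sorted, 0-based z
    nz <- dim(a)[1]
    out <- array(0, dim(a))
    for (z in seq_len(nz)) {
      zc <- z - 1
      if (zc <= anchors[1]) {
        out[z, , ] <- convs[[1]][z, , ]
      } else if (zc >= anchors[length(anchors)]) {
        out[z, , ] <- convs[[length(convs)]][z, , ]
      } else {
        hi <- which(anchors >= zc)[1]
        lo <- hi - 1L
        w <- (zc - anchors[lo]) / (anchors[hi] - anchors[lo])
        out[z, , ] <- (1 - w) * convs[[lo]][z, , ] + w * convs[[hi]][z, , ]
      }
    }
  }
  out[out < 0] <- 0  # FFT round-off can leave tiny negatives
  volume3d(out, vs)
}

#' Enlarge labels by PSF convolution
#'
#' Manual annotations of real data include the apparent size increase caused
#' by optical blur; simulated labels can optionally mimic it. Each
#' instance's binary mask is convolved with the kernel and re-binarized at
#' `threshold` times its own maximum response. Voxels claimed by several
#' instances go to the instance with the larger response, original labeled
#' voxels are always retained, so instance supports stay disjoint and the
#' instance count is preserved.
#'
#' @param labels a [label_volume()].
#' @param psfs a [psf_stack()]; the first kernel is used.
#' @param threshold fraction in (0, 1) of the per-instance maximum response.
#' @return A [label_volume()].
#' @export
psf_enlarge_labels <- function(labels, psfs, threshold = 0.5) {
  stopifnot(inherits(psfs, "psf_stack"))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  kernel <- psfs$kernels[[1]]
  lab <- as_plain_array(labels)
  d <- dim(lab)
  kd <- dim(kernel)
  h <- (kd - 1L) %/% 2L
  best_resp <- array(0, d)
  best_id <- array(0L, d)
  for (id in label_ids(labels)) {
    sel <- lab == id
    # work in the instance bounding box padded by the kernel half-extent
    rng <- lapply(1:3, function(ax) range(which(apply(sel, ax, any))))
    lo <- pmax(c(rng[[1]][1], rng[[2]][1], rng[[3]][1]) - h, 1L)
    hi <- pmin(c(rng[[1]][2], rng[[2]][2], rng[[3]][2]) + h, d)
    sub <- sel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    resp <- conv3d_fft(array(as.numeric(sub), dim(sub)), kernel)
    keep <- resp >= threshold * max(resp)
    dst_resp <- best_resp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dst_id <- best_id[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    claim <- keep & (resp > dst_resp)
    dst_resp[claim] <- resp[claim]
    dst_id[claim] <- id
    best_resp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- dst_resp
    best_id[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- dst_id
  }
  best_id[lab != 0L] <- lab[lab != 0L]  # originals always retained
  label_volume(best_id, voxel_size(labels))
}

#' Anti-aliased downsampling to a target voxel size
#'
#' Models the discretization of the image sensor: the simulation runs at a
#' finer grid than the output. A separable Gaussian prefilter (sigma =
#' `(ratio - 1) / 2` per axis) suppresses aliasing, then the volume is
#' linearly interpolated at the coarse voxel centers. Output shape is
#' `floor(extent_um / target_voxel_size)`. Non-integer ratios (e.g. z 0.9 ->
#' 1.5 um, a factor 5/3) are handled naturally by the interpolation.
#' Requesting a finer grid than the source is an error.
#'
#' @param image a [volume3d()] or (with `method = "nearest"`) a
#'   [label_volume()].
#' @param target_voxel_size `(z, y, x)` in um, elementwise >= the source
#'   voxel size.
#' @param method `"linear"` (Gaussian prefilter + trilinear, for
#'   intensities) or `"nearest"` (no prefilter, for labels).
#' @return Downsampled volume with the updated `voxel_size`.
#' @export
downsample <- function(image, target_voxel_size,
                       method = c("linear", "nearest")) {
  method <- match.arg(method)
  src_vs <- voxel_size(image)
  tgt_vs <- check_voxel_size(target_voxel_size)
  ratio <- tgt_vs / src_vs
  if (any(ratio < 1 - 1e-9)) {
    stop("downsample: target voxel size must be >= source (no upsampling)",
      call. = FALSE)
  }
  d <- dim(image)
  out_d <- pmax(1L, as.integer(floor(d * src_vs / tgt_vs + 1e-9)))
  a <- as_plain_array(image)
  if (identical(as.integer(d), out_d) && all(abs(ratio - 1) < 1e-9)) {
    return(rewrap_volume(image, a, tgt_vs))
  }
  if (method == "linear") {
    sig <- pmax(0, (ratio - 1) / 2)
    a <- gaussian_smooth(a, sig)
  }
  # source coordinate of output voxel center j (0-based): (j + .5) ratio - .5
  coords <- lapply(1:3, function(ax) {
    (seq_len(out_d[ax]) - 0.5) * ratio[ax] - 0.5 + 1  # 1-based
  })
  out <- resample_grid(a, coords, nearest = (method == "nearest"))
  rewrap_volume(image, out, tgt_vs)
}

rewrap_volume <- function(template, data, vs) {
  if (inherits(template, "label_volume")) {
    label_volume(data, vs)
  } else if (inherits(template, "shape_mask")) {
    shape_mask(data != 0, vs)
  } else {
    data[data < 0] <- 0
    volume3d(data, vs)
  }
}

# Trilinear / nearest resampling of a 3D array at per-axis coordinate
# vectors (1-based, clamped to the grid).
resample_grid <- function(a, coords, nearest = FALSE) {
  d <- dim(a)
  out_d <- vapply(coords, length, integer(1))
  if (nearest) {
    idx <- lapply(1:3, function(ax) {
      pmin(pmax(floor(coords[[ax]] + 0.5), 1L), d[ax])
    })
    return(a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  base <- lapply(1:3, function(ax) {
    c0 <- pmin(pmax(coords[[ax]], 1), d[ax])
    i0 <- pmin(floor(c0), d[ax] - ifelse(d[ax] > 1L, 1L, 0L))
    i0 <- pmax(i0, 1L)
    list(i0 = i0, f = c0 - i0)
  })
  out <- array(0, out_d)
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    iz <- pmin(base[[1]]$i0 + bz, d[1])
    iy <- pmin(base[[2]]$i0 + by, d[2])
    ix <- pmin(base[[3]]$i0 + bx, d[3])
    wz <- if (bz == 0) 1 - base[[1]]$f else base[[1]]$f
    wy <- if (by == 0) 1 - base[[2]]$f else base[[2]]$f
    wx <- if (bx == 0) 1 - base[[3]]$f else base[[3]]$f
    w <- outer(outer(wz, wy), wx)
    dim(w) <- out_d
    out <- out + a[iz, iy, ix, drop = FALSE] * w
  }
  out
}

#' Apply Poisson shot noise
#'
#' Photon counting noise: each voxel intensity `v` is replaced by
#' `Poisson(gain * v) / gain`, independently per voxel. `gain` is the number
#' of photons per intensity unit; a larger gain means relatively less noise.
#' Zero voxels stay exactly zero.
#'
#' @param image a [volume3d()].
#' @param gain photons per intensity unit (> 0).
#' @param seed integer seed; `NULL` uses the ambient RNG.
#' @return A [volume3d()].
#' @export
apply_poisson_noise <- function(image, gain = 1, seed = NULL) {
  if (!is.numeric(gain) || gain <= 0) {
    stop("gain must be positive", call. = FALSE)
  }
  a <- as_plain_array(image)
  if (any(a < 0)) stop("negative intensities", call. = FALSE)
  out <- with_seed_or_current(
    if (is.null(seed)) NULL else substream_seed(seed, "noise"),
    stats::rpois(length(a), lambda = gain * as.vector(a)) / gain
  )
  volume3d(array(out, dim(a)), voxel_size(image))
}

#' Imaging configuration
#'
#' Stage parameters and per-stage enable flags for [simulate_imaging()].
#' Defaults follow the paper-scale profile: decay `p = 150`, simulation at
#' 0.9 x 0.122 x 0.122 um voxels downsampled to 1.5 x 0.489 x 0.489 um,
#' Poisson noise after downsampling.
#'
#' @param p brightness decay parameter (> 0).
#' @param psfs a [psf_stack()], or `NULL` to build a Gaussian PSF from
#'   `psf_sigma_um` at simulation resolution.
#' @param psf_sigma_um Gaussian PSF sigmas `(z, y, x)` in um (used when
#'   `psfs` is `NULL`).
#' @param psf_mode `"global"` or `"depth_varying"`.
#' @param enlarge_labels logical; run [psf_enlarge_labels()] on the labels.
#' @param enlarge_threshold threshold for the label enlargement.
#' @param target_voxel_size output voxel size `(z, y, x)` um, or `NULL` to
#'   skip downsampling.
#' @param gain Poisson gain (photons per intensity unit).
#' @param seed integer seed for the noise substream.
#' @param enable_brightness,enable_psf,enable_downsample,enable_noise
#'   per-stage switches for ablation and testing.
#' @return An `imaging_config` object.
#' @export
imaging_config <- function(p = 150,
                           psfs = NULL,
                           psf_sigma_um = c(1.8, 0.3, 0.3),
                           psf_mode = "global",
                           enlarge_labels = FALSE,
                           enlarge_threshold = 0.5,
                           target_voxel_size = NULL,
                           gain = 1,
                           seed = NULL,
                           enable_brightness = TRUE,
                           enable_psf = TRUE,
                           enable_downsample = !is.null(target_voxel_size),
                           enable_noise = TRUE) {
  structure(list(
    p = p, psfs = psfs, psf_sigma_um = psf_sigma_um, psf_mode = psf_mode,
    enlarge_labels = isTRUE(enlarge_labels),
    enlarge_threshold = enlarge_threshold,
    target_voxel_size = target_voxel_size,
    gain = gain, seed = seed,
    enable_brightness = isTRUE(enable_brightness),
    enable_psf = isTRUE(enable_psf),
    enable_downsample = isTRUE(enable_downsample),
    enable_noise = isTRUE(enable_noise)
  ), class = "imaging_config")
}

#' Run the full imaging simulation
#'
#' Applies the microscope model to a placed scene in the stated order:
#' brightness reduction (from the shape-mask occlusion map), PSF convolution
#' (with optional label enlargement by the same kernels), downsampling to
#' the target resolution (labels via nearest neighbor), and Poisson noise.
#' The label instance count is preserved.
#'
#' @param image a [volume3d()] from [place_nuclei()].
#' @param labels the matching [label_volume()].
#' @param mask the culture [shape_mask()] used for the occlusion map.
#' @param config an [imaging_config()].
#' @return List with `image` ([volume3d()]) and `labels` ([label_volume()]).
#' @export
simulate_imaging <- function(image, labels, mask, config = imaging_config()) {
  stopifnot(inherits(config, "imaging_config"))
  if (!identical(dim(image), dim(labels)) ||
      !identical(dim(image), dim(mask))) {
    stop("image, labels and mask must share one lattice", call. = FALSE)
  }
  n_before <- n_instances(labels)
  psfs <- config$psfs
  if (is.null(psfs) && (config$enable_psf || config$enlarge_labels)) {
    psfs <- gaussian_psf(config$psf_sigma_um, voxel_size(image))
  }
  out <- image
  if (config$enable_brightness) {
    occ <- occlusion_depth(mask)
    out <- brightness_reduction(out, occ, config$p)
  }
  if (config$enable_psf) {
    out <- psf_convolve(out, psfs, mode = config$psf_mode)
  }
  lab <- labels
  if (config$enlarge_labels) {
    lab <- psf_enlarge_labels(lab, psfs, config$enlarge_threshold)
  }
  if (config$enable_downsample) {
    if (is.null(config$target_voxel_size)) {
      stop("downsampling enabled but no target_voxel_size given",
        call. = FALSE)
    }
    out <- downsample(out, config$target_voxel_size, method = "linear")
    lab <- downsample(lab, config$target_voxel_size, method = "nearest")
  }
  if (config$enable_noise) {
    out <- apply_poisson_noise(out, gain = config$gain, seed = config$seed)
  }
  if (n_instances(lab) > n_before) {
    stop("internal error: label instances multiplied", call. = FALSE)
  }
  list(image = out, labels = lab)
}
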