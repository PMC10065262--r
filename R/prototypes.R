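#' Nucleus prototype
#'
#' A cropped intensity patch and binary mask of a single nucleus, used as the
#' stamp during placement. The bounding box is tight (every face of the box
#' touches the mask) and the intensity is zero outside the mask.
#'
#' @param intensity 3D nonnegative array `(z, y, x)`.
#' @param mask logical array of identical shape with at least one `TRUE`.
#' @param voxel_size voxel size `(z, y, x)` in um.
#' @param provenance free-text identifier (source image / augmentation trail).
#' @return A `nucleus_prototype` object.
#' @export
nucleus_prototype <- function(intensity, mask, voxel_size = c(1, 1, 1),
                              provenance = "unknown") {
  intensity <- check_grid(intensity, "nucleus_prototype")
  if (!is.logical(mask)) mask <- array(mask != 0, dim(mask))
  if (!identical(dim(intensity), dim(mask))) {
    stop("intensity and mask shapes differ", call. = FALSE)
  }
  if (!any(mask)) stop("prototype mask is empty", call. = FALSE)
  if (any(intensity < 0)) stop("prototype intensity negative", call. = FALSE)
  if (any(intensity[!mask] != 0)) {
    stop("prototype intensity must be zero outside the mask", call. = FALSE)
  }
  cropped <- crop_tight(intensity, mask)
  structure(
    list(intensity = cropped$intensity, mask = cropped$mask,
      voxel_size = check_voxel_size(voxel_size),
      provenance = as.character(provenance)),
    class = "nucleus_prototype"
  )
}

#' @export
print.nucleus_prototype <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<nucleus_prototype> %d x %d x %d (z, y, x), %d voxels [%s]\n",
    d[1], d[2], d[3], sum(x$mask), x$provenance))
  invisible(x)
}

# Crop both grids to the tight bounding box of the mask.
crop_tight <- function(intensity, mask) {
  stopifnot(any(mask))
  rng <- lapply(1:3, function(ax) range(which(apply(mask, ax, any))))
  iz <- rng[[1]][1]:rng[[1]][2]
  iy <- rng[[2]][1]:rng[[2]][2]
  ix <- rng[[3]][1]:rng[[3]][2]
  list(
    intensity = intensity[iz, iy, ix, drop = FALSE],
    mask = mask[iz, iy, ix, drop = FALSE]
  )
}

#' Extract a nucleus prototype from a labeled volume
#'
#' Crops the tight bounding box of one instance and zeroes the intensity
#' outside the instance mask. Instances touching the volume border are
#' allowed (the crop is simply truncated there) but reported via a message,
#' since a clipped nucleus is usually a poor prototype.
#'
#' @param image a [volume3d()].
#' @param labels a [label_volume()] on the same lattice.
#' @param label_id instance id to extract.
#' @return A [nucleus_prototype()].
#' @export
extract_prototype <- function(image, labels, label_id) {
  if (!identical(dim(image), dim(labels))) {
    stop("image and labels shapes differ", call. = FALSE)
  }
  sel <- as_plain_array(labels) == label_id
  if (!any(sel)) {
    stop("label id ", label_id, " not present in labels", call. = FALSE)
  }
  d <- dim(sel)
  touches <- any(sel[1, , ]) || any(sel[d[1], , ]) ||
    any(sel[, 1, ]) || any(sel[, d[2], ]) ||
    any(sel[, , 1]) || any(sel[, , d[3]])
  if (touches) {
    message("extract_prototype: label ", label_id, " touches the volume border")
  }
  intens <- as_plain_array(image)
  intens[!sel] <- 0
  nucleus_prototype(intens, sel, voxel_size(image),
    provenance = paste0("label_", label_id))
}

#' Augmentation configuration
#'
#' Parameter ranges for the offline database augmentation (applied once when
#' the database is built) and flags for the cheap per-placement online
#' augmentation. Each offline range is sampled uniformly per variant.
#' Geometric transforms act in the `(y, x)` plane only: the strong z
#' anisotropy of confocal stacks makes free 3D rotation unrealistic.
#'
#' @param rotation rotation angle range in degrees, `(y, x)` plane.
#' @param scale in-plane isotropic scale factor range.
#' @param blur in-plane Gaussian blur sigma range, voxels.
#' @param contrast linear gain range applied to intensities normalized to
#'   `[0, 1]` within the prototype (unit-free).
#' @param gamma gamma exponent range on the same normalized intensities.
#' @param elastic_amplitude displacement amplitude range, voxels, of a coarse
#'   random in-plane displacement grid upsampled to voxel resolution.
#' @param elastic_spacing control-point spacing of that grid, voxels.
#' @param variants_per_prototype offline variants generated per input
#'   prototype (>= 1). Default 32: ten annotated nuclei then yield a
#'   320-entry database.
#' @param online_flip enable independent random axis flips at sampling time.
#' @param online_swap enable random y/x axis swap at sampling time.
#' @return An `augmentation_config` object.
#' @export
augmentation_config <- function(rotation = c(0, 360),
                                scale = c(0.85, 1.15),
                                blur = c(0, 0.8),
                                contrast = c(0.85, 1.15),
                                gamma = c(0.8, 1.25),
                                elastic_amplitude = c(0, 1.5),
                                elastic_spacing = 8,
                                variants_per_prototype = 32,
                                online_flip = TRUE,
                                online_swap = TRUE) {
  chk_range <- function(r, name, lo_ok = -Inf) {
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < lo_ok) {
      stop("augmentation_config: invalid range for ", name, call. = FALSE)
    }
    as.numeric(r)
  }
  if (variants_per_prototype < 1) {
    stop("variants_per_prototype must be >= 1", call. = FALSE)
  }
  structure(list(
    rotation = chk_range(rotation, "rotation"),
    scale = chk_range(scale, "scale", lo_ok = 1e-6),
    blur = chk_range(blur, "blur", lo_ok = 0),
    contrast = chk_range(contrast, "contrast", lo_ok = 0),
    gamma = chk_range(gamma, "gamma", lo_ok = 1e-6),
    elastic_amplitude = chk_range(elastic_amplitude, "elastic_amplitude",
      lo_ok = 0),
    elastic_spacing = max(2, as.numeric(elastic_spacing)),
    variants_per_prototype = as.integer(variants_per_prototype),
    online_flip = isTRUE(online_flip),
    online_swap = isTRUE(online_swap)
  ), class = "augmentation_config")
}

#' Identity augmentation configuration
#'
#' All transform ranges pinned to their neutral values; useful for tests and
#' for building a database that replicates its inputs verbatim.
#'
#' @param variants_per_prototype copies per prototype.
#' @param online_flip,online_swap online augmentation flags.
#' @return An `augmentation_config`.
#' @export
identity_augmentation <- function(variants_per_prototype = 1,
                                  online_flip = FALSE, online_swap = FALSE) {
  augmentation_config(
    rotation = c(0, 0), scale = c(1, 1), blur = c(0, 0),
    contrast = c(1, 1), gamma = c(1, 1), elastic_amplitude = c(0, 0),
    variants_per_prototype = variants_per_prototype,
    online_flip = online_flip, online_swap = online_swap
  )
}

#' Offline augmentation of one prototype
#'
#' Draws `cfg$variants_per_prototype` augmented variants: an in-plane
#' rotation + scale + elastic warp (bilinear intensity, nearest-neighbor
#' mask), optional Gaussian blur, and contrast/gamma mapping of the
#' normalized intensities. A draw that empties the mask is retried with
#' fresh parameters; after 100 retries an error is raised. Deterministic for
#' a fixed seed.
#'
#' @param proto a [nucleus_prototype()].
#' @param cfg an [augmentation_config()].
#' @param seed integer seed.
#' @return List of `cfg$variants_per_prototype` prototypes.
#' @export
augment_offline <- function(proto, cfg, seed = 1L) {
  stopifnot(inherits(proto, "nucleus_prototype"),
    inherits(cfg, "augmentation_config"))
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(cfg$variants_per_prototype), function(v) {
      for (try in 1:100) {
        out <- try_augment_once(proto, cfg, v)
        if (!is.null(out)) return(out)
      }
      stop("augment_offline: transform emptied the mask 100 times in a row",
        call. = FALSE)
    })
  })
}

try_augment_once <- function(proto, cfg, variant) {
  angle <- stats::runif(1, cfg$rotation[1], cfg$rotation[2])
  scale <- stats::runif(1, cfg$scale[1], cfg$scale[2])
  blur <- stats::runif(1, cfg$blur[1], cfg$blur[2])
  contrast <- stats::runif(1, cfg$contrast[1], cfg$contrast[2])
  gamma <- stats::runif(1, cfg$gamma[1], cfg$gamma[2])
  amp <- stats::runif(1, cfg$elastic_amplitude[1], cfg$elastic_amplitude[2])

  geo <- warp_inplane(proto$intensity, proto$mask, angle, scale, amp,
    cfg$elastic_spacing)
  if (!any(geo$mask)) return(NULL)
  intens <- geo$intensity
  if (blur > 0) {
    intens <- gaussian_smooth(intens, c(0, blur, blur))
  }
  mx <- max(intens[geo$mask])
  if (mx > 0 && (contrast != 1 || gamma != 1)) {
    norm <- intens / mx
    norm <- pmin(pmax(contrast * norm^gamma, 0), 1)
    intens <- norm * mx
  }
  intens[!geo$mask] <- 0
  nucleus_prototype(intens, geo$mask, proto$voxel_size,
    provenance = sprintf("%s/aug%d", proto$provenance, variant))
}

# In-plane rotation + isotropic scale + elastic displacement, applied to
# every z slice identically. Intensity is sampled bilinearly (zero outside),
# the mask with nearest neighbor. The output canvas is enlarged so no
# foreground can be clipped; the caller re-crops tight.
warp_inplane <- function(intensity, mask, angle_deg, scale, elastic_amp,
                         elastic_spacing) {
  d <- dim(intensity)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  half <- ceiling(sqrt(ny^2 + nx^2) / 2 * max(scale, 1)) +
    ceiling(elastic_amp) + 2L
  oy <- 2L * half + 1L
  ox <- oy
  # output-centered coordinates
  vc <- seq_len(oy) - (half + 1L)
  uc <- seq_len(ox) - (half + 1L)
  V <- matrix(vc, oy, ox)
  U <- matrix(uc, oy, ox, byrow = TRUE)
  th <- -angle_deg * pi / 180  # inverse rotation
  sv <- (cos(th) * V - sin(th) * U) / scale
  su <- (sin(th) * V + cos(th) * U) / scale
  if (elastic_amp > 0) {
    disp <- elastic_field(oy, ox, elastic_spacing, elastic_amp)
    sv <- sv + disp$dy
    su <- su + disp$dx
  }
  # map back to 1-based input indices
  cy <- (ny + 1) / 2
  cx <- (nx + 1) / 2
  sy <- sv + cy
  sx <- su + cx

  M <- matrix(intensity, nz, ny * nx)  # column j = y + (x-1)*ny
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  gather <- function(yi, xi, w) {
    ok <- yi >= 1 & yi <= ny & xi >= 1 & xi <= nx
    col <- ifelse(ok, yi + (xi - 1) * ny, 1L)
    w <- w * ok
    M[, col, drop = FALSE] * rep(w, each = nz)
  }
  out <- gather(y0, x0, (1 - fy) * (1 - fx)) +
    gather(y0 + 1, x0, fy * (1 - fx)) +
    gather(y0, x0 + 1, (1 - fy) * fx) +
    gather(y0 + 1, x0 + 1, fy * fx)
  out_arr <- array(out, c(nz, oy, ox))

  yr <- floor(sy + 0.5); xr <- floor(sx + 0.5)
  okm <- yr >= 1 & yr <= ny & xr >= 1 & xr <= nx
  mcol <- ifelse(okm, yr + (xr - 1) * ny, 1L)
  Mm <- matrix(mask, nz, ny * nx)
  mout <- Mm[, mcol, drop = FALSE] & rep(okm, each = nz)
  mask_arr <- array(mout, c(nz, oy, ox))

  out_arr[!mask_arr] <- 0
  out_arr[out_arr < 0] <- 0
  if (!any(mask_arr)) {
    return(list(intensity = out_arr, mask = mask_arr))
  }
  crop_tight(out_arr, mask_arr)
}

# Smooth random in-plane displacement: coarse iid normal control grid,
# bilinearly upsampled, scaled to the requested amplitude (max |disp|).
elastic_field <- function(ny, nx, spacing, amplitude) {
  gy <- max(2L, ceiling(ny / spacing) + 1L)
  gx <- max(2L, ceiling(nx / spacing) + 1L)
  up <- function(g) {
    # bilinear upsample a gy x gx grid to ny x nx
    yi <- seq(1, gy, length.out = ny)
    xi <- seq(1, gx, length.out = nx)
    y0 <- pmin(floor(yi), gy - 1L); fy <- yi - y0
    x0 <- pmin(floor(xi), gx - 1L); fx <- xi - x0
    a <- g[cbind(rep(y0, nx), rep(x0, each = ny))]
    b <- g[cbind(rep(y0 + 1, nx), rep(x0, each = ny))]
    cc <- g[cbind(rep(y0, nx), rep(x0 + 1, each = ny))]
    dd <- g[cbind(rep(y0 + 1, nx), rep(x0 + 1, each = ny))]
    wy <- rep(fy, nx); wx <- rep(fx, each = ny)
    matrix(a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) +
      cc * (1 - wy) * wx + dd * wy * wx, ny, nx)
  }
  dy <- up(matrix(stats::rnorm(gy * gx), gy, gx))
  dx <- up(matrix(stats::rnorm(gy * gx), gy, gx))
  peak <- max(abs(c(dy, dx)), 1e-12)
  list(dy = dy / peak * amplitude, dx = dx / peak * amplitude)
}
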