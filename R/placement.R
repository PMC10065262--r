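#' Generate a perturbed ellipsoidal culture shape mask
#'
#' A voxel belongs to the mask iff its normalized radial coordinate
#' `rho = sqrt(((z-cz)/rz)^2 + ((y-cy)/ry)^2 + ((x-cx)/rx)^2)` satisfies
#' `rho <= 1 + a * f`, where `f` is a smooth random field (coarse Gaussian
#' control grid, trilinearly upsampled, normalized to unit standard
#' deviation) and `a = perturb_amplitude`. With zero amplitude this is the
#' exact discrete ellipsoid, independent of the seed. Spheroid cultures are
#' roughly ball-shaped; the perturbation supplies the irregular boundary of
#' real aggregates.
#'
#' @param shape volume extents `(z, y, x)` in voxels.
#' @param radii ellipsoid semi-axes `(rz, ry, rx)` in voxels; must fit within
#'   half the shape.
#' @param perturb_amplitude relative radial perturbation (fraction of the
#'   radius); 0 disables.
#' @param perturb_scale control-point spacing of the random field, voxels.
#' @param seed integer seed (only used when the amplitude is positive).
#' @param voxel_size voxel size `(z, y, x)` in um.
#' @param center ellipsoid center, 1-based voxel coordinates; default is the
#'   volume center.
#' @return A [shape_mask()].
#' @export
generate_spheroid_mask <- function(shape, radii, perturb_amplitude = 0.08,
                                   perturb_scale = 12, seed = 1L,
                                   voxel_size = c(1, 1, 1), center = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), length(radii) == 3L)
  radii <- as.numeric(radii)
  if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
  if (any(radii > shape / 2)) {
    stop("radii exceed half the volume extents", call. = FALSE)
  }
  if (is.null(center)) center <- (shape + 1) / 2
  zz <- (seq_len(shape[1]) - center[1]) / radii[1]
  yy <- (seq_len(shape[2]) - center[2]) / radii[2]
  xx <- (seq_len(shape[3]) - center[3]) / radii[3]
  rho <- sqrt(
    outer(outer(zz^2, yy^2, "+"), xx^2, "+")
  )
  if (perturb_amplitude > 0) {
    field <- with_seed_or_current(substream_seed(seed, "mask"),
      smooth_field3d(shape, perturb_scale))
    thresh <- 1 + perturb_amplitude * field
  } else {
    thresh <- 1
  }
  shape_mask(rho <= thresh, voxel_size)
}

# Smooth random scalar field: iid normal control grid with given spacing,
# trilinear upsample, normalized to sd 1.
smooth_field3d <- function(shape, spacing) {
  g <- pmax(2L, ceiling(shape / spacing) + 1L)
  ctrl <- array(stats::rnorm(prod(g)), g)
  axes <- lapply(1:3, function(ax) {
    t <- seq(1, g[ax], length.out = shape[ax])
    i0 <- pmin(floor(t), g[ax] - 1L)
    list(i0 = i0, f = t - i0)
  })
  out <- array(0, shape)
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    wz <- if (bz == 0) 1 - axes[[1]]$f else axes[[1]]$f
    wy <- if (by == 0) 1 - axes[[2]]$f else axes[[2]]$f
    wx <- if (bx == 0) 1 - axes[[3]]$f else axes[[3]]$f
    sub <- ctrl[axes[[1]]$i0 + bz, axes[[2]]$i0 + by, axes[[3]]$i0 + bx,
      drop = FALSE]
    w <- outer(outer(wz, wy), wx)
    dim(w) <- shape
    out <- out + sub * w
  }
  s <- stats::sd(out)
  if (s > 0) out / s else out
}

#' Placement configuration
#'
#' @param max_consecutive_failures stop once this many placement attempts
#'   fail in a row (paper-scale default 1000; lower values leave holes in the
#'   culture, higher values fill it evenly).
#' @param min_gap optional enlargement (voxels, Chebyshev) of the prototype
#'   mask during the collision test, enforcing clearance between nuclei;
#'   0 disables (nuclei may touch but never overlap).
#' @param require_fully_inside_mask require every prototype voxel to fall
#'   inside the culture shape mask.
#' @param seed integer seed for the placement substream; `NULL` uses the
#'   ambient RNG.
#' @return A `placement_config` object.
#' @export
placement_config <- function(max_consecutive_failures = 1000,
                             min_gap = 0,
                             require_fully_inside_mask = TRUE,
                             seed = NULL) {
  stopifnot(max_consecutive_failures >= 0, min_gap >= 0)
  structure(list(
    max_consecutive_failures = as.integer(max_consecutive_failures),
    min_gap = as.integer(min_gap),
    require_fully_inside_mask = isTRUE(require_fully_inside_mask),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "placement_config")
}

#' Validity check for one candidate position
#'
#' A position (the 1-based corner of the prototype bounding box) is valid iff
#' the box lies within the volume, every prototype mask voxel maps inside the
#' shape mask (when required), and the prototype mask — dilated by `min_gap`
#' (Chebyshev) — touches no already-labeled voxel.
#'
#' @param labels current [label_volume()].
#' @param mask culture [shape_mask()] (or `NULL` for no mask constraint).
#' @param proto candidate [nucleus_prototype()].
#' @param corner integer `(z, y, x)` 1-based corner of the prototype box.
#' @param cfg a [placement_config()].
#' @return List with `valid` (logical) and `reason` (`"ok"`,
#'   `"out_of_bounds"`, `"outside_mask"` or `"overlap"`).
#' @export
check_position <- function(labels, mask, proto, corner, cfg) {
  d <- dim(labels)
  pd <- dim(proto$mask)
  corner <- as.integer(corner)
  if (any(corner < 1L) || any(corner + pd - 1L > d)) {
    return(list(valid = FALSE, reason = "out_of_bounds"))
  }
  iz <- corner[1]:(corner[1] + pd[1] - 1L)
  iy <- corner[2]:(corner[2] + pd[2] - 1L)
  ix <- corner[3]:(corner[3] + pd[3] - 1L)
  pm <- proto$mask
  if (cfg$require_fully_inside_mask && !is.null(mask)) {
    sub_mask <- mask[iz, iy, ix, drop = FALSE]
    if (any(pm & !sub_mask)) {
      return(list(valid = FALSE, reason = "outside_mask"))
    }
  }
  if (cfg$min_gap > 0L) {
    g <- cfg$min_gap
    # dilate within an enlarged window, clipped at the volume faces
    lo <- pmax(corner - g, 1L)
    hi <- pmin(corner + pd - 1L + g, d)
    big <- array(FALSE, hi - lo + 1L)
    off <- corner - lo
    big[off[1] + seq_len(pd[1]), off[2] + seq_len(pd[2]),
      off[3] + seq_len(pd[3])] <- pm
    big <- dilate_chebyshev(big, g)
    sub_lab <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    if (any(big & (sub_lab != 0L))) {
      return(list(valid = FALSE, reason = "overlap"))
    }
  } else {
    sub_lab <- labels[iz, iy, ix, drop = FALSE]
    if (any(pm & (sub_lab != 0L))) {
      return(list(valid = FALSE, reason = "overlap"))
    }
  }
  list(valid = TRUE, reason = "ok")
}

#' Place nuclei into an empty volume until saturation
#'
#' The placement loop of the prototype-generation stage: draw a prototype
#' from the database (with online augmentation), draw a uniformly random
#' corner among positions whose box fits the volume, and test validity. A
#' success stamps the intensity and the next instance id and resets the
#' failure counter; the loop stops once `cfg$max_consecutive_failures`
#' attempts fail in a row. Placed instances are pairwise disjoint by
#' construction.
#'
#' @param mask culture [shape_mask()]; defines both the allowed region and
#'   the volume extents.
#' @param db a [build_database()] result.
#' @param cfg a [placement_config()].
#' @return A `placement_result`: list with `image` ([volume3d()]), `labels`
#'   ([label_volume()]), `n_placed`, and `attempts` (tibble with columns
#'   `attempt`, `accepted`, `reason`).
#' @export
place_nuclei <- function(mask, db, cfg = placement_config()) {
  if (db_size(db) == 0L) stop("empty nuclei database", call. = FALSE)
  d <- dim(mask)
  vs <- voxel_size(mask)
  image <- array(0, d)
  labels <- array(0L, d)
  run <- function() {
    n_placed <- 0L
    failures <- 0L
    acc <- logical(0)
    reas <- character(0)
    while (failures < cfg$max_consecutive_failures) {
      proto <- sample_prototype(db)
      pd <- dim(proto$mask)
      room <- d - pd
      if (any(room < 0L)) {
        verdict <- list(valid = FALSE, reason = "out_of_bounds")
      } else {
        corner <- c(
          sample.int(room[1] + 1L, 1L),
          sample.int(room[2] + 1L, 1L),
          sample.int(room[3] + 1L, 1L)
        )
        verdict <- check_position(labels, mask, proto, corner, cfg)
      }
      acc <- c(acc, verdict$valid)
      reas <- c(reas, verdict$reason)
      if (verdict$valid) {
        n_placed <- n_placed + 1L
        failures <- 0L
        iz <- corner[1]:(corner[1] + pd[1] - 1L)
        iy <- corner[2]:(corner[2] + pd[2] - 1L)
        ix <- corner[3]:(corner[3] + pd[3] - 1L)
        sel <- proto$mask
        sub_img <- image[iz, iy, ix, drop = FALSE]
        # maximum blending: inert under disjoint masks, guards stray overlaps
        sub_img[sel] <- pmax(sub_img[sel], proto$intensity[sel])
        image[iz, iy, ix] <<- sub_img
        sub_lab <- labels[iz, iy, ix, drop = FALSE]
        sub_lab[sel] <- n_placed
        labels[iz, iy, ix] <<- sub_lab
      } else {
        failures <- failures + 1L
      }
    }
    list(n_placed = n_placed, accepted = acc, reason = reas)
  }
  res <- with_seed_or_current(
    if (is.null(cfg$seed)) NULL else substream_seed(cfg$seed, "placement"),
    run()
  )
  structure(list(
    image = volume3d(image, vs),
    labels = label_volume(labels, vs),
    n_placed = res$n_placed,
    attempts = tibble::tibble(
      attempt = seq_along(res$accepted),
      accepted = res$accepted,
      reason = res$reason
    )
  ), class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("<placement_result> %d nuclei placed in %d attempts\n",
    x$n_placed, nrow(x$attempts)))
  invisible(x)
}
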