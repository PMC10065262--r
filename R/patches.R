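#' Plan an overlapping patch grid with border trimming
#'
#' Patch-based volume transforms (e.g. a GAN run on GPU-sized chunks)
#' produce artifacts near patch borders. The grid therefore uses
#' overlapping patches with stride `patch_size - 2 * trim` and discards a
#' `trim`-voxel border of every transformed patch before reassembly —
#' except at the volume faces, where there is no neighboring patch to take
#' over. The last patch per axis is shifted inward to stay in bounds. The
#' retained regions tile the volume exactly once: no averaging, so the
#' noise statistics of the transform output are preserved.
#'
#' @param shape volume extents `(z, y, x)`.
#' @param patch_size patch extents `(z, y, x)`, elementwise `<= shape`.
#' @param trim border voxels discarded per patch face, `< patch_size / 2`.
#' @return A `patch_grid`: per-patch 1-based corners and retained
#'   (absolute) index ranges.
#' @export
plan_patches <- function(shape, patch_size, trim = c(0, 0, 0)) {
  shape <- as.integer(rep_len(shape, 3L))
  patch_size <- as.integer(rep_len(patch_size, 3L))
  trim <- as.integer(rep_len(trim, 3L))
  if (any(trim < 0L)) stop("trim must be >= 0", call. = FALSE)
  if (any(2L * trim >= patch_size)) {
    stop("trim must be < patch_size / 2", call. = FALSE)
  }
  if (any(patch_size > shape)) {
    stop("patch_size exceeds volume shape (pad first)", call. = FALSE)
  }
  axes <- lapply(1:3, function(ax) {
    n <- shape[ax]; p <- patch_size[ax]; t <- trim[ax]
    s <- p - 2L * t
    anchors <- seq.int(1L, by = s, length.out = max(1L, ceiling((n - p) / s) + 1L))
    anchors <- anchors[anchors <= n - p + 1L]
    if (anchors[length(anchors)] < n - p + 1L) {
      anchors <- c(anchors, n - p + 1L)
    }
    k <- length(anchors)
    lo <- anchors + t
    hi <- anchors + p - 1L - t
    lo[1] <- 1L                       # volume faces keep their border
    hi[k] <- n
    if (k > 1L) {
      # shifted last anchor: hand the seam over at the previous patch's edge
      lo[k] <- max(lo[k], hi[k - 1L] + 1L)
    }
    list(anchors = anchors, lo = lo, hi = hi)
  })
  structure(list(
    shape = shape, patch_size = patch_size, trim = trim,
    stride = patch_size - 2L * trim, axes = axes
  ), class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  k <- vapply(x$axes, function(a) length(a$anchors), integer(1))
  cat(sprintf(
    "<patch_grid> %d patches (%d x %d x %d) of %s, trim %s, stride %s\n",
    prod(k), k[1], k[2], k[3],
    paste(x$patch_size, collapse = "x"),
    paste(x$trim, collapse = "x"),
    paste(x$stride, collapse = "x")
  ))
  invisible(x)
}

#' Coverage multiplicity of a patch grid
#'
#' How many retained regions claim each voxel; the grid invariant is that
#' this is identically 1.
#'
#' @param grid a [plan_patches()] result.
#' @return Integer 3D array of counts.
#' @export
patch_coverage <- function(grid) {
  cov <- array(0L, grid$shape)
  ax <- grid$axes
  for (i in seq_along(ax[[1]]$anchors)) {
    for (j in seq_along(ax[[2]]$anchors)) {
      for (k in seq_along(ax[[3]]$anchors)) {
        cov[ax[[1]]$lo[i]:ax[[1]]$hi[i],
            ax[[2]]$lo[j]:ax[[2]]$hi[j],
            ax[[3]]$lo[k]:ax[[3]]$hi[k]] <-
          cov[ax[[1]]$lo[i]:ax[[1]]$hi[i],
              ax[[2]]$lo[j]:ax[[2]]$hi[j],
              ax[[3]]$lo[k]:ax[[3]]$hi[k]] + 1L
      }
    }
  }
  cov
}

#' Transform a volume patchwise and reassemble seam-free
#'
#' Splits the volume according to the grid, applies `transform` to each
#' patch independently, and writes only the retained (trimmed) region of
#' each transformed patch into the output. With the identity transform the
#' output equals the input exactly — the contract that makes the trimming
#' scheme seam-free. Volumes smaller than the patch size are reflect-padded
#' to the patch size and cropped back after transformation.
#'
#' @param volume a [volume3d()] (or plain 3D array).
#' @param patch_size patch extents `(z, y, x)`.
#' @param trim border trim per face `(z, y, x)`.
#' @param transform function mapping a 3D array patch to an equal-shaped 3D
#'   array; default identity.
#' @return Transformed volume of the same class and shape as the input.
#' @export
transform_volume <- function(volume, patch_size, trim = c(0, 0, 0),
                             transform = identity) {
  a <- if (is.array(volume)) as_plain_array(volume) else
    stop("volume must be a 3D array", call. = FALSE)
  d <- dim(a)
  patch_size <- as.integer(rep_len(patch_size, 3L))
  pad <- pmax(patch_size - d, 0L)
  if (any(pad > 0L)) {
    idx <- lapply(1:3, function(ax) {
      reflect_index(seq_len(d[ax] + pad[ax]), d[ax])
    })
    a_work <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    a_work <- a
  }
  grid <- plan_patches(dim(a_work), patch_size, trim)
  out <- array(0, dim(a_work))
  ax <- grid$axes
  p <- grid$patch_size
  for (i in seq_along(ax[[1]]$anchors)) {
    for (j in seq_along(ax[[2]]$anchors)) {
      for (k in seq_along(ax[[3]]$anchors)) {
        az <- ax[[1]]$anchors[i]; ay <- ax[[2]]$anchors[j]
        axx <- ax[[3]]$anchors[k]
        patch <- a_work[az:(az + p[1] - 1L), ay:(ay + p[2] - 1L),
          axx:(axx + p[3] - 1L), drop = FALSE]
        tp <- transform(patch)
        if (!is.array(tp) || !identical(dim(tp), dim(patch))) {
          stop("transform must return an equal-shaped patch", call. = FALSE)
        }
        rz <- ax[[1]]$lo[i]:ax[[1]]$hi[i]
        ry <- ax[[2]]$lo[j]:ax[[2]]$hi[j]
        rx <- ax[[3]]$lo[k]:ax[[3]]$hi[k]
        out[rz, ry, rx] <- tp[rz - az + 1L, ry - ay + 1L, rx - axx + 1L,
          drop = FALSE]
      }
    }
  }
  out <- out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  if (inherits(volume, "volume3d")) {
    out[out < 0] <- 0
    volume3d(out, voxel_size(volume))
  } else {
    out
  }
}
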