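#' 3D intensity volume
#'
#' A `volume3d` is a nonnegative 3D numeric array indexed `(z, y, x)` with an
#' anisotropic physical voxel size in micrometers. The first array dimension is
#' depth: `vol[1, , ]` is the top optical section. All pipeline stages operate
#' on this container.
#'
#' @param data 3D numeric array, all values >= 0, indexed `(z, y, x)`.
#' @param voxel_size numeric length-3, physical voxel extent in um per axis
#'   `(z, y, x)`; strictly positive. Confocal stacks are typically anisotropic
#'   with z much coarser than y/x.
#' @return A `volume3d` object (the array with `voxel_size` attribute).
#' @examples
#' v <- volume3d(array(0, c(4, 8, 8)), voxel_size = c(0.9, 0.122, 0.122))
#' dim(v)
#' @export
volume3d <- function(data, voxel_size = c(1, 1, 1)) {
  data <- check_grid(data, "volume3d")
  if (any(data < 0)) {
    stop("volume3d: intensities must be nonnegative", call. = FALSE)
  }
  structure(data,
    voxel_size = check_voxel_size(voxel_size),
    class = "volume3d"
  )
}

#' 3D instance label volume
#'
#' Integer grid on the same `(z, y, x)` lattice as [volume3d()]; `0` is
#' background and each positive value is one nucleus instance. Instance ids
#' need not be contiguous but must each denote a single object.
#'
#' @param data 3D array of nonnegative integers, indexed `(z, y, x)`.
#' @inheritParams volume3d
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, voxel_size = c(1, 1, 1)) {
  data <- check_grid(data, "label_volume")
  if (any(data < 0)) {
    stop("label_volume: label ids must be nonnegative", call. = FALSE)
  }
  if (any(abs(data - round(data)) > 0)) {
    stop("label_volume: label ids must be integers", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  structure(data,
    voxel_size = check_voxel_size(voxel_size),
    class = "label_volume"
  )
}

check_grid <- function(data, what) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop(what, ": `data` must be a 3D array (z, y, x)", call. = FALSE)
  }
  if (any(dim(data) < 1L)) {
    stop(what, ": all dimensions must be >= 1", call. = FALSE)
  }
  if (anyNA(data)) stop(what, ": NA values not allowed", call. = FALSE)
  data
}

check_voxel_size <- function(voxel_size) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be 3 strictly positive values (z, y, x) in um",
      call. = FALSE)
  }
  names(voxel_size) <- c("z", "y", "x")
  voxel_size
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  vs <- voxel_size(x)
  cat(sprintf(
    "<volume3d> %d x %d x %d (z, y, x), voxel %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], vs[1], vs[2], vs[3]
  ))
  cat(sprintf("  intensity range [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<label_volume> %d x %d x %d (z, y, x), %d instance(s)\n",
    d[1], d[2], d[3], n_instances(x)
  ))
  invisible(x)
}

#' Voxel size accessor
#'
#' @param x a `volume3d`, `label_volume` or `shape_mask`.
#' @return Named numeric length-3 `(z, y, x)` in um.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size")
  if (is.null(vs)) c(z = 1, y = 1, x = 1) else vs
}

#' Instance ids present in a label volume
#'
#' @param labels a `label_volume` (or integer array).
#' @return Sorted integer vector of positive ids.
#' @export
label_ids <- function(labels) {
  ids <- sort(unique(as.integer(labels)))
  ids[ids > 0L]
}

n_instances <- function(labels) length(label_ids(labels))

#' Binary culture shape mask
#'
#' Logical grid on the `(z, y, x)` lattice marking the interior of the cell
#' culture. Nucleus placement is restricted to the mask and the imaging
#' model's occlusion depth counts mask voxels. A mask may be empty.
#'
#' @param data 3D logical (or 0/1) array.
#' @inheritParams volume3d
#' @return A `shape_mask` object.
#' @export
shape_mask <- function(data, voxel_size = c(1, 1, 1)) {
  data <- check_grid(data, "shape_mask")
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) {
      stop("shape_mask: values must be logical or 0/1", call. = FALSE)
    }
    data <- array(as.logical(data), dim(data))
  }
  structure(data,
    voxel_size = check_voxel_size(voxel_size),
    class = "shape_mask"
  )
}

#' @export
print.shape_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<shape_mask> %d x %d x %d (z, y, x), %d / %d voxels foreground\n",
    d[1], d[2], d[3], sum(x), length(x)
  ))
  invisible(x)
}

# strip class/attrs down to a plain array (arithmetic-safe)
as_plain_array <- function(x) {
  array(as.vector(x), dim(x))
}
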