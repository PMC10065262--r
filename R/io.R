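#' Read a 3D volume from a multi-page TIFF
#'
#' Pages are stacked in file order as the z axis, so a single-page file yields
#' shape `(1, H, W)`. Integer sample formats are returned as raw integer
#' intensities without any rescaling; float samples are returned as stored.
#' Intensities are never normalized on load — normalization is an explicit
#' pipeline step, because the comparison metrics operate on raw histograms.
#'
#' @param path path to a grayscale multi-page TIFF.
#' @param voxel_size physical voxel size `(z, y, x)` in um to attach; the
#'   plain TIFF container does not carry it.
#' @param as how to interpret the grid: `"intensity"` returns a [volume3d()],
#'   `"labels"` a [label_volume()], `"mask"` a [shape_mask()].
#' @return A `volume3d`, `label_volume` or `shape_mask`.
#' @export
read_volume <- function(path, voxel_size = c(1, 1, 1),
                        as = c("intensity", "labels", "mask")) {
  as <- match.arg(as)
  if (!file.exists(path)) {
    stop("read_volume: file not found: ", path, call. = FALSE)
  }
  info <- tryCatch(
    tiff::readTIFF(path, payload = FALSE, all = TRUE),
    error = function(e) {
      stop("read_volume: not a readable TIFF: ", path, " (",
        conditionMessage(e), ")", call. = FALSE)
    }
  )
  is_float <- any(info$sample.format == "float")
  bits <- max(info$bits.per.sample)
  # 8/16-bit integer samples come back exactly via as.is; 32-bit ones
  # overflow R's signed integers, so they are read scaled and rescaled
  scaled32 <- !is_float && bits >= 32
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float && !scaled32)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) {
    stop("read_volume: TIFF has zero planes: ", path, call. = FALSE)
  }
  pages <- lapply(pages, drop_channel)
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("read_volume: inconsistent plane shapes in ", path, call. = FALSE)
  }
  grid <- array(0, c(length(pages), shapes[1, 1], shapes[2, 1]))
  for (z in seq_along(pages)) grid[z, , ] <- pages[[z]]
  if (scaled32) {
    # r-tiff rescales 32-bit samples through single precision, which is
    # lossy in the upper range; re-read uncompressed files bit-exactly
    exact <- tryCatch(read_tiff_uint32(path), error = function(e) NULL)
    if (!is.null(exact) && identical(dim(exact), dim(grid))) {
      grid <- exact
    } else {
      grid <- round(grid * (2^32 - 1))
    }
  }
  switch(as,
    intensity = volume3d(grid, voxel_size),
    labels = label_volume(grid, voxel_size),
    mask = shape_mask(grid != 0, voxel_size)
  )
}

drop_channel <- function(m) {
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L) {
      stop("read_volume: multi-channel TIFF not supported", call. = FALSE)
    }
    m <- m[, , 1]
  }
  m
}

#' Write a 3D volume to a multi-page TIFF
#'
#' Integer encodings round-trip voxelwise exactly through [read_volume()].
#' Writing fractional values to an integer encoding is refused unless
#' `round = TRUE`, because silent quantization corrupts noise statistics.
#'
#' @param vol a `volume3d`, `label_volume` or `shape_mask`.
#' @param path output path.
#' @param encoding `"uint8"`, `"uint16"`, `"uint32"` or `"float32"`.
#' @param round round fractional values before integer encoding.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path,
                         encoding = c("uint16", "uint8", "uint32", "float32"),
                         round = FALSE) {
  encoding <- match.arg(encoding)
  grid <- as_plain_array(vol)
  storage.mode(grid) <- "double"
  nz <- dim(grid)[1]
  if (encoding == "float32") {
    write_tiff_raw32(grid, path, format = "float32")
    return(invisible(path))
  }
  bits <- c(uint8 = 8L, uint16 = 16L, uint32 = 32L)[[encoding]]
  vmax <- 2^bits - 1
  if (any(grid < 0) || any(grid > vmax)) {
    stop(sprintf("write_volume: values outside [0, %.0f] overflow %s",
      vmax, encoding), call. = FALSE)
  }
  frac <- any(abs(grid - base::round(grid)) > 0)
  if (frac) {
    if (!round) {
      stop("write_volume: fractional values need an integer encoding with ",
        "round = TRUE (or encoding = \"float32\")", call. = FALSE)
    }
    grid <- base::round(grid)
  }
  if (encoding == "uint32") {
    # r-tiff's scaled write path loses precision near the top of the
    # 32-bit range; write the samples verbatim instead
    write_tiff_raw32(grid, path, format = "uint32")
    return(invisible(path))
  }
  pages <- lapply(seq_len(nz), function(z) {
    m <- grid[z, , , drop = FALSE] / vmax
    dim(m) <- dim(grid)[2:3]   # keep degenerate axes as 2D pages
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  invisible(path)
}

# Minimal multi-page grayscale 32-bit TIFF writer (little-endian, one strip
# per page; SampleFormat IEEE float or unsigned integer). r-tiff reads both
# formats but writes neither losslessly.
write_tiff_raw32 <- function(grid, path, format = c("float32", "uint32")) {
  format <- match.arg(format)
  d <- dim(grid)
  nz <- d[1]; h <- d[2]; w <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(0x49L, 0x49L), con, size = 1)          # "II" little-endian
  writeBin(42L, con, size = 2, endian = "little")
  ifd0_offset <- 8L
  writeBin(ifd0_offset, con, size = 4, endian = "little")
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  strip_size <- 4L * w * h
  offset <- ifd0_offset
  for (z in seq_len(nz)) {
    data_offset <- offset + ifd_size
    next_ifd <- if (z < nz) data_offset + strip_size else 0L
    entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3L) {                              # SHORT, left-justified
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, w)                           # ImageWidth
    entry(257L, 4L, 1L, h)                           # ImageLength
    entry(258L, 3L, 1L, 32L)                         # BitsPerSample
    entry(259L, 3L, 1L, 1L)                          # Compression: none
    entry(262L, 3L, 1L, 1L)                          # Photometric: min-is-black
    entry(273L, 4L, 1L, data_offset)                 # StripOffsets
    entry(278L, 4L, 1L, h)                           # RowsPerStrip
    entry(279L, 4L, 1L, strip_size)                  # StripByteCounts
    entry(339L, 3L, 1L, if (format == "float32") 3L else 1L)  # SampleFormat
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    page <- grid[z, , , drop = FALSE]
    dim(page) <- c(h, w)
    v <- as.numeric(t(page))
    if (format == "float32") {
      writeBin(v, con, size = 4, endian = "little")
    } else {
      # little-endian unsigned 32-bit, assembled bytewise (R integers are
      # signed and cannot hold the top half of the range)
      bytes <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
        (v %/% 16777216) %% 256)
      writeBin(as.raw(bytes), con)
    }
    offset <- next_ifd
  }
  invisible(path)
}

# Bit-exact reader for uncompressed grayscale 32-bit unsigned multi-page
# TIFFs (both byte orders, strip-organized). Returns a (z, y, x) double
# array; errors on any layout it does not cover (the caller falls back to
# the general reader then).
read_tiff_uint32 <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off, endian) {
    b <- as.integer(raw_all[off + 1:2])
    if (endian == "little") b[1] + 256 * b[2] else b[2] + 256 * b[1]
  }
  u32 <- function(off, endian) {
    b <- as.integer(raw_all[off + 1:4])
    if (endian == "big") b <- rev(b)
    b[1] + 256 * (b[2] + 256 * (b[3] + 256 * b[4]))
  }
  magic <- rawToChar(raw_all[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF")
  if (u16(2, endian) != 42) stop("bad TIFF version")
  pages <- list()
  ifd <- u32(4, endian)
  while (ifd != 0) {
    n <- u16(ifd, endian)
    tags <- list()
    for (k in seq_len(n) - 1L) {
      off <- ifd + 2L + 12L * k
      tag <- u16(off, endian)
      type <- u16(off + 2L, endian)
      count <- u32(off + 4L, endian)
      size <- c(1, 1, 2, 4, 8)[type]
      vals <- if (size * count <= 4) {
        vo <- off + 8L
        vapply(seq_len(count) - 1L, function(i) {
          if (type == 3L) u16(vo + 2L * i, endian) else u32(vo + 4L * i,
            endian)
        }, numeric(1))
      } else {
        vo <- u32(off + 8L, endian)
        vapply(seq_len(count) - 1L, function(i) {
          if (type == 3L) u16(vo + 2L * i, endian) else u32(vo + 4L * i,
            endian)
        }, numeric(1))
      }
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("missing tag ", tag)
        default
      } else v
    }
    if (!identical(need(259, 1), 1)) stop("compressed")
    if (!identical(need(277, 1), 1)) stop("multi-sample")
    if (!identical(need(258), 32)) stop("not 32-bit")
    if (!need(339, 1) %in% c(1)) stop("not unsigned int")
    w <- need(256); h <- need(257)
    offs <- need(273); cnts <- need(279)
    bytes <- unlist(lapply(seq_along(offs), function(i) {
      as.integer(raw_all[offs[i] + seq_len(cnts[i])])
    }))
    if (length(bytes) != 4 * w * h) stop("strip size mismatch")
    m <- matrix(bytes, nrow = 4)
    if (endian == "big") m <- m[4:1, , drop = FALSE]
    vals <- m[1, ] + 256 * (m[2, ] + 256 * (m[3, ] + 256 * m[4, ]))
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
      byrow = TRUE)
    ifd <- u32(ifd + 2L + 12L * n, endian)
  }
  if (length(pages) == 0L) stop("no pages")
  grid <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) grid[z, , ] <- pages[[z]]
  grid
}

#' Read center-point annotations
#'
#' Reads a comma-separated file with header `id,z,y,x`. Coordinates are
#' 0-based voxel positions in `(z, y, x)` order, matching the axis convention
#' of [read_volume()].
#'
#' @param path CSV path.
#' @return A tibble with columns `id` (integer, unique), `z`, `y`, `x`
#'   (numeric), one row per annotated center, file order preserved.
#' @export
read_centers <- function(path) {
  if (!file.exists(path)) {
    stop("read_centers: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), c("id", "z", "y", "x"))) {
    stop("read_centers: header must be exactly `id,z,y,x`", call. = FALSE)
  }
  out <- tibble::tibble(
    id = suppressWarnings(as.integer(df$id)),
    z = suppressWarnings(as.numeric(df$z)),
    y = suppressWarnings(as.numeric(df$y)),
    x = suppressWarnings(as.numeric(df$x))
  )
  if (anyNA(out)) {
    stop("read_centers: non-numeric id or coordinates", call. = FALSE)
  }
  if (anyDuplicated(out$id)) {
    stop("read_centers: duplicate ids", call. = FALSE)
  }
  out
}

#' Write center-point annotations
#'
#' @param centers tibble/data frame with columns `id,z,y,x`.
#' @param path output CSV path.
#' @export
write_centers <- function(centers, path) {
  utils::write.csv(centers[, c("id", "z", "y", "x")], path, row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

#' Validate centers against a volume
#'
#' @param centers tibble from [read_centers()].
#' @param vol volume whose bounds to check (0-based coordinates must round
#'   into `[0, dim - 1]`).
#' @return `centers`, invisibly; errors on out-of-bounds coordinates.
#' @export
validate_centers <- function(centers, vol) {
  d <- dim(vol)
  idx <- cbind(floor(centers$z + 0.5), floor(centers$y + 0.5),
    floor(centers$x + 0.5))
  bad <- idx[, 1] < 0 | idx[, 1] >= d[1] |
    idx[, 2] < 0 | idx[, 2] >= d[2] |
    idx[, 3] < 0 | idx[, 3] >= d[3]
  if (any(bad)) {
    stop("centers out of volume bounds: id(s) ",
      paste(centers$id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(centers)
}

#' PSF kernel stack
#'
#' A list of nonnegative 3D kernels with odd extents, each attached to a depth
#' anchor (a 0-based z index, or `"global"` for a depth-independent kernel).
#' Kernels are renormalized to unit sum at construction; a deviation of more
#' than 1% from unit sum triggers a warning, since convolution is expected to
#' conserve energy.
#'
#' @param kernels list of 3D arrays (or a single array).
#' @param depth_anchors numeric vector of 0-based z anchors, or `"global"`.
#' @return A `psf_stack` object.
#' @export
psf_stack <- function(kernels, depth_anchors = "global") {
  if (is.array(kernels)) kernels <- list(kernels)
  stopifnot(length(kernels) >= 1L)
  kernels <- lapply(kernels, function(k) {
    if (length(dim(k)) != 3L) stop("PSF kernels must be 3D", call. = FALSE)
    if (any(dim(k) %% 2L == 0L)) {
      stop("PSF kernel extents must be odd", call. = FALSE)
    }
    if (any(k < 0)) stop("PSF kernels must be nonnegative", call. = FALSE)
    s <- sum(k)
    if (s <= 0) stop("PSF kernel sums to zero", call. = FALSE)
    if (abs(s - 1) > 0.01) {
      warning(sprintf("PSF kernel sum %.4g deviates >1%% from 1; renormalized",
        s), call. = FALSE)
    }
    k / s
  })
  if (identical(depth_anchors, "global")) {
    if (length(kernels) != 1L) {
      stop("a global PSF stack holds exactly one kernel", call. = FALSE)
    }
    anchors <- "global"
  } else {
    anchors <- as.numeric(depth_anchors)
    if (length(anchors) != length(kernels) || anyDuplicated(anchors)) {
      stop("depth_anchors must be distinct, one per kernel", call. = FALSE)
    }
    ord <- order(anchors)
    kernels <- kernels[ord]
    anchors <- anchors[ord]
  }
  structure(list(kernels = kernels, depth_anchors = anchors),
    class = "psf_stack")
}

#' Read a PSF kernel from TIFF
#'
#' @param path multi-page TIFF holding one 3D kernel.
#' @param depth_anchor 0-based z anchor or `"global"`.
#' @return A single-kernel [psf_stack()].
#' @export
read_psf <- function(path, depth_anchor = "global") {
  v <- read_volume(path)
  psf_stack(list(as_plain_array(v)), depth_anchor)
}

#' Gaussian PSF model
#'
#' Anisotropic Gaussian stand-in for a measured point spread function,
#' parameterized in physical units so the kernel footprint follows the voxel
#' grid. The axial sigma is normally largest, mirroring the elongation of
#' confocal PSFs along z.
#'
#' @param sigma_um sigmas `(z, y, x)` in um.
#' @param voxel_size voxel size `(z, y, x)` in um of the grid the PSF will be
#'   applied on.
#' @return A single-kernel, global [psf_stack()].
#' @export
gaussian_psf <- function(sigma_um = c(1.8, 0.3, 0.3),
                         voxel_size = c(1, 1, 1)) {
  voxel_size <- check_voxel_size(voxel_size)
  sv <- rep_len(sigma_um, 3L) / voxel_size
  ks <- lapply(sv, gaussian_kernel1d)
  k <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
  dim(k) <- c(length(ks[[1]]), length(ks[[2]]), length(ks[[3]]))
  psf_stack(list(k / sum(k)), "global")
}

#' @export
print.psf_stack <- function(x, ...) {
  n <- length(x$kernels)
  cat(sprintf("<psf_stack> %d kernel(s), anchors: %s\n", n,
    paste(x$depth_anchors, collapse = ", ")))
  invisible(x)
}
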