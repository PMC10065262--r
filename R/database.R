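#' Build a nuclei prototype database
#'
#' Expands a small set of annotated prototypes by offline augmentation into
#' the pool sampled during placement. With the default 32 variants per
#' prototype, ten annotated nuclei yield a 320-entry database. Reproducible:
#' identical inputs and seed give a voxelwise identical database.
#'
#' @param protos nonempty list of [nucleus_prototype()].
#' @param cfg an [augmentation_config()].
#' @param seed integer seed for the offline augmentation.
#' @return A `nuclei_database`: prototypes plus a manifest recording the
#'   configuration and seed.
#' @export
build_database <- function(protos, cfg = augmentation_config(), seed = 1L) {
  if (inherits(protos, "nucleus_prototype")) protos <- list(protos)
  if (length(protos) == 0L) {
    stop("build_database: empty prototype list", call. = FALSE)
  }
  stopifnot(all(vapply(protos, inherits, TRUE, "nucleus_prototype")))
  vs <- protos[[1]]$voxel_size
  same_vs <- vapply(protos, function(p) all(p$voxel_size == vs), TRUE)
  if (!all(same_vs)) {
    stop("build_database: prototypes must share one voxel size", call. = FALSE)
  }
  entries <- list()
  for (i in seq_along(protos)) {
    entries <- c(entries, augment_offline(protos[[i]], cfg,
      seed = substream_seed(seed, paste0("augment_", i))))
  }
  structure(list(
    prototypes = entries,
    config = cfg,
    manifest = list(
      n_input = length(protos),
      variants_per_prototype = cfg$variants_per_prototype,
      n_entries = length(entries),
      seed = as.integer(seed),
      voxel_size = vs
    )
  ), class = "nuclei_database")
}

#' @export
print.nuclei_database <- function(x, ...) {
  cat(sprintf("<nuclei_database> %d entries (%d input x %d variants), seed %d\n",
    x$manifest$n_entries, x$manifest$n_input,
    x$manifest$variants_per_prototype, x$manifest$seed))
  invisible(x)
}

#' Number of database entries
#' @param db a `nuclei_database`.
#' @export
db_size <- function(db) length(db$prototypes)

#' Draw one prototype with online augmentation
#'
#' Uniform draw over database entries, followed by the cheap per-placement
#' augmentation: independent random flips along each axis and an optional
#' y/x swap (both controlled by the database's configuration). These
#' transforms are exact index permutations, so the foreground voxel count is
#' preserved and the mask transforms identically to the intensity.
#'
#' Draws from the ambient RNG; seed at the caller (placement wraps this in
#' its own substream).
#'
#' @param db a [build_database()] result.
#' @param flip,swap override the database's online augmentation flags.
#' @return A [nucleus_prototype()].
#' @export
sample_prototype <- function(db, flip = NULL, swap = NULL) {
  if (db_size(db) == 0L) stop("empty nuclei database", call. = FALSE)
  flip <- if (is.null(flip)) db$config$online_flip else isTRUE(flip)
  swap <- if (is.null(swap)) db$config$online_swap else isTRUE(swap)
  p <- db$prototypes[[sample.int(db_size(db), 1L)]]
  intens <- p$intensity
  mask <- p$mask
  if (flip) {
    for (axis in 1:3) {
      if (stats::runif(1) < 0.5) {
        intens <- flip_axis(intens, axis)
        mask <- flip_axis(mask, axis)
      }
    }
  }
  if (swap && stats::runif(1) < 0.5) {
    intens <- aperm(intens, c(1, 3, 2))
    mask <- aperm(mask, c(1, 3, 2))
  }
  nucleus_prototype(intens, mask, p$voxel_size, provenance = p$provenance)
}

flip_axis <- function(a, axis) {
  n <- dim(a)[axis]
  idx <- n:1
  switch(axis,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE]
  )
}

#' Write a nuclei database to disk
#'
#' Layout: one directory with paired float32 TIFFs `<id>_img.tif` /
#' `<id>_mask.tif` per entry and a `manifest.json` holding voxel size,
#' augmentation configuration, seed and the entry list.
#'
#' @param db a `nuclei_database`.
#' @param dir output directory (created if missing).
#' @export
write_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- db$manifest$voxel_size
  ids <- sprintf("n%04d", seq_len(db_size(db)))
  for (i in seq_len(db_size(db))) {
    p <- db$prototypes[[i]]
    write_volume(volume3d(p$intensity, vs),
      file.path(dir, paste0(ids[i], "_img.tif")), encoding = "float32")
    write_volume(label_volume(array(as.integer(p$mask), dim(p$mask)), vs),
      file.path(dir, paste0(ids[i], "_mask.tif")), encoding = "uint8")
  }
  manifest <- list(
    voxel_size = unname(vs),
    seed = db$manifest$seed,
    n_input = db$manifest$n_input,
    variants_per_prototype = db$manifest$variants_per_prototype,
    config = unclass(db$config),
    entries = lapply(seq_len(db_size(db)), function(i) {
      list(id = ids[i], provenance = db$prototypes[[i]]$provenance)
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a nuclei database from disk
#'
#' @param dir directory written by [write_database()].
#' @return A `nuclei_database`.
#' @export
read_database <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("read_database: no manifest.json in ", dir, call. = FALSE)
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  vs <- as.numeric(mf$voxel_size)
  cfg <- do.call(augmentation_config, mf$config[
    setdiff(names(mf$config), character(0))])
  entries <- lapply(seq_len(nrow(mf$entries)), function(i) {
    id <- mf$entries$id[i]
    img <- read_volume(file.path(dir, paste0(id, "_img.tif")), vs)
    msk <- read_volume(file.path(dir, paste0(id, "_mask.tif")), vs,
      as = "labels")
    nucleus_prototype(as_plain_array(img), as_plain_array(msk) != 0, vs,
      provenance = mf$entries$provenance[i])
  })
  structure(list(
    prototypes = entries,
    config = cfg,
    manifest = list(
      n_input = mf$n_input,
      variants_per_prototype = mf$variants_per_prototype,
      n_entries = length(entries),
      seed = as.integer(mf$seed),
      voxel_size = check_voxel_size(vs)
    )
  ), class = "nuclei_database")
}
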