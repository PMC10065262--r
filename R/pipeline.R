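# Structured configuration + single entry point used by the command-line
# script. Config files are YAML with one section per pipeline stage; unknown
# keys are errors so typos cannot silently fall back to defaults. Every run
# writes a JSON manifest (command, config, seed, package version, outputs)
# sufficient for exact re-execution.

check_keys <- function(lst, allowed, path) {
  if (is.null(lst)) return(invisible(NULL))
  if (!is.list(lst)) stop("config: `", path, "` must be a mapping",
    call. = FALSE)
  extra <- setdiff(names(lst), allowed)
  if (length(extra) > 0L) {
    stop("config: unknown key(s) under `", path, "`: ",
      paste(extra, collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

need_key <- function(lst, key, path) {
  if (is.null(lst[[key]])) {
    stop("config: missing required key `", path, ".", key, "`",
      call. = FALSE)
  }
  lst[[key]]
}

#' Default simulation profile
#'
#' The parameter set of the full-scale study conditions: brightness decay
#' `p = 150`, 1000 consecutive placement attempts with no overlap and no
#' enlargement, simulation voxels 0.9 x 0.122 x 0.122 um downsampled to
#' 1.5 x 0.489 x 0.489 um, Poisson noise after downsampling. Volume shape
#' and database are left to the caller.
#'
#' @return Nested config list for the `simulate` command.
#' @export
default_simulation_config <- function() {
  list(
    voxel_size = c(0.9, 0.122, 0.122),
    mask = list(shape = c(64, 256, 256), radii = c(28, 110, 110),
      perturb_amplitude = 0.08, perturb_scale = 12),
    placement = list(max_consecutive_failures = 1000, min_gap = 0,
      require_fully_inside_mask = TRUE),
    imaging = list(p = 150, psf_sigma_um = c(1.8, 0.3, 0.3),
      enlarge_labels = FALSE, enlarge_threshold = 0.5,
      target_voxel_size = c(1.5, 0.489, 0.489), gain = 1,
      enable_brightness = TRUE, enable_psf = TRUE,
      enable_downsample = TRUE, enable_noise = TRUE)
  )
}

#' Run a pipeline command
#'
#' Programmatic equivalent of the `spheroidsim` command-line tool. All
#' randomness flows from `seed` through named substreams, so identical
#' config + seed reproduce identical outputs (bytewise for integer TIFF
#' encodings). On failure, partially written outputs are removed.
#'
#' @param command one of `"build-db"`, `"simulate"`, `"transform"`,
#'   `"measure"`, `"eval-det"`, `"fixtures"`.
#' @param config nested config list (e.g. from [yaml::read_yaml()]), or a
#'   path to a YAML file.
#' @param seed top-level integer seed.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the run manifest (also written as
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(command, config = list(), seed = 1L,
                         out_dir = ".") {
  command <- match.arg(command,
    c("build-db", "simulate", "transform", "measure", "eval-det",
      "fixtures"))
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  note <- function(path) {
    outputs[[length(outputs) + 1L]] <<- path
    path
  }
  result <- tryCatch(
    switch(command,
      "build-db" = cmd_build_db(config, seed, out_dir, note),
      "simulate" = cmd_simulate(config, seed, out_dir, note),
      "transform" = cmd_transform(config, seed, out_dir, note),
      "measure" = cmd_measure(config, seed, out_dir, note),
      "eval-det" = cmd_eval_det(config, seed, out_dir, note),
      "fixtures" = cmd_fixtures(config, seed, out_dir, note)
    ),
    error = function(e) {
      unlink(outputs)
      stop(e)
    }
  )
  manifest <- c(list(
    command = command,
    seed = as.integer(seed),
    package = "spheroidsim",
    version = as.character(utils::packageVersion("spheroidsim")),
    config = config,
    outputs = outputs
  ), result)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

load_db <- function(spec, seed) {
  if (is.character(spec)) return(read_database(spec))
  if (is.list(spec) && identical(spec$kind, "fixture")) {
    check_keys(spec, c("kind", "n_prototypes", "variants_per_prototype"),
      "db")
    return(make_fixture_database(
      n_prototypes = spec$n_prototypes %||% 3,
      cfg = augmentation_config(
        variants_per_prototype = spec$variants_per_prototype %||% 4),
      seed = seed))
  }
  if (inherits(spec, "nuclei_database")) return(spec)
  stop("config: `db` must be a database directory path or a fixture spec",
    call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cmd_build_db <- function(config, seed, out_dir, note) {
  check_keys(config, c("prototypes", "augmentation", "name"), "build-db")
  pspec <- need_key(config, "prototypes", "build-db")
  aug <- do.call(augmentation_config, config$augmentation %||% list())
  if (identical(pspec$kind, "fixture")) {
    check_keys(pspec, c("kind", "n_prototypes", "semi_axes"),
      "build-db.prototypes")
    protos <- lapply(seq_len(pspec$n_prototypes %||% 3), function(i) {
      make_ellipsoid_prototype(
        semi_axes = pspec$semi_axes %||% c(2.5, 5, 5),
        seed = substream_seed(seed, paste0("proto_", i)))
    })
  } else {
    check_keys(pspec, c("image", "labels", "ids", "voxel_size"),
      "build-db.prototypes")
    vs <- pspec$voxel_size %||% c(1, 1, 1)
    img <- read_volume(need_key(pspec, "image", "build-db.prototypes"), vs)
    lab <- read_volume(need_key(pspec, "labels", "build-db.prototypes"), vs,
      as = "labels")
    ids <- pspec$ids %||% label_ids(lab)
    protos <- lapply(ids, function(id) extract_prototype(img, lab, id))
  }
  db <- build_database(protos, aug, seed = seed)
  dbdir <- note(file.path(out_dir, config$name %||% "nuclei_db"))
  write_database(db, dbdir)
  list(n_entries = db_size(db), db_dir = dbdir)
}

cmd_simulate <- function(config, seed, out_dir, note) {
  check_keys(config, c("voxel_size", "mask", "db", "placement", "imaging",
    "encoding"), "simulate")
  vs <- config$voxel_size %||% c(1, 1, 1)
  mspec <- need_key(config, "mask", "simulate")
  if (is.character(mspec)) {
    mask <- read_volume(mspec, vs, as = "mask")
  } else {
    check_keys(mspec, c("shape", "radii", "perturb_amplitude",
      "perturb_scale"), "simulate.mask")
    mask <- generate_spheroid_mask(
      shape = need_key(mspec, "shape", "simulate.mask"),
      radii = need_key(mspec, "radii", "simulate.mask"),
      perturb_amplitude = mspec$perturb_amplitude %||% 0.08,
      perturb_scale = mspec$perturb_scale %||% 12,
      seed = seed, voxel_size = vs)
  }
  db <- load_db(need_key(config, "db", "simulate"),
    substream_seed(seed, "db"))
  pl <- config$placement %||% list()
  check_keys(pl, c("max_consecutive_failures", "min_gap",
    "require_fully_inside_mask"), "simulate.placement")
  pcfg <- placement_config(
    max_consecutive_failures = pl$max_consecutive_failures %||% 1000,
    min_gap = pl$min_gap %||% 0,
    require_fully_inside_mask = pl$require_fully_inside_mask %||% TRUE,
    seed = seed)
  placed <- place_nuclei(mask, db, pcfg)
  im <- config$imaging %||% list()
  check_keys(im, c("p", "psf", "psf_sigma_um", "enlarge_labels",
    "enlarge_threshold", "target_voxel_size", "gain", "enable_brightness",
    "enable_psf", "enable_downsample", "enable_noise"), "simulate.imaging")
  psfs <- if (is.character(im$psf)) read_psf(im$psf) else NULL
  icfg <- imaging_config(
    p = im$p %||% 150, psfs = psfs,
    psf_sigma_um = im$psf_sigma_um %||% c(1.8, 0.3, 0.3),
    enlarge_labels = im$enlarge_labels %||% FALSE,
    enlarge_threshold = im$enlarge_threshold %||% 0.5,
    target_voxel_size = im$target_voxel_size,
    gain = im$gain %||% 1, seed = seed,
    enable_brightness = im$enable_brightness %||% TRUE,
    enable_psf = im$enable_psf %||% TRUE,
    enable_downsample = im$enable_downsample %||%
      !is.null(im$target_voxel_size),
    enable_noise = im$enable_noise %||% TRUE)
  sim <- simulate_imaging(placed$image, placed$labels, mask, icfg)
  enc <- config$encoding %||% "float32"
  write_volume(sim$image, note(file.path(out_dir, "image.tif")),
    encoding = enc, round = FALSE)
  write_volume(sim$labels, note(file.path(out_dir, "labels.tif")),
    encoding = "uint16")
  write_volume(mask, note(file.path(out_dir, "mask.tif")),
    encoding = "uint8")
  list(n_placed = placed$n_placed, n_attempts = nrow(placed$attempts))
}

cmd_transform <- function(config, seed, out_dir, note) {
  check_keys(config, c("input", "patch_size", "trim", "transform",
    "voxel_size"), "transform")
  vol <- read_volume(need_key(config, "input", "transform"),
    config$voxel_size %||% c(1, 1, 1))
  tf <- config$transform %||% "identity"
  if (!identical(tf, "identity")) {
    stop("config: only the identity transform is built in; plug external ",
      "operators in via transform_volume()", call. = FALSE)
  }
  out <- transform_volume(vol,
    patch_size = need_key(config, "patch_size", "transform"),
    trim = config$trim %||% c(0, 0, 0),
    transform = identity)
  write_volume(out, note(file.path(out_dir, "transformed.tif")),
    encoding = "float32")
  list(patch_size = config$patch_size, trim = config$trim %||% c(0, 0, 0))
}

cmd_measure <- function(config, seed, out_dir, note) {
  check_keys(config, c("type", "real", "syn", "real_mask", "real_labels",
    "syn_mask", "syn_labels", "image", "dilation_radius", "section_size",
    "sigma", "t_b", "t_r", "a", "b", "column", "alternative"), "measure")
  type <- match.arg(need_key(config, "type", "measure"),
    c("wasserstein", "edgeq", "compare"))
  if (type == "wasserstein") {
    real <- read_volume(need_key(config, "real", "measure"))
    syn <- read_volume(need_key(config, "syn", "measure"))
    rp <- partition_regions(
      read_volume(need_key(config, "real_mask", "measure"), as = "mask"),
      read_volume(need_key(config, "real_labels", "measure"), as = "labels"),
      config$dilation_radius %||% 1)
    sp <- partition_regions(
      read_volume(need_key(config, "syn_mask", "measure"), as = "mask"),
      read_volume(need_key(config, "syn_labels", "measure"), as = "labels"),
      config$dilation_radius %||% 1)
    res <- normalized_wasserstein(real, syn, rp, sp)
    utils::write.csv(tibble::as_tibble(res),
      note(file.path(out_dir, "wasserstein.csv")), row.names = FALSE)
    summ <- summarize_wasserstein(res)
    utils::write.csv(summ,
      note(file.path(out_dir, "wasserstein_summary.csv")),
      row.names = FALSE)
    list(n_slices = nrow(res))
  } else if (type == "edgeq") {
    img <- read_volume(need_key(config, "image", "measure"))
    prof <- q95_edge_profile(img,
      section_size = config$section_size %||% c(100, 100),
      sigma = config$sigma %||% 3,
      t_b = config$t_b, t_r = config$t_r %||% 20)
    utils::write.csv(tibble::as_tibble(prof),
      note(file.path(out_dir, "edge_profile.csv")), row.names = FALSE)
    list(s_n = edge_profile_sn(prof))
  } else {
    da <- utils::read.csv(need_key(config, "a", "measure"))
    db_ <- utils::read.csv(need_key(config, "b", "measure"))
    col <- config$column %||% "w_norm"
    test <- paired_wilcoxon_exact(da[[col]], db_[[col]],
      alternative = config$alternative %||% "greater")
    list(statistic = test$statistic, p_value = test$p_value, n = test$n)
  }
}

cmd_eval_det <- function(config, seed, out_dir, note) {
  check_keys(config, c("pred", "centers", "weights"), "eval-det")
  pred <- read_volume(need_key(config, "pred", "eval-det"), as = "labels")
  gt <- read_centers(need_key(config, "centers", "eval-det"))
  res <- det_score(pred, gt, weights = config$weights %||% c(5, 10, 1))
  jsonlite::write_json(
    list(det = res$det, fp = res$fp, fn = res$fn, ns = res$ns),
    note(file.path(out_dir, "det.json")), auto_unbox = TRUE, digits = NA)
  list(det = res$det, fp = res$fp, fn = res$fn, ns = res$ns)
}

cmd_fixtures <- function(config, seed, out_dir, note) {
  check_keys(config, c("what", "shape"), "fixtures")
  what <- match.arg(need_key(config, "what", "fixtures"),
    c("prototype", "spheroid", "degraded-pair"))
  if (what == "prototype") {
    p <- make_ellipsoid_prototype(seed = seed)
    write_volume(volume3d(p$intensity), note(file.path(out_dir,
      "prototype_img.tif")), encoding = "float32")
    write_volume(label_volume(array(as.integer(p$mask), dim(p$mask))),
      note(file.path(out_dir, "prototype_mask.tif")), encoding = "uint8")
    list(shape = dim(p$mask))
  } else if (what == "spheroid") {
    toy <- make_toy_spheroid(shape = config$shape %||% c(32, 96, 96),
      seed = seed)
    write_volume(toy$placement$image, note(file.path(out_dir, "image.tif")),
      encoding = "float32")
    write_volume(toy$placement$labels, note(file.path(out_dir,
      "labels.tif")), encoding = "uint16")
    write_volume(toy$mask, note(file.path(out_dir, "mask.tif")),
      encoding = "uint8")
    list(n_placed = toy$placement$n_placed)
  } else {
    pair <- make_degraded_pair(shape = config$shape %||% c(32, 100, 100),
      seed = seed)
    write_volume(pair$reference, note(file.path(out_dir, "reference.tif")),
      encoding = "float32")
    write_volume(pair$degraded, note(file.path(out_dir, "degraded.tif")),
      encoding = "float32")
    write_volume(pair$mask, note(file.path(out_dir, "mask.tif")),
      encoding = "uint8")
    write_volume(pair$labels, note(file.path(out_dir, "labels.tif")),
      encoding = "uint16")
    list(shape = dim(pair$reference))
  }
}
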