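#' Partition a lattice into outside / inside-background / foreground
#'
#' The three regions of the region-split intensity comparison: voxels
#' outside the culture shape mask (`bg_outside`), mask voxels not claimed by
#' any nucleus (`bg_inside`), and the nucleus foreground. The foreground is
#' the label support dilated by `dilation_radius` (Chebyshev) and
#' intersected with the mask — the dilation captures nucleus borders blurred
#' by the PSF. The regions are disjoint and cover the lattice. The split
#' makes the comparison independent of the foreground/background ratio
#' (e.g. the cell density).
#'
#' @param mask a [shape_mask()].
#' @param labels a [label_volume()] on the same lattice.
#' @param dilation_radius Chebyshev dilation of the label support, voxels.
#' @return A `region_partition`: integer array with codes 0 =
#'   `bg_outside`, 1 = `bg_inside`, 2 = `foreground`.
#' @export
partition_regions <- function(mask, labels, dilation_radius = 1) {
  if (!identical(dim(mask), dim(labels))) {
    stop("mask and labels shapes differ", call. = FALSE)
  }
  fg <- dilate_chebyshev(as_plain_array(labels) != 0L, dilation_radius)
  m <- as_plain_array(mask)
  code <- array(0L, dim(m))
  code[m & !fg] <- 1L
  code[m & fg] <- 2L
  structure(code, class = "region_partition",
    region_levels = c("bg_outside", "bg_inside", "foreground"))
}

region_names <- c("bg_outside", "bg_inside", "foreground")

#' @export
print.region_partition <- function(x, ...) {
  counts <- tabulate(as.vector(x) + 1L, 3L)
  cat(sprintf(
    "<region_partition> bg_outside %d, bg_inside %d, foreground %d voxels\n",
    counts[1], counts[2], counts[3]))
  invisible(x)
}

#' First-order Wasserstein distance between two 1D samples
#'
#' The earth-mover's distance between the empirical distributions of two
#' intensity multisets, computed exactly as the area between the two
#' empirical CDFs (no binning).
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return Nonnegative distance.
#' @export
wasserstein_1d <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("wasserstein_1d: empty sample", call. = FALSE)
  }
  values <- sort(unique(c(sample_a, sample_b)))
  if (length(values) == 1L) return(0)
  fa <- stats::ecdf(sample_a)(values)
  fb <- stats::ecdf(sample_b)(values)
  n <- length(values)
  sum(abs(fa[-n] - fb[-n]) * diff(values))
}

#' Depth grouping of z slices
#'
#' Named half-open intervals of 0-based z depth (px). The reporting default
#' groups slices into upper `[0, 41)`, middle `[41, 82)` and lower
#' `[82, Inf)`.
#'
#' @param ... named `c(lo, hi)` pairs, half-open `[lo, hi)`,
#'   non-overlapping.
#' @return A `depth_grouping` object.
#' @export
depth_grouping <- function(upper = c(0, 41), middle = c(41, 82),
                           lower = c(82, Inf), ...) {
  iv <- c(list(upper = upper, middle = middle, lower = lower), list(...))
  iv <- iv[!vapply(iv, is.null, TRUE)]
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2L || v[1] >= v[2]) {
      stop("invalid interval for ", nm, call. = FALSE)
    }
  }
  ord <- order(vapply(iv, `[`, numeric(1), 1))
  iv <- iv[ord]
  lows <- vapply(iv, `[`, numeric(1), 1)
  highs <- vapply(iv, `[`, numeric(1), 2)
  if (any(lows[-1] < highs[-length(highs)])) {
    stop("depth intervals overlap", call. = FALSE)
  }
  structure(iv, class = "depth_grouping")
}

#' Assign indexed values to depth groups
#'
#' Each value goes to the interval containing its (0-based) index; values in
#' no interval are dropped.
#'
#' @param df data frame with an index column and value column(s).
#' @param grouping a [depth_grouping()].
#' @param index name of the index column.
#' @return The rows falling in some interval, with a `group` factor column.
#' @export
group_by_depth <- function(df, grouping = depth_grouping(), index = "z") {
  stopifnot(index %in% names(df))
  idx <- df[[index]]
  grp <- rep(NA_character_, length(idx))
  for (nm in names(grouping)) {
    v <- grouping[[nm]]
    grp[idx >= v[1] & idx < v[2]] <- nm
  }
  out <- df[!is.na(grp), , drop = FALSE]
  out$group <- factor(grp[!is.na(grp)], levels = names(grouping))
  tibble::as_tibble(out)
}

#' Region-split normalized Wasserstein comparison
#'
#' For every region and z slice, compares the intensity distribution of a
#' synthetic volume against a real one:
#' `W_norm = 1 - W(p_real, p_syn) / W(p_real, p_black)`, where `p_black` is
#' the distribution of a completely black image (a point mass at zero) — the
#' worst possible synthetic result. 1 means the distributions coincide; 0
#' means the synthetic slice is as far from the real one as black is.
#' Negative values are possible (farther than black) and are reported
#' unclamped. Slices whose real-side region is entirely zero (denominator 0)
#' are excluded, as are slices where either side has no region voxels.
#'
#' @param real,syn [volume3d()]s on equal-depth stacks.
#' @param regions_real,regions_syn [partition_regions()] results for each
#'   side (the real side usually comes from an external segmentation).
#' @param grouping a [depth_grouping()] for reporting.
#' @return A `wasserstein_result` tibble: columns `region`, `z` (0-based),
#'   `group`, `w_syn`, `w_black`, `w_norm`, plus attribute `excluded`
#'   (tibble of skipped region/slices and why).
#' @export
normalized_wasserstein <- function(real, syn, regions_real, regions_syn,
                                   grouping = depth_grouping()) {
  if (dim(real)[1] != dim(syn)[1]) {
    stop("real and syn must have the same number of z slices", call. = FALSE)
  }
  stopifnot(identical(dim(real), dim(regions_real)),
    identical(dim(syn), dim(regions_syn)))
  nz <- dim(real)[1]
  rows <- list()
  skipped <- list()
  for (ri in 0:2) {
    for (z in seq_len(nz)) {
      pr <- real[z, , ][regions_real[z, , ] == ri]
      ps <- syn[z, , ][regions_syn[z, , ] == ri]
      reason <- NULL
      if (length(pr) == 0L || length(ps) == 0L) {
        reason <- "empty_region"
      } else {
        w_black <- wasserstein_1d(pr, 0)
        if (w_black == 0) {
          reason <- "black_real_slice"
        }
      }
      if (!is.null(reason)) {
        skipped[[length(skipped) + 1L]] <- tibble::tibble(
          region = region_names[ri + 1L], z = z - 1L, reason = reason)
        next
      }
      w_syn <- wasserstein_1d(pr, ps)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        region = region_names[ri + 1L], z = z - 1L,
        w_syn = w_syn, w_black = w_black,
        w_norm = 1 - w_syn / w_black)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L) {
    out <- group_by_depth(out, grouping, index = "z")
    out$region <- factor(out$region, levels = region_names)
    out <- out[, c("region", "z", "group", "w_syn", "w_black", "w_norm")]
  }
  structure(out,
    class = c("wasserstein_result", class(out)),
    excluded = dplyr::bind_rows(skipped))
}

#' Summarize a Wasserstein comparison by region and depth group
#'
#' @param x a [normalized_wasserstein()] result.
#' @param ... unused.
#' @return Tibble with per region x group median, IQR and slice count.
#' @export
summarize_wasserstein <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$region, .data$group),
    median_w_norm = stats::median(.data$w_norm),
    iqr_w_norm = stats::IQR(.data$w_norm),
    n_slices = dplyr::n(),
    .groups = "drop"
  )
}

#' Boxplot of normalized Wasserstein scores by region and depth group
#'
#' @param object a [normalized_wasserstein()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot wasserstein_result
#' @export
autoplot.wasserstein_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df,
    ggplot2::aes(x = .data$group, y = .data$w_norm)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::facet_wrap(~region) +
    ggplot2::coord_cartesian(ylim = c(min(0, min(df$w_norm)), 1)) +
    ggplot2::labs(
      x = "image depth group", y = expression(W[norm]),
      title = "Region-split normalized Wasserstein distance"
    ) +
    ggplot2::theme_minimal()
}
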