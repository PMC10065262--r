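#' q95 edge-quality depth profile
#'
#' Quantifies how sharpness decays with imaging depth. Every z slice is
#' smoothed with a 2D Gaussian (`sigma`, default 3 px, large enough that the
#' edge response reflects foreground/background contrast rather than noise)
#' and filtered with the Sobel operator (in-plane gradient magnitude). The
#' `(y, x)` plane is tiled into non-overlapping `section_size` sections
#' (default 100 x 100 px, anchored at the origin; border remainders are
#' dropped). For each section `j` and slice `i` the 95% quantile
#' `e[j, i]` of the edge image is taken.
#'
#' Because the culture is roundish, the foreground starts at a different
#' depth in every section, so sections are aligned before averaging: each
#' section is re-indexed by `d = i - argmax_i e[j, i]`, the offset from its
#' own peak-response slice. Sections whose maximum response is below `t_b`
#' only show background and are discarded; sections whose peak lies deeper
#' than slice `t_r` (0-based) are discarded as unreliable alignments. The
#' profile value at each aligned depth `d` is the mean over the retained
#' sections that possess that `d`; `s_n` is the retained-section count.
#'
#' @param image a [volume3d()].
#' @param section_size `(y, x)` section extent in px.
#' @param sigma Gaussian smoothing sigma (px) before Sobel.
#' @param t_b background threshold on the per-section maximum edge response;
#'   `NULL` defaults to 1% of the largest response a full-range intensity
#'   step could produce (`0.01 * 4 * max(image)`).
#' @param t_r maximum allowed 0-based peak slice index.
#' @param probs quantile level of the edge response per section/slice.
#' @return An `edge_profile`: tibble with columns `d` (aligned depth),
#'   `e095` (mean response) and `n_sections` (sections contributing at that
#'   `d`), with attributes `s_n`, `config` and `sections` (per-section peak
#'   bookkeeping).
#' @export
q95_edge_profile <- function(image, section_size = c(100, 100), sigma = 3,
                             t_b = NULL, t_r = 20, probs = 0.95) {
  d <- dim(image)
  section_size <- as.integer(rep_len(section_size, 2L))
  if (any(d[2:3] < section_size)) {
    stop("image (y, x) extents are smaller than the section size",
      call. = FALSE)
  }
  if (is.null(t_b)) t_b <- max(0.01 * 4 * max(image), .Machine$double.eps)
  a <- as_plain_array(image)
  smoothed <- gaussian_smooth(a, c(0, sigma, sigma))
  edges <- sobel_magnitude_slices(smoothed)

  ny_s <- d[2] %/% section_size[1]
  nx_s <- d[3] %/% section_size[2]
  nz <- d[1]
  sections <- list()
  for (sy in seq_len(ny_s)) {
    for (sx in seq_len(nx_s)) {
      iy <- ((sy - 1L) * section_size[1] + 1L):(sy * section_size[1])
      ix <- ((sx - 1L) * section_size[2] + 1L):(sx * section_size[2])
      block <- edges[, iy, ix, drop = FALSE]
      e <- vapply(seq_len(nz), function(z) {
        stats::quantile(block[z, , ], probs = probs, names = FALSE)
      }, numeric(1))
      peak <- which.max(e)
      sections[[length(sections) + 1L]] <- tibble::tibble(
        section = length(sections) + 1L,
        sy = sy, sx = sx,
        peak_index = peak - 1L,        # 0-based
        max_e = max(e),
        retained = max(e) >= t_b & (peak - 1L) <= t_r,
        e = list(e)
      )
    }
  }
  sec <- dplyr::bind_rows(sections)
  kept <- sec[sec$retained, , drop = FALSE]
  s_n <- nrow(kept)
  if (s_n == 0L) {
    profile <- tibble::tibble(d = integer(0), e095 = numeric(0),
      n_sections = integer(0))
  } else {
    per <- dplyr::bind_rows(lapply(seq_len(s_n), function(r) {
      e <- kept$e[[r]]
      tibble::tibble(d = seq_along(e) - 1L - kept$peak_index[r], e095 = e)
    }))
    profile <- dplyr::summarise(
      dplyr::group_by(per, .data$d),
      e095 = mean(.data$e095),
      n_sections = dplyr::n(),
      .groups = "drop"
    )
    profile <- dplyr::arrange(profile, .data$d)
  }
  structure(profile,
    class = c("edge_profile", class(profile)),
    s_n = s_n,
    config = list(section_size = section_size, sigma = sigma, t_b = t_b,
      t_r = t_r, probs = probs),
    sections = sec[, c("section", "sy", "sx", "peak_index", "max_e",
      "retained")]
  )
}

#' Retained-section count of an edge profile
#'
#' @param profile an [q95_edge_profile()] result.
#' @return Integer `s_n`.
#' @export
edge_profile_sn <- function(profile) attr(profile, "s_n")

#' Line plot of the aligned q95 edge-quality profile
#'
#' @param object an [q95_edge_profile()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot edge_profile
#' @export
autoplot.edge_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$e095)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_sections), alpha = 0.5) +
    ggplot2::scale_size_continuous(name = "sections") +
    ggplot2::labs(
      x = "aligned depth d (slices from section peak)",
      y = expression(e[0.95 * "," ~ d]),
      title = sprintf("q95 edge-quality profile (s_n = %d)",
        attr(object, "s_n"))
    ) +
    ggplot2::theme_minimal()
}
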