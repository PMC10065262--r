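#' Match ground-truth centers to predicted labels
#'
#' Each annotated center is mapped to the predicted label value at its
#' voxel (coordinates rounded half-up, 0-based); a background voxel (0)
#' leaves the center unmatched.
#'
#' @param pred predicted [label_volume()].
#' @param gt center table (`id, z, y, x`, 0-based voxel coordinates), as
#'   from [read_centers()].
#' @return Tibble with columns `id`, `z`, `y`, `x`, `label` (0 =
#'   unmatched).
#' @export
match_centers <- function(pred, gt) {
  validate_centers(gt, pred)
  iz <- floor(gt$z + 0.5) + 1L
  iy <- floor(gt$y + 0.5) + 1L
  ix <- floor(gt$x + 0.5) + 1L
  lab <- as_plain_array(pred)[cbind(iz, iy, ix)]
  tibble::tibble(id = gt$id, z = gt$z, y = gt$y, x = gt$x,
    label = as.integer(lab))
}

#' Detection accuracy (DET / AOGM) from center-point ground truth
#'
#' Scores a predicted label volume against annotated nucleus centers with
#' the cell-tracking-challenge style detection measure. From the center
#' assignment of [match_centers()]:
#' * `fn` — centers on background (missed nuclei),
#' * `ns` — required splitting operations, `sum(max(0, centers_in_label - 1))`
#'   for labels claiming several centers (merged nuclei),
#' * `fp` — predicted labels claiming no center (spurious detections; false
#'   splits are folded into this count, the measure does not separate them).
#'
#' The weighted error `AOGM_D = w_ns * ns + w_fn * fn + w_fp * fp` is
#' compared against the cost of building the detection from scratch,
#' `AOGM_D0 = w_fn * n_centers`, giving
#' `det = 1 - min(AOGM_D, AOGM_D0) / AOGM_D0` in `[0, 1]` (1 = perfect).
#'
#' @param pred predicted [label_volume()].
#' @param gt center table (`id, z, y, x`, 0-based), nonempty.
#' @param weights `(w_ns, w_fn, w_fp)`; default `c(5, 10, 1)`, the
#'   published AOGM-D convention.
#' @return A `det_result`: list with `det`, `fp`, `fn`, `ns`, `n_centers`,
#'   `aogm_d`, `aogm_d0`, `weights` and the `assignment` tibble.
#' @export
det_score <- function(pred, gt, weights = c(5, 10, 1)) {
  if (nrow(gt) == 0L) {
    stop("det_score: empty ground truth (AOGM_D0 = 0, measure undefined)",
      call. = FALSE)
  }
  stopifnot(length(weights) == 3L, all(weights >= 0))
  asg <- match_centers(pred, gt)
  fn <- sum(asg$label == 0L)
  matched <- asg$label[asg$label != 0L]
  per_label <- table(matched)
  ns <- sum(pmax(0L, as.integer(per_label) - 1L))
  all_ids <- label_ids(pred)
  fp <- sum(!(all_ids %in% as.integer(names(per_label))))
  aogm_d <- weights[1] * ns + weights[2] * fn + weights[3] * fp
  aogm_d0 <- weights[2] * nrow(gt)
  det <- 1 - min(aogm_d, aogm_d0) / aogm_d0
  structure(list(
    det = det, fp = as.integer(fp), fn = as.integer(fn),
    ns = as.integer(ns), n_centers = nrow(gt),
    aogm_d = aogm_d, aogm_d0 = aogm_d0,
    weights = c(w_ns = weights[1], w_fn = weights[2], w_fp = weights[3]),
    assignment = asg
  ), class = "det_result")
}

#' @export
print.det_result <- function(x, ...) {
  cat(sprintf(
    "<det_result> DET = %.3f  (FP %d, FN %d, missed splits %d; %d centers)\n",
    x$det, x$fp, x$fn, x$ns, x$n_centers))
  invisible(x)
}

#' Tidy a detection result
#'
#' @param x a [det_score()] result.
#' @param ... unused.
#' @return One-row tibble with `det`, `fp`, `fn`, `ns`, `n_centers`.
#' @method tidy det_result
#' @export
tidy.det_result <- function(x, ...) {
  tibble::tibble(det = x$det, fp = x$fp, fn = x$fn, ns = x$ns,
    n_centers = x$n_centers)
}
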