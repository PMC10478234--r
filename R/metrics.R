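#' Voxelwise confusion counts between two binary masks
#'
#' @param pred,gt [label_mask]s or binary arrays of identical shape.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`, `fn`
#'   (true negatives are not used by any vessel metric).
#' @export
confusion <- function(pred, gt) {
  p <- vox(pred); g <- vox(gt)
  if (!identical(dim(p), dim(g)))
    cx_stop("shape_mismatch", "pred and gt must have identical shapes")
  p <- p != 0; g <- g != 0
  structure(list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g)),
            class = "confusion_counts")
}

#' Dice similarity coefficient from confusion counts
#'
#' `2TP / (2TP + FN + FP)`. Undefined (typed error
#' `corovox_error_undefined_metric`) when both masks are empty.
#'
#' @param c A [confusion()] result.
#' @return Value in `[0, 1]`.
#' @export
dsc <- function(c) {
  den <- 2 * c$tp + c$fn + c$fp
  if (den == 0) cx_stop("undefined_metric", "DSC undefined: both masks empty")
  2 * c$tp / den
}

#' Recall (sensitivity) from confusion counts
#'
#' `TP / (TP + FN)`; undefined on empty ground truth.
#'
#' @inheritParams dsc
#' @return Value in `[0, 1]`.
#' @export
recall <- function(c) {
  den <- c$tp + c$fn
  if (den == 0) cx_stop("undefined_metric", "recall undefined: empty ground truth")
  c$tp / den
}

#' Precision from confusion counts
#'
#' `TP / (TP + FP)`; undefined on empty prediction.
#'
#' @inheritParams dsc
#' @return Value in `[0, 1]`.
#' @export
precision <- function(c) {
  den <- c$tp + c$fp
  if (den == 0) cx_stop("undefined_metric", "precision undefined: empty prediction")
  c$tp / den
}

#' Extract the boundary (surface) voxels of a mask
#'
#' A foreground voxel is a surface voxel when at least one of its six
#' face-neighbours is background or lies outside the volume.
#'
#' @param mask A [label_mask] or binary 3-D array.
#' @return A `surface_set`: integer matrix (n x 3) of 0-based voxel
#'   coordinates `(slice, row, col)`; zero rows for an empty mask.
#' @export
extract_surface <- function(mask) {
  m <- vox(mask)
  d <- dim(m)
  m <- m != 0
  interior <- array(TRUE, d)
  shift_ok <- function(ax, by) {
    # TRUE where the neighbour at offset `by` along axis `ax` is foreground
    out <- array(FALSE, d)
    n <- d[ax]
    src <- if (by > 0) 1:(n - 1) else 2:n
    dst <- if (by > 0) 2:n else 1:(n - 1)
    if (n == 1L) return(out)
    if (ax == 1L) { out[dst, , ] <- m[src, , ] }
    else if (ax == 2L) { out[, dst, ] <- m[, src, ] }
    else { out[, , dst] <- m[, , src] }
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift_ok(ax, by)
  surf <- which(m & !interior, arr.ind = TRUE) - 1L
  colnames(surf) <- c("slice", "row", "col")
  structure(surf, class = c("surface_set", class(surf)))
}

surface_coords <- function(s, spacing = NULL) {
  m <- unclass(s)
  m <- matrix(as.numeric(m), nrow = nrow(m), ncol = 3)
  if (!is.null(spacing)) m <- sweep(m, 2, as.numeric(spacing), "*")
  m
}

check_surfaces <- function(sp, sg) {
  if (nrow(sp) == 0 || nrow(sg) == 0)
    cx_stop("undefined_metric", "surface distance undefined for an empty surface")
}

#' Average symmetric surface distance
#'
#' The sum, over both surfaces, of each voxel's Euclidean distance to the
#' nearest voxel of the other surface, divided by the total number of
#' surface voxels. Units are voxels, or mm when `spacing` is given.
#'
#' @param sp,sg [extract_surface()] results (both non-empty).
#' @param spacing Optional mm triple; coordinates are scaled per-axis before
#'   distances are computed.
#' @return Non-negative real.
#' @export
assd <- function(sp, sg, spacing = NULL) {
  a <- surface_coords(sp, spacing); b <- surface_coords(sg, spacing)
  check_surfaces(a, b)
  dab <- cv_nn_dists(a, b)
  dba <- cv_nn_dists(b, a)
  (sum(dab) + sum(dba)) / (nrow(a) + nrow(b))
}

#' Symmetric Hausdorff distance between two surfaces
#'
#' The larger of the two directed maximum nearest-neighbour distances.
#'
#' @inheritParams assd
#' @return Non-negative real.
#' @export
hausdorff <- function(sp, sg, spacing = NULL) {
  a <- surface_coords(sp, spacing); b <- surface_coords(sg, spacing)
  check_surfaces(a, b)
  max(max(cv_nn_dists(a, b)), max(cv_nn_dists(b, a)))
}

#' All five segmentation metrics for one case
#'
#' DSC, recall, precision, ASSD and Hausdorff distance between a predicted
#' and a reference mask. Metrics that are undefined for the pair (empty mask
#' or surface) are reported as `NA` rather than raising.
#'
#' @param pred,gt [label_mask]s or binary arrays of identical shape.
#' @param spacing Optional mm triple for the surface distances; when `NULL`
#'   distances are in voxel units.
#' @return A `metrics_report`: list with `dsc`, `recall`, `precision`,
#'   `assd`, `hd` and `units` ("voxel" or "mm").
#' @export
evaluate_case <- function(pred, gt, spacing = NULL) {
  cc <- confusion(pred, gt)
  safe <- function(expr) tryCatch(expr, corovox_error_undefined_metric = function(e) NA_real_)
  sp <- extract_surface(pred)
  sg <- extract_surface(gt)
  structure(list(
    dsc = safe(dsc(cc)),
    recall = safe(recall(cc)),
    precision = safe(precision(cc)),
    assd = safe(assd(sp, sg, spacing)),
    hd = safe(hausdorff(sp, sg, spacing)),
    units = if (is.null(spacing)) "voxel" else "mm"
  ), class = "metrics_report")
}
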