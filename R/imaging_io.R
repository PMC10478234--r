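#' CT volume container
#'
#' A 3-D scalar grid of Hounsfield-unit values indexed `(slice, row, col)`,
#' together with the voxel spacing in mm (slice interval, row, col) and the
#' original NIfTI header, which is passed through unchanged on write.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing Positive numeric triple, mm.
#' @param header Optional NIfTI header (as returned by
#'   [RNifti::niftiHeader()]); carried opaquely.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(0.45, 0.35, 0.35), header = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    cx_stop("not_3d", "voxels must be a 3-D array")
  if (any(dim(voxels) < 1L)) cx_stop("bad_shape", "all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    cx_stop("bad_spacing", "spacing must be three positive reals (mm)")
  structure(list(voxels = voxels, spacing = spacing, header = header),
            class = "ct_volume")
}

#' Binary label mask container
#'
#' A `{0, 1}` grid on the same lattice as its CT volume; 1 marks vessel
#' (coronary-artery) voxels.
#'
#' @inheritParams ct_volume
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(voxels, spacing = c(0.45, 0.35, 0.35), header = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    cx_stop("not_3d", "voxels must be a 3-D array")
  if (!all(voxels %in% c(0, 1)))
    cx_stop("bad_labels", "mask values must be 0 or 1")
  storage.mode(voxels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    cx_stop("bad_spacing", "spacing must be three positive reals (mm)")
  structure(list(voxels = voxels, spacing = spacing, header = header),
            class = "label_mask")
}

# Shared accessor: raw array of any volume-like object.
vox <- function(x) {
  if (is.list(x) && !is.null(x$voxels)) x$voxels else x
}

#' Read a 3-D NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file containing a 3-D image.
#' @return A [ct_volume] with voxels in the stored (HU) units and spacing
#'   taken from the header.
#' @details Raises a `corovox_error_missing_file` condition if the file does
#'   not exist, `corovox_error_not_3d` for images of other dimensionality,
#'   and `corovox_error_bad_header` for unreadable files.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) cx_stop("missing_file", paste0("no such file: ", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) cx_stop("bad_header",
                    paste0("unreadable NIfTI file: ", conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 3L)
    cx_stop("not_3d", sprintf("expected a 3-D image, got %d dimensions", length(d)))
  hdr <- RNifti::niftiHeader(img)
  sp <- RNifti::pixdim(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = d)
  ct_volume(arr, spacing = sp, header = hdr)
}

#' Read a binary NIfTI mask
#'
#' @inheritParams read_volume
#' @return A [label_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  arr <- v$voxels
  if (!all(arr %in% c(0, 1)))
    cx_stop("bad_labels", "mask file contains values other than 0/1")
  label_mask(arr, spacing = v$spacing, header = v$header)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are stored as unsigned 8-bit, everything else as float64 so a
#' read-back is voxel-identical.
#'
#' @param vol A [ct_volume], [label_mask], [normalized_volume] or plain 3-D
#'   array.
#' @param path Destination path (`.nii` or `.nii.gz`); the parent directory
#'   must exist and be writable.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    cx_stop("unwritable", paste0("cannot write to directory: ", dir))
  arr <- vox(vol)
  spacing <- if (is.list(vol) && !is.null(vol$spacing)) vol$spacing else c(1, 1, 1)
  header <- if (is.list(vol)) vol$header else NULL
  dt <- if (inherits(vol, "label_mask")) "uint8" else "double"
  storage.mode(arr) <- "double"
  img <- if (is.null(header)) RNifti::asNifti(arr) else RNifti::asNifti(arr, reference = header)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Normalized volume container
#'
#' Voxels rescaled to `[0, 1]` by [window_and_normalize()], carrying the HU
#' window used to produce them.
#'
#' @param voxels 3-D numeric array with values in `[0, 1]`.
#' @param window Numeric `(lo, hi)` HU pair.
#' @inheritParams ct_volume
#' @return An object of class `normalized_volume`.
#' @export
normalized_volume <- function(voxels, window, spacing = c(0.45, 0.35, 0.35),
                              header = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    cx_stop("not_3d", "voxels must be a 3-D array")
  if (any(voxels < 0 | voxels > 1))
    cx_stop("bad_range", "normalized voxels must lie in [0, 1]")
  structure(list(voxels = voxels, window = as.numeric(window),
                 spacing = as.numeric(spacing), header = header),
            class = "normalized_volume")
}

#' Window HU values and rescale to \eqn{[0,1]}
#'
#' Clamps every voxel to the HU window `[lo, hi]` and maps the window
#' linearly onto `[0, 1]`: `(clamp(v, lo, hi) - lo) / (hi - lo)`. The default
#' window `[-260, 760]` HU is a conservative contrast-enhanced-vessel window;
#' it suppresses lung/air and most soft tissue while keeping the full
#' contrast-filled lumen range.
#'
#' @param vol A [ct_volume] or plain 3-D array of HU values.
#' @param lo,hi Window bounds in HU; `lo < hi`.
#' @return A [normalized_volume] of the same shape.
#' @export
window_and_normalize <- function(vol, lo = -260, hi = 760) {
  if (!(lo < hi)) cx_stop("window", "window lower bound must be below upper bound")
  arr <- vox(vol)
  out <- (pmin(pmax(arr, lo), hi) - lo) / (hi - lo)
  dim(out) <- dim(arr)
  normalized_volume(out, window = c(lo, hi),
                    spacing = if (is.list(vol)) vol$spacing else c(0.45, 0.35, 0.35),
                    header = if (is.list(vol)) vol$header else NULL)
}

#' Plan fixed-depth blocks over a long volume
#'
#' The network consumes blocks of `block_depth` slices. Block starts are laid
#' out every `stride` slices from 0, and the final start is clamped to
#' `depth - block_depth` so the last block ends exactly at the volume end.
#' Volumes shallower than `block_depth` get a single block and are
#' replicate-padded at the end to `block_depth`.
#'
#' @param depth Number of slices in the volume (>= 1).
#' @param block_depth Block depth in slices (default 16, the network's input
#'   thickness).
#' @param stride Start-to-start spacing, `1 <= stride <= block_depth`
#'   (default 8: half-overlapping blocks whose predictions are averaged).
#' @return A `block_plan`: list with `starts` (0-based slice indices),
#'   `block_depth`, `stride`, `depth` and `padded_depth`.
#' @export
plan_blocks <- function(depth, block_depth = 16L, stride = 8L) {
  depth <- as.integer(depth); block_depth <- as.integer(block_depth)
  stride <- as.integer(stride)
  if (depth < 1L) cx_stop("bad_shape", "depth must be >= 1")
  if (block_depth < 1L || stride < 1L)
    cx_stop("bad_plan", "block_depth and stride must be positive")
  if (stride > block_depth)
    cx_stop("bad_plan", "stride must not exceed block_depth")
  padded <- max(depth, block_depth)
  last <- padded - block_depth
  starts <- seq.int(0L, last, by = stride)
  if (starts[length(starts)] != last) starts <- c(starts, last)
  structure(list(starts = as.integer(starts), block_depth = block_depth,
                 stride = stride, depth = depth, padded_depth = padded),
            class = "block_plan")
}

# Extract the planned blocks from a (D, H, W) array, replicate-padding the
# tail slices when the volume is shallower than the block depth.
extract_blocks <- function(arr, plan) {
  d <- dim(arr)
  if (plan$padded_depth > d[1])
    arr <- arr[c(seq_len(d[1]), rep(d[1], plan$padded_depth - d[1])), , , drop = FALSE]
  lapply(plan$starts, function(s) arr[(s + 1):(s + plan$block_depth), , , drop = FALSE])
}

#' Stitch per-block class probabilities back to full volume
#'
#' Overlapping slices receive the arithmetic mean of all contributing blocks;
#' replicate-padded slices are discarded.
#'
#' @param plan A [plan_blocks()] result.
#' @param block_outputs List with one `(C, block_depth, H, W)` array per
#'   planned block.
#' @return A `(C, depth, H, W)` array of averaged probabilities.
#' @export
stitch_blocks <- function(plan, block_outputs) {
  if (length(block_outputs) != length(plan$starts))
    cx_stop("bad_blocks", "one output per planned block is required")
  d0 <- dim(block_outputs[[1]])
  if (length(d0) != 4L || d0[2] != plan$block_depth)
    cx_stop("bad_blocks", "block outputs must be (C, block_depth, H, W)")
  for (b in block_outputs)
    if (!identical(dim(b), d0)) cx_stop("bad_blocks", "block output shapes differ")
  acc <- array(0, c(d0[1], plan$padded_depth, d0[3], d0[4]))
  cnt <- numeric(plan$padded_depth)
  for (i in seq_along(block_outputs)) {
    sl <- (plan$starts[i] + 1):(plan$starts[i] + plan$block_depth)
    acc[, sl, , ] <- acc[, sl, , , drop = FALSE] + block_outputs[[i]]
    cnt[sl] <- cnt[sl] + 1
  }
  for (s in seq_len(plan$padded_depth)) acc[, s, , ] <- acc[, s, , , drop = FALSE] / cnt[s]
  acc[, seq_len(plan$depth), , , drop = FALSE]
}
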