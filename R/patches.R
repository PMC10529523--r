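#' Construct a texture patch
#'
#' @param pixels Square grayscale matrix in \[0, 1\].
#' @param origin_px Top-left `c(row, col)` in the source image.
#' @param inside_fraction Fraction of patch pixels inside the nodule mask.
#' @return A list of class `texture_patch`.
#' @export
texture_patch <- function(pixels, origin_px = c(1L, 1L), inside_fraction = 1) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels)) {
    stop("`pixels` must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1) {
    stop("patch pixels must be finite values in [0, 1]", call. = FALSE)
  }
  check_scalar(inside_fraction, "inside_fraction", 0, 1)
  structure(list(pixels = pixels,
                 origin_px = as.integer(origin_px),
                 inside_fraction = inside_fraction),
            class = "texture_patch")
}

#' Extract texture patches over a nodule mask
#'
#' Tiles the mask's bounding box with `patch_size_px`-sided patches on a
#' stride grid (row-major order), keeping only patches whose fraction of
#' in-mask pixels reaches `min_inside_fraction`. Patches are clamped to the
#' image frame.
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param mask Binary matrix of the same shape.
#' @param patch_size_px Patch side, pixels.
#' @param stride_px Grid stride, pixels.
#' @param min_inside_fraction Minimum in-mask pixel fraction per patch.
#' @return List of [texture_patch()] objects (possibly empty, with a
#'   warning when the mask cannot host a qualifying patch).
#' @export
extract_patches <- function(image, mask, patch_size_px = 20L, stride_px = 10L,
                            min_inside_fraction = 0.8) {
  if (!identical(dim(image), dim(mask))) {
    stop("`image` and `mask` must share one shape", call. = FALSE)
  }
  check_binary_mask(mask)
  check_scalar(stride_px, "stride_px", lower = 1)
  check_scalar(min_inside_fraction, "min_inside_fraction", 0, 1)
  p <- as.integer(patch_size_px)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("mask is empty: no patches extracted")
    return(list())
  }
  r0 <- max(min(idx[, 1]), 1L); r1 <- min(max(idx[, 1]), nrow(image))
  c0 <- max(min(idx[, 2]), 1L); c1 <- min(max(idx[, 2]), ncol(image))
  row_starts <- seq.int(r0, max(r0, r1 - p + 1L), by = stride_px)
  col_starts <- seq.int(c0, max(c0, c1 - p + 1L), by = stride_px)
  row_starts <- row_starts[row_starts + p - 1L <= nrow(image)]
  col_starts <- col_starts[col_starts + p - 1L <= ncol(image)]

  out <- list()
  for (r in row_starts) {
    for (cc in col_starts) {
      sub_mask <- mask[r:(r + p - 1L), cc:(cc + p - 1L)]
      inside <- mean(sub_mask != 0)
      if (inside >= min_inside_fraction) {
        out[[length(out) + 1L]] <- texture_patch(
          image[r:(r + p - 1L), cc:(cc + p - 1L)],
          origin_px = c(r, cc),
          inside_fraction = inside)
      }
    }
  }
  if (length(out) == 0) warning("mask too small to host a qualifying patch")
  out
}

#' Truth label of a patch from the phantom label mask
#'
#' A patch is labelled `"cystic"` when more than half of its in-nodule
#' pixels carry the cystic truth label, otherwise `"solid"`.
#'
#' @param patch A [texture_patch()].
#' @param label_mask Phantom label matrix (0 background, 1 solid, 2 cystic).
#' @return `"solid"` or `"cystic"`.
#' @export
patch_truth_label <- function(patch, label_mask) {
  stopifnot(inherits(patch, "texture_patch"))
  p <- nrow(patch$pixels)
  r <- patch$origin_px[1]; cc <- patch$origin_px[2]
  sub <- label_mask[r:(r + p - 1L), cc:(cc + p - 1L)]
  in_nodule <- sub > 0
  if (!any(in_nodule)) return("solid")
  if (mean(sub[in_nodule] == 2L) > 0.5) "cystic" else "solid"
}
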