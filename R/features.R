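# Feature assembly: four scans x three bands x (order-2 AR coefficients +
# log residual variance) = 36 features per patch.

LOG_VARIANCE_FLOOR_EPS <- 1e-12

#' Autoregressive texture features of one patch
#'
#' Runs the full hand-crafted feature core on a patch: four directional
#' scan signals, three frequency bands per signal, and an order-`ar_order`
#' Burg fit per band. Each (signal, band) contributes its AR coefficients
#' plus `log(residual_variance + 1e-12)`, in signal-major band-minor order,
#' giving `4 * 3 * (ar_order + 1)` values -- 36 at the default order 2.
#' The computation involves no randomness.
#'
#' @param patch A [texture_patch()].
#' @param ar_order AR model order (default 2).
#' @param band_edges Band edges in cycles/sample, see [decompose_bands()].
#' @return Named numeric vector of length `4 * 3 * (ar_order + 1)`.
#' @export
#' @examples
#' p <- texture_patch(matrix(runif(400), 20, 20))
#' length(patch_features(p))  # 36
patch_features <- function(patch, ar_order = 2L, band_edges = c(0.05, 0.20)) {
  stopifnot(inherits(patch, "texture_patch"))
  bands <- decompose_bands(patch_to_signals(patch), band_edges)$bands
  out <- numeric(0)
  nms <- character(0)
  for (sig in names(bands)) {
    for (bd in names(bands[[sig]])) {
      fit <- ar_fit(bands[[sig]][[bd]], order = ar_order)
      out <- c(out, fit$coefficients,
               log(fit$residual_variance + LOG_VARIANCE_FLOOR_EPS))
      nms <- c(nms,
               paste(sig, bd, paste0("ar", seq_len(ar_order)), sep = "_"),
               paste(sig, bd, "logvar", sep = "_"))
    }
  }
  stats::setNames(out, nms)
}

#' Feature matrix for a list of patches
#'
#' @param patches List of [texture_patch()] objects.
#' @inheritParams patch_features
#' @return Numeric matrix, one row per patch.
#' @export
patch_feature_matrix <- function(patches, ar_order = 2L,
                                 band_edges = c(0.05, 0.20)) {
  stopifnot(length(patches) >= 1)
  t(vapply(patches, patch_features,
           numeric(4L * 3L * (as.integer(ar_order) + 1L)),
           ar_order = ar_order, band_edges = band_edges))
}

#' Labelled feature table for a synthetic nodule
#'
#' Extracts patches over the nodule mask, computes their feature vectors
#' and attaches the truth label from the phantom label mask -- the training
#' table for the patch classifier.
#'
#' @param nodule A `synthetic_nodule`.
#' @param config A [run_config()].
#' @return A data.frame with `nodule_id`, `origin_y`, `origin_x`,
#'   `inside_fraction`, `label`, and feature columns `f01..f36`.
#' @export
nodule_feature_table <- function(nodule, config = run_config()) {
  stopifnot(inherits(nodule, "synthetic_nodule"))
  patches <- extract_patches(nodule$image, nodule$nodule_mask,
                             patch_size_px = config$patch_size_px,
                             stride_px = config$stride_px,
                             min_inside_fraction = config$min_inside_fraction)
  if (length(patches) == 0) return(NULL)
  feats <- patch_feature_matrix(patches, ar_order = config$ar_order,
                                band_edges = config$band_edges)
  colnames(feats) <- sprintf("f%02d", seq_len(ncol(feats)))
  data.frame(
    nodule_id = nodule$nodule_id %||% NA_integer_,
    origin_y = vapply(patches, function(p) p$origin_px[1], integer(1)),
    origin_x = vapply(patches, function(p) p$origin_px[2], integer(1)),
    inside_fraction = vapply(patches, function(p) p$inside_fraction, numeric(1)),
    label = vapply(patches, patch_truth_label, character(1), nodule$label_mask),
    feats
  )
}
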