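#' Pipeline configuration
#'
#' Bundles every tunable constant of the region-estimation pipeline with its
#' default. Defaults mirror the published analysis where it states them
#' (patch footprint 20 x 20 px at 0.2648 mm/px, i.e. 5.296 x 5.296 mm;
#' 36 features per patch) and the package's documented choices elsewhere.
#'
#' @param patch_size_px Side of a square texture patch, pixels.
#' @param stride_px Patch grid stride, pixels (10 gives 50% overlap).
#' @param min_inside_fraction Minimum fraction of patch pixels that must lie
#'   inside the nodule mask for the patch to be used.
#' @param ar_order Autoregressive model order per band signal.
#' @param band_edges Two ascending band edges in cycles/sample splitting
#'   \eqn{[0, 0.5]} into low/mid/high bands.
#' @param rf_trees Number of trees in the random-forest patch classifier.
#' @param composition_breakpoints Cystic-percentage breakpoints of the
#'   nodule composition categories.
#' @param pixel_spacing_mm Physical pixel spacing, mm per pixel.
#' @param seed Base RNG seed for stochastic stages.
#'
#' @return A list of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$patch_size_px * cfg$pixel_spacing_mm  # patch footprint in mm
run_config <- function(patch_size_px = 20L,
                       stride_px = 10L,
                       min_inside_fraction = 0.8,
                       ar_order = 2L,
                       band_edges = c(0.05, 0.20),
                       rf_trees = 200L,
                       composition_breakpoints = c(10, 50, 90),
                       pixel_spacing_mm = 0.2648,
                       seed = 1L) {
  check_scalar(patch_size_px, "patch_size_px", lower = 2)
  check_scalar(stride_px, "stride_px", lower = 1)
  check_scalar(min_inside_fraction, "min_inside_fraction", 0, 1)
  check_scalar(ar_order, "ar_order", lower = 1)
  check_scalar(rf_trees, "rf_trees", lower = 1)
  check_scalar(pixel_spacing_mm, "pixel_spacing_mm", lower = 0, allow_lower = FALSE)
  if (length(band_edges) != 2L || any(!is.finite(band_edges)) ||
      band_edges[1] <= 0 || band_edges[2] <= band_edges[1] || band_edges[2] >= 0.5) {
    stop("`band_edges` must be two ascending values strictly inside (0, 0.5)",
         call. = FALSE)
  }
  if (any(diff(composition_breakpoints) <= 0) ||
      any(composition_breakpoints <= 0) || any(composition_breakpoints >= 100)) {
    stop("`composition_breakpoints` must be strictly increasing inside (0, 100)",
         call. = FALSE)
  }
  structure(list(
    patch_size_px = as.integer(patch_size_px),
    stride_px = as.integer(stride_px),
    min_inside_fraction = min_inside_fraction,
    ar_order = as.integer(ar_order),
    band_edges = band_edges,
    rf_trees = as.integer(rf_trees),
    composition_breakpoints = composition_breakpoints,
    pixel_spacing_mm = pixel_spacing_mm,
    seed = as.integer(seed)
  ), class = "run_config")
}

# Feature layout identifier embedded in trained models so that a model is
# never applied to features with a different ordering convention.
FEATURE_LAYOUT_VERSION <- "scan4-band3-ar2/1"

#' Write a resolved configuration as a plain key=value sidecar
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(k) {
    paste0(k, "=", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
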