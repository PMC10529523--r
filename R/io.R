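# File-format plumbing: PNG masks (8-bit 0/255), 16-bit TIFF images,
# truth/estimate CSVs and the seeded dataset writer binding them together.

#' Write / read a binary mask as 8-bit PNG
#'
#' Foreground is stored as 255, background as 0.
#'
#' @param mask Binary matrix.
#' @param path File path.
#' @return `path` invisibly (writer); binary 0/1 matrix (reader).
#' @export
write_mask_png <- function(mask, path) {
  check_binary_mask(mask)
  png::writePNG((mask != 0) * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  as_binary(img > 0.5)
}

#' Write / read a grayscale image as 16-bit TIFF
#'
#' @param image Matrix with values in \[0, 1\].
#' @param path File path.
#' @return `path` invisibly (writer); matrix in \[0, 1\] (reader).
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(is.matrix(image), min(image) >= 0, max(image) <= 1)
  tiff::writeTIFF(image, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write a seeded synthetic dataset to disk
#'
#' Renders the nodule suite and writes, per nodule, the image (16-bit
#' TIFF), nodule mask and truth label masks (8-bit PNG), plus a truth CSV
#' (`nodule_id`, `cystic_fraction_true`, `pixel_spacing_mm`) and a
#' `config.txt` sidecar recording the resolved configuration and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param n Number of nodules.
#' @param config A [run_config()]; its seed drives the generator.
#' @param image_shape Frame size in pixels.
#' @return Invisibly, the list of generated `synthetic_nodule` objects.
#' @export
write_nodule_dataset <- function(out_dir, n = 20L, config = run_config(),
                                 image_shape = c(224L, 224L)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  suite <- synthesize_nodule_suite(n = n, image_shape = image_shape,
                                   seed = config$seed,
                                   pixel_spacing_mm = config$pixel_spacing_mm)
  truth <- data.frame(
    nodule_id = vapply(suite, `[[`, integer(1), "nodule_id"),
    cystic_fraction_true = vapply(suite, `[[`, numeric(1), "cystic_fraction_true"),
    pixel_spacing_mm = config$pixel_spacing_mm)
  for (nod in suite) {
    stem <- sprintf("nodule_%02d", nod$nodule_id)
    write_image_tiff(nod$image, file.path(out_dir, paste0(stem, ".tiff")))
    write_mask_png(nod$nodule_mask, file.path(out_dir, paste0(stem, "_mask.png")))
    write_mask_png(as_binary(nod$label_mask == 2L),
                   file.path(out_dir, paste0(stem, "_cystic.png")))
  }
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  write_config(config, file.path(out_dir, "config.txt"))
  invisible(suite)
}

#' Write per-nodule cystic estimates as CSV
#'
#' @param estimates List of `cystic_estimate` objects or the `per_nodule`
#'   data.frame of [evaluate_recovery()] / [recover_cystic_suite()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  df <- if (is.data.frame(estimates)) estimates else {
    do.call(rbind, lapply(estimates, function(e) {
      data.frame(nodule_id = e$nodule_id, dss_cystic_pct = e$cystic_percent,
                 n_patches = e$n_patches)
    }))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an observer table from CSV
#'
#' Expects a header with `nodule_id` and one column per observer; the NA
#' literal is `"NA"`.
#'
#' @param path CSV path.
#' @return An [observer_table()].
#' @export
read_observer_csv <- function(path) {
  observer_table(utils::read.csv(path))
}

#' Write a variance table as CSV with `NA` literals
#'
#' @param vt A [variance_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_variance_csv <- function(vt, path) {
  utils::write.csv(vt, path, row.names = FALSE, na = "NA")
  invisible(path)
}
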