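#' Annotator mask set
#'
#' A set of co-registered binary nodule masks, one per annotator, with the
#' shared pixel spacing needed to express areas in mm^2.
#'
#' @param masks List of >= 2 binary matrices of identical shape, each
#'   non-empty.
#' @param pixel_spacing_mm Pixel spacing, mm per pixel.
#' @return A list of class `annotator_mask_set`.
#' @export
annotator_mask_set <- function(masks, pixel_spacing_mm) {
  if (!is.list(masks) || length(masks) < 2L) {
    stop("`masks` must be a list of at least two masks", call. = FALSE)
  }
  check_scalar(pixel_spacing_mm, "pixel_spacing_mm", 0, allow_lower = FALSE)
  shapes <- lapply(masks, dim)
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]]))) {
    stop("all annotator masks must share one shape", call. = FALSE)
  }
  masks <- lapply(masks, function(m) as_binary(check_binary_mask(m)))
  if (any(vapply(masks, sum, numeric(1)) == 0)) {
    stop("annotator masks must be non-empty", call. = FALSE)
  }
  structure(list(masks = masks, pixel_spacing_mm = pixel_spacing_mm),
            class = "annotator_mask_set")
}

#' Area of a binary mask in mm^2
#'
#' @param mask Binary matrix.
#' @param pixel_spacing_mm Pixel spacing, mm per pixel.
#' @return Set-pixel count times the squared spacing; 0 for an empty mask.
#' @export
#' @examples
#' mask_area_mm2(matrix(1, 20, 20), 0.2648)  # 5.296 x 5.296 mm footprint
mask_area_mm2 <- function(mask, pixel_spacing_mm) {
  check_binary_mask(mask)
  check_scalar(pixel_spacing_mm, "pixel_spacing_mm", 0, allow_lower = FALSE)
  sum(mask != 0) * pixel_spacing_mm^2
}

#' Consensus ground-truth mask by area averaging
#'
#' Fuses multiple annotators' masks into one binary consensus whose area
#' equals the mean of the input areas (to within one pixel). The pixelwise
#' mean of the masks is thresholded over its distinct levels; the target
#' area always falls between two consecutive superlevel sets, and pixels of
#' the critical level are then added in order of increasing distance from
#' the consensus centroid (row-major tie-break) until the rounded target
#' area is reached. Spatial consensus is therefore respected: a pixel is
#' never included before another pixel more annotators agreed on.
#'
#' @param set An [annotator_mask_set()].
#' @return A binary matrix.
#' @export
average_ground_truth <- function(set) {
  stopifnot(inherits(set, "annotator_mask_set"))
  masks <- set$masks
  k <- length(masks)
  mean_img <- Reduce(`+`, masks) / k
  if (max(mean_img) <= 1 / k + 1e-12) {
    stop("annotator masks are pairwise disjoint: no consensus region exists",
         call. = FALSE)
  }
  target <- mean(vapply(masks, sum, numeric(1)))
  n_target <- round(target)

  levels_desc <- sort(unique(mean_img[mean_img > 0]), decreasing = TRUE)
  # grow the superlevel set until it reaches the target area
  out <- matrix(0L, nrow(mean_img), ncol(mean_img))
  for (lv in levels_desc) {
    sl <- mean_img >= lv - 1e-12
    if (sum(sl) >= n_target) {
      # partially include the critical level, nearest-to-centroid first
      core <- out
      need <- n_target - sum(core)
      cand <- which(sl & !core)
      if (need > 0 && length(cand) > 0) {
        base <- if (sum(core) > 0) core else sl
        ci <- arrayInd(which(base == 1L), dim(base))
        ctr <- colMeans(ci)
        pos <- arrayInd(cand, dim(base))
        d <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2
        keep <- cand[order(d, cand)][seq_len(min(need, length(cand)))]
        core[keep] <- 1L
      }
      return(as_binary(core))
    }
    out <- sl * 1L
  }
  as_binary(out)
}

#' Overlap metrics between two binary masks
#'
#' @param a,b Binary matrices of identical shape.
#' @return A list with `dice` = 2|a&b|/(|a|+|b|) and
#'   `jaccard` = intersection over union. Two empty masks are defined as perfectly
#'   overlapping (both metrics 1).
#' @export
overlap_metrics <- function(a, b) {
  check_binary_mask(a, "a"); check_binary_mask(b, "b")
  if (!identical(dim(a), dim(b))) stop("masks must share one shape", call. = FALSE)
  a <- a != 0; b <- b != 0
  inter <- sum(a & b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(list(dice = 1.0, jaccard = 1.0))
  list(dice = 2 * inter / (na + nb),
       jaccard = inter / sum(a | b))
}
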