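#' Specification of a synthetic thyroid nodule
#'
#' Describes an elliptical nodule containing a hypoechoic (cystic)
#' compartment with a known target area fraction and an echoic textured
#' (solid) remainder. The cystic compartment is rendered as 1--3 random
#' elliptical blobs scaled until their area fraction matches
#' `cystic_fraction_true`.
#'
#' @param center_px Nodule centre `c(row, col)`, pixels.
#' @param axes_px Semi-axes `c(row, col)`, pixels, both positive.
#' @param cystic_fraction_true Target cystic area fraction in \[0, 1\].
#' @param solid_params,cystic_params [speckle_params()] for each compartment.
#'   Defaults follow ultrasound semantics: the cyst is hypoechoic (dark) and
#'   nearly anechoic, the solid tissue is brighter and speckled.
#' @param seed Integer seed controlling blob geometry and texture.
#' @return A list of class `nodule_spec`.
#' @export
nodule_spec <- function(center_px, axes_px, cystic_fraction_true,
                        solid_params = speckle_params(0.60, 4, 0),
                        cystic_params = speckle_params(0.08, 8, 0),
                        seed = 1L) {
  stopifnot(length(center_px) == 2L, length(axes_px) == 2L)
  if (any(axes_px <= 0)) stop("`axes_px` must be positive", call. = FALSE)
  check_scalar(cystic_fraction_true, "cystic_fraction_true", 0, 1)
  stopifnot(inherits(solid_params, "speckle_params"),
            inherits(cystic_params, "speckle_params"))
  structure(list(center_px = as.numeric(center_px),
                 axes_px = as.numeric(axes_px),
                 cystic_fraction_true = cystic_fraction_true,
                 solid_params = solid_params,
                 cystic_params = cystic_params,
                 seed = as.integer(seed)),
            class = "nodule_spec")
}

# Binary mask of a (possibly rotated, possibly scaled) ellipse on a pixel grid.
ellipse_mask <- function(shape, center, axes, angle = 0, scale = 1) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dy <- rows - center[1]
  dx <- cols - center[2]
  u <- (dy * cos(angle) + dx * sin(angle)) / (axes[1] * scale)
  v <- (-dy * sin(angle) + dx * cos(angle)) / (axes[2] * scale)
  (u^2 + v^2 <= 1) * 1L
}

# Draw the 1-3 random blob geometries (centres, base axes, angles) used for
# the cystic compartment; deterministic given the spec seed.
draw_cystic_blobs <- function(spec) {
  with_seed(spec$seed + 1L, {
    n <- sample(1:3, 1L)
    lapply(seq_len(n), function(i) {
      # centre offset expressed in the nodule's elliptical coordinates so the
      # blob seed point always lies well inside the nodule
      r <- sqrt(stats::runif(1)) * 0.5
      th <- stats::runif(1, 0, 2 * pi)
      list(center = spec$center_px +
             c(r * cos(th) * spec$axes_px[1], r * sin(th) * spec$axes_px[2]),
           axes = spec$axes_px * stats::runif(2, 0.25, 0.45),
           angle = stats::runif(1, 0, pi))
    })
  })
}

cystic_mask_at_scale <- function(shape, blobs, nodule_mask, s) {
  acc <- matrix(0L, shape[1], shape[2])
  for (b in blobs) {
    acc <- acc | ellipse_mask(shape, b$center, b$axes, b$angle, scale = s)
  }
  as_binary(acc & nodule_mask)
}

#' Render a synthetic nodule image with known composition
#'
#' Builds the nodule and cystic-compartment masks, then renders a
#' speckle-textured image: each compartment's echo level is multiplied by
#' unit-mean gamma noise of its own shape, and a single global Gaussian
#' point-spread blur (the background's `smoothing_sigma_px`) is applied,
#' since the point-spread belongs to the imaging system rather than the
#' tissue. The cystic blob scale is found by bisection so the realised
#' cystic area fraction is within 0.02 of `cystic_fraction_true`.
#'
#' @param image_shape `c(rows, cols)` of the output image.
#' @param spec A [nodule_spec()].
#' @param background [speckle_params()] of the surrounding parenchyma; its
#'   `smoothing_sigma_px` acts as the global point-spread width.
#' @param pixel_spacing_mm Physical pixel spacing, mm per pixel.
#' @return A list of class `synthetic_nodule` with elements `image`
#'   (matrix in \[0,1\]), `pixel_spacing_mm`, `nodule_mask` (0/1 matrix),
#'   `label_mask` (0 background, 1 solid, 2 cystic), `cystic_fraction_true`,
#'   and the generating `spec`.
#' @export
#' @examples
#' sp <- nodule_spec(c(64, 64), c(40, 30), 0.3, seed = 2)
#' nod <- render_nodule(c(128, 128), sp, speckle_params(0.35, 6, 1), 0.2648)
#' mean(nod$label_mask == 2) / mean(nod$nodule_mask == 1)  # ~0.3
render_nodule <- function(image_shape, spec,
                          background = speckle_params(0.35, 6, 1),
                          pixel_spacing_mm = 0.2648) {
  stopifnot(inherits(spec, "nodule_spec"), inherits(background, "speckle_params"))
  check_scalar(pixel_spacing_mm, "pixel_spacing_mm", 0, allow_lower = FALSE)
  image_shape <- as.integer(image_shape)
  lo <- spec$center_px - spec$axes_px
  hi <- spec$center_px + spec$axes_px
  if (any(lo < 1) || any(hi > image_shape)) {
    stop("nodule ellipse does not fit inside the image frame", call. = FALSE)
  }

  nodule_mask <- ellipse_mask(image_shape, spec$center_px, spec$axes_px)
  n_nod <- sum(nodule_mask)
  frac <- spec$cystic_fraction_true

  if (frac <= 0) {
    cyst <- matrix(0L, image_shape[1], image_shape[2])
  } else if (frac >= 1) {
    cyst <- nodule_mask
  } else {
    blobs <- draw_cystic_blobs(spec)
    f_of <- function(s) sum(cystic_mask_at_scale(image_shape, blobs, nodule_mask, s)) / n_nod
    s_lo <- 1e-3; s_hi <- 1
    while (f_of(s_hi) < frac && s_hi < 64) s_hi <- s_hi * 2
    for (i in 1:60) {
      s_mid <- (s_lo + s_hi) / 2
      if (f_of(s_mid) < frac) s_lo <- s_mid else s_hi <- s_mid
    }
    cyst <- cystic_mask_at_scale(image_shape, blobs, nodule_mask, s_hi)
    achieved <- sum(cyst) / n_nod
    if (abs(achieved - frac) > 0.02) {
      stop(sprintf(
        "cystic fraction %.3f unreachable with the drawn blob geometry (achieved %.3f)",
        frac, achieved), call. = FALSE)
    }
  }

  label_mask <- nodule_mask          # 1 = solid
  label_mask[cyst == 1L] <- 2L       # 2 = cystic

  level <- matrix(background$mean_intensity, image_shape[1], image_shape[2])
  level[label_mask == 1L] <- spec$solid_params$mean_intensity
  level[label_mask == 2L] <- spec$cystic_params$mean_intensity
  shape_map <- matrix(background$speckle_shape, image_shape[1], image_shape[2])
  shape_map[label_mask == 1L] <- spec$solid_params$speckle_shape
  shape_map[label_mask == 2L] <- spec$cystic_params$speckle_shape

  img <- with_seed(spec$seed, {
    noise <- stats::rgamma(length(level), shape = as.vector(shape_map),
                           rate = as.vector(shape_map))
    matrix(as.vector(level) * noise, image_shape[1], image_shape[2])
  })
  img <- gaussian_blur(img, background$smoothing_sigma_px)
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = img,
                 pixel_spacing_mm = pixel_spacing_mm,
                 nodule_mask = nodule_mask,
                 label_mask = label_mask,
                 cystic_fraction_true = frac,
                 spec = spec),
            class = "synthetic_nodule")
}

#' Generate the default synthetic nodule suite
#'
#' The package's standard study conditions: `n` elliptical nodules on a
#' square frame, true cystic fractions spanning 10--90% on an even grid,
#' randomised nodule size and blob geometry, default echogenicity contrast.
#'
#' @param n Number of nodules (default 20).
#' @param image_shape Frame size, pixels.
#' @param cystic_fractions True cystic fractions; recycled to length `n`.
#' @param seed Integer base seed.
#' @param pixel_spacing_mm Pixel spacing, mm per pixel.
#' @return A list of `synthetic_nodule` objects; each carries a `nodule_id`.
#' @export
synthesize_nodule_suite <- function(n = 20L,
                                    image_shape = c(224L, 224L),
                                    cystic_fractions = seq(0.10, 0.90, length.out = n),
                                    seed = 1L,
                                    pixel_spacing_mm = 0.2648) {
  stopifnot(n >= 1)
  cystic_fractions <- rep_len(cystic_fractions, n)
  geom <- with_seed(seed, {
    data.frame(ay = stats::runif(n, 45, 70),
               ax = stats::runif(n, 35, 60),
               sub_seed = sample.int(.Machine$integer.max %/% 2L, n))
  })
  center <- (as.integer(image_shape) + 1) / 2
  lapply(seq_len(n), function(i) {
    sp <- nodule_spec(center, c(geom$ay[i], geom$ax[i]), cystic_fractions[i],
                      seed = geom$sub_seed[i])
    nod <- render_nodule(image_shape, sp, pixel_spacing_mm = pixel_spacing_mm)
    nod$nodule_id <- i
    nod
  })
}
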