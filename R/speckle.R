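#' Speckle texture parameters
#'
#' Parameters of the fully-developed-speckle approximation used by the
#' phantom generator: a constant echo level multiplied by gamma-distributed
#' noise of unit mean (shape `speckle_shape`), then blurred by a Gaussian
#' point-spread of width `smoothing_sigma_px`. Smaller shape means grainier
#' speckle (relative variance is `1/speckle_shape` before blurring).
#'
#' @param mean_intensity Target grayscale level in \[0, 1\].
#' @param speckle_shape Positive gamma shape parameter.
#' @param smoothing_sigma_px Non-negative Gaussian blur sigma, pixels.
#' @return A list of class `speckle_params`.
#' @export
#' @examples
#' speckle_params(0.5, speckle_shape = 4, smoothing_sigma_px = 1)
speckle_params <- function(mean_intensity, speckle_shape = 4,
                           smoothing_sigma_px = 1) {
  check_scalar(mean_intensity, "mean_intensity", 0, 1)
  check_scalar(speckle_shape, "speckle_shape", lower = 0, allow_lower = FALSE)
  check_scalar(smoothing_sigma_px, "smoothing_sigma_px", lower = 0)
  structure(list(mean_intensity = mean_intensity,
                 speckle_shape = speckle_shape,
                 smoothing_sigma_px = smoothing_sigma_px),
            class = "speckle_params")
}

# Gaussian blur that tolerates sigma = 0 and guards EBImage's requirement
# that the brush not exceed the image.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  brush <- 2 * ceiling(3 * sigma) + 1
  if (brush > min(dim(x))) {
    stop("image too small for the requested smoothing sigma", call. = FALSE)
  }
  out <- EBImage::gblur(x, sigma = sigma)
  out <- as.matrix(out)
  dimnames(out) <- NULL
  out
}

#' Generate a speckle-textured field
#'
#' Multiplicative model for ultrasound speckle: per-pixel unit-mean gamma
#' noise on a constant level, followed by Gaussian point-spread blurring,
#' clipped to \[0, 1\]. The result is a pure function of
#' `(shape, params, seed)`.
#'
#' @param shape Integer vector `c(rows, cols)`, both positive.
#' @param params A [speckle_params()] object.
#' @param seed Integer RNG seed.
#' @return A `rows x cols` matrix with values in \[0, 1\].
#' @export
#' @examples
#' f <- generate_speckle_field(c(64, 64), speckle_params(0.4), seed = 7)
#' mean(f)
generate_speckle_field <- function(shape, params, seed) {
  stopifnot(inherits(params, "speckle_params"))
  if (length(shape) != 2L || any(shape < 1) || any(shape != round(shape))) {
    stop("`shape` must be two positive integers", call. = FALSE)
  }
  shape <- as.integer(shape)
  if (params$mean_intensity == 0) {
    return(matrix(0, shape[1], shape[2]))
  }
  field <- with_seed(seed, {
    k <- params$speckle_shape
    noise <- matrix(stats::rgamma(prod(shape), shape = k, rate = k),
                    shape[1], shape[2])
    params$mean_intensity * noise
  })
  field <- gaussian_blur(field, params$smoothing_sigma_px)
  pmin(pmax(field, 0), 1)
}
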