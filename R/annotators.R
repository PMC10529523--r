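#' Simulated annotator model
#'
#' Emulates a physician reading a nodule image: the drawn nodule boundary is
#' a smoothly jittered version of the true boundary, and the reported cystic
#' percentage is the truth plus a systematic bias and random spread, rounded
#' to the annotator's reporting granularity. Larger `boundary_jitter_px`,
#' `|cystic_bias_pct|` and `cystic_noise_pct` model less experienced readers.
#'
#' @param boundary_jitter_px RMS radial boundary perturbation, pixels (>= 0).
#' @param cystic_bias_pct Systematic over/under-estimation, percentage points.
#' @param cystic_noise_pct SD of random estimation spread, percentage points.
#' @param rounding_step_pct Reporting granularity (default 5, the step most
#'   visible in published per-nodule estimates).
#' @param seed Integer seed.
#' @return A list of class `annotator_model`.
#' @export
annotator_model <- function(boundary_jitter_px = 0,
                            cystic_bias_pct = 0,
                            cystic_noise_pct = 0,
                            rounding_step_pct = 5,
                            seed = 1L) {
  check_scalar(boundary_jitter_px, "boundary_jitter_px", lower = 0)
  check_scalar(cystic_bias_pct, "cystic_bias_pct")
  check_scalar(cystic_noise_pct, "cystic_noise_pct", lower = 0)
  check_scalar(rounding_step_pct, "rounding_step_pct", lower = 0, allow_lower = FALSE)
  structure(list(boundary_jitter_px = boundary_jitter_px,
                 cystic_bias_pct = cystic_bias_pct,
                 cystic_noise_pct = cystic_noise_pct,
                 rounding_step_pct = rounding_step_pct,
                 seed = as.integer(seed)),
            class = "annotator_model")
}

#' Default three-annotator panel
#'
#' One experienced reader (small jitter, no bias, tight spread) and two less
#' experienced readers with larger boundary jitter, opposite systematic
#' biases and wider spread, mirroring an experience-dependent reading panel.
#'
#' @param seed Integer base seed; each annotator gets a distinct sub-seed.
#' @return Named list of three [annotator_model()] objects (`P1`,`P2`,`P3`).
#' @export
default_annotator_panel <- function(seed = 1L) {
  list(
    P1 = annotator_model(1.5, 0,  4, 5, seed = seed + 101L),
    P2 = annotator_model(3.0, 6,  9, 5, seed = seed + 202L),
    P3 = annotator_model(3.5, -6, 11, 5, seed = seed + 303L)
  )
}

#' Simulate an annotator's nodule segmentation
#'
#' Perturbs the true elliptical boundary radially by a smooth periodic
#' jitter field (four random harmonics, RMS amplitude `boundary_jitter_px`),
#' producing a closed region. With zero jitter the truth mask is returned
#' unchanged.
#'
#' @param truth A `synthetic_nodule`.
#' @param model An [annotator_model()].
#' @return A binary matrix of the same shape as `truth$nodule_mask`.
#' @export
simulate_annotator_mask <- function(truth, model) {
  stopifnot(inherits(truth, "synthetic_nodule"), inherits(model, "annotator_model"))
  if (model$boundary_jitter_px == 0) return(truth$nodule_mask)

  coef <- with_seed(model$seed, stats::rnorm(8, sd = model$boundary_jitter_px / 2))
  spec <- truth$spec
  shape <- dim(truth$nodule_mask)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dy <- rows - spec$center_px[1]
  dx <- cols - spec$center_px[2]
  r <- sqrt(dy^2 + dx^2)
  theta <- atan2(dx, dy)
  jitter <- matrix(0, shape[1], shape[2])
  for (h in 1:4) {
    jitter <- jitter + coef[2 * h - 1] * cos(h * theta) +
      coef[2 * h] * sin(h * theta)
  }
  # boundary radius of the true ellipse along each pixel's direction
  r_b <- 1 / sqrt((cos(theta) / spec$axes_px[1])^2 +
                  (sin(theta) / spec$axes_px[2])^2)
  as_binary(r <= r_b + jitter)
}

round_to_step <- function(x, step) round(x / step) * step

#' Simulate a per-nodule observer table
#'
#' One row per nodule, one column per annotator; each entry is the true
#' cystic percentage plus the annotator's bias and Gaussian noise, rounded
#' to the annotator's reporting step and clipped to \[0, 100\].
#'
#' @param truths List of `synthetic_nodule` objects.
#' @param annotators Named list of [annotator_model()] objects.
#' @return A data.frame with `nodule_id` and one column per annotator.
#' @export
simulate_observer_table <- function(truths, annotators) {
  stopifnot(length(truths) >= 1, length(annotators) >= 1)
  if (is.null(names(annotators))) {
    names(annotators) <- paste0("A", seq_along(annotators))
  }
  truth_pct <- vapply(truths, function(t) 100 * t$cystic_fraction_true, numeric(1))
  out <- data.frame(nodule_id = seq_along(truths))
  for (nm in names(annotators)) {
    m <- annotators[[nm]]
    noise <- with_seed(m$seed, stats::rnorm(length(truth_pct), sd = m$cystic_noise_pct))
    raw <- truth_pct + m$cystic_bias_pct + noise
    out[[nm]] <- pmin(pmax(round_to_step(raw, m$rounding_step_pct), 0), 100)
  }
  out
}
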