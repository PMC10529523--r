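#' Autoregressive fit by the Burg method
#'
#' Fits an AR(p) model \eqn{x_t = \phi_1 x_{t-1} + \dots + \phi_p x_{t-p} +
#' \epsilon_t} by Burg's recursion, which minimises the summed forward and
#' backward prediction error and yields reflection coefficients bounded by
#' one in magnitude, so the fitted model is stationary on well-conditioned
#' inputs. The sequence is not mean-removed: the band decomposition already
#' isolates the DC level in the low band, where it is meaningful
#' (echogenicity). A zero-variance input returns the documented degenerate
#' result (all-zero coefficients, zero residual variance).
#'
#' @param x Numeric sequence; length must exceed `10 * order`.
#' @param order Positive integer model order.
#' @return A list with `coefficients` (length `order`, predictor
#'   convention) and `residual_variance` (>= 0).
#' @export
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 2000))
#' ar_fit(x, 2)$coefficients
ar_fit <- function(x, order = 2L) {
  order <- as.integer(order)
  check_scalar(order, "order", lower = 1)
  x <- as.numeric(x)
  n <- length(x)
  if (n <= 10L * order) {
    stop(sprintf("sequence length %d too short for order %d (need > %d)",
                 n, order, 10L * order), call. = FALSE)
  }
  if (any(!is.finite(x))) stop("sequence must be finite", call. = FALSE)
  if (stats::var(x) < 1e-20) {
    return(list(coefficients = rep(0, order), residual_variance = 0))
  }

  # Burg recursion: a holds the error-filter coefficients in polynomial
  # convention (x_t + sum a_i x_{t-i} = e_t); phi = -a.
  ef <- x
  eb <- x
  a <- numeric(0)
  E <- sum(x^2) / n
  for (m in seq_len(order)) {
    f <- ef[(m + 1L):n]
    b <- eb[m:(n - 1L)]
    den <- sum(f^2) + sum(b^2)
    k <- if (den > 0) -2 * sum(f * b) / den else 0
    a <- c(a + k * rev(a), k)
    ef_new <- f + k * b
    eb_new <- b + k * f
    ef <- c(rep(0, m), ef_new)
    eb <- c(rep(0, m), eb_new)
    E <- E * (1 - k^2)
  }
  list(coefficients = -a, residual_variance = max(E, 0))
}
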