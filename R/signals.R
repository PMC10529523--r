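# Patch-to-signal scans and frequency-band decomposition.
#
# A square texture patch is read out along four directions so that
# one-dimensional signal models can see its texture from several
# orientations; every scan is a permutation of the same pixel multiset.

# Zig-zag orderings over anti-diagonals (i + j constant, JPEG-style) and
# main diagonals (i - j constant), alternating direction per diagonal.
zigzag_orders <- function(n) {
  ij <- expand.grid(row = seq_len(n), col = seq_len(n))
  anti <- ij$row + ij$col
  main <- ij$row - ij$col
  ord_by <- function(diag_id, flip_key) {
    # within each diagonal, alternate traversal direction
    key <- ifelse(diag_id %% 2 == 0, flip_key, -flip_key)
    order(diag_id, key)
  }
  list(diag = ord_by(anti, ij$row), anti = ord_by(main, ij$col))
}

#' Convert a texture patch into four directional signals
#'
#' Reads the patch along four scan paths -- row-major, column-major, a
#' zig-zag over anti-diagonals and a zig-zag over main diagonals -- giving
#' four 1-D signals of length `patch_size^2`, each a permutation of the
#' patch pixels.
#'
#' @param patch A [texture_patch()].
#' @return A list of class `patch_signal_set` with element `signals`
#'   (named list of four numeric vectors).
#' @export
#' @examples
#' p <- texture_patch(matrix(runif(400), 20, 20))
#' s <- patch_to_signals(p)
#' lengths(s$signals)
patch_to_signals <- function(patch) {
  stopifnot(inherits(patch, "texture_patch"))
  px <- patch$pixels
  n <- nrow(px)
  zz <- zigzag_orders(n)
  flat <- as.vector(px)  # column-major storage
  signals <- list(
    row      = as.vector(t(px)),
    column   = flat,
    diagonal = flat[zz$diag],
    antidiag = flat[zz$anti]
  )
  structure(list(signals = signals), class = "patch_signal_set")
}

#' Split signals into low / mid / high frequency bands
#'
#' Zero-phase brick-wall band-pass via FFT bin partition: every frequency
#' bin is assigned to exactly one band by its absolute frequency in
#' cycles/sample -- low \eqn{[0, e_1]}, mid \eqn{(e_1, e_2]}, high
#' \eqn{(e_2, 0.5]} with default edges \eqn{e_1 = 0.05}, \eqn{e_2 = 0.20}.
#' The three bands of a signal therefore sum to the signal exactly, and the
#' DC level (echogenicity) is retained in the low band.
#'
#' @param signals A [patch_to_signals()] result.
#' @param band_edges Two ascending edges in cycles/sample.
#' @return A list of class `band_set`: `bands[[signal]][[band]]` numeric
#'   vectors, bands named `low`, `mid`, `high`.
#' @export
decompose_bands <- function(signals, band_edges = c(0.05, 0.20)) {
  stopifnot(inherits(signals, "patch_signal_set"))
  e1 <- band_edges[1]; e2 <- band_edges[2]
  stopifnot(0 < e1, e1 < e2, e2 < 0.5)
  bands <- lapply(signals$signals, function(x) {
    n <- length(x)
    X <- stats::fft(x)
    k <- seq_len(n) - 1L
    f <- pmin(k, n - k) / n  # absolute frequency of each bin, cycles/sample
    pick <- function(sel) Re(stats::fft(X * sel, inverse = TRUE)) / n
    list(low  = pick(f <= e1 + 1e-12),
         mid  = pick(f > e1 + 1e-12 & f <= e2 + 1e-12),
         high = pick(f > e2 + 1e-12))
  })
  structure(list(bands = bands, band_edges = band_edges), class = "band_set")
}
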