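test_that("patch extraction tiles the mask grid deterministically", {
  img <- matrix(0.5, 60, 60)
  mask <- matrix(0L, 60, 60); mask[11:50, 11:50] <- 1L  # 40 x 40 block
  p20 <- extract_patches(img, mask, 20, stride_px = 20, min_inside_fraction = 1)
  expect_length(p20, 4)
  p10 <- extract_patches(img, mask, 20, stride_px = 10, min_inside_fraction = 1)
  expect_length(p10, 9)
  # row-major ordering by origin
  origins <- t(sapply(p10, function(p) p$origin_px))
  expect_equal(order(origins[, 1], origins[, 2]), seq_len(9))
  expect_true(all(sapply(p10, function(p) p$inside_fraction) == 1))
  expect_warning(out <- extract_patches(img, matrix(0L, 60, 60), 20), "empty")
  expect_length(out, 0)
  expect_warning(extract_patches(img, disk_mask(c(60, 60), c(30, 30), 4), 20),
                 "too small")
})

test_that("the four scan signals are permutations of the patch pixels", {
  px <- matrix(runif(400), 20, 20)
  s <- patch_to_signals(texture_patch(px))
  expect_named(s$signals, c("row", "column", "diagonal", "antidiag"))
  for (sig in s$signals) {
    expect_length(sig, 400)
    expect_equal(sort(sig), sort(as.vector(px)))
  }
  # constant patch -> four constant signals
  sc <- patch_to_signals(texture_patch(matrix(0.3, 20, 20)))
  for (sig in sc$signals) expect_equal(sig, rep(0.3, 400))
})

test_that("scan directions read stripes as expected", {
  # vertical stripes of period 2: columns alternate between two values
  px <- matrix(rep(c(0.2, 0.8), each = 20, times = 10), 20, 20)
  s <- patch_to_signals(texture_patch(px))
  expect_equal(s$signals$row, rep(c(0.2, 0.8), 200))          # alternates each sample
  expect_equal(s$signals$column, rep(c(0.2, 0.8), each = 20, times = 10))
})

test_that("band decomposition splits frequency content and conserves the signal", {
  # constant signal: all content in the low band
  bc <- decompose_bands(patch_to_signals(texture_patch(matrix(0.4, 20, 20))))
  expect_equal(bc$bands$row$low, rep(0.4, 400))
  expect_lt(max(abs(bc$bands$row$mid)), 1e-9)
  expect_lt(max(abs(bc$bands$row$high)), 1e-9)

  # synthesized tone at 0.30 cycles/sample lands in the high band
  n <- 400
  tone <- sin(2 * pi * 0.30 * seq_len(n))
  fake <- structure(list(signals = list(s = tone)), class = "patch_signal_set")
  bt <- decompose_bands(fake)$bands$s
  expect_gt(sum(bt$high^2) / sum(tone^2), 0.95)

  # white noise: bands sum back to the signal, energies to the total
  set.seed(8)
  noise <- rnorm(n)
  bn <- decompose_bands(structure(list(signals = list(s = noise)),
                                  class = "patch_signal_set"))$bands$s
  expect_equal(bn$low + bn$mid + bn$high, noise, tolerance = 1e-10)
  # mean-removed energies are Parseval-consistent within 5%
  tot <- sum((noise - mean(noise))^2)
  banded <- sum((bn$low - mean(noise))^2) + sum(bn$mid^2) + sum(bn$high^2)
  expect_lt(abs(banded - tot) / tot, 0.05)
})

test_that("Burg fits recover known AR structure", {
  # constant sequence: documented degenerate return
  fit0 <- ar_fit(rep(2.5, 100), 2)
  expect_equal(fit0$coefficients, c(0, 0))
  expect_equal(fit0$residual_variance, 0)

  set.seed(1234)
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 4000))
  fit <- ar_fit(x, 2)
  expect_lt(max(abs(fit$coefficients - c(0.5, -0.3))), 0.05)
  expect_gt(fit$residual_variance, 0)
  # agrees with the reference Burg implementation
  oracle <- stats::ar.burg(x, order.max = 2, aic = FALSE, demean = FALSE)
  expect_equal(fit$coefficients, unname(oracle$ar), tolerance = 1e-8)

  set.seed(77)
  w <- rnorm(4000)
  expect_lt(max(abs(ar_fit(w, 2)$coefficients)), 0.1)

  expect_error(ar_fit(rnorm(15), 2), "too short")
})

test_that("fitted AR models are stationary on speckle-like inputs", {
  for (seed in 1:5) {
    f <- generate_speckle_field(c(20, 20), speckle_params(0.5, 2, 0), seed)
    bands <- decompose_bands(patch_to_signals(texture_patch(f)))$bands
    for (sig in bands) for (b in sig) {
      phi <- ar_fit(b, 2)$coefficients
      roots <- polyroot(c(1, -phi))
      expect_true(all(Mod(roots) > 1))
    }
  }
})

test_that("patch features have the documented layout and are deterministic", {
  px <- matrix(runif(400), 20, 20)
  f <- patch_features(texture_patch(px))
  expect_length(f, 36)
  expect_true(all(is.finite(f)))
  # signal-major, band-minor, (ar1, ar2, logvar) per block
  expect_equal(names(f)[1:6],
               c("row_low_ar1", "row_low_ar2", "row_low_logvar",
                 "row_mid_ar1", "row_mid_ar2", "row_mid_logvar"))
  expect_identical(f, patch_features(texture_patch(px)))
  # constant patch: zero coefficients, log-variances at the floor
  fc <- patch_features(texture_patch(matrix(0.7, 20, 20)))
  expect_true(all(fc[grep("ar[12]$", names(fc))] == 0))
  expect_true(all(fc[grep("logvar$", names(fc))] == log(1e-12)))
  # alternate order changes dimensionality accordingly
  expect_length(patch_features(texture_patch(px), ar_order = 3), 48)
})

test_that("AR features separate solid from cystic speckle", {
  solid <- generate_speckle_field(c(160, 160), speckle_params(0.60, 4, 0), 21)
  cyst  <- generate_speckle_field(c(160, 160), speckle_params(0.08, 8, 0), 22)
  all_mask <- matrix(1L, 160, 160)
  ps <- extract_patches(solid, all_mask, 20, 10, 1)
  pc <- extract_patches(cyst, all_mask, 20, 10, 1)
  expect_gte(length(ps), 200)
  expect_gte(length(pc), 200)
  feats <- rbind(patch_feature_matrix(ps), patch_feature_matrix(pc))
  is_cyst <- rep(c(FALSE, TRUE), c(length(ps), length(pc)))
  best <- max(apply(feats, 2, function(col) {
    a <- auroc(col, is_cyst); max(a, 1 - a)
  }))
  expect_gt(best, 0.7)
})
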