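test_that("speckle fields are seeded-deterministic and hit the target level", {
  prm <- speckle_params(0.4, speckle_shape = 4, smoothing_sigma_px = 1)
  f1 <- generate_speckle_field(c(128, 128), prm, seed = 3)
  f2 <- generate_speckle_field(c(128, 128), prm, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, generate_speckle_field(c(128, 128), prm, seed = 4)))
  expect_true(all(f1 >= 0 & f1 <= 1))
  # sample mean within 10% of the requested level on a large field
  expect_lt(abs(mean(f1) - 0.4) / 0.4, 0.10)
})

test_that("smoothing reduces per-pixel speckle variance", {
  rough  <- generate_speckle_field(c(128, 128), speckle_params(0.4, 1.5, 0), seed = 5)
  smooth <- generate_speckle_field(c(128, 128), speckle_params(0.4, 1.5, 3), seed = 5)
  expect_gt(var(as.vector(rough)), var(as.vector(smooth)))
})

test_that("degenerate speckle inputs behave as documented", {
  expect_equal(generate_speckle_field(c(8, 8), speckle_params(0), seed = 1),
               matrix(0, 8, 8))
  expect_error(generate_speckle_field(c(0, 10), speckle_params(0.5), seed = 1),
               "positive")
  expect_error(speckle_params(1.2), "range")
  expect_error(speckle_params(0.5, speckle_shape = 0), "range")
})

test_that("rendered nodules honour the target cystic fraction", {
  for (frac in c(0.30, 0.55)) {
    sp <- nodule_spec(c(80, 80), c(45, 38), frac, seed = 7)
    nod <- render_nodule(c(160, 160), sp)
    achieved <- sum(nod$label_mask == 2) / sum(nod$nodule_mask)
    expect_lt(abs(achieved - frac), 0.02)
  }
  # target 0.30 specifically lands in [0.28, 0.32]
  sp <- nodule_spec(c(80, 80), c(45, 38), 0.30, seed = 9)
  nod <- render_nodule(c(160, 160), sp)
  expect_gte(sum(nod$label_mask == 2) / sum(nod$nodule_mask), 0.28)
  expect_lte(sum(nod$label_mask == 2) / sum(nod$nodule_mask), 0.32)
})

test_that("degenerate cystic fractions give all-solid / all-cystic nodules", {
  sp0 <- nodule_spec(c(60, 60), c(30, 25), 0, seed = 1)
  n0 <- render_nodule(c(120, 120), sp0)
  expect_equal(sum(n0$label_mask == 2), 0)
  sp1 <- nodule_spec(c(60, 60), c(30, 25), 1, seed = 1)
  n1 <- render_nodule(c(120, 120), sp1)
  expect_equal(sum(n1$label_mask == 2), sum(n1$nodule_mask))
})

test_that("nodules that do not fit the frame are rejected", {
  sp <- nodule_spec(c(40, 40), c(45, 30), 0.3)
  expect_error(render_nodule(c(80, 80), sp), "fit")
})

test_that("composition is conserved and the cyst is hypoechoic on every phantom", {
  for (nod in small_suite()) {
    expect_equal(sum(nod$label_mask == 1) + sum(nod$label_mask == 2),
                 sum(nod$nodule_mask))
    expect_true(all((nod$label_mask > 0) == (nod$nodule_mask == 1)))
    expect_identical(dim(nod$image), dim(nod$label_mask))
    if (any(nod$label_mask == 2) && any(nod$label_mask == 1)) {
      expect_lt(mean(nod$image[nod$label_mask == 2]),
                mean(nod$image[nod$label_mask == 1]))
    }
  }
})

test_that("annotator masks jitter the boundary as specified", {
  nod <- one_nodule()
  expect_identical(simulate_annotator_mask(nod, annotator_model(0)),
                   nod$nodule_mask)
  # a 60-px-radius nodule with 3-px jitter stays close to the truth
  sp <- nodule_spec(c(80, 80), c(60, 60), 0.3, seed = 3)
  big <- render_nodule(c(160, 160), sp)
  m <- simulate_annotator_mask(big, annotator_model(3, seed = 5))
  d <- overlap_metrics(m, big$nodule_mask)$dice
  expect_lt(d, 1)
  expect_gt(d, 0.8)
  # different seeds give different masks; same seed reproduces
  m2 <- simulate_annotator_mask(big, annotator_model(3, seed = 6))
  expect_false(identical(m, m2))
  expect_identical(m, simulate_annotator_mask(big, annotator_model(3, seed = 5)))
})

test_that("observer tables follow truth, bias, rounding and clipping", {
  suite <- small_suite()
  exact <- annotator_model(0, 0, 0, rounding_step_pct = 1, seed = 1)
  tab <- simulate_observer_table(suite, list(E = exact))
  truth <- sapply(suite, function(n) 100 * n$cystic_fraction_true)
  expect_equal(tab$E, round(truth))
  biased <- annotator_model(0, 10, 0, rounding_step_pct = 1, seed = 1)
  tab2 <- simulate_observer_table(suite, list(B = biased))
  expect_equal(tab2$B, pmin(round(truth + 10), 100))
  # entries always clipped to [0, 100] and rounded to the step
  noisy <- annotator_model(0, -20, 30, rounding_step_pct = 5, seed = 2)
  tab3 <- simulate_observer_table(suite, list(N = noisy))
  expect_true(all(tab3$N >= 0 & tab3$N <= 100))
  expect_true(all(tab3$N %% 5 == 0))
})

test_that("reported estimate spread matches the annotator noise model", {
  # Monte-Carlo: noise SD 5 with fine rounding recovers an SD near 5
  truths <- lapply(seq_len(200), function(i) {
    structure(list(cystic_fraction_true = 0.2 + 0.6 * ((i - 1) / 199)),
              class = "synthetic_nodule")
  })
  m <- annotator_model(0, 0, 5, rounding_step_pct = 1, seed = 31)
  tab <- simulate_observer_table(truths, list(A = m))
  err <- tab$A - sapply(truths, function(t) 100 * t$cystic_fraction_true)
  expect_gt(sd(err), 3.5)
  expect_lt(sd(err), 6.5)
})
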