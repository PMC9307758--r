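test_that("the median filter matches a brute-force oracle", {
  set.seed(3)
  m <- matrix(rnorm(20 * 20, sd = 10), 20, 20)
  for (w in c(3, 5))
    expect_equal(median_filter2d(m, w), oracle_median_filter(m, w),
                 tolerance = 1e-12)
  expect_error(median_filter2d(m, 4), "odd")
})

test_that("lesion masks implement filter-threshold-intersect exactly", {
  cfg <- inversion_config(median_window = 3)
  x <- matrix(0, 20, 20)
  brain <- matrix(TRUE, 20, 20)
  # identical reconstruction -> empty mask
  expect_identical(sum(compute_lesion_mask(x, x, brain, list(), cfg)), 0L)
  # 9x9 interior square of 100 HU residual, window 3: computed with the
  # brute-force oracle, 77 pixels survive -- the four corners see only 4 of
  # their 9 window entries above threshold, so their median is 0
  recon <- x
  recon[6:14, 6:14] <- -100
  M <- compute_lesion_mask(x, recon, brain, list(), cfg)
  oracle_sq <- sum(oracle_median_filter(abs(x - recon), 3) > 5)
  expect_identical(sum(M), 77L)
  expect_identical(sum(M), oracle_sq)
  expect_true(all(M[7:13, 7:13] == 1L))
  expect_identical(M[6, 6] + M[6, 14] + M[14, 6] + M[14, 14], 0L)
  # dual route: equals literal median filtering + thresholding
  set.seed(8)
  recon2 <- x + matrix(rnorm(400, sd = 6), 20, 20)
  M2 <- compute_lesion_mask(x, recon2, brain, list(), cfg)
  lit <- (oracle_median_filter(abs(x - recon2) * brain, 3) > 5) * 1L
  expect_identical(M2, matrix(as.integer(lit), 20, 20))
  # intersection with an empty previous mask kills everything
  empty <- matrix(0L, 20, 20)
  expect_identical(sum(compute_lesion_mask(x, recon, brain, list(empty), cfg)), 0L)
  # masked area is non-increasing under intersection
  M3 <- compute_lesion_mask(x, recon2, brain, list(M), cfg)
  expect_lte(sum(M3), sum(M))
  expect_error(inversion_config(median_window = 4), "odd")
  expect_error(compute_lesion_mask(x, recon[1:10, ], brain), "shape")
})

test_that("brain extraction agrees with the phantom's own labels", {
  sc <- generate_normal_scan(17, c(64, 64), 4)
  for (k in c(1, 4)) {
    bm <- extract_brain_mask(sc$slices[[k]])
    truth <- sc$labels[[k]] %in% c(2L, 3L)
    dim(truth) <- dim(bm)
    agree <- sum(bm & truth) / sum(bm | truth)
    expect_gt(agree, 0.95)
    expect_identical(sum(bm & (sc$labels[[k]] == 0L)), 0L)  # no air
  }
})

test_that("Eq-style masked target has the exact limit behaviour", {
  set.seed(4)
  x <- matrix(rnorm(64), 8, 8)
  recon <- matrix(rnorm(64), 8, 8)
  M <- matrix(rbinom(64, 1, 0.4), 8, 8)
  tgt <- masked_target(M, recon, x)
  expect_identical(tgt[M == 1], recon[M == 1])
  expect_identical(tgt[M == 0], x[M == 0])
  expect_identical(masked_target(matrix(1, 8, 8), recon, x), recon)
  expect_identical(masked_target(matrix(0, 8, 8), recon, x), x)
  expect_error(masked_target(M[1:4, ], recon, x), "shape")
})

test_that("zero-epoch inversion returns the encoder code unchanged", {
  m <- tiny_model()
  st <- tiny_latent_stats()
  x <- generate_normal_scan(55, c(16, 16), 1)$slices[[1]]
  cfg0 <- inversion_config(latent_epochs = 0, seed = 2)
  out <- invert_latent(x, m, st, slice_order = 1, cfg0)
  expect_identical(out$w, encode_image(m, x))
})

test_that("latent optimization does not worsen the objective (best iterate)", {
  m <- tiny_model()
  st <- tiny_latent_stats()
  cfg <- m$cfg
  # fixture whose perfect solution exists: x = G(w0, n_init)
  icfg <- inversion_config(latent_epochs = 25, seed = 6)
  w0 <- matrix(rnorm(cfg$n_layers * cfg$style_dim, sd = 0.5), cfg$n_layers)
  n0 <- sample_noise_maps(m, 1, seed = icfg$seed)
  x <- generate_image(m, w0, n0)
  w_init <- encode_image(m, x)
  l1 <- function(w) mean(abs(generate_image(m, w, n0) - x))
  out <- invert_latent(x, m, st, slice_order = 1, icfg)
  expect_lte(l1(out$w), l1(w_init) + 1e-12)
})

test_that("masked noise optimization shrinks the mask monotonically", {
  m <- tiny_model()
  st <- tiny_latent_stats()
  sc <- generate_normal_scan(23, c(16, 16), 1)
  inj <- inject_lesion(sc, lesion_spec("hyperdense", c(1, 8, 6), 2, 60), 1)
  x <- inj$scan$slices[[1]]
  icfg <- inversion_config(latent_epochs = 10, noise_iters = 8, seed = 3)
  w <- invert_latent(x, m, st, 1, icfg)$w
  brain <- sc$labels[[1]] %in% c(2L, 3L)
  dim(brain) <- dim(x)
  out <- masked_noise_optimization(x, w, m, brain, icfg)
  expect_true(all(diff(out$mask_sizes) <= 0))
  expect_identical(dim(out$mask), dim(x))
  expect_identical(dim(out$recon), dim(x))
  # brain extraction guarantees zero mask outside the brain
  expect_identical(sum(out$mask[!brain]), 0L)
})
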