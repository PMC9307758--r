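test_that("configuration arithmetic matches the full-scale code size", {
  full <- backbone_config(512)
  expect_identical(full$n_layers, 16L)
  expect_identical(full$style_dim, 512L)
  expect_identical(full$code_dim, 8192L)   # 16 layers x 512 dims in W+
  tiny <- tiny_cfg()
  expect_identical(tiny$code_dim, tiny$n_layers * tiny$style_dim)
  expect_error(backbone_config(48), "power of two")
})

test_that("generation is deterministic and responds to every style layer", {
  m <- tiny_model()
  cfg <- m$cfg
  w <- matrix(rnorm(cfg$n_layers * cfg$style_dim), cfg$n_layers)
  n <- sample_noise_maps(m, 1, seed = 4)
  img1 <- generate_image(m, w, n)
  img2 <- generate_image(m, w, n)
  expect_identical(img1, img2)
  # finite-difference response: perturbing any one layer's style changes
  # the output of the untrained random-weight generator
  for (l in seq_len(cfg$n_layers)) {
    w2 <- w
    w2[l, ] <- w2[l, ] + 0.5
    expect_gt(max(abs(generate_image(m, w2, n) - img1)), 0)
  }
  expect_error(generate_image(m, w[-1, , drop = FALSE], n), "latent code")
})

test_that("a zero-initialized generator emits a constant image", {
  mz <- tiny_zero_model()
  w <- matrix(rnorm(mz$cfg$n_layers * mz$cfg$style_dim), mz$cfg$n_layers)
  img <- generate_image(mz, w, sample_noise_maps(mz, 1, seed = 1), units = "unit")
  expect_identical(max(img) - min(img), 0)
})

test_that("encoding is deterministic with the configured code shape", {
  m <- tiny_model()
  x <- generate_normal_scan(3, c(16, 16), 1)$slices[[1]]
  w1 <- encode_image(m, x)
  expect_identical(dim(w1), c(m$cfg$n_layers, m$cfg$style_dim))
  expect_identical(w1, encode_image(m, x))
  y <- generate_normal_scan(4, c(16, 16), 1)$slices[[1]]
  expect_gt(max(abs(encode_image(m, y) - w1)), 0)
  expect_error(encode_image(m, x[1:8, 1:8]), "16")
})

test_that("generator gradients agree with finite differences", {
  # property-style regression guard on the hand-written backward pass
  m <- tiny_model()
  cfg <- m$cfg
  set.seed(9)
  codes <- lapply(seq_len(cfg$n_layers), function(l)
    matrix(rnorm(cfg$style_dim), 1))
  noise <- sample_noise_maps(cfg, 1, seed = 2)
  gf <- getFromNamespace("g_forward", "ctanomaly")
  gb <- getFromNamespace("g_backward", "ctanomaly")
  out <- gf(m, codes, noise, 1, keep = TRUE)
  grads <- gb(m, out$cache, matrix(1, 1, ncol(out$img)), 1,
              wrt_params = TRUE, wrt_w = TRUE, wrt_noise = TRUE)
  f0 <- sum(out$img)
  eps <- 1e-6
  # one weight of a 3x3 conv layer, one of a pointwise layer, one style dim
  m2 <- m
  m2$G$levels[[1]][[1]]$W[3] <- m2$G$levels[[1]][[1]]$W[3] + eps
  num <- (sum(gf(m2, codes, noise, 1)$img) - f0) / eps
  expect_equal(grads$dG$levels[[1]][[1]]$W[3], num, tolerance = 1e-4)
  vtop <- m$cfg$n_levels
  m2 <- m
  m2$G$levels[[vtop]][[2]]$W[2] <- m2$G$levels[[vtop]][[2]]$W[2] + eps
  num <- (sum(gf(m2, codes, noise, 1)$img) - f0) / eps
  expect_equal(grads$dG$levels[[vtop]][[2]]$W[2], num, tolerance = 1e-4)
  codes2 <- codes
  codes2[[3]][5] <- codes2[[3]][5] + eps
  num <- (sum(gf(m, codes2, noise, 1)$img) - f0) / eps
  expect_equal(grads$dw[[3]][5], num, tolerance = 1e-4)
  noise2 <- noise
  noise2[[4]][7] <- noise2[[4]][7] + eps
  num <- (sum(gf(m, codes, noise2, 1)$img) - f0) / eps
  expect_equal(grads$dnoise[[4]][7], num, tolerance = 1e-4)
})

test_that("perceptual distance is a symmetric monotone pseudo-metric", {
  set.seed(21)
  x <- matrix(rnorm(256), 16, 16)
  expect_lte(perceptual_distance(x, x), 1e-6)
  y <- matrix(rnorm(256), 16, 16)
  expect_equal(perceptual_distance(x, y), perceptual_distance(y, x))
  noise <- matrix(rnorm(256), 16, 16)
  d <- vapply(c(0.1, 0.4, 1.0), function(a)
    perceptual_distance(x, x + a * noise, 8), 0)
  expect_true(all(diff(d) > 0))
  expect_error(perceptual_distance(x, y[1:8, 1:8]), "shape")
})

test_that("domain-guided loss follows its definition", {
  x <- matrix(rnorm(16), 4)
  expect_identical(domain_guided_loss(x, encode = function(z) z,
                                      synthesize = function(c) c), 0)
  # hand-computed two-dimensional stub: E(x) = (1,2), E(G(E(x))) = (0,4)
  enc <- local({
    first <- TRUE
    function(z) {
      if (first) { first <<- FALSE; c(1, 2) } else c(0, 4)
    }
  })
  expect_equal(domain_guided_loss(x, enc, function(c) c), 1.5)
  expect_gte(domain_guided_loss(x, function(z) rnorm(4),
                                function(c) matrix(0, 4, 4)), 0)
})

test_that("adversarial losses follow the non-saturating form and R1 schedule", {
  mz <- tiny_zero_model()     # D(x) = 0 everywhere, and constant => R1 = 0
  real <- list(matrix(rnorm(256), 16, 16))
  fake <- list(matrix(rnorm(256), 16, 16))
  on16 <- adversarial_step_losses(real, fake, 16, mz, units = "unit")
  expect_equal(on16$g_loss, log(2))
  expect_equal(on16$d_loss, 2 * log(2))
  expect_identical(on16$r1_term, 0)        # constant D has zero gradient
  off <- adversarial_step_losses(real, fake, 5, mz, units = "unit")
  expect_identical(off$r1_term, 0)
  # a random discriminator has a strictly positive penalty on scheduled steps
  m <- tiny_model()
  expect_gt(adversarial_step_losses(real, fake, 32, m, units = "unit")$r1_term, 0)
  expect_identical(adversarial_step_losses(real, fake, 33, m, units = "unit")$r1_term, 0)
  expect_error(adversarial_step_losses(list(), fake, 1, m), "non-empty")
})

test_that("random erasing touches exactly one rectangle, deterministically", {
  x <- matrix(rnorm(64 * 64), 64, 64)
  y <- random_erase(x, seed = 3)
  rect <- attr(y, "erase_rect")
  expect_false(is.null(rect))
  inside <- matrix(FALSE, 64, 64)
  inside[rect["row0"]:rect["row1"], rect["col0"]:rect["col1"]] <- TRUE
  expect_identical(y[!inside], x[!inside])
  expect_true(all(y[inside] == mean(x)))
  frac <- sum(inside) / length(x)
  expect_gte(frac, 0.05 * 0.8)
  expect_lte(frac, 0.25 * 1.2)
  expect_identical(unclass(y), unclass(random_erase(x, seed = 3)))
})

test_that("two-phase training freezes G in phase 2 and logs finite losses", {
  slices <- unlist(lapply(1:4, function(i)
    generate_normal_scan(100 + i, c(16, 16), 2)$slices), recursive = FALSE)
  cfg <- tiny_cfg()
  tc <- train_config(iters_phase1 = 6, iters_phase2 = 6, batch_size = 2,
                     r1_interval = 4, seed = 5)
  fit <- train_backbone(slices, cfg, tc)
  expect_identical(nrow(fit$log), 12L)
  expect_true(all(is.finite(fit$log$g_loss)))
  expect_true(all(is.finite(fit$log$d_loss)))
  expect_true(all(is.finite(fit$log$percep[fit$log$phase == 2])))
  # R1 only on scheduled steps
  expect_true(all(fit$log$r1[fit$log$step %% 4 != 0] == 0))
  # G frozen over phase 2: retrain phase 1 only and compare G weights
  fit1 <- train_backbone(slices, cfg,
                         train_config(iters_phase1 = 6, iters_phase2 = 0,
                                      batch_size = 2, r1_interval = 4, seed = 5))
  expect_identical(fit1$model$G, fit$model$G)
  # seeded training reproduces the loss log exactly
  fit2 <- train_backbone(slices, cfg, tc)
  expect_identical(fit$log, fit2$log)
  expect_error(train_backbone(list(), cfg, tc), "empty")
})

test_that("checkpoints reload bit-exactly", {
  m <- tiny_model()
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  w <- matrix(0.3, m$cfg$n_layers, m$cfg$style_dim)
  n <- sample_noise_maps(m, 1, seed = 8)
  expect_identical(generate_image(m, w, n), generate_image(m2, w, n))
  expect_error(load_checkpoint(tempfile()), "no checkpoint")
})
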