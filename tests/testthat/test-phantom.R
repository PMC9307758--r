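test_that("normal scans are deterministic in the seed and vary across seeds", {
  a <- generate_normal_scan(7, c(64, 64), 8)
  b <- generate_normal_scan(7, c(64, 64), 8)
  expect_identical(a, b)
  c <- generate_normal_scan(8, c(64, 64), 8)
  expect_true(any(a$slices[[1]] != c$slices[[1]]))
  expect_error(generate_normal_scan(1, c(64, 64), 0), "1..32")
  expect_error(generate_normal_scan(1, c(64, 64), 33), "1..32")
})

test_that("phantom HU values are plausible on the generator's own labels", {
  sc <- generate_normal_scan(11, c(64, 64), 8)
  for (k in seq_along(sc$slices)) {
    img <- sc$slices[[k]]; lab <- sc$labels[[k]]
    expect_true(all(img[lab == 0L] < -900))
    expect_true(all(img[lab == 1L] > 500))
    expect_true(all(img[lab == 2L] >= 20 & img[lab == 2L] <= 50))
    expect_true(all(img[lab == 3L] >= 0 & img[lab == 3L] <= 12))
    expect_gte(mean(img[lab == 2L]), 20)
    expect_lte(mean(img[lab == 2L]), 45)
  }
  # ventricle area grows monotonically with slice order
  va <- vapply(sc$labels, function(l) sum(l == 3L), 0L)
  expect_true(all(diff(va) > 0))
})

test_that("lesion injection returns the exact footprint and is invertible", {
  sc <- generate_normal_scan(5, c(64, 64), 8)
  spec <- lesion_spec("hyperdense", c(4, 32, 26), 6, 60)
  inj <- inject_lesion(sc, spec, seed = 2)
  m <- inj$mask[[4]]
  expect_gte(sum(m), 1)
  pre <- mean(sc$slices[[4]][m == 1])
  post <- mean(inj$scan$slices[[4]][m == 1])
  expect_gte(post - pre, 40)
  # mask == set of changed pixels, exactly
  diffpix <- inj$scan$slices[[4]] != sc$slices[[4]]
  expect_identical(m == 1L, diffpix)
  for (k in setdiff(seq_along(sc$slices), 4))
    expect_identical(inj$scan$slices[[k]], sc$slices[[k]])
  # subtracting delta inside the mask restores the original bit-exactly
  rec <- inj$scan$slices[[4]]
  rec[m == 1L] <- rec[m == 1L] - spec$delta_hu
  expect_identical(rec, sc$slices[[4]])
})

test_that("degenerate and invalid lesions behave per contract", {
  sc <- generate_normal_scan(5, c(64, 64), 8)
  tiny <- inject_lesion(sc, lesion_spec("hyperdense", c(1, 32, 32), 1e-9, 10), 1)
  expect_identical(sum(tiny$mask[[1]]), 1L)
  expect_error(inject_lesion(sc, lesion_spec("hyperdense", c(1, 2, 2), 3, 10), 1),
               "brain")
  expect_error(lesion_spec("hyperdense", c(1, 5, 5), 3, -10), "delta_hu > 0")
  expect_error(lesion_spec("hypodense", c(1, 5, 5), 3, 10), "delta_hu < 0")
  expect_error(lesion_spec("mass", c(1, 5, 5), 0, 10), "radius_px")
})

test_that("mass lesions displace tissue and the footprint covers it", {
  sc <- generate_normal_scan(9, c(64, 64), 4)
  spec <- lesion_spec("mass", c(2, 32, 24), 5, 50, midline_shift_px = 3)
  inj <- inject_lesion(sc, spec, 1)
  m <- inj$mask[[2]]
  diffpix <- inj$scan$slices[[2]] != sc$slices[[2]]
  expect_identical(m == 1L, diffpix)
  # displaced zone extends beyond the core disc
  expect_gt(sum(m), pi * 5^2 * 0.8 + 10)
})

test_that("cohorts have the requested prevalence structure", {
  coh <- generate_cohort(100, 0.11, seed = 1, shape = c(32, 32), n_slices = 2)
  n_em <- sum(coh$manifest$is_emergency)
  expect_gte(n_em, 5)    # binomial 99% interval for p = 0.11, n = 100
  expect_lte(n_em, 19)
  expect_identical(coh$manifest$is_emergency,
                   coh$manifest$category %in% c("urgent", "immediate"))
  for (cid in coh$manifest$case_id[coh$manifest$is_emergency])
    expect_gt(sum(vapply(coh$masks[[cid]], sum, 0)), 0)
  coh0 <- generate_cohort(40, 0, seed = 2, shape = c(32, 32), n_slices = 2)
  expect_identical(sum(coh0$manifest$is_emergency), 0L)
  expect_error(generate_cohort(10, 1.2, 1), "prevalence")
  # determinism
  coh2 <- generate_cohort(100, 0.11, seed = 1, shape = c(32, 32), n_slices = 2)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$scans[[3]], coh2$scans[[3]])
})
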