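test_that("dose decay correction follows the half-life law", {
  expect_equal(decay_correct_dose(9, 0), 9)
  expect_equal(decay_correct_dose(9, 109.77), 4.5)
  expect_equal(decay_correct_dose(9, 10), 8.449263, tolerance = 1e-6)
  # assay after injection: corrected dose exceeds the assayed value
  expect_gt(decay_correct_dose(9, -10), 9)
})

test_that("SUV conversion is dose-per-weight normalization", {
  m <- scan_meta(injected_dose_MBq = 8.3, body_weight_g = 25)
  v <- image_volume(array(8.3e6 / 25, c(3, 3, 3)), spacing = 0.4,
                    units = "Bq_per_ml")
  expect_equal(unique(as.numeric(to_suv(v, m)$values)), 1)
  vk <- image_volume(array(332, c(3, 3, 3)), spacing = 0.4,
                     units = "kBq_per_ml")
  expect_equal(unique(as.numeric(to_suv(vk, m)$values)), 1)
  m2 <- scan_meta(injected_dose_MBq = 8.3, body_weight_g = 50)
  expect_equal(to_suv(vk, m2)$values, 2 * to_suv(vk, m)$values)
  bad <- image_volume(array(1, c(3, 3, 3)), spacing = 0.4, units = "SUV")
  expect_error(to_suv(bad, m), "Bq_per_ml")
})

test_that("isocontour threshold is 40% of SUVmax, displayed to 1 decimal", {
  sh <- c(12, 12, 12)
  img <- array(0.2, sh)
  img[5:7, 5:7, 5:7] <- 2
  img[6, 6, 6] <- 3.8
  suv <- image_volume(img, spacing = 0.4, units = "SUV")
  search <- voi_mask(array(TRUE, sh), spacing = 0.4)
  seg <- segment_iso40(suv, search)
  expect_equal(seg$suv_max, 3.8)
  expect_equal(seg$threshold, 1.52)
  expect_equal(seg$threshold_display, 1.5)
  # cohort-mean SUVmax 3.9 displays as 1.6
  img[6, 6, 6] <- 3.9
  seg2 <- segment_iso40(image_volume(img, spacing = 0.4, units = "SUV"),
                        search)
  expect_equal(seg2$threshold_display, 1.6)
})

test_that("a uniform hot sphere is segmented exactly", {
  sh <- c(24L, 24L, 24L)
  sphere <- ellipsoid_mask(sh, rep(0.4, 3), c(4.6, 4.6, 4.6), rep(2, 3))
  img <- array(0.1, sh); img[sphere] <- 4.0
  suv <- image_volume(img, spacing = 0.4, units = "SUV")
  seg <- segment_iso40(suv, voi_mask(array(TRUE, sh), spacing = 0.4))
  expect_identical(seg$mask$values, sphere)
  expect_equal(seg$threshold, 1.6)
})

test_that("isocontour component matches a brute-force flood fill", {
  set.seed(5)
  sh <- c(16L, 16L, 16L)
  base <- array(0, sh)
  base[ellipsoid_mask(sh, rep(0.4, 3), c(2.6, 2.6, 3), rep(1.4, 3))] <- 4
  base[ellipsoid_mask(sh, rep(0.4, 3), c(4.6, 4.6, 3), rep(1, 3))] <- 3
  img <- blur3d(base, rep(1.2, 3)) + array(runif(prod(sh), 0, 0.05), sh)
  suv <- image_volume(img, spacing = 0.4, units = "SUV")
  search <- voi_mask(array(TRUE, sh), spacing = 0.4)
  seg <- segment_iso40(suv, search)
  idx <- which.max(img)
  oracle <- flood_oracle(img >= 0.4 * max(img), idx)
  expect_identical(seg$mask$values, oracle)
  # invariants: every mask voxel above threshold, max voxel inside
  expect_true(all(img[seg$mask$values] >= seg$threshold))
  expect_true(seg$mask$values[idx])
})

test_that("exclusion masks remove organs from the search region", {
  sh <- c(10, 10, 10)
  img <- array(0.2, sh)
  img[2, 2, 2] <- 9           # "bladder" hot spot
  img[7, 7, 7] <- 3
  suv <- image_volume(img, spacing = 0.4, units = "SUV")
  search <- voi_mask(array(TRUE, sh), spacing = 0.4)
  excl <- array(FALSE, sh); excl[1:3, 1:3, 1:3] <- TRUE
  seg <- segment_iso40(suv, search, list(voi_mask(excl, spacing = 0.4)))
  expect_equal(seg$suv_max, 3)
  expect_false(seg$mask$values[2, 2, 2])
  expect_error(segment_iso40(suv, voi_mask(excl, spacing = 0.4),
                             list(voi_mask(excl, spacing = 0.4))),
               "empty")
})

test_that("fixed-threshold rule keeps all qualifying voxels, no filter", {
  sh <- c(10, 10, 10)
  img <- array(0.2, sh)
  img[2, 2, 2] <- 3; img[8, 8, 8] <- 3.4       # two separate islands
  suv <- image_volume(img, spacing = 0.4, units = "SUV")
  search <- voi_mask(array(TRUE, sh), spacing = 0.4)
  m <- segment_fixed(suv, search, threshold = 2.5)
  expect_equal(mask_count(m), 2L)               # union of components
  # empty result is flagged, not an error
  low <- segment_fixed(image_volume(array(2.4, sh), spacing = 0.4,
                                    units = "SUV"), search)
  expect_true(low$empty)
  # threshold 0 returns the whole search region
  all_in <- segment_fixed(suv, search, threshold = 0)
  expect_equal(mask_count(all_in), prod(sh))
  # raising the threshold never grows the mask
  sizes <- vapply(c(0.5, 1.5, 2.5, 3.2), function(th)
    mask_count(segment_fixed(suv, search, threshold = th)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("iso40 volume exceeds the fixed-2.5 volume when 40% max < 2.5", {
  sh <- c(24L, 24L, 24L)
  base <- array(0.1, sh)
  sphere <- ellipsoid_mask(sh, rep(0.4, 3), rep(4.6, 3), rep(2.4, 3))
  base[sphere] <- 3.8
  img <- blur3d(base, rep(1, 3))
  suv <- image_volume(img, spacing = 0.4, units = "SUV")
  search <- voi_mask(array(TRUE, sh), spacing = 0.4)
  seg <- segment_iso40(suv, search)
  fx <- segment_fixed(suv, search, threshold = 2.5)
  expect_lt(0.4 * seg$suv_max, 2.5)
  expect_gt(static_metrics(suv, seg$mask)$mtv_mm3,
            static_metrics(suv, fx)$mtv_mm3)
  # the fixed mask is nested inside the isocontour mask
  expect_true(all(seg$mask$values[fx$values]))
})

test_that("static metrics match arithmetic and the brute-force oracle", {
  sh <- c(10, 10, 10)
  img <- array(0.5, sh)
  m <- array(FALSE, sh); m[1:4, 1:5, 1:5] <- TRUE   # 100 voxels
  img[m] <- 2.0
  suv <- image_volume(img, spacing = 0.4, units = "SUV")
  met <- static_metrics(suv, voi_mask(m, spacing = 0.4), rule = "iso40")
  expect_equal(met$mtv_mm3, 6.4)
  expect_equal(met$suv_mean, 2.0)
  expect_equal(met$tlg, 12.8)
  # TLG identity and oracle equality on a random phantom
  ph <- random_suv_phantom(seed = 42)
  met2 <- static_metrics(ph$vol, ph$mask)
  vals <- ph$vol$values[ph$mask$values]
  expect_identical(met2$tlg, met2$suv_mean * met2$mtv_mm3)
  expect_equal(met2$suv_max, max(vals))
  expect_equal(met2$suv_mean, mean(vals))
  expect_equal(met2$mtv_mm3, sum(ph$mask$values) * 0.4^3)
  expect_error(static_metrics(ph$vol, voi_mask(array(FALSE, dim(ph$vol$values)),
                                               spacing = 0.4)), "empty")
})

test_that("liver reference is the masked mean SUV", {
  sh <- c(6, 6, 6)
  suv <- image_volume(array(0.53, sh), spacing = 0.4, units = "SUV")
  liver <- voi_mask(array(TRUE, sh), spacing = 0.4)
  expect_equal(liver_reference(suv, liver), 0.53)
  ph <- random_suv_phantom(seed = 3)
  expect_equal(liver_reference(ph$vol, ph$mask),
               mean(ph$vol$values[ph$mask$values]))
  expect_error(liver_reference(suv, voi_mask(array(FALSE, sh),
                                             spacing = 0.4)), "empty")
})
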