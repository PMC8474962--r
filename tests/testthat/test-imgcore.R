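test_that("volume write/read round-trips values, spacing, units", {
  v <- image_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                    spacing = c(0.4, 0.4, 0.4), origin = c(1, 2, 3),
                    units = "kBq_per_ml")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(r$values, v$values, tolerance = 0)
  expect_lt(max(abs(r$spacing - v$spacing)), 1e-6)
  expect_identical(r$units, "kBq_per_ml")
  expect_equal(r$origin, c(1, 2, 3))
  expect_equal(voxel_volume(r), 0.4^3, tolerance = 1e-6)
})

test_that("missing sidecar flags unknown units", {
  v <- image_volume(array(1, c(3, 3, 3)), spacing = 0.4)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  file.remove(sub("\\.nii\\.gz$", ".json", path))
  expect_identical(read_volume(path)$units, "unknown")
})

test_that("negative header spacings are normalized with flips recorded", {
  ns <- petmrq:::normalize_spacing(c(-0.4, 0.5, 0.6))
  expect_equal(ns$spacing, c(0.4, 0.5, 0.6))
  expect_equal(ns$flipped, c(TRUE, FALSE, FALSE))
  expect_error(petmrq:::normalize_spacing(c(0, 1, 1)), "zero")

  # byte-patch a negative dx into a real header; the reader must agree
  # with the reference reader and deliver strictly positive spacing
  v <- image_volume(array(as.numeric(1:24), c(2, 3, 4)),
                    spacing = c(0.4, 0.5, 0.6), units = "SUV")
  path <- tempfile(fileext = ".nii")
  write_volume(v, path)
  con <- file(path, "r+b")
  seek(con, 80, rw = "write")
  writeBin(c(-0.4), con, size = 4)
  close(con)
  r <- read_volume(path)
  ref <- abs(RNifti::pixdim(RNifti::readNifti(path))[1:3])
  expect_true(all(r$spacing > 0))
  expect_equal(r$spacing, unname(ref))
  expect_equal(r$values, v$values)
})

test_that("image_volume and voi_mask validate geometry", {
  expect_error(image_volume(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
  expect_error(image_volume(array(1, c(2, 2, 2, 2)), spacing = 0.4), "3D")
  ref <- image_volume(array(0, c(3, 3, 3)), spacing = 0.4)
  expect_error(voi_mask(array(TRUE, c(2, 3, 3)), reference = ref),
               "shape")
  m <- voi_mask(array(FALSE, c(3, 3, 3)), reference = ref)
  expect_true(m$empty)
  expect_identical(mask_count(m), 0L)
  expect_error(scan_meta(injected_dose_MBq = -1, body_weight_g = 25),
               "dose")
})

test_that("the 1-h dynamic frame scheme has the published structure", {
  sch <- dynamic_1h_schedule()
  expect_length(sch, 19L)
  expect_equal(sum(sch$durations_s), 3600)
  expect_equal(tail(mid_times(sch, "s"), 1), 3300)
  expect_equal(mid_times(sch, "min"), mid_times(sch, "s") / 60)
  expect_equal(sch$starts_s[1], 0)
})

test_that("frame_schedule rejects malformed timing", {
  expect_error(frame_schedule(c(0, 2, 1), rep(1, 3)), "increasing")
  expect_error(frame_schedule(c(0, 2), c(2, 0)), "> 0")
  expect_error(frame_schedule(c(0, 5), c(2, 2), contiguous = TRUE), "gaps")
  sch <- frame_schedule(c(0, 5), c(2, 2), contiguous = FALSE)
  expect_length(sch, 2L)
})

test_that("dynamic series round-trips through 4D NIfTI + schedule CSV", {
  sch <- frame_schedule(c(0, 2, 4), c(2, 2, 10))
  frames <- lapply(1:3, function(i)
    image_volume(array(rnorm(27), c(3, 3, 3)) + i, spacing = 0.4,
                 units = "kBq_per_ml"))
  ds <- dynamic_series(frames, sch)
  p <- tempfile(fileext = ".nii.gz"); sp <- tempfile(fileext = ".csv")
  write_dynamic(ds, p, sp)
  r <- read_dynamic(p, sp)
  expect_length(r, 3L)
  expect_equal(r$frames[[2]]$values, frames[[2]]$values)
  expect_equal(r$schedule$starts_s, sch$starts_s)
  expect_identical(r$frames[[1]]$units, "kBq_per_ml")

  # shuffled schedule rows give the same series as sorted input
  tab <- read.csv(sp)
  write.csv(tab[c(3, 1, 2), ], sp, row.names = FALSE)
  r2 <- read_dynamic(p, sp)
  expect_equal(r2$schedule$starts_s, sch$starts_s)
  expect_equal(r2$frames[[3]]$values, frames[[3]]$values)

  # frame-count mismatch is a hard error
  write.csv(tab[1:2, ], sp, row.names = FALSE)
  expect_error(read_dynamic(p, sp), "mismatch")
  # 3D reader refuses true 4D input
  expect_error(read_volume(p), "read_dynamic")
})

test_that("single-frame 4D file reads as a length-1 series", {
  sch <- frame_schedule(0, 60)
  ds <- dynamic_series(list(image_volume(array(1, c(3, 3, 3)),
                                         spacing = 0.4)), sch)
  p <- tempfile(fileext = ".nii.gz"); sp <- tempfile(fileext = ".csv")
  write_dynamic(ds, p, sp)
  expect_length(read_dynamic(p, sp), 1L)
})

test_that("mask resampling preserves world-coordinate placement", {
  ref <- image_volume(array(0, c(20, 20, 20)), spacing = 0.5)
  cube <- array(FALSE, c(20, 20, 20))
  cube[6:15, 6:15, 6:15] <- TRUE               # world span [2.5, 7] mm
  m <- voi_mask(cube, spacing = 0.5, label = "cube")
  # identical grid: identity
  expect_identical(resample_mask_to(m, ref)$values, m$values)
  # empty in, empty out
  e <- voi_mask(array(FALSE, c(20, 20, 20)), spacing = 0.5)
  expect_true(suppressWarnings(resample_mask_to(e, ref))$empty)

  # 2x coarser target: count drops ~8x; oracle = nearest-source-voxel
  # membership evaluated directly in world coordinates
  tgt <- image_volume(array(0, c(10, 10, 10)), spacing = 1.0)
  r <- resample_mask_to(m, tgt)
  expected <- array(FALSE, c(10, 10, 10))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    w <- (c(i, j, k) - 1) * 1.0
    src <- round(w / 0.5) + 1
    expected[i, j, k] <- all(src >= 6) && all(src <= 15)
  }
  expect_identical(r$values, expected)
  expect_lt(abs(sum(r$values) * 1 - sum(cube) * 0.5^3), 0.3 * 125)

  # disjoint fields of view: empty + warning
  far <- image_volume(array(0, c(5, 5, 5)), spacing = 0.5,
                      origin = c(100, 100, 100))
  expect_warning(rr <- resample_mask_to(m, far), "empty")
  expect_true(rr$empty)
})
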