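test_that("fully separated 5-vs-4 groups give the exact tail p", {
  mw <- mann_whitney_exact(1:5, 6:9)
  expect_equal(mw$u, 0)
  expect_equal(mw$p_two_sided, 2 / 126, tolerance = 1e-12)
  expect_identical(mw$method, "exact")
})

test_that("the test is symmetric in its two groups", {
  set.seed(2)
  x <- rnorm(5); y <- rnorm(4) + 1
  a <- mann_whitney_exact(x, y)
  b <- mann_whitney_exact(y, x)
  expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
  expect_equal(b$u, length(x) * length(y) - a$u)
})

test_that("identical tied samples give p = 1", {
  mw <- mann_whitney_exact(c(2, 2, 2), c(2, 2))
  expect_equal(mw$p_two_sided, 1)
})

test_that("exact p equals brute-force enumeration, with and without ties", {
  set.seed(11)
  for (trial in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1), sample(0:1, 1))     # rounding induces ties
    y <- round(rnorm(n2), 1)
    mine <- mann_whitney_exact(x, y)
    oracle <- mw_oracle(x, y)
    expect_equal(mine$u, oracle$u, tolerance = 1e-12)
    expect_equal(mine$p_two_sided, oracle$p, tolerance = 1e-12)
  }
})

test_that("exact p agrees with the standard implementation when tie-free", {
  set.seed(4)
  for (trial in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    mine <- mann_whitney_exact(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(7)
  x <- rnorm(15); y <- rnorm(12) + 0.8
  mine <- mann_whitney_exact(x, y)
  expect_identical(mine$method, "normal_approx")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-9)
})

test_that("the exact test controls type-I error at n = 5 vs 4", {
  set.seed(123)
  rej <- mean(vapply(1:2000, function(i)
    mann_whitney_exact(runif(5), runif(4))$p_two_sided <= 0.05,
    logical(1)))
  expect_lte(rej, 0.05)
  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("normality screen behaves on normal and exponential samples", {
  normal_ok <- vapply(1:100, function(s) {
    set.seed(s); shapiro_wilk(rnorm(500))$p > 0.05
  }, logical(1))
  expect_gte(sum(normal_ok), 95)
  expo_flag <- vapply(1:100, function(s) {
    set.seed(s); shapiro_wilk(rexp(50))$p < 0.05
  }, logical(1))
  expect_gte(sum(expo_flag), 95)
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
  expect_error(shapiro_wilk(1:2), "3 <= n")
})

test_that("linear fit recovers exact lines and degenerate cases", {
  x <- c(1, 2, 3, 5, 8)
  f <- linear_r2(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  fc <- linear_r2(x, rep(4, 5))
  expect_equal(fc$r2, 0)
  expect_error(linear_r2(rep(1, 5), x), "variance")
  expect_error(linear_r2(1:2, 1:2), ">= 3")
})

test_that("volume couplings in the simulated cohort are strongly linear", {
  df <- as.data.frame(simulate_cohort(seed = 42))
  t2 <- df[df$modality == "T2", c("mouse_id", "week", "vmri_mm3")]
  pet <- df[df$modality == "PET", c("mouse_id", "week", "mtv_mm3")]
  paired <- merge(t2, pet, by = c("mouse_id", "week"))
  expect_gte(linear_r2(paired$vmri_mm3, paired$mtv_mm3)$r2, 0.8)
})

test_that("Spearman rho and exact permutation p match the oracle", {
  x <- c(0.2, 1.4, 2.2, 3.9, 5.1, 6.0)
  expect_equal(spearman_r(x, exp(x))$rho, 1)
  expect_equal(spearman_r(x, -x^3)$rho, -1)
  set.seed(21)
  for (trial in 1:5) {
    xx <- rnorm(6); yy <- rnorm(6)
    mine <- spearman_r(xx, yy)
    expect_identical(mine$method, "exact")
    expect_equal(mine$p, spearman_oracle(xx, yy), tolerance = 1e-12)
    expect_equal(mine$rho, cor(xx, yy, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman_r(rep(1, 5), rnorm(5)), "constant")
})

test_that("Spearman rho is invariant under monotone transforms", {
  set.seed(31)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- spearman_r(x, y)$rho
  expect_equal(spearman_r(exp(x), y)$rho, r0)
  expect_equal(spearman_r(x, y^3 + 5 * y)$rho, r0)
})

test_that("treatment report flags the expected effect directions", {
  df <- as.data.frame(simulate_cohort(seed = 42))
  rep42 <- treatment_report(df[df$phase == "endpoint", ])
  expect_true(all(rep42$direction_ok))
  expect_true(all(rep42$p < 0.05))

  # arms fully separated on every marker: p = 2/126 each
  sep <- data.frame(
    arm = c(rep("treated", 5), rep("control", 4)),
    adc_mean_mm2_s = c(11:15, 1:4) * 1e-4,
    vmri_mm3 = c(1:5, 11:14) * 100,
    density_cells_mm2 = c(1:5, 11:14) * 1000)
  rs <- treatment_report(sep)
  expect_equal(rs$p, rep(2 / 126, 3), tolerance = 1e-12)
  expect_true(all(rs$direction_ok))

  # identical arms: p in the no-evidence region, no direction claimed
  same <- data.frame(
    arm = c(rep("treated", 4), rep("control", 4)),
    adc_mean_mm2_s = rep(1e-3, 8), vmri_mm3 = rep(500, 8),
    density_cells_mm2 = rep(1e4, 8))
  ri <- treatment_report(same)
  expect_true(all(ri$p == 1))
  expect_true(all(is.na(ri$direction_ok)))
  expect_error(treatment_report(sep[sep$arm == "treated", ]), "both")
})
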