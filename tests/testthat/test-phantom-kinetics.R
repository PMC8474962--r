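test_that("bolus input function follows its closed form", {
  p <- aif_params()
  expect_identical(feng_aif(p, 0), 0)
  # A2 = A3 = 0 reduces to A1 t exp(-lam1 t), peaking at t = 1/lam1
  p0 <- aif_params(A1 = 100, A2 = 0, A3 = 0, lam1 = 2.5)
  tg <- seq(0, 5, by = 1e-4)
  cp <- feng_aif(p0, tg)
  expect_equal(cp, 100 * tg * exp(-2.5 * tg), tolerance = 1e-12)
  expect_equal(tg[which.max(cp)], 1 / 2.5, tolerance = 1e-3)
})

test_that("default bolus peaks before 2 min and decays monotonically", {
  tg <- seq(0, 60, by = 0.01)
  cp <- feng_aif(aif_params(), tg)
  pk <- which.max(cp)
  expect_lt(tg[pk], 2)
  expect_true(all(diff(cp[pk:length(cp)]) <= 1e-9))
  expect_true(all(cp >= 0))
})

test_that("parameter sets that go negative are rejected", {
  bad <- aif_params(A1 = 0.001, A2 = 100, A3 = 0.001, lam1 = 0.1, lam2 = 5)
  expect_error(feng_aif(bad, seq(0, 10, by = 0.1)), "negative")
})

test_that("K1 = 0 collapses the tissue curve to the blood term", {
  sch <- dynamic_1h_schedule()
  aif <- aif_params()
  kin <- two_tc_params(K1 = 0, k2 = 0.2, k3 = 0.05, vb = 0.3)
  tt <- simulate_2tc_tac(aif, kin, sch)
  cp <- aif_frame_tac(aif, sch)
  expect_equal(tt$conc, 0.3 * cp$conc, tolerance = 1e-10)
})

test_that("k2 = k3 = 0 matches the quadrature oracle", {
  sch <- dynamic_1h_schedule()
  aif <- aif_params()
  kin <- two_tc_params(K1 = 0.15, k2 = 0, k3 = 0, vb = 0.1)
  tt <- simulate_2tc_tac(aif, kin, sch)
  t_fine <- seq(0, 60, by = 1 / 600)          # 0.1 s
  cp_fine <- feng_aif(aif, t_fine)
  auc <- c(0, cumsum((cp_fine[-1] + cp_fine[-length(cp_fine)]) / 2 *
                       diff(t_fine)))
  ct_fine <- (1 - 0.1) * 0.15 * auc + 0.1 * cp_fine
  expected <- frame_avg_oracle(ct_fine, t_fine * 60, sch)
  expect_equal(tt$conc, expected, tolerance = 1e-6)
})

test_that("simulator agrees with an adaptive stiff integrator", {
  skip_if_not_installed("deSolve")
  sch <- dynamic_1h_schedule()
  aif <- aif_params()
  kin <- two_tc_params(K1 = 0.1, k2 = 0.2, k3 = 0.05, vb = 0)
  tt <- simulate_2tc_tac(aif, kin, sch)
  rhs <- function(t, y, p)
    list(c(p$K1 * feng_aif(aif, t) - (p$k2 + p$k3) * y[1], p$k3 * y[1]))
  t_fine <- seq(0, 60, by = 0.001)
  sol <- deSolve::ode(c(0, 0), t_fine, rhs,
                      list(K1 = 0.1, k2 = 0.2, k3 = 0.05),
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  ct <- sol[, 2] + sol[, 3]
  expected <- frame_avg_oracle(ct, t_fine * 60, sch)
  # absolute agreement everywhere (bolus-frame values are interpolation
  # limited); tight relative agreement once real signal has built up
  expect_lt(max(abs(tt$conc - expected)), 0.05)
  big <- expected > 50
  expect_lt(max(abs(tt$conc[big] / expected[big] - 1)), 1e-4)
})

test_that("Patlak recovers an exact synthetic line perfectly", {
  t <- mid_times(dynamic_1h_schedule())
  cp <- tac(t, rep(1, length(t)))
  # with Cp == 1, x = t, y = CT, so CT = 0.02 t + 0.05 is an exact line
  ct <- tac(t, 0.02 * t + 0.05)
  f <- patlak_fit(ct, cp, t_star_min = 20)
  expect_equal(f$ki, 0.02, tolerance = 1e-12)
  # the (0,0) AUC anchor shifts x by half the first mid-time, displacing
  # the intercept by Ki * t1 / 2 (~3e-4 here) but never the slope
  expect_equal(f$intercept, 0.05, tolerance = 0.01)
  expect_equal(f$rel_se_pct, 0, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_true(f$qc_pass)
})

test_that("Patlak on noiseless 2TC data recovers closed-form Ki within 2%", {
  sch <- dynamic_1h_schedule()
  aif <- aif_params()
  for (kin in list(two_tc_params(K1 = 0.1, k2 = 0.2, k3 = 0.05, vb = 0),
                   two_tc_params())) {
    tt <- simulate_2tc_tac(aif, kin, sch)
    cp <- aif_frame_tac(aif, sch)
    f <- patlak_fit(tt, cp, t_star_min = 20)
    expect_lt(abs(f$ki / ki_2tc(kin) - 1), 0.02)
  }
})

test_that("Ki is insensitive to t* beyond equilibration", {
  sch <- dynamic_1h_schedule()
  aif <- aif_params()
  tt <- simulate_2tc_tac(aif, two_tc_params(), sch)
  cp <- aif_frame_tac(aif, sch)
  k20 <- patlak_fit(tt, cp, 20)$ki
  k30 <- patlak_fit(tt, cp, 30)$ki
  expect_lt(abs(k30 / k20 - 1), 0.005)
})

test_that("Patlak scale invariances hold", {
  sch <- dynamic_1h_schedule()
  aif <- aif_params()
  tt <- simulate_2tc_tac(aif, two_tc_params(), sch)
  cp <- aif_frame_tac(aif, sch)
  f0 <- patlak_fit(tt, cp, 20)
  both <- patlak_fit(tac(tt$mid_min, 3.7 * tt$conc),
                     tac(cp$mid_min, 3.7 * cp$conc), 20)
  expect_equal(both$ki, f0$ki, tolerance = 1e-12)
  ct_only <- patlak_fit(tac(tt$mid_min, 3.7 * tt$conc), cp, 20)
  expect_equal(ct_only$ki, 3.7 * f0$ki, tolerance = 1e-12)
})

test_that("Patlak rejects unusable inputs", {
  t <- mid_times(dynamic_1h_schedule())
  cp <- tac(t, rep(1, length(t)))
  ct <- tac(t, t)
  expect_error(patlak_fit(ct, cp, t_star_min = 50), ">= 3 frames")
  cp_bad <- tac(t, c(rep(1, length(t) - 2), 0, -1))
  expect_error(patlak_fit(ct, cp_bad, 20), "nonpositive")
  expect_error(patlak_fit(ct, tac(t[-1], rep(1, length(t) - 1)), 20),
               "time grid")
})
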