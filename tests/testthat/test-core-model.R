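test_that("allometric typical values reproduce the published scaling", {
  m <- population_model()
  expect_equal(typical_clearance(m, 70), 13.1)
  expect_equal(round(typical_clearance(m, 5), 3), 1.810)
  expect_equal(round(typical_clearance(m, 5) / 5, 2), 0.36)
  expect_equal(round(typical_clearance(m, 20), 3), 5.119)
  expect_equal(round(typical_clearance(m, 20) / 20, 2), 0.26)
  expect_equal(typical_volume(m, 70), 10900)
  expect_equal(typical_volume(m, 7), 1090)
  expect_equal(typical_volume(m, 35), 5450)
  expect_error(typical_clearance(m, 0), "positive")
  expect_error(typical_volume(m, -1), "positive")
})

test_that("typical values increase with weight, per-kg clearance decreases", {
  m <- population_model()
  w <- seq(3, 40, by = 0.5)
  expect_true(all(diff(typical_clearance(m, w)) > 0))
  expect_true(all(diff(typical_volume(m, w)) > 0))
  expect_true(all(diff(typical_clearance(m, w) / w) < 0))
})

test_that("individual_params applies lognormal random effects around typicals", {
  m <- population_model()
  p0 <- individual_params(m, 70, random_effects(0, 0))
  expect_equal(c(p0$cl_f, p0$v_f, p0$ka), c(13.1, 10900, 4.48))
  p2 <- individual_params(m, 70, random_effects(log(2), 0))
  expect_equal(p2$cl_f, 26.2)
  set.seed(42)
  cl <- typical_clearance(m, 70) * exp(rnorm(1e5, 0, 0.451))
  expect_lt(abs(median(cl) - 13.1) / 13.1, 0.01)
  # log CL is normal with SD omega_cl
  ks <- suppressWarnings(stats::ks.test(log(cl / 13.1) / 0.451, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("concentration_profile: zero before dosing, linear in dose, split-invariant", {
  p <- pk_params(3.044, 1557, 4.48)
  doses <- data.frame(time = c(12, 24), amount = c(3, 3))
  expect_equal(concentration_profile(p, doses, c(0, 5, 11.999)), c(0, 0, 0))
  tt <- c(13, 26, 48, 96)
  c1 <- concentration_profile(p, doses, tt)
  c2 <- concentration_profile(p, transform(doses, amount = 2 * amount), tt)
  expect_equal(c2, 2 * c1)
  split <- data.frame(time = c(12, 12, 24, 24), amount = c(1, 2, 1.5, 1.5))
  expect_equal(concentration_profile(p, split, tt), c1)
})

test_that("closed-form profile matches RK4 integration of the ODE system", {
  p <- pk_params(3.044, 1557, 4.48)
  dt <- seq(0, 72, by = 12)
  da <- rep(3, length(dt))
  tt <- c(2, 6, 12, 24, 36, 60, 84)
  a <- concentration_profile(p, data.frame(time = dt, amount = da), tt)
  b <- ode_profile(3.044, 1557, 4.48, dt, da, tt)
  expect_lt(max(abs(a - b) / abs(b)), 1e-6)
})

test_that("ka ~ ke limit branch stays continuous and positive", {
  # force ke into the ka neighbourhood: cl/v = 4.48 * (1 +/- tiny)
  v <- 10
  tt <- c(0.5, 1, 2, 5)
  doses <- data.frame(time = 0, amount = 5)
  near <- concentration_profile(pk_params(4.48 * v * (1 + 1e-13), v, 4.48), doses, tt)
  limit_exact <- 5 * 4.48 * tt / v * exp(-4.48 * tt) * 1000
  expect_equal(near, limit_exact, tolerance = 1e-6)
  just_outside <- concentration_profile(pk_params(4.48 * v * (1 + 1e-6), v, 4.48),
                                        doses, tt)
  expect_equal(just_outside, limit_exact, tolerance = 1e-4)
  expect_true(all(near > 0))
})

test_that("pk_params rejects non-positive values and exact flip-flop", {
  expect_error(pk_params(0, 100, 4.48))
  expect_error(pk_params(10, 100, 0))
  expect_error(pk_params(448, 100, 4.48), "separable")
})

test_that("residual-error model: direct evaluation and variance calibration", {
  m <- population_model()
  expect_equal(apply_residual_error(m, 10, c(0, 0)), 10)
  expect_equal(apply_residual_error(m, 10, c(0.1, -0.5)), 10.5)
  expect_error(apply_residual_error(m, -1, c(0, 0)))
  set.seed(7)
  n <- 1e6
  eps <- cbind(rnorm(n, 0, m$sigma_prop), rnorm(n, 0, m$sigma_add))
  y <- apply_residual_error(m, rep(10, n), eps)
  expected_sd <- sqrt(10^2 * 0.257^2 + 1.265^2)  # 2.867
  expect_lt(abs(sd(y) - expected_sd) / expected_sd, 0.01)
})

test_that("profile agrees with the ODE oracle on randomized parameter sets", {
  set.seed(101)
  m <- population_model()
  for (r in 1:10) {
    wt <- runif(1, 4, 20)
    cl <- typical_clearance(m, wt) * exp(rnorm(1, 0, 0.45))
    v <- typical_volume(m, wt) * exp(rnorm(1, 0, 0.59))
    dt <- seq(0, 72, by = 12)
    da <- rep(wt * runif(1, 0.05, 0.4), length(dt))
    tt <- sort(sample(seq(2, 84, by = 2), 5))
    a <- concentration_profile(pk_params(cl, v, 4.48),
                               data.frame(time = dt, amount = da), tt)
    b <- ode_profile(cl, v, 4.48, dt, da, tt)
    expect_lt(max(abs(a - b) / abs(b)), 1e-6)
  }
})
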