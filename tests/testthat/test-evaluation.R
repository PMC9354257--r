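test_that("bias_percent reproduces every published bootstrap bias cell", {
  est <- c(13.1, 109, 0.451, 0.592, 0.257, 1.265)
  med <- c(12.8, 107, 0.444, 0.546, 0.258, 1.233)
  expect_equal(bias_percent(est, med),
               c(-2.290, -1.835, -1.552, -7.770, 0.389, -2.530))
  expect_equal(bias_percent(5.7, 5.7), 0)
  expect_error(bias_percent(0, 1), "zero estimate")
})

test_that("diagnostics: perfect fit gives zero residuals; rows are conserved", {
  # data generated with zero variability from the typical model, fitted model
  # forced to the truth with omegas ~ 0: IPRED = PRED = DV
  m0 <- population_model(omega_cl = 0, omega_v = 0, sigma_prop = 0.1,
                         sigma_add = 0.5)
  d <- simulate_toy(3, c(6, 8, 10),
                    population_model(omega_cl = 0, omega_v = 0,
                                     sigma_prop = 0, sigma_add = 1e-9),
                    obs_days = c(2, 4, 6), seed = 6)
  f <- fit_popmodel(d, start = m0,
                    fixed = c("ka", "tv_cl", "tv_v", "omega_cl", "omega_v",
                              "sigma_prop", "sigma_add"))
  tab <- diagnostics(d, f)
  expect_equal(nrow(tab), sum(d$EVID == 0))
  expect_equal(tab$PRED, tab$IPRED)
  expect_lt(max(abs(tab$DV - tab$IPRED)), 2e-4)  # DVs rounded to 4 decimals
  expect_lt(max(abs(tab$IWRES)), 1e-3)
})

test_that("additive-only single subject: iWRES is (DV - IPRED)/sigma_add", {
  m <- population_model(omega_cl = 0.3, omega_v = 0.3, sigma_prop = 0,
                        sigma_add = 1.1)
  d <- simulate_toy(1, 8, m, obs_days = c(2, 4, 6, 9), seed = 44)
  f <- fit_popmodel(d, start = m,
                    fixed = c("ka", "tv_cl", "tv_v", "omega_cl", "omega_v",
                              "sigma_prop", "sigma_add"))
  tab <- diagnostics(d, f)
  expect_equal(tab$IWRES, (tab$DV - tab$IPRED) / 1.1, tolerance = 1e-10)
})

test_that("CWRES are calibrated under the true model at the study size", {
  m <- population_model()
  d <- simulate_cohort(cohort_spec(), m, seed = 23)
  f <- fit_popmodel(d, start = m,
                    fixed = c("ka", "tv_cl", "tv_v", "omega_cl", "omega_v",
                              "sigma_prop", "sigma_add"))
  tab <- diagnostics(d, f)
  expect_equal(nrow(tab), 130)
  expect_lt(abs(mean(tab$CWRES)), 0.15)
  expect_gt(sd(tab$CWRES), 0.8)
  expect_lt(sd(tab$CWRES), 1.2)
})

test_that("degenerate residual model is rejected", {
  m0 <- population_model(sigma_prop = 0, sigma_add = 0)
  d <- simulate_toy(2, c(6, 9), population_model(), obs_days = c(2, 4),
                    seed = 2)
  fake_fit <- structure(list(estimates = m0, converged = TRUE,
                             post_hoc = data.frame(id = 1:2, eta_cl = 0,
                                                   eta_v = 0)),
                        class = "pk_fit")
  expect_error(diagnostics(d, fake_fit), "zero residual variance")
})

test_that("identity resample gives median = estimate and zero bias", {
  m <- population_model(omega_cl = 0.3, omega_v = 0.35, sigma_prop = 0.2,
                        sigma_add = 0.8)
  d <- simulate_toy(6, c(5, 7, 9), m, obs_days = c(2, 4, 6, 8), seed = 12)
  f <- fit_popmodel(d, start = m)
  b <- bootstrap_model(d, f, n = 1, indices = list(unique(d$ID)))
  expect_equal(b$n_converged, 1)
  expect_equal(b$table$median, b$table$estimate, tolerance = 1e-4)
  expect_true(all(abs(b$table$bias_percent) <= 0.05))
})

test_that("bootstrap percentile CIs widen as the cohort shrinks", {
  m <- population_model(omega_cl = 0.3, omega_v = 0.35, sigma_prop = 0.2,
                        sigma_add = 0.8)
  d_big <- simulate_toy(24, c(5, 6, 7, 8, 9, 10), m,
                        obs_days = c(2, 4, 6, 8), seed = 14)
  d_small <- make_dataset(as.data.frame(d_big[d_big$ID <= 8, ]))
  f_big <- fit_popmodel(d_big, start = m)
  f_small <- fit_popmodel(d_small, start = m)
  b_big <- bootstrap_model(d_big, f_big, n = 40, seed = 15)
  b_small <- bootstrap_model(d_small, f_small, n = 40, seed = 15)
  w <- function(b, p) {
    r <- b$table[b$table$parameter == p, ]
    (r$ci_high - r$ci_low) / r$estimate
  }
  expect_gt(w(b_small, "tv_cl"), w(b_big, "tv_cl"))
  expect_gt(w(b_small, "tv_v"), w(b_big, "tv_v"))
})
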