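test_that("Wald intervals use the exact normal quantiles", {
  ci <- wald_ci(0, 1, gamma = 0.05)
  expect_equal(unname(ci[1, ]), c(-1, 1) * qnorm(0.975), tolerance = 1e-9)
  expect_equal(unname(round(ci[1, 2], 2)), 1.96)
  # degenerate SE gives a point interval
  expect_equal(unname(wald_ci(2.5, 0)[1, ]), c(2.5, 2.5))
  # gamma = 0.10 uses the 0.95 quantile
  expect_equal(unname(wald_ci(0, 1, gamma = 0.10)[1, 2]), 1.644854,
               tolerance = 1e-6)
})

test_that("DerSimonian-Laird pooling matches hand computation", {
  # two studies (1.0, se 0.5) and (3.0, se 0.5):
  # w = 4, Q = 8, C = 8 - 32/8 = 4, tau2 = (8 - 1)/4 = 1.75,
  # w* = 1/(0.25 + 1.75) = 0.5 -> pooled 2.0, SE = 1
  p <- pool_study_effects(c(1, 3), c(0.5, 0.5))
  expect_equal(p$tau2, 1.75)
  expect_equal(p$estimate, 2.0)
  expect_equal(p$se, 1.0)

  # identical estimates: tau2 = 0, pooled = common value
  p0 <- pool_study_effects(c(1.2, 1.2, 1.2), c(0.3, 0.3, 0.3))
  expect_equal(p0$tau2, 0)
  expect_equal(p0$estimate, 1.2)
  # tau2 = 0 reduces to fixed-effect inverse-variance pooling,
  # and the pooled SE cannot exceed the smallest per-study SE
  ses <- c(0.2, 0.4, 0.3)
  est <- c(1.19, 1.21, 1.20)
  pf <- pool_study_effects(est, ses)
  expect_equal(pf$tau2, 0)
  w <- 1 / ses^2
  expect_equal(pf$estimate, sum(w * est) / sum(w))
  expect_lte(pf$se, min(ses))

  # single study: pass-through with undefined tau2
  p1 <- pool_study_effects(2.5, 0.4)
  expect_equal(p1$estimate, 2.5)
  expect_true(is.na(p1$tau2))
  expect_error(pool_study_effects(c(1, 2), c(0.5, Inf)), "finite")
})

test_that("bootstrap is reproducible, counts failures, and tracks the model SE", {
  sc <- sim_scenario(K = 2, n_per_study = 60, alpha2 = 0, alpha3 = 0,
                     A = matrix(0, 2, 2), beta21 = 1,
                     meas_times = c(0, 0.5, 1, 2, 3, 4))
  d <- sim_joint_data(sc, seed = 73)$data
  ctl <- mjm_control(fix_alpha = c(alpha2 = 0), max_iter = 20,
                     tol_param = 1e-3)
  bt <- mjm_boot(d, group = 0, control = ctl, B = 12, seed = 7)
  bt2 <- mjm_boot(d, group = 0, control = ctl, B = 12, seed = 7)
  expect_identical(bt$est, bt2$est)      # same seed, bit-identical
  expect_true(bt$reliable)
  expect_lte(bt$n_failed, 2)
  # with no association the bootstrap SE of the survival treatment effect
  # should be near the model-based Cox SE (loose: 12 resamples)
  sep <- mjm_separate(d, group = 0)
  se_model <- sqrt(diag(sep$surv$vcov_beta2))[1]
  expect_gt(bt$se[["surv.treat"]], se_model / 2.5)
  expect_lt(bt$se[["surv.treat"]], se_model * 2.5)
})
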