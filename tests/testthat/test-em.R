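test_that("adapted Gauss-Hermite moments match dense-grid integration to 1e-6", {
  # 1-subject, 1-dimensional posterior: Gaussian prior x survival-like factor
  logpost <- function(b) -0.5 * (b - 0.3)^2 / 0.2 - 0.4 * exp(0.8 * b)
  qm <- metajoint:::gh_posterior_moments_1d(logpost, mu = 0.1,
                                            sd = sqrt(0.2), n_quad = 25)
  f0 <- function(b) exp(logpost(b))
  Z <- stats::integrate(f0, -20, 20, rel.tol = 1e-12)$value
  m1 <- stats::integrate(function(b) b * f0(b), -20, 20,
                         rel.tol = 1e-12)$value / Z
  m2 <- stats::integrate(function(b) b^2 * f0(b), -20, 20,
                         rel.tol = 1e-12)$value / Z
  expect_equal(qm$norm_const, Z, tolerance = 1e-6)
  expect_equal(qm$mean, m1, tolerance = 1e-6)
  expect_equal(qm$second, m2, tolerance = 1e-6)
})

test_that("Breslow increments reduce to d_r / |risk set| under a null model", {
  Tsurv <- c(1, 1, 2, 3)
  delta <- c(1, 1, 1, 0)
  rs <- metajoint:::make_riskset(Tsurv, delta, rep(1L, 4))
  bl <- metajoint:::breslow_baseline(rs, riskexp = rep(1, 4), delta = delta)
  expect_equal(bl$haz[[1]]$time, c(1, 2))
  expect_equal(bl$haz[[1]]$haz, c(2 / 4, 1 / 2))
  expect_equal(bl$H0, c(0.5, 0.5, 1, 1))
  # stratified: risk sets never cross the stratum boundary
  rs2 <- metajoint:::make_riskset(Tsurv, delta, c(1L, 1L, 2L, 2L))
  bl2 <- metajoint:::breslow_baseline(rs2, rep(1, 4), delta)
  expect_equal(bl2$haz[[1]]$haz, 2 / 2)
  expect_equal(bl2$haz[[2]]$haz, 1 / 2)
})

test_that("with the association fixed at zero the joint fit equals the separate fits", {
  d <- toy_data(toy_scenario_2(alpha2 = 0, alpha3 = 0), seed = 41)
  sep <- mjm_separate(d, group = 0)
  fit <- mjm(d, group = 0, separate = sep,
             control = mjm_control(fix_alpha = c(alpha2 = 0)))
  expect_false(isTRUE(fit$failed))
  expect_identical(unname(fit$alpha[["alpha2"]]), 0)
  expect_equal(fit$beta1, sep$long$beta1, tolerance = 1e-4)
  expect_equal(fit$beta2, sep$surv$beta2, tolerance = 1e-4)
  expect_equal(fit$sigma_e2, sep$long$sigma_e2, tolerance = 1e-4)
  expect_equal(fit$D, sep$long$D, tolerance = 1e-3)
  expect_monotone_trace(fit)

  # and with study-level effects too (group 3, both alphas pinned)
  d5 <- toy_data(toy_scenario_5(alpha2 = 0, alpha3 = 0), seed = 43)
  sep5 <- mjm_separate(d5, group = 3)
  expect_true(sep5$converged)
  fit5 <- mjm(d5, group = 3, separate = sep5,
              control = mjm_control(fix_alpha = c(alpha2 = 0, alpha3 = 0)))
  expect_false(isTRUE(fit5$failed))
  expect_equal(fit5$beta1, sep5$long$beta1, tolerance = 1e-4)
  expect_equal(fit5$beta2, sep5$surv$beta2, tolerance = 1e-4)
  expect_monotone_trace(fit5)
})

test_that("at the starting values the joint log-likelihood decomposes into LMM + Cox parts", {
  d <- toy_data(toy_scenario_2(alpha2 = 0, alpha3 = 0), seed = 47)
  sep <- mjm_separate(d, group = 0)
  fit <- mjm(d, group = 0, separate = sep,
             control = mjm_control(max_iter = 1))
  # independent oracle: Cox full likelihood with the Breslow hazard plugged in
  # equals the partial likelihood + sum_r d_r (log d_r - 1)
  ev <- d$surv$survtime[d$surv$status == 1]
  dr <- as.numeric(table(ev))
  cox_full <- sep$surv$loglik + sum(dr * log(dr)) - sum(dr)
  expect_equal(fit$loglik_trace[1], sep$long$loglik + cox_full,
               tolerance = 1e-6)
})

test_that("EM trace is monotone and fits converge for all six model groups", {
  d <- toy_data(toy_scenario_5(), seed = 59)
  for (g in 0:5) {
    fit <- mjm(d, group = g, control = mjm_control(max_iter = 2000))
    expect_false(isTRUE(fit$failed), label = sprintf("group %d fit", g))
    expect_monotone_trace(fit)
    expect_true(fit$converged, label = sprintf("group %d converged", g))
    expect_gt(fit$alpha[["alpha2"]], 0)   # true association is positive
    # variance components stay positive semidefinite
    expect_gte(min(eigen(fit$D, symmetric = TRUE)$values), 0)
    if (!is.null(fit$A))
      expect_gte(min(eigen(fit$A, symmetric = TRUE)$values), 0)
  }
})

test_that("group-4 baseline hazards are stratified with increments at study event times", {
  d <- toy_data(toy_scenario_5(), seed = 59)
  fit <- mjm(d, group = 4)
  expect_false(isTRUE(fit$failed))
  expect_length(fit$baseline, d$K)
  for (k in seq_len(d$K)) {
    ev_k <- sort(unique(d$surv$survtime[d$surv$status == 1 &
                                          d$surv$study == d$studies[k]]))
    expect_equal(fit$baseline[[k]]$time, ev_k)
    expect_true(all(fit$baseline[[k]]$haz >= 0))
  }
})

test_that("the observed log-likelihood is invariant to study relabelling", {
  d <- toy_data(toy_scenario_2(), seed = 61)
  fit <- mjm(d, group = 0)
  long2 <- d$long; surv2 <- d$surv
  relab <- c(S01 = "ZZ", S02 = "AA")
  long2$study <- unname(relab[long2$study])
  surv2$study <- unname(relab[surv2$study])
  fit2 <- mjm(mjm_data(long2, surv2), group = 0)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(unname(fit2$beta1), unname(fit$beta1), tolerance = 1e-5)
})

test_that("failed initial fits propagate as structured failures, not errors", {
  d <- toy_data(toy_scenario_2(), seed = 67)
  d$surv$status[] <- 0
  fit <- mjm(d, group = 0)
  expect_s3_class(fit, "mjm")
  expect_true(fit$failed)
  expect_false(fit$converged)
  expect_match(fit$message, "separate fit failed")
})

test_that("coef, logLik, summary and plot methods work on a fitted model", {
  d <- toy_data(toy_scenario_2(), seed = 71)
  fit <- mjm(d, group = 0)
  co <- coef(fit)
  expect_true(all(c("long.treat", "surv.treat", "alpha2") %in% names(co)))
  expect_s3_class(logLik(fit), "logLik")
  expect_output(print(summary(fit)), "Association")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
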