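test_that("Gompertz parameters reproduce the target moments formulae", {
  g <- gompertz_moments(3, 0.5)
  expect_equal(g$theta1, pi / (0.5 * sqrt(6)), tolerance = 1e-12)
  expect_equal(round(g$theta1, 4), 2.5651)
  expect_equal(round(g$theta0, 6), -7.330517)
  # formula reduction: sigma0 = pi/sqrt(6) gives unit shape
  expect_equal(gompertz_moments(1, pi / sqrt(6))$theta1, 1, tolerance = 1e-12)
  expect_error(gompertz_moments(3, 0), "positive")
})

test_that("event-time inversion agrees with a numerical cumulative-hazard root", {
  g <- gompertz_moments(3, 0.5)
  # hazard: exp(theta0 + beta21 treat + a2 b0 + a3 w3) * exp((theta1 + a2 b1) t)
  cases <- list(
    list(U = 0.37, treat = 0, b0 = 0.3, b1 = -1.2, w3 = 0.2),
    list(U = 0.81, treat = 1, b0 = -0.5, b1 = 0.7, w3 = -0.4),
    list(U = 0.05, treat = 0, b0 = 0, b1 = 0, w3 = 0)
  )
  for (cs in cases) {
    te <- sim_event_times(cs$U, cs$treat, cs$b0, cs$b1, cs$w3,
                          beta21 = 3, alpha2 = 0.5, alpha3 = 0.5,
                          gompertz = g)
    haz <- function(t) exp(g$theta0 + 3 * cs$treat + 0.5 * cs$b0 +
                             0.5 * cs$w3 + (g$theta1 + 0.5 * cs$b1) * t)
    Lam <- function(t) stats::integrate(haz, 0, t, rel.tol = 1e-11)$value
    root <- stats::uniroot(function(t) Lam(t) + log(cs$U), c(1e-9, 50),
                           tol = 1e-10)$root
    expect_equal(te, root, tolerance = 1e-6)
  }
})

test_that("inversion limits: U near 1 gives time near 0; exponential reduction", {
  g <- gompertz_moments(3, 0.5)
  expect_lt(sim_event_times(1 - 1e-12, 0, 0, 0, 0, beta21 = 0, alpha2 = 0,
                            alpha3 = 0, gompertz = g), 1e-6)
  # alpha2*b1 = -theta1 makes the hazard time-constant (exponential limit)
  te <- sim_event_times(exp(-1), 0, 0, -g$theta1 / 0.5, 0, beta21 = 0,
                        alpha2 = 0.5, alpha3 = 0, gompertz = g)
  expect_equal(te, 1 / exp(g$theta0), tolerance = 1e-6)
})

test_that("cure conditions assign infinite latent times that resolve to censoring", {
  g <- gompertz_moments(3, 0.5)
  # negative effective shape and tiny U: certain cure
  te <- sim_event_times(1e-12, 0, b0 = 0, b1 = -3, 0, beta21 = 0,
                        alpha2 = 2, alpha3 = 0, gompertz = g)
  expect_identical(te, Inf)
  # same configuration, U above the cure threshold: finite time
  te2 <- sim_event_times(0.99995, 0, b0 = 0, b1 = -3, 0, beta21 = 0,
                         alpha2 = 2, alpha3 = 0, gompertz = g)
  expect_true(is.finite(te2))
  # reduced form of the cure probability uses only theta0 + a2 b0, so for a
  # treated subject a U between the two thresholds is cured under one reading
  # and not the other
  shape <- g$theta1 + 2 * (-3)
  p_full <- exp(exp(g$theta0 + 3) / shape)
  p_red <- exp(exp(g$theta0) / shape)
  u_mid <- sqrt(p_full * p_red)
  t_full <- sim_event_times(u_mid, 1, 0, -3, 0, beta21 = 3, alpha2 = 2,
                            alpha3 = 0, gompertz = g,
                            cure_condition = "full")
  t_red <- sim_event_times(u_mid, 1, 0, -3, 0, beta21 = 3, alpha2 = 2,
                           alpha3 = 0, gompertz = g,
                           cure_condition = "reduced")
  expect_identical(is.finite(t_full), p_full < u_mid)
  expect_identical(is.finite(t_red), p_red < u_mid)
  expect_true(is.finite(t_full) != is.finite(t_red))
  # in a dataset, infinite latent times always resolve to censoring
  sc <- sim_scenario(K = 2, n_per_study = 50, alpha2 = 2,
                     D = matrix(c(1, 0, 0, 4), 2), A = matrix(0, 2, 2),
                     alpha3 = 0)
  sim <- sim_joint_data(sc, seed = 31)
  inf_i <- !is.finite(sim$truth$T_E)
  if (any(inf_i)) {
    expect_true(all(sim$data$surv$status[inf_i] == 0))
    expect_equal(sim$data$surv$survtime[inf_i], sim$truth$T_C[inf_i])
  }
  # events always carry the latent event time
  ev <- sim$data$surv$status == 1
  expect_equal(sim$data$surv$survtime[ev], sim$truth$T_E[ev])
})

test_that("censoring times follow the exponential inversion", {
  expect_equal(sim_censoring(exp(-1), 1), 1)
  expect_lt(sim_censoring(1 - 1e-12, 5), 1e-9)
  set.seed(4)
  x <- sim_censoring(runif(20000), exp(-0.426))
  expect_equal(mean(x), exp(0.426), tolerance = 0.02)
  expect_error(sim_censoring(0.5, 0), "> 0")
})

test_that("null-covariate event times match the target Gompertz moments", {
  g <- gompertz_moments(3, 0.5)
  set.seed(9)
  te <- sim_event_times(runif(20000), 0, 0, 0, 0, beta21 = 0, alpha2 = 0,
                        alpha3 = 0, gompertz = g)
  expect_equal(mean(te), 3, tolerance = 0.01)
  expect_equal(sd(te), 0.5, tolerance = 0.02)
})

test_that("simulated datasets satisfy the structural invariants", {
  sc <- toy_scenario_5()
  sim <- sim_joint_data(sc, seed = 11)
  d <- sim$data
  # delta = 1 iff the event time was observed
  expect_true(all((d$surv$status == 1) ==
                    (sim$truth$T_E <= sim$truth$T_C)))
  # exact 1:1 allocation within study
  tr <- tapply(d$surv$treat, d$surv$study, sum)
  expect_true(all(tr == sc$n_per_study / 2))
  # truncation monotonicity: with a common measurement grid, the number of
  # retained measurements is a nondecreasing function of the survival time
  m <- d$m_ki[paste(d$surv$study, d$surv$subject, sep = ".")]
  ord <- order(d$surv$survtime)
  expect_true(all(diff(m[ord]) >= 0))
  expect_equal(unname(m),
               findInterval(d$surv$survtime, sc$meas_times))
  # reproducibility: identical scenario + seed => identical dataset
  sim2 <- sim_joint_data(sc, seed = 11)
  expect_identical(sim$data$long, sim2$data$long)
  expect_identical(sim$data$surv, sim2$data$surv)
})

test_that("noise-free generator returns the exact fixed-effect trajectory", {
  sc <- sim_scenario(K = 2, n_per_study = 10, sigma_e2 = 0,
                     D = matrix(0, 2, 2), A = matrix(0, 2, 2),
                     alpha2 = 0, alpha3 = 0)
  d <- sim_joint_data(sc, seed = 2)$data
  expect_equal(d$long$y, 1 + 3 * d$long$time + 2 * d$long$treat,
               tolerance = 1e-12)
})

test_that("scenario presets load from packaged YAML configurations", {
  f <- system.file("extdata", "scenarios", "set1_a2-0.5_a3-0.5.yaml",
                   package = "metajoint")
  expect_true(nzchar(f))
  sc <- read_scenario(f)
  expect_identical(sc$K, 5L)
  expect_identical(sc$n_per_study, 500L)
  expect_equal(sc$alpha2, 0.5)
  expect_equal(sc$lambda_cens, exp(-0.426), tolerance = 1e-12)
  expect_equal(sc$D, matrix(c(1, 0.5, 0.5, 1.5), 2), tolerance = 1e-12)
  # Set-3 no-heterogeneity preset has a zero study covariance
  sc3 <- read_scenario(system.file("extdata", "scenarios", "set3_A1.yaml",
                                   package = "metajoint"))
  expect_true(all(sc3$A == 0))
})
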