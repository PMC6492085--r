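test_that("separate longitudinal fit recovers the generating parameters", {
  sc <- sim_scenario(K = 2, n_per_study = 150, alpha2 = 0, alpha3 = 0,
                     A = matrix(0, 2, 2))
  d <- toy_data(sc, seed = 13)
  sep <- mjm_separate(d, group = 0)
  expect_true(sep$converged)
  lf <- sep$long
  expect_equal(lf$sigma_e2, 0.01, tolerance = 0.2)
  expect_equal(unname(diag(lf$D)), c(1, 1.5), tolerance = 0.25)
  expect_equal(lf$D[1, 2], 0.5, tolerance = 0.3)
  expect_equal(unname(lf$beta1), c(1, 3, 2), tolerance = 0.25)
})

test_that("conditional modes equal the closed-form BLUP solution", {
  d <- toy_data(toy_scenario_2(alpha2 = 0, alpha3 = 0, A = matrix(0, 2, 2)),
                seed = 17)
  sep <- mjm_separate(d, group = 0)
  lf <- sep$long
  des <- sep$design
  resid <- des$y - as.numeric(des$X1 %*% lf$beta1)
  for (i in c(1L, 5L, 20L)) {
    rows <- which(des$subj == i)
    Zi <- cbind(1, des$t[rows])
    Vi <- Zi %*% lf$D %*% t(Zi) + lf$sigma_e2 * diag(length(rows))
    blup <- as.numeric(lf$D %*% t(Zi) %*% solve(Vi, resid[rows]))
    expect_equal(unname(lf$modes2[i, ]), blup, tolerance = 1e-6)
  }
})

test_that("survival fit maximizes the partial likelihood on a 3-subject toy", {
  # two events, one binary covariate, no ties: brute-force grid oracle.
  # pl(b) = [b - log(2 e^b + 1)] + [- log(1 + e^b)], maximized at
  # b = -log(2)/2 (solve 1/(2u+1) = u/(1+u) with u = e^b).
  long <- data.frame(study = "A", subject = as.character(1:3),
                     time = 0, y = c(0.1, -0.2, 0.3), treat = c(1, 0, 1))
  surv <- data.frame(study = "A", subject = as.character(1:3),
                     survtime = c(1, 2, 3), status = c(1, 1, 0),
                     treat = c(1, 0, 1))
  d <- mjm_data(long, surv)
  sep <- mjm_separate(d, group = 0)
  expect_true(sep$surv$ok)
  pl <- function(b) b - log(2 * exp(b) + 1) - log(1 + exp(b))
  grid <- seq(-5, 5, by = 1e-4)
  expect_equal(unname(sep$surv$beta2), grid[which.max(pl(grid))],
               tolerance = 1e-3)
  expect_equal(unname(sep$surv$beta2), -log(2) / 2, tolerance = 1e-4)
  # Breslow increments: 1 / (risk-set sum of exp(b x)) at each event time
  b <- unname(sep$surv$beta2)
  expect_equal(sep$surv$baseline[[1]]$haz,
               c(1 / (2 * exp(b) + 1), 1 / (1 + exp(b))), tolerance = 1e-6)
})

test_that("degenerate survival and longitudinal inputs are flagged, not thrown", {
  d <- toy_data(toy_scenario_2(), seed = 23)
  d$surv$status[] <- 0
  sep <- mjm_separate(d, group = 0)
  expect_false(sep$converged)
  expect_match(sep$message, "no events")
  # near-zero random-effect variance flags a singular fit
  sc0 <- sim_scenario(K = 2, n_per_study = 40, D = diag(c(1e-12, 1e-12)),
                      alpha2 = 0, alpha3 = 0, A = matrix(0, 2, 2),
                      sigma_e2 = 0.01)
  d0 <- toy_data(sc0, seed = 29)
  sep0 <- mjm_separate(d0, group = 0)
  expect_false(sep0$converged)
  expect_match(sep0$message, "singular")
})

test_that("stratified separate survival fit keeps risk sets within study", {
  d <- toy_data(toy_scenario_5(), seed = 37)
  sep <- mjm_separate(d, group = 4)
  expect_true(sep$converged)
  expect_length(sep$surv$baseline, d$K)
  # each stratum's increments live at that stratum's own event times
  for (k in seq_len(d$K)) {
    ev_k <- sort(unique(d$surv$survtime[d$surv$status == 1 &
                                          d$surv$study == d$studies[k]]))
    expect_equal(sep$surv$baseline[[k]]$time, ev_k)
  }
})
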