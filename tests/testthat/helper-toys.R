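# Small fixtures built in code.

# two-study toy for fast fits of groups without study-level random effects;
# a moderate survival treatment effect keeps small-sample Cox fits away from
# monotone-likelihood degeneracies
toy_scenario_2 <- function(...) {
  sim_scenario(K = 2, n_per_study = 40, beta21 = 1,
               meas_times = c(0, 0.5, 1, 2, 3, 4), ...)
}

# five-study toy (study-level random effects and per-study interactions
# estimable)
toy_scenario_5 <- function(...) {
  sim_scenario(K = 5, n_per_study = 60, beta21 = 1,
               meas_times = c(0, 0.5, 1, 2, 3, 4), ...)
}

toy_data <- function(scenario, seed = 101) sim_joint_data(scenario, seed)$data

# hand-built two-study joint tables (3 subjects, deterministic)
toy_tables <- function() {
  long <- data.frame(
    study = c("A", "A", "A", "B", "B"),
    subject = c("1", "1", "2", "1", "1"),
    time = c(0, 1, 0, 0, 2),
    y = c(1.0, 2.5, 0.7, 1.2, 4.0),
    treat = c(0, 0, 1, 1, 1)
  )
  surv <- data.frame(
    study = c("A", "A", "B"),
    subject = c("1", "2", "1"),
    survtime = c(2, 0.5, 3),
    status = c(1, 0, 1),
    treat = c(0, 1, 1)
  )
  list(long = long, surv = surv)
}

expect_monotone_trace <- function(fit, slack = 1e-6) {
  expect_false(isTRUE(fit$failed))
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) > -slack * (abs(tr[length(tr)]) + 1)),
              label = "EM log-likelihood trace is non-decreasing")
}
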