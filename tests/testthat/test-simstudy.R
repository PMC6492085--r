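test_that("coverage counts Wald intervals containing the generating value", {
  expect_equal(coverage(c(1, 1.1), c(1, 1), truth = 1), 1)
  expect_equal(coverage(c(0, 10), c(1, 1), truth = 0), 0.5)
  expect_true(is.na(coverage(NA_real_, NA_real_, 0)))
  # normal-theory check: nominal 95% coverage when the SE is the truth
  set.seed(12)
  est <- rnorm(1000, 5, 0.3)
  cv <- coverage(est, rep(0.3, 1000), truth = 5)
  expect_equal(cv, 0.95, tolerance = 0.035)
})

test_that("cell rendering follows the mean (SE) [coverage] format and round-trips", {
  expect_identical(render_sim_cell(3.0401, 0.2649, 0.8504),
                   "3.04 (0.26) [85.0]")
  expect_identical(render_sim_cell(NA, NA, NA), "NA")
  parsed <- parse_sim_cell("3.04 (0.26) [85.0]")
  expect_equal(unname(parsed[1, ]), c(3.04, 0.26, 0.850))
  # round-trip at the printed precision
  cell <- render_sim_cell(2.736, 0.291, 0.435)
  expect_equal(unname(parse_sim_cell(cell)[1, ]),
               c(round(2.736, 2), round(0.291, 2), round(0.435, 3)))
  # empty input passes through without error
  empty <- data.frame(group = integer(), model = character(),
                      parameter = character(), truth = numeric(),
                      n_success = integer(), mean = numeric(),
                      emp_se = numeric(), coverage = numeric())
  expect_identical(nrow(summarize_sim(empty)), 0L)
})

test_that("run_scenario assembles per-replicate fits into summary rows", {
  sc <- toy_scenario_2(alpha2 = 0.5, alpha3 = 0, A = matrix(0, 2, 2))
  ctl <- mjm_control(max_iter = 30, tol_param = 1e-3)
  res <- run_scenario(sc, groups = c(0, 1), n_replicates = 2, seed = 5,
                      control = ctl)
  expect_true(all(c("group", "model", "parameter", "n_success", "mean",
                    "emp_se", "coverage") %in% names(res)))
  # group 0: beta12/beta21 for separate + joint, alpha2 joint only
  g0 <- res[res$group == 0, ]
  expect_setequal(paste(g0$model, g0$parameter),
                  c("separate beta12", "separate beta21",
                    "joint beta12", "joint beta21", "joint alpha2"))
  expect_true(all(res$n_success <= 2))
  expect_true(all(is.na(res$coverage) | (res$coverage >= 0 &
                                           res$coverage <= 1)))
  # deterministic given the master seed
  res2 <- run_scenario(sc, groups = c(0, 1), n_replicates = 2, seed = 5,
                       control = ctl)
  expect_equal(res$mean, res2$mean)
  # single replicate: empirical SE undefined
  res1 <- run_scenario(sc, groups = 0, n_replicates = 1, seed = 5,
                       control = ctl)
  expect_true(all(is.na(res1$emp_se)))
  expect_true(all(res1$coverage %in% c(0, 1, NA)))
  # replicate-level estimates attached for downstream use
  expect_s3_class(attr(res, "replicates"), "data.frame")
})
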