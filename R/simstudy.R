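#' Empirical coverage of Wald confidence intervals
#'
#' Proportion of replicates whose Wald interval
#' \code{estimate +/- z_{1-gamma/2} * se} contains the generating value.
#' \code{NA} estimate/SE pairs are dropped.
#'
#' @param estimates,ses replicate estimates and standard errors.
#' @param truth generating parameter value.
#' @param gamma significance level (default 0.05).
#' @return fraction in [0, 1], or \code{NA} if no complete pairs.
#' @export
coverage <- function(estimates, ses, truth, gamma = 0.05) {
  stopifnot(length(estimates) == length(ses))
  ok <- is.finite(estimates) & is.finite(ses)
  if (!any(ok)) return(NA_real_)
  z <- stats::qnorm(1 - gamma / 2)
  mean(abs(estimates[ok] - truth) <= z * ses[ok])
}

#' Run one simulation scenario: repeated simulate-and-fit
#'
#' For each replicate, simulates a multi-study joint dataset from the
#' scenario, fits the separate longitudinal and survival one-stage
#' meta-analysis models and the joint EM model for every requested model
#' group, and records the treatment effects and association parameters with
#' their (model-based) standard errors.  Study-specific coefficients (the
#' longitudinal treatment effect in groups 1 and 4 and the survival treatment
#' effect in group 1) are pooled across studies by DerSimonian--Laird
#' random-effects meta-analysis before summarizing.  Replicates where either
#' the separate or the joint fit fails are excluded from the summaries but
#' counted (the separate fits seed the EM, so failure counts coincide by
#' construction).
#'
#' @param scenario a \code{"sim_scenario"} object.
#' @param groups model groups to fit (subset of 0:5).
#' @param n_replicates number of simulated datasets.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param control \code{\link{mjm_control}} for the joint fits.
#' @param gamma significance level for coverage.
#' @return A data frame of summary rows (one per group x model x parameter)
#'   with columns \code{group}, \code{model} (\code{"separate"} /
#'   \code{"joint"}), \code{parameter}, \code{truth}, \code{n_success},
#'   \code{mean}, \code{emp_se} (SD of estimates across replicates, \code{NA}
#'   for a single replicate) and \code{coverage}.  The per-replicate
#'   estimates are attached as \code{attr(, "replicates")}.
#' @export
run_scenario <- function(scenario, groups = 0:5, n_replicates = 100,
                         seed = 1, control = mjm_control(), gamma = 0.05) {
  stopifnot(inherits(scenario, "sim_scenario"), n_replicates >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_replicates)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    dat <- sim_joint_data(scenario, seed = seeds[r])$data
    rows <- lapply(groups, function(g) {
      fit_one_group(dat, g, control, replicate = r)
    })
    reps[[r]] <- do.call(rbind, rows)
  }
  est <- do.call(rbind, reps)

  truth <- c(beta12 = scenario$beta12, beta21 = scenario$beta21,
             alpha2 = scenario$alpha2, alpha3 = scenario$alpha3)
  keys <- unique(est[c("group", "model", "parameter")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- est$group == k$group & est$model == k$model &
      est$parameter == k$parameter
    e <- est$estimate[sel]; s <- est$se[sel]
    tr <- truth[[k$parameter]]
    ok <- is.finite(e)
    data.frame(group = k$group, model = k$model, parameter = k$parameter,
               truth = tr, n_success = sum(ok),
               mean = if (any(ok)) mean(e[ok]) else NA_real_,
               emp_se = if (sum(ok) > 1) stats::sd(e[ok]) else NA_real_,
               coverage = coverage(e, s, tr, gamma))
  }))
  attr(out, "replicates") <- est
  out
}

# fit separate + joint models of one group to one dataset and extract the
# reported parameters (pooling study-specific effects where the group
# produces them)
fit_one_group <- function(dat, g, control, replicate = NA) {
  sep <- tryCatch(suppressWarnings(mjm_separate(dat, group = g)),
                  error = function(e) NULL)
  sep_ok <- !is.null(sep) && sep$converged
  jnt <- if (sep_ok)
    mjm(dat, group = g, control = control, separate = sep) else NULL
  jnt_ok <- !is.null(jnt) && !isTRUE(jnt$failed) && jnt$converged

  row <- function(model, parameter, estimate, se) {
    data.frame(replicate = replicate, group = g, model = model,
               parameter = parameter, estimate = estimate, se = se)
  }
  na_row <- function(model, parameter) row(model, parameter, NA_real_,
                                           NA_real_)
  pooled_or_plain <- function(beta, vc, studies, study_specific) {
    if (study_specific) {
      eff <- study_effects(beta, vc, studies)
      p <- pool_study_effects(eff$estimate, eff$se)
      c(p$estimate, p$se)
    } else {
      i <- match("treat", names(beta))
      c(beta[i], if (is.null(vc)) NA_real_ else sqrt(vc[i, i]))
    }
  }

  out <- list()
  ss_long <- g %in% c(1, 4)
  ss_surv <- g == 1
  studies <- dat$studies
  if (sep_ok && jnt_ok) {
    b12s <- pooled_or_plain(sep$long$beta1, sep$long$vcov_beta1, studies,
                            ss_long)
    b21s <- pooled_or_plain(sep$surv$beta2, sep$surv$vcov_beta2, studies,
                            ss_surv)
    p2 <- length(jnt$beta2)
    b12j <- pooled_or_plain(jnt$beta1, jnt$vcov_beta1, studies, ss_long)
    b21j <- pooled_or_plain(jnt$beta2,
                            jnt$vcov_psi[seq_len(p2), seq_len(p2),
                                         drop = FALSE],
                            studies, ss_surv)
    out <- list(
      row("separate", "beta12", b12s[1], b12s[2]),
      row("separate", "beta21", b21s[1], b21s[2]),
      row("joint", "beta12", b12j[1], b12j[2]),
      row("joint", "beta21", b21j[1], b21j[2]),
      row("joint", "alpha2", jnt$alpha[["alpha2"]], jnt$se$alpha[["alpha2"]])
    )
    if ("alpha3" %in% names(jnt$alpha))
      out <- c(out, list(row("joint", "alpha3", jnt$alpha[["alpha3"]],
                             jnt$se$alpha[["alpha3"]])))
  } else {
    out <- list(na_row("separate", "beta12"), na_row("separate", "beta21"),
                na_row("joint", "beta12"), na_row("joint", "beta21"),
                na_row("joint", "alpha2"))
    if (length(mjm_spec(g)$study_re))
      out <- c(out, list(na_row("joint", "alpha3")))
  }
  do.call(rbind, out)
}

#' Render simulation summaries in "mean (SE) [coverage]" format
#'
#' @param rows summary data frame from \code{\link{run_scenario}}.
#' @return the input with an extra character column \code{cell} formatted as
#'   \code{"m.mm (s.ss) [cc.c]"} (mean to 2 decimals, empirical SE to 2,
#'   coverage in percent to 1).
#' @export
summarize_sim <- function(rows) {
  if (!nrow(rows)) {
    rows$cell <- character(0)
    return(rows)
  }
  rows$cell <- render_sim_cell(rows$mean, rows$emp_se, rows$coverage)
  rows
}

#' @rdname summarize_sim
#' @param mean,emp_se,cov numeric vectors.
#' @export
render_sim_cell <- function(mean, emp_se, cov) {
  ifelse(is.na(mean), "NA",
         sprintf("%.2f (%s) [%s]", mean,
                 ifelse(is.na(emp_se), "NA", sprintf("%.2f", emp_se)),
                 ifelse(is.na(cov), "NA", sprintf("%.1f", 100 * cov))))
}

#' @rdname summarize_sim
#' @param cell character vector in \code{"m.mm (s.ss) [cc.c]"} form.
#' @export
parse_sim_cell <- function(cell) {
  m <- regmatches(cell,
                  regexec("^(-?[0-9.]+) \\(([-0-9.NA]+)\\) \\[([0-9.NA]+)\\]$",
                          cell))
  t(vapply(m, function(g) {
    if (length(g) != 4) return(c(NA_real_, NA_real_, NA_real_))
    c(as.numeric(g[2]), suppressWarnings(as.numeric(g[3])),
      suppressWarnings(as.numeric(g[4])) / 100)
  }, numeric(3))) |>
    `colnames<-`(c("mean", "emp_se", "coverage"))
}
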