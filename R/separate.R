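#' Fit separate one-stage longitudinal and survival meta-analysis models
#'
#' Fits, independently, (i) the linear mixed model of the chosen model
#' group's longitudinal sub-model by maximum likelihood, and (ii) the Cox
#' proportional-hazards model of its survival sub-model (Breslow tie
#' handling, stratified by study when the group specifies it).  These
#' separate fits serve two roles: they are the comparator analyses that
#' ignore the longitudinal--survival association, and they supply starting
#' values and the conditional modes/covariances of the random effects used to
#' center the pseudo-adaptive quadrature of the joint EM fit.
#'
#' @param data an \code{"mjm_data"} object.
#' @param group model group 0..5 (see \code{\link{mjm_spec}}).
#' @param reference optional reference study label.
#' @param extra_basis optional extra longitudinal basis functions of time.
#' @param spec alternatively, a ready-made \code{"mjm_spec"}.
#' @return An object of class \code{"mjm_separate"}: a list with elements
#'   \code{spec}, \code{design}, \code{long} (fixed effects \code{beta1} with
#'   covariance, \code{sigma_e2}, \code{D}, \code{A}, conditional modes and
#'   covariances of both random-effect levels, \code{loglik}),
#'   \code{surv} (\code{beta2} with covariance, Breslow \code{baseline},
#'   partial \code{loglik}), and \code{converged}.  A failed component fit
#'   yields \code{converged = FALSE} with the reason in \code{message};
#'   no error is thrown for non-convergence.
#' @export
mjm_separate <- function(data, group = 0, reference = NULL,
                         extra_basis = NULL, spec = NULL) {
  stopifnot(inherits(data, "mjm_data"))
  if (is.null(spec)) spec <- mjm_spec(group, reference, extra_basis)
  des <- build_design(data, spec)
  lf <- fit_separate_long(des)
  sf <- fit_separate_surv(des)
  structure(
    list(spec = spec, design = des, long = lf, surv = sf,
         converged = isTRUE(lf$ok) && isTRUE(sf$ok),
         message = paste(c(lf$msg, sf$msg), collapse = "; ")),
    class = "mjm_separate"
  )
}

#' @export
print.mjm_separate <- function(x, digits = 4, ...) {
  cat("Separate one-stage meta-analysis fits (model group ",
      x$spec$group, ")\n", sep = "")
  if (!x$converged) {
    cat("  FAILED:", x$message, "\n")
    return(invisible(x))
  }
  cat("Longitudinal (ML linear mixed model):\n")
  print(round(x$long$beta1, digits))
  cat(sprintf("  sigma_e2 = %.*g; diag(D) = (%s)\n", digits, x$long$sigma_e2,
              paste(signif(diag(x$long$D), digits), collapse = ", ")))
  if (!is.null(x$long$A))
    cat("  study-level RE variance(s):",
        paste(signif(diag(as.matrix(x$long$A)), digits), collapse = ", "),
        "\n")
  cat("Time-to-event (Cox PH, Breslow ties):\n")
  print(round(x$surv$beta2, digits))
  invisible(x)
}

# ML linear mixed model for the longitudinal sub-model, with conditional
# modes/covariances of the random effects at both levels.
fit_separate_long <- function(des) {
  spec <- des$spec
  id <- factor(des$subj, levels = seq_along(des$Tsurv))
  d3 <- ncol(des$Z3)
  df <- data.frame(y = des$y, tt = des$t, id = id,
                   st = factor(des$studies[des$study[des$subj]],
                               levels = des$studies),
                   trt = des$X1[, "treat"])
  df$X1 <- des$X1
  fml <- if (d3 == 0L) {
    y ~ 0 + X1 + (1 + tt | id)
  } else if (identical(spec$study_re, "treatment")) {
    y ~ 0 + X1 + (1 + tt | id) + (0 + trt | st)
  } else {
    y ~ 0 + X1 + (1 + tt | id) + (1 + trt | st)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )),
    error = function(e) e
  )
  if (inherits(fit, "error"))
    return(list(ok = FALSE, msg = paste("longitudinal fit failed:",
                                        conditionMessage(fit))))

  beta1 <- lme4::fixef(fit)
  names(beta1) <- colnames(des$X1)
  vc <- lme4::VarCorr(fit)
  D <- as.matrix(vc$id)[c("(Intercept)", "tt"), c("(Intercept)", "tt")]
  dimnames(D) <- list(c("intercept", "slope"), c("intercept", "slope"))
  sigma_e2 <- stats::sigma(fit)^2
  A <- NULL
  if (d3 > 0L) {
    A <- as.matrix(vc$st)
    A <- matrix(as.numeric(A), d3, d3,
                dimnames = list(spec$study_re, spec$study_re))
  }
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    return(list(ok = FALSE,
                msg = "singular individual random-effect covariance"))
  if (d3 > 0L &&
      min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    return(list(ok = FALSE, msg = "singular study random-effect covariance"))

  re <- lme4::ranef(fit, condVar = TRUE)
  n <- length(des$Tsurv)
  modes2 <- matrix(0, n, 2)
  ri <- re$id
  rows <- match(as.character(seq_len(n)), rownames(ri))
  modes2[, 1] <- ri[rows, "(Intercept)"]
  modes2[, 2] <- ri[rows, "tt"]
  pv <- attr(ri, "postVar")[, , rows, drop = FALSE]
  condvar2 <- pv                                  # 2 x 2 x n

  modes3 <- NULL; condvar3 <- NULL
  if (d3 > 0L) {
    rs <- re$st
    rows3 <- match(des$studies, rownames(rs))
    modes3 <- matrix(as.numeric(as.matrix(rs)[rows3, , drop = FALSE]),
                     ncol = d3)
    condvar3 <- attr(rs, "postVar")[, , rows3, drop = FALSE]
  }

  list(ok = TRUE, msg = NULL, beta1 = beta1,
       vcov_beta1 = as.matrix(stats::vcov(fit)),
       sigma_e2 = sigma_e2, D = D, A = A,
       modes2 = modes2, condvar2 = condvar2,
       modes3 = modes3, condvar3 = condvar3,
       loglik = as.numeric(stats::logLik(fit)))
}

# Cox PH fit for the survival sub-model (partial likelihood, Breslow ties),
# plus Breslow baseline increments on the scale used by the EM algorithm.
fit_separate_surv <- function(des) {
  if (sum(des$delta) == 0L)
    return(list(ok = FALSE, msg = "no events: survival model cannot be fit"))
  rs <- make_riskset(des$Tsurv, des$delta, des$strata)
  empty <- vapply(rs, function(r) r$n_event == 0L, TRUE)
  if (any(empty))
    warning(sum(empty), " hazard stratum/strata without events contribute ",
            "no baseline increments", call. = FALSE)
  df <- data.frame(Ts = des$Tsurv, d = des$delta, stra = des$strata)
  df$X2 <- des$X2
  fml <- if (des$spec$stratified_hazard)
    survival::Surv(Ts, d) ~ X2 + survival::strata(stra)
  else survival::Surv(Ts, d) ~ X2
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = df, ties = "breslow")),
    error = function(e) e
  )
  if (inherits(fit, "error"))
    return(list(ok = FALSE, msg = paste("survival fit failed:",
                                        conditionMessage(fit))))
  beta2 <- stats::coef(fit)
  names(beta2) <- colnames(des$X2)
  # fail on genuinely inestimable / divergent coefficients rather than on
  # coxph's (often spurious) monotone-likelihood warning
  if (anyNA(beta2) || any(!is.finite(beta2)) || any(abs(beta2) > 15))
    return(list(ok = FALSE, msg = "survival coefficients not estimable"))
  riskexp <- exp(as.numeric(des$X2 %*% beta2))
  bl <- breslow_baseline(rs, riskexp, des$delta)
  list(ok = TRUE, msg = NULL, beta2 = beta2,
       vcov_beta2 = stats::vcov(fit),
       baseline = bl$haz, H0 = bl$H0, logh0 = bl$logh0, riskset = rs,
       loglik = fit$loglik[2])
}
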