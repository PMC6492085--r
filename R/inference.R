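#' Wald confidence interval
#'
#' \code{estimate} plus/minus the standard normal \code{1 - gamma/2} quantile
#' times \code{se}.
#'
#' @param estimate,se point estimate(s) and standard error(s).
#' @param gamma significance level (default 0.05, i.e. 95\% intervals).
#' @return matrix with columns \code{lower}, \code{upper}.
#' @export
wald_ci <- function(estimate, se, gamma = 0.05) {
  z <- stats::qnorm(1 - gamma / 2)
  cbind(lower = estimate - z * se, upper = estimate + z * se)
}

#' Random-effects pooling of study-specific estimates
#'
#' DerSimonian--Laird random-effects meta-analysis of study-specific
#' coefficients: the between-study variance \eqn{\tau^2} is the moment
#' estimator truncated at zero, weights are \eqn{1/(se_k^2 + \tau^2)}, and
#' the pooled estimate and standard error follow inverse-variance rules.
#' With a single study the study's own estimate and SE are returned with
#' \code{tau2 = NA}.
#'
#' @param estimates per-study estimates.
#' @param ses per-study standard errors (finite, > 0 with >= 2 studies).
#' @return list of class \code{"pooled_effect"} with \code{estimate},
#'   \code{se}, \code{tau2}, \code{k}, and the per-study inputs.
#' @examples
#' pool_study_effects(c(1, 3), c(0.5, 0.5))
#' @export
pool_study_effects <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses))
  k <- length(estimates)
  if (k == 1L) {
    out <- list(estimate = estimates, se = ses, tau2 = NA_real_, k = 1L,
                study_estimates = estimates, study_ses = ses)
    class(out) <- "pooled_effect"
    return(out)
  }
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("need finite positive per-study standard errors", call. = FALSE)
  w <- 1 / ses^2
  xbar <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - xbar)^2)
  Cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / Cc)
  wstar <- 1 / (ses^2 + tau2)
  est <- sum(wstar * estimates) / sum(wstar)
  out <- list(estimate = est, se = sqrt(1 / sum(wstar)), tau2 = tau2, k = k,
              study_estimates = estimates, study_ses = ses)
  class(out) <- "pooled_effect"
  out
}

#' @export
print.pooled_effect <- function(x, digits = 4, ...) {
  cat(sprintf("Random-effects pooled estimate: %.*g (SE %.*g), tau2 = %s, k = %d\n",
              digits, x$estimate, digits, x$se,
              if (is.na(x$tau2)) "NA" else signif(x$tau2, digits), x$k))
  invisible(x)
}

#' Bootstrap standard errors for a one-stage joint meta-analysis fit
#'
#' Resamples subjects with replacement within each study (the study structure
#' is preserved), refits the separate and joint models on each resample, and
#' reports the standard deviation of the converged resample estimates with
#' percentile confidence intervals.  Failed resample fits are counted, never
#' imputed; the result is flagged unreliable when more than half fail.
#' Optionally whole studies can be resampled instead
#' (\code{resample = "studies"}) as a sensitivity analysis.
#'
#' @param data an \code{"mjm_data"} object.
#' @param group,reference,extra_basis,spec,control model specification as in
#'   \code{\link{mjm}}.
#' @param B number of bootstrap resamples (>= 2).
#' @param seed integer seed; resampling is reproducible given the seed.
#' @param resample \code{"subjects"} (default) or \code{"studies"}.
#' @return list of class \code{"mjm_boot"}: \code{est} (B x p matrix of
#'   resample coefficient vectors, failed rows NA), \code{se}, \code{ci}
#'   (2.5/97.5 percentiles), \code{n_failed}, \code{reliable}, \code{B}.
#' @export
mjm_boot <- function(data, group = 0, reference = NULL, extra_basis = NULL,
                     spec = NULL, control = mjm_control(), B = 50,
                     seed = NULL, resample = c("subjects", "studies")) {
  stopifnot(inherits(data, "mjm_data"), B >= 2)
  resample <- match.arg(resample)
  if (is.null(spec)) spec <- mjm_spec(group, reference, extra_basis)
  if (!is.null(seed)) set.seed(seed)

  surv <- data$surv
  long <- data$long
  key_s <- paste(surv$study, surv$subject, sep = "\r")
  long_by <- split(seq_len(nrow(long)),
                   factor(paste(long$study, long$subject, sep = "\r"),
                          levels = key_s))

  est <- NULL
  n_failed <- 0L
  for (b in seq_len(B)) {
    if (resample == "subjects") {
      pick <- unlist(lapply(data$studies, function(s) {
        rows <- which(surv$study == s)
        sample(rows, length(rows), replace = TRUE)
      }), use.names = FALSE)
    } else {
      ks <- sample(data$studies, data$K, replace = TRUE)
      pick <- unlist(lapply(ks, function(s) which(surv$study == s)),
                     use.names = FALSE)
    }
    sb <- surv[pick, , drop = FALSE]
    # resampled subjects get fresh unique ids (a subject may be drawn twice)
    sb$subject <- sprintf("b%05d", seq_along(pick))
    if (resample == "studies")
      sb$study <- rep(sprintf("S%02d*", seq_len(data$K)),
                      times = vapply(ks, function(s) sum(surv$study == s), 0L))
    lrows <- long_by[pick]
    reps <- lengths(lrows)
    lb <- long[unlist(lrows, use.names = FALSE), , drop = FALSE]
    lb$subject <- rep(sb$subject, reps)
    lb$study <- rep(sb$study, reps)
    db <- tryCatch(mjm_data(lb, sb), error = function(e) NULL)
    fit <- if (is.null(db)) NULL else
      mjm(db, spec = spec, control = control)
    if (is.null(fit) || isTRUE(fit$failed) || !fit$converged) {
      n_failed <- n_failed + 1L
      co <- NULL
    } else {
      co <- coef(fit)
    }
    if (is.null(est) && !is.null(co))
      est <- matrix(NA_real_, B, length(co),
                    dimnames = list(NULL, names(co)))
    if (!is.null(co)) est[b, ] <- co
  }
  if (is.null(est))
    stop("all bootstrap resamples failed", call. = FALSE)
  se <- apply(est, 2, stats::sd, na.rm = TRUE)
  ci <- t(apply(est, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  structure(list(est = est, se = se, ci = ci, B = B, n_failed = n_failed,
                 reliable = n_failed <= B / 2, resample = resample),
            class = "mjm_boot")
}

#' @export
print.mjm_boot <- function(x, digits = 4, ...) {
  cat(sprintf("Bootstrap (%s, B = %d, %d failed%s)\n", x$resample, x$B,
              x$n_failed, if (!x$reliable) "; UNRELIABLE" else ""))
  print(round(cbind(SE = x$se, x$ci), digits))
  invisible(x)
}
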