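#' @export
print.mjm <- function(x, digits = 4, ...) {
  cat("One-stage joint meta-analysis model (group ", x$spec$group, ")\n",
      sep = "")
  if (isTRUE(x$failed)) {
    cat("  FAILED FIT:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  %d studies, %d subjects, %d events; loglik %.2f (%s, %d EM iterations)\n",
              x$K, x$n, x$n_events, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("Longitudinal sub-model:\n")
  print(round(x$beta1, digits))
  cat("Survival sub-model:\n")
  print(round(x$beta2, digits))
  cat("Association:\n")
  print(round(x$alpha, digits))
  invisible(x)
}

#' @export
summary.mjm <- function(object, ...) {
  x <- object
  if (isTRUE(x$failed)) {
    cat("Failed joint fit:", x$message, "\n")
    return(invisible(x))
  }
  ctab <- function(est, se) {
    z <- est / se
    data.frame(Estimate = est, `Std.Err` = se,
               `z` = z, `p` = 2 * stats::pnorm(-abs(z)),
               check.names = FALSE)
  }
  out <- list(
    spec = x$spec,
    longitudinal = ctab(x$beta1, x$se$beta1),
    survival = ctab(x$beta2, x$se$beta2),
    association = ctab(x$alpha, x$se$alpha),
    sigma_e2 = x$sigma_e2, D = x$D, A = x$A,
    loglik = x$loglik, converged = x$converged, n_iter = x$n_iter,
    se_method = x$se$method
  )
  class(out) <- "summary.mjm"
  out
}

#' @export
print.summary.mjm <- function(x, digits = 4, ...) {
  cat("One-stage joint meta-analysis model (group ", x$spec$group, ")\n\n",
      sep = "")
  cat("Longitudinal sub-model (linear mixed model):\n")
  print(round(x$longitudinal, digits))
  cat(sprintf("\nResidual variance sigma_e2 = %.*g\n", digits, x$sigma_e2))
  cat("Individual random-effect covariance D:\n")
  print(round(x$D, digits))
  if (!is.null(x$A)) {
    cat("Study random-effect covariance A:\n")
    print(round(x$A, digits))
  }
  cat("\nSurvival sub-model (proportional hazards, Breslow baseline):\n")
  print(round(x$survival, digits))
  cat("\nAssociation parameters:\n")
  print(round(x$association, digits))
  cat(sprintf("\nlog-likelihood %.3f; %s after %d EM iterations\n",
              x$loglik, if (x$converged) "converged" else "not converged",
              x$n_iter))
  cat("Standard errors:", x$se_method,
      "(use mjm_boot for bootstrap SEs)\n")
  invisible(x)
}

#' Extract coefficients from a joint meta-analysis fit
#'
#' @param object an \code{"mjm"} fit.
#' @param ... unused.
#' @return named vector: longitudinal fixed effects (prefix \code{long.}),
#'   survival fixed effects (prefix \code{surv.}), association parameters.
#' @export
coef.mjm <- function(object, ...) {
  if (isTRUE(object$failed)) return(NULL)
  c(stats::setNames(object$beta1, paste0("long.", names(object$beta1))),
    stats::setNames(object$beta2, paste0("surv.", names(object$beta2))),
    object$alpha)
}

#' @export
logLik.mjm <- function(object, ...) {
  if (isTRUE(object$failed)) return(NA_real_)
  p <- length(object$beta1) + length(object$beta2) + length(object$alpha) +
    1L + 3L + if (!is.null(object$A)) ncol(object$A) * (ncol(object$A) + 1) / 2 else 0L
  structure(object$loglik, df = p, class = "logLik")
}

#' Plot a joint meta-analysis fit
#'
#' Shows the EM log-likelihood trace and the cumulative baseline hazard(s).
#'
#' @param x an \code{"mjm"} fit.
#' @param which subset of \code{c("trace", "hazard")}.
#' @param ... passed to the base plotting functions.
#' @export
plot.mjm <- function(x, which = c("trace", "hazard"), ...) {
  if (isTRUE(x$failed)) stop("cannot plot a failed fit", call. = FALSE)
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if ("trace" %in% which) {
    graphics::plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
                   xlab = "EM iteration", ylab = "log-likelihood",
                   main = "EM trace", ...)
  }
  if ("hazard" %in% which) {
    tmax <- max(unlist(lapply(x$baseline, `[[`, "time")), 0)
    hmax <- max(unlist(lapply(x$baseline, function(b) sum(b$haz))), 0.01)
    graphics::plot(NA, xlim = c(0, tmax), ylim = c(0, hmax),
                   xlab = "time", ylab = "cumulative baseline hazard",
                   main = "Breslow baseline", ...)
    for (s in seq_along(x$baseline)) {
      b <- x$baseline[[s]]
      if (length(b$time))
        graphics::lines(stats::stepfun(b$time, c(0, cumsum(b$haz))),
                        do.points = FALSE, col = s)
    }
    if (length(x$baseline) > 1L)
      graphics::legend("topleft", legend = names(x$baseline),
                       col = seq_along(x$baseline), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Study-specific treatment effects from a joint or separate fit
#'
#' For model groups with fixed treatment-by-study interactions, reconstructs
#' the study-specific treatment effects: the reference study's effect is the
#' main treatment coefficient and non-reference studies add their interaction
#' coefficient.  Standard errors combine the coefficient variances and
#' covariance.
#'
#' @param beta named coefficient vector containing \code{treat} and
#'   \code{treat:study<label>} entries.
#' @param vcov corresponding covariance matrix (same order as \code{beta});
#'   may be \code{NULL}, yielding \code{NA} standard errors.
#' @param studies all study labels; the reference is the one without an
#'   interaction column.
#' @return data frame with columns \code{study}, \code{estimate}, \code{se}.
#' @export
study_effects <- function(beta, vcov = NULL, studies) {
  stopifnot("treat" %in% names(beta))
  est <- se <- numeric(length(studies))
  i0 <- match("treat", names(beta))
  for (j in seq_along(studies)) {
    nm <- paste0("treat:study", studies[j])
    if (nm %in% names(beta)) {
      i1 <- match(nm, names(beta))
      est[j] <- beta[i0] + beta[i1]
      se[j] <- if (is.null(vcov)) NA_real_ else
        sqrt(vcov[i0, i0] + vcov[i1, i1] + 2 * vcov[i0, i1])
    } else {
      est[j] <- beta[i0]
      se[j] <- if (is.null(vcov)) NA_real_ else sqrt(vcov[i0, i0])
    }
  }
  data.frame(study = studies, estimate = est, se = se)
}
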