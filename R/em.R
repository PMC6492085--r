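#' Control parameters for the joint EM fit
#'
#' @param max_iter maximum number of EM iterations.
#' @param tol_param relative parameter-change convergence tolerance (applied
#'   to all scalar parameters except the baseline-hazard increments).
#' @param tol_loglik log-likelihood change tolerance, relative to
#'   \code{1 + |loglik|}.
#' @param n_quad Gauss-Hermite points per dimension for the individual-level
#'   random effects (2 dimensions).
#' @param n_quad_study Gauss-Hermite points per dimension for the study-level
#'   random effects.
#' @param newton_max_iter,newton_tol inner Newton-Raphson controls for the
#'   survival/association update (step-halving is always applied).
#' @param fix_alpha optional named numeric vector fixing association
#'   parameters instead of estimating them, e.g.
#'   \code{c(alpha2 = 0, alpha3 = 0)}.
#' @param verbose print the log-likelihood each iteration.
#' @return a list of class \code{"mjm_control"}.
#' @export
mjm_control <- function(max_iter = 500L, tol_param = 1e-4, tol_loglik = 1e-6,
                        n_quad = 5L, n_quad_study = 5L,
                        newton_max_iter = 30L, newton_tol = 1e-7,
                        fix_alpha = NULL, verbose = FALSE) {
  stopifnot(max_iter >= 1, n_quad >= 2, n_quad_study >= 2,
            tol_param > 0, tol_loglik > 0)
  if (!is.null(fix_alpha) &&
      !all(names(fix_alpha) %in% c("alpha2", "alpha3")))
    stop("'fix_alpha' names must be among 'alpha2', 'alpha3'", call. = FALSE)
  structure(list(max_iter = as.integer(max_iter), tol_param = tol_param,
                 tol_loglik = tol_loglik, n_quad = as.integer(n_quad),
                 n_quad_study = as.integer(n_quad_study),
                 newton_max_iter = as.integer(newton_max_iter),
                 newton_tol = newton_tol, fix_alpha = fix_alpha,
                 verbose = isTRUE(verbose)),
            class = "mjm_control")
}

#' Fit a one-stage joint meta-analysis model by EM
#'
#' Fits the one-stage joint model for multi-study longitudinal and
#' time-to-event data: a linear mixed longitudinal sub-model and a Cox
#' proportional-hazards survival sub-model with nonparametric (Breslow)
#' baseline hazard, linked by shared zero-mean random effects with
#' association parameters \eqn{\alpha^{(2)}} (individual level) and
#' \eqn{\alpha^{(3)}} (study level, when the model group includes study-level
#' random effects).  In the association structure the longitudinal time is
#' replaced by the subject's survival time, so the random-effect contribution
#' to the log hazard is \eqn{\alpha_2 (b_0 + b_1 T_S) + \alpha_3 z_3' b^{(3)}}.
#'
#' Fitting alternates an E-step -- posterior expectations of random-effect
#' functions computed by pseudo-adaptive Gauss-Hermite quadrature, with
#' abscissae centered at the conditional modes (and scaled by the conditional
#' covariances) from the initial separate mixed-model fit -- and an M-step
#' with closed-form updates for the longitudinal coefficients (generalized
#' least squares), residual variance and random-effect covariances, a
#' Breslow-profiled baseline hazard, and a damped Newton-Raphson update of
#' the survival coefficients and association parameters on the profiled
#' expected log-likelihood.  Starting values come from the separate fits;
#' association parameters start at zero.
#'
#' Non-convergence, singular starting fits and numerical failure do not throw
#' errors: the returned object carries \code{converged = FALSE} (and
#' \code{failed = TRUE} with a message when no usable estimates exist), so
#' that large simulation grids can count failures.
#'
#' @param data an \code{"mjm_data"} object (see \code{\link{mjm_data}},
#'   \code{\link{read_mjm_data}}, \code{\link{sim_joint_data}}).
#' @param group model group 0..5; see \code{\link{mjm_spec}}.
#' @param reference optional reference study label for fixed study effects.
#' @param extra_basis optional extra longitudinal bases, see
#'   \code{\link{mjm_spec}}.
#' @param spec alternatively a ready-made \code{"mjm_spec"} (overrides
#'   \code{group}, \code{reference}, \code{extra_basis}).
#' @param control an \code{\link{mjm_control}} list.
#' @param separate optionally, a pre-computed \code{\link{mjm_separate}} fit
#'   of the same specification, reused for starting values and quadrature
#'   centering.
#' @return An object of class \code{"mjm"} with components \code{beta1},
#'   \code{beta2}, \code{alpha} (named vector), \code{sigma_e2}, \code{D},
#'   \code{A}, \code{baseline} (per-stratum event times and hazard
#'   increments), \code{loglik}, \code{loglik_trace}, \code{converged},
#'   \code{n_iter}, \code{se} (approximate standard errors; see Details),
#'   \code{ranef} (posterior means of the random effects), \code{separate},
#'   \code{spec}, \code{failed}, \code{message}.
#' @details The reported standard errors are approximations: survival and
#'   association SEs come from the inverse curvature of the profiled EM
#'   objective at convergence, and longitudinal SEs from the initial mixed
#'   model; with a nonparametric baseline hazard these underestimate the
#'   sampling variability, and \code{\link{mjm_boot}} should be used for
#'   inference-grade standard errors.
#' @examples
#' sc <- sim_scenario(K = 2, n_per_study = 40)
#' d <- sim_joint_data(sc, seed = 7)$data
#' fit <- mjm(d, group = 0, control = mjm_control(max_iter = 30))
#' fit
#' @export
mjm <- function(data, group = 0, reference = NULL, extra_basis = NULL,
                spec = NULL, control = mjm_control(), separate = NULL) {
  cl <- match.call()
  stopifnot(inherits(data, "mjm_data"), inherits(control, "mjm_control"))
  if (is.null(spec)) spec <- mjm_spec(group, reference, extra_basis)
  if (is.null(separate)) separate <- mjm_separate(data, spec = spec)
  if (!separate$converged) {
    return(mjm_failure(spec, cl, paste("initial separate fit failed:",
                                       separate$message), separate))
  }
  des <- separate$design
  st <- em_state(des, separate, control)
  res <- tryCatch(em_run(st, control),
                  error = function(e) conditionMessage(e))
  if (is.character(res))
    return(mjm_failure(spec, cl, paste("EM failure:", res), separate))
  out <- em_collect(res, st, des, separate, control)
  out$call <- cl
  out
}

mjm_failure <- function(spec, call, msg, separate = NULL) {
  structure(list(spec = spec, call = call, failed = TRUE, converged = FALSE,
                 message = msg, separate = separate),
            class = "mjm")
}

# ---------------------------------------------------------------------------
# internal state: subjects reordered into contiguous study blocks, fixed
# quadrature grids, per-subject sufficient statistics, and the risk-set /
# event-time bookkeeping of the (possibly stratified) baseline hazard.
em_state <- function(des, separate, control) {
  n <- length(des$Tsurv)
  perm <- order(des$study)                  # contiguous study blocks
  inv <- integer(n); inv[perm] <- seq_len(n)
  lf <- separate$long
  d3 <- ncol(des$Z3)

  sub <- list(Tsurv = des$Tsurv[perm], delta = des$delta[perm],
              treat = des$treat[perm],
              X2 = des$X2[perm, , drop = FALSE],
              strata = des$strata[perm], study = des$study[perm])
  nk <- as.integer(table(factor(sub$study, levels = seq_along(des$studies))))

  subj_new <- inv[des$subj]
  t_l <- des$t

  # fixed per-subject longitudinal stats
  m_i <- acc_by(rep(1, length(t_l)), subj_new, n)
  St  <- acc_by(t_l, subj_new, n)
  Stt <- acc_by(t_l^2, subj_new, n)

  # pseudo-adaptive individual grids (2-dim), centered at separate-fit modes
  rule2 <- gh_rule(control$n_quad, 2L)
  mo2 <- lf$modes2[perm, , drop = FALSE]
  cv2 <- lf$condvar2[, , perm, drop = FALSE]
  l11 <- sqrt(cv2[1, 1, ])
  l21 <- cv2[2, 1, ] / l11
  l22 <- sqrt(pmax(cv2[2, 2, ] - l21^2, 1e-12))
  s2 <- sqrt(2)
  B0 <- mo2[, 1] + s2 * outer(l11, rule2$nodes[, 1])
  B1 <- mo2[, 2] + s2 * (outer(l21, rule2$nodes[, 1]) +
                         outer(l22, rule2$nodes[, 2]))
  logw2_base <- matrix(rule2$logw, n, length(rule2$logw), byrow = TRUE)
  logjac2 <- sum(log(2) + log(l11) + log(l22))

  # study-level grids
  K <- length(des$studies)
  if (d3 > 0L) {
    rule3 <- gh_rule(control$n_quad_study, d3)
    Q3 <- nrow(rule3$nodes)
    B3a <- matrix(0, K, Q3); B3b <- matrix(0, K, Q3)
    logjac3 <- 0
    for (k in seq_len(K)) {
      Sk <- matrix(lf$condvar3[, , k], d3, d3)
      g <- adapt_grid(rule3, lf$modes3[k, ], Sk)
      if (d3 == 2L) {
        B3a[k, ] <- g$B[, 1]; B3b[k, ] <- g$B[, 2]
      } else {
        B3b[k, ] <- g$B[, 1]          # treatment-only study effect
      }
      logjac3 <- logjac3 + g$logjac
    }
    logw3_base <- matrix(rule3$logw, K, Q3, byrow = TRUE)
  } else {
    Q3 <- 1L
    B3a <- matrix(0, K, 1); B3b <- matrix(0, K, 1)
    logw3_base <- matrix(0, K, 1)
    logjac3 <- 0
  }

  # risk-set / event-time bookkeeping (per hazard stratum)
  rs <- make_riskset(sub$Tsurv, sub$delta, sub$strata)
  ue <- unlist(lapply(rs, `[[`, "ue"), use.names = FALSE)
  dr <- unlist(lapply(rs, `[[`, "dr"), use.names = FALSE)
  str_off <- c(0L, cumsum(vapply(rs, function(r) length(r$ue), 0L)))
  stratum0 <- integer(n)
  cumpos <- integer(n)
  for (s in seq_along(rs)) {
    stratum0[rs[[s]]$idx] <- s - 1L
    cumpos[rs[[s]]$idx] <- rs[[s]]$cumpos
  }

  # initial parameters: separate fits, association zero, Breslow baseline
  sf <- separate$surv
  beta2 <- sf$beta2
  riskexp0 <- exp(as.numeric(sub$X2 %*% beta2))
  bl0 <- breslow_baseline(rs, riskexp0, sub$delta)
  lam0 <- unlist(lapply(bl0$haz, `[[`, "haz"), use.names = FALSE)

  A0 <- if (d3 > 0L) matrix(as.numeric(lf$A), d3, d3) else NULL
  alpha <- c(alpha2 = 0)
  if (d3 > 0L) alpha <- c(alpha, alpha3 = 0)
  if (!is.null(control$fix_alpha)) {
    keep <- names(control$fix_alpha)[names(control$fix_alpha) %in%
                                       names(alpha)]
    alpha[keep] <- control$fix_alpha[keep]
  }

  X1 <- des$X1
  XtX <- crossprod(X1)

  list(n = n, K = K, d3 = d3, nk = nk, perm = perm, sub = sub,
       y = des$y, t_l = t_l, X1 = X1, XtX = XtX, subj = subj_new,
       m_i = m_i, St = St, Stt = Stt,
       B0 = B0, B1 = B1, logw2_base = logw2_base,
       B3a = B3a, B3b = B3b, logw3_base = logw3_base, Q3 = Q3,
       logjac = logjac2 + logjac3,
       rs = rs, ue = ue, dr = dr, str_off = str_off,
       stratum0 = stratum0, cumpos = cumpos,
       init = list(beta1 = lf$beta1, sigma2 = lf$sigma_e2, D = lf$D, A = A0,
                   beta2 = beta2, alpha = alpha,
                   lam = lam0, logh0 = bl0$logh0))
}

acc_by <- function(x, g, n) {
  out <- numeric(n)
  tmp <- rowsum(x, g)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

# E-step: posterior moments + observed log-likelihood via the quadrature
# kernel.  `par` carries the current parameters and baseline hazard.
em_estep <- function(st, par) {
  r0 <- st$y - as.numeric(st$X1 %*% par$beta1)
  Sr  <- acc_by(r0, st$subj, st$n)
  Srt <- acc_by(r0 * st$t_l, st$subj, st$n)
  Srr <- acc_by(r0^2, st$subj, st$n)

  Dinv <- solve(par$D)
  logdetD <- determinant(par$D)$modulus[1]
  logw2 <- st$logw2_base -
    0.5 * (Dinv[1, 1] * st$B0^2 + 2 * Dinv[1, 2] * st$B0 * st$B1 +
             Dinv[2, 2] * st$B1^2) - log(2 * pi) - 0.5 * logdetD

  if (st$d3 > 0L) {
    if (st$d3 == 2L) {
      Ainv <- solve(par$A)
      logdetA <- determinant(par$A)$modulus[1]
      q3 <- Ainv[1, 1] * st$B3a^2 + 2 * Ainv[1, 2] * st$B3a * st$B3b +
        Ainv[2, 2] * st$B3b^2
      logw3 <- st$logw3_base - 0.5 * q3 - log(2 * pi) - 0.5 * logdetA
    } else {
      a <- as.numeric(par$A)
      logw3 <- st$logw3_base - 0.5 * st$B3b^2 / a -
        0.5 * (log(2 * pi) + log(a))
    }
  } else {
    logw3 <- st$logw3_base
  }

  xb2 <- as.numeric(st$sub$X2 %*% par$beta2)
  a3 <- if ("alpha3" %in% names(par$alpha)) par$alpha[["alpha3"]] else 0
  ke <- mjm_estep_kernel(st$nk, st$m_i, st$St, st$Stt, Sr, Srt, Srr,
                         st$sub$treat, st$sub$Tsurv, st$sub$delta,
                         par$logh0, xb2,
                         st$stratum0, st$cumpos, st$ue, par$lam, st$str_off,
                         st$B0, st$B1, logw2,
                         st$B3a, st$B3b, logw3,
                         par$sigma2, par$alpha[["alpha2"]], a3)
  ke$loglik <- ke$loglik + st$logjac
  ke$xb2 <- xb2
  ke
}

# Profiled expected survival log-likelihood, score and Hessian in
# psi = (beta2, alpha2[, alpha3]); the baseline hazard is profiled out by its
# Breslow expression, and the association is evaluated at the risk-set event
# times (time-varying covariate).
surv_profile <- function(psi, st, ke, free) {
  p2 <- ncol(st$sub$X2)
  beta2 <- psi[seq_len(p2)]
  a2 <- psi[p2 + 1L]
  a3 <- if (length(psi) > p2 + 1L) psi[p2 + 2L] else 0
  xb2 <- as.numeric(st$sub$X2 %*% beta2)
  sc <- mjm_surv_score(st$nk, st$sub$treat, st$sub$Tsurv, xb2, st$sub$X2,
                       st$stratum0, st$str_off, st$ue, st$dr,
                       st$B0, st$B1, st$B3a, st$B3b,
                       ke$P, ke$CW, a2, a3, st$d3)
  if (!isTRUE(sc$ok)) return(NULL)

  Ew2T <- ke$mom[, 1] + ke$mom[, 2] * st$sub$Tsurv
  Ew3 <- ke$mom[, 6]
  ev <- st$sub$delta == 1
  lp <- sum(xb2[ev]) + a2 * sum(Ew2T[ev]) +
    (if (st$d3 > 0L) a3 * sum(Ew3[ev]) else 0) - sc$lp_risk
  score_ev <- c(colSums(st$sub$X2[ev, , drop = FALSE]), sum(Ew2T[ev]))
  if (st$d3 > 0L) score_ev <- c(score_ev, sum(Ew3[ev]))
  score <- score_ev - sc$score_risk
  hess <- -sc$hess_risk
  list(lp = lp, score = score[free], hess = hess[free, free, drop = FALSE],
       S0 = sc$S0)
}

# damped Newton-Raphson on the profiled expected survival log-likelihood
newton_psi <- function(psi0, st, ke, free, control,
                       max_steps = control$newton_max_iter) {
  psi <- psi0
  pr <- surv_profile(psi, st, ke, free)
  if (is.null(pr)) stop("survival update: non-finite risk-set sums")
  if (!any(free)) return(list(psi = psi, pr = pr))
  for (it in seq_len(max_steps)) {
    step <- tryCatch(solve(pr$hess, pr$score), error = function(e) NULL)
    if (is.null(step))
      step <- solve(pr$hess - 1e-6 * diag(nrow(pr$hess)), pr$score)
    step <- -step
    ok <- FALSE
    fac <- 1
    for (h in 1:20) {
      cand <- psi
      cand[free] <- psi[free] + fac * step
      prc <- surv_profile(cand, st, ke, free)
      if (!is.null(prc) && is.finite(prc$lp) && prc$lp >= pr$lp - 1e-12) {
        ok <- TRUE; break
      }
      fac <- fac / 2
    }
    if (!ok) break
    moved <- max(abs(fac * step))
    psi <- cand; pr <- prc
    if (max(abs(pr$score)) < control$newton_tol || moved < 1e-10) break
  }
  list(psi = psi, pr = pr)
}

em_run <- function(st, control) {
  par <- st$init
  p2 <- ncol(st$sub$X2)
  free <- c(rep(TRUE, p2), TRUE, if (st$d3 > 0L) TRUE)
  fx <- control$fix_alpha
  if (!is.null(fx)) {
    if ("alpha2" %in% names(fx)) free[p2 + 1L] <- FALSE
    if ("alpha3" %in% names(fx) && st$d3 > 0L) free[p2 + 2L] <- FALSE
  }

  trace <- numeric(0)
  converged <- FALSE
  final_hess <- NULL

  for (iter in seq_len(control$max_iter)) {
    ke <- em_estep(st, par)
    if (!is.finite(ke$loglik)) stop("non-finite log-likelihood")
    trace <- c(trace, ke$loglik)
    if (control$verbose)
      cat(sprintf("iter %3d  loglik %.6f\n", iter, ke$loglik))

    old <- par_vector(par)

    # longitudinal updates (closed form given the posterior moments)
    mom <- ke$mom
    Ere_l <- mom[st$subj, 1] + mom[st$subj, 2] * st$t_l + mom[st$subj, 6]
    beta1 <- as.numeric(solve(st$XtX, crossprod(st$X1, st$y - Ere_l)))
    names(beta1) <- names(par$beta1)
    r <- st$y - as.numeric(st$X1 %*% beta1)
    # E[(b0 + b1 t + c3)^2] assembled from the posterior moments
    M2 <- mom[st$subj, 3] + 2 * st$t_l * mom[st$subj, 4] +
      st$t_l^2 * mom[st$subj, 5] +
      2 * mom[st$subj, 8] + 2 * st$t_l * mom[st$subj, 9] + mom[st$subj, 7]
    sigma2 <- mean(r^2 - 2 * r * Ere_l + M2)
    if (!is.finite(sigma2) || sigma2 <= 0) stop("residual variance collapsed")

    D <- matrix(c(mean(mom[, 3]), mean(mom[, 4]),
                  mean(mom[, 4]), mean(mom[, 5])), 2, 2,
                dimnames = dimnames(par$D))
    A <- par$A
    if (st$d3 == 2L) {
      A <- matrix(c(mean(ke$Eb3b3[, 1]), mean(ke$Eb3b3[, 2]),
                    mean(ke$Eb3b3[, 2]), mean(ke$Eb3b3[, 3])), 2, 2,
                  dimnames = dimnames(par$A))
    } else if (st$d3 == 1L) {
      A <- matrix(mean(ke$Eb3b3[, 3]), 1, 1, dimnames = dimnames(par$A))
    }
    if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < 1e-12)
      stop("individual random-effect covariance became singular")
    if (st$d3 > 0L &&
        min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) < 1e-12)
      stop("study random-effect covariance became singular")

    # survival + association update with baseline hazard profiled out
    a3 <- if ("alpha3" %in% names(par$alpha)) par$alpha[["alpha3"]] else NULL
    psi0 <- c(par$beta2, par$alpha[["alpha2"]], a3)
    nw <- newton_psi(psi0, st, ke, free, control)
    beta2 <- nw$psi[seq_len(p2)]
    names(beta2) <- names(par$beta2)
    alpha <- par$alpha
    alpha[["alpha2"]] <- nw$psi[p2 + 1L]
    if (st$d3 > 0L) alpha[["alpha3"]] <- nw$psi[p2 + 2L]
    final_hess <- nw$pr$hess

    # Breslow baseline at the updated coefficients
    lam <- st$dr / nw$pr$S0
    logh0 <- numeric(st$n)
    for (s in seq_along(st$rs)) {
      rr <- st$rs[[s]]
      if (!length(rr$ue)) next
      lam_s <- lam[(st$str_off[s] + 1L):st$str_off[s + 1L]]
      evs <- which(st$sub$delta[rr$idx] == 1)
      logh0[rr$idx][evs] <- log(lam_s[rr$ev_at[evs]])
    }

    par <- list(beta1 = beta1, sigma2 = sigma2, D = D, A = A,
                beta2 = beta2, alpha = alpha, lam = lam, logh0 = logh0)

    new <- par_vector(par)
    # mixed absolute-relative change: relative for |theta| >> 0.1,
    # absolute (x10) for near-zero parameters
    rel <- max(abs(new - old) / (abs(old) + 0.1))
    dll <- if (iter > 1L) trace[iter] - trace[iter - 1L] else Inf
    if (rel < control$tol_param &&
        abs(dll) < control$tol_loglik * (1 + abs(trace[iter]))) {
      converged <- TRUE
      break
    }
  }

  ke <- em_estep(st, par)
  trace <- c(trace, ke$loglik)
  list(par = par, trace = trace, converged = converged,
       n_iter = length(trace) - 1L, ke = ke, hess = final_hess, free = free)
}

par_vector <- function(par) {
  c(par$beta1, par$sigma2, par$D[lower.tri(par$D, diag = TRUE)],
    if (!is.null(par$A)) par$A[lower.tri(par$A, diag = TRUE)],
    par$beta2, par$alpha)
}

em_collect <- function(res, st, des, separate, control) {
  par <- res$par
  p2 <- ncol(st$sub$X2)
  # approximate SEs: survival/association from the profiled curvature,
  # longitudinal from the initial mixed model (see ?mjm Details)
  npsi <- p2 + 1L + (st$d3 > 0L)
  se_psi <- rep(NA_real_, npsi)
  vcov_psi <- matrix(NA_real_, npsi, npsi)
  if (!is.null(res$hess)) {
    vc <- tryCatch(solve(-res$hess), error = function(e) NULL)
    if (!is.null(vc)) {
      se_psi[res$free] <- sqrt(pmax(diag(vc), 0))
      vcov_psi[res$free, res$free] <- vc
    }
  }
  nm_psi <- c(names(par$beta2), names(par$alpha))
  names(se_psi) <- nm_psi
  dimnames(vcov_psi) <- list(nm_psi, nm_psi)
  se_beta1 <- sqrt(diag(separate$long$vcov_beta1))
  names(se_beta1) <- names(par$beta1)

  # baseline hazard increments per stratum
  strat <- des$spec$stratified_hazard
  baseline <- lapply(seq_along(st$rs), function(s) {
    sel <- if (st$str_off[s + 1L] > st$str_off[s])
      (st$str_off[s] + 1L):st$str_off[s + 1L] else integer(0)
    list(time = st$ue[sel], haz = par$lam[sel])
  })
  names(baseline) <- if (strat) des$studies else "all"

  # posterior random-effect means, back in the original subject order
  unperm <- integer(st$n); unperm[st$perm] <- seq_len(st$n)
  ranef2 <- res$ke$mom[unperm, 1:2, drop = FALSE]
  colnames(ranef2) <- c("intercept", "slope")
  ranef3 <- NULL
  if (st$d3 > 0L) {
    ranef3 <- if (st$d3 == 2L) res$ke$Eb3[, 1:2, drop = FALSE]
      else res$ke$Eb3[, 2, drop = FALSE]
    rownames(ranef3) <- des$studies
    colnames(ranef3) <- des$spec$study_re
  }

  structure(
    list(spec = des$spec, studies = des$studies, reference = des$reference,
         n = st$n, K = st$K, n_events = sum(st$sub$delta),
         beta1 = par$beta1, beta2 = par$beta2, alpha = par$alpha,
         sigma_e2 = par$sigma2, D = par$D, A = par$A,
         baseline = baseline,
         loglik = res$trace[length(res$trace)],
         loglik_trace = res$trace,
         converged = res$converged, n_iter = res$n_iter,
         se = list(beta1 = se_beta1,
                   beta2 = se_psi[seq_len(p2)],
                   alpha = se_psi[p2 + seq_len(length(par$alpha))],
                   method = "profile-curvature/initial-LMM approximation"),
         vcov_psi = vcov_psi,
         vcov_beta1 = separate$long$vcov_beta1,
         ranef = list(individual = ranef2, study = ranef3),
         separate = separate, control = control,
         failed = FALSE, message = if (res$converged) "converged"
           else "maximum iterations reached"),
    class = "mjm"
  )
}
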