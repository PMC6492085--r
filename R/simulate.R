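#' Gompertz parameters from target event-time moments
#'
#' Computes the Gompertz shape and log-scale parameters that give event times
#' a target mean and standard deviation, using the extreme-value
#' representation of the Gompertz distribution: the shape is
#' \eqn{\theta_1 = \pi / (\sigma_0 \sqrt 6)} and the log-scale is
#' \eqn{\theta_0 = \log\theta_1 - \gamma - \mu_0 \theta_1}, with
#' \eqn{\gamma} Euler's constant.  The baseline hazard implied is
#' \eqn{\lambda_0(t) = \exp(\theta_0 + \theta_1 t)}.
#'
#' @param mu0 target mean event time.
#' @param sigma0 target standard deviation of event times (> 0).
#' @return list with components \code{theta0}, \code{theta1}, \code{mu0},
#'   \code{sigma0}.
#' @examples
#' gompertz_moments(3, 0.5) # theta1 ~ 2.5651, theta0 ~ -7.330517
#' @export
gompertz_moments <- function(mu0, sigma0) {
  if (!is.numeric(sigma0) || length(sigma0) != 1L || sigma0 <= 0)
    stop("'sigma0' must be a single positive number", call. = FALSE)
  euler_gamma <- -digamma(1)
  theta1 <- pi / (sigma0 * sqrt(6))
  theta0 <- log(theta1) - euler_gamma - mu0 * theta1
  list(theta0 = theta0, theta1 = theta1, mu0 = mu0, sigma0 = sigma0)
}

#' Simulate event times under the shared random-effects Gompertz hazard
#'
#' Inverts the cumulative hazard of a proportional-hazards model with a
#' Gompertz baseline and a time-constant plus time-varying shared
#' random-effect association:
#' \eqn{\lambda(t) = \exp(\theta_0 + \theta_1 t)\exp(\beta_{21} treat +
#' \alpha_2 (b_0 + b_1 t) + \alpha_3 w_3)}.  The effective shape is
#' \eqn{\theta_1 + \alpha_2 b_1}; when it is negative the subject has positive
#' probability of never experiencing the event ("cure"), in which case the
#' latent event time is \code{Inf}.
#'
#' @param U uniform(0, 1) draws, one per subject.
#' @param treat 0/1 treatment indicator per subject.
#' @param b0,b1 individual-level random intercept and slope per subject.
#' @param w3 study-level random-effect contribution to the log hazard per
#'   subject (the term multiplied by \code{alpha3}); 0 when absent.
#' @param beta21 treatment log-hazard ratio.
#' @param alpha2,alpha3 association parameters at the individual and study
#'   level.
#' @param gompertz list from \code{\link{gompertz_moments}} (or any list with
#'   \code{theta0}, \code{theta1}).
#' @param cure_condition \code{"full"} (default) evaluates the cure
#'   probability with the full time-constant linear predictor
#'   \eqn{\theta_0 + \beta_{21} treat + \alpha_2 b_0 + \alpha_3 w_3};
#'   \code{"reduced"} uses only \eqn{\theta_0 + \alpha_2 b_0}.  The full form
#'   is the one consistent with the inversion formula; the reduced form is
#'   retained for comparison.
#' @return numeric vector of latent event times; \code{Inf} marks cured
#'   subjects.
#' @export
sim_event_times <- function(U, treat, b0, b1, w3 = 0, beta21, alpha2, alpha3,
                            gompertz, cure_condition = c("full", "reduced")) {
  cure_condition <- match.arg(cure_condition)
  if (any(U <= 0 | U >= 1)) stop("'U' must lie in (0, 1)", call. = FALSE)
  n <- length(U)
  treat <- rep_len(treat, n); b0 <- rep_len(b0, n); b1 <- rep_len(b1, n)
  w3 <- rep_len(w3, n)
  th0 <- gompertz$theta0; th1 <- gompertz$theta1
  shape <- th1 + alpha2 * b1
  eta <- th0 + beta21 * treat + alpha2 * b0 + alpha3 * w3
  eta_cure <- if (cure_condition == "full") eta else th0 + alpha2 * b0

  te <- numeric(n)
  cured <- shape < 0 & U < exp(exp(eta_cure) / shape)
  te[cured] <- Inf
  idx <- which(!cured)
  if (length(idx)) {
    sh <- shape[idx]
    arg <- 1 + sh * (-log(U[idx])) / exp(eta[idx])
    bad <- arg <= 0 | abs(sh) < 1e-12
    # exponential limit at shape == 0
    zero <- abs(sh) < 1e-12
    out <- numeric(length(idx))
    out[!zero] <- log(arg[!zero]) / sh[!zero]
    out[zero] <- -log(U[idx][zero]) / exp(eta[idx][zero])
    if (any(arg <= 0 & !zero))
      stop("non-positive argument in event-time inversion; cure conditions ",
           "should have intercepted this case", call. = FALSE)
    te[idx] <- out
  }
  te
}

#' Simulate exponential censoring times
#'
#' @param U uniform(0, 1) draws.
#' @param lambda_cens exponential censoring rate (> 0).
#' @return censoring times \code{-log(U) / lambda_cens}.
#' @export
sim_censoring <- function(U, lambda_cens) {
  if (lambda_cens <= 0) stop("'lambda_cens' must be > 0", call. = FALSE)
  if (any(U <= 0 | U >= 1)) stop("'U' must lie in (0, 1)", call. = FALSE)
  -log(U) / lambda_cens
}

#' Define a simulation scenario for multi-study joint data
#'
#' Collects the full parameter set of the package's multi-study joint-data
#' generator.  The defaults are the base configuration of the simulation
#' study: 5 studies of 500 subjects randomized 1:1, up to 10 measurements on
#' the grid 0, 0.25, 0.5, 1, ..., 4, fixed effects
#' \eqn{\beta_{10}=1, \beta_{11}=3, \beta_{12}=2, \beta_{21}=3},
#' individual random-effect covariance \code{D = [1 0.5; 0.5 1.5]},
#' study random-effect covariance \code{A = [1 0.5; 0.5 1.5]},
#' association \eqn{\alpha_2 = \alpha_3 = 0.5}, residual variance 0.01,
#' Gompertz event times with mean 3 and SD 0.5, and exponential censoring
#' with rate \eqn{\exp(-0.426)} (calibrated to a ~25\% event rate).
#'
#' @param K number of studies.
#' @param n_per_study subjects per study (randomized 1:1 to treatment).
#' @param meas_times measurement-time grid starting at 0, strictly
#'   increasing.
#' @param beta10,beta11,beta12 longitudinal fixed effects (intercept, time,
#'   treatment).
#' @param beta21 survival treatment effect.
#' @param D 2x2 covariance of the individual-level random intercept and slope.
#' @param A 2x2 covariance of the study-level random intercept and treatment
#'   effect (positive semidefinite; the zero matrix encodes no between-study
#'   heterogeneity).
#' @param alpha2,alpha3 association parameters.
#' @param sigma_e2 residual variance (> 0).
#' @param mu0,sigma0 target Gompertz event-time mean and SD.
#' @param lambda_cens exponential censoring rate.
#' @param cure_condition passed to \code{\link{sim_event_times}}.
#' @return an object of class \code{"sim_scenario"} (a list of the above plus
#'   the derived \code{gompertz} parameters).
#' @export
sim_scenario <- function(K = 5, n_per_study = 500,
                         meas_times = c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4),
                         beta10 = 1, beta11 = 3, beta12 = 2, beta21 = 3,
                         D = matrix(c(1, 0.5, 0.5, 1.5), 2, 2),
                         A = matrix(c(1, 0.5, 0.5, 1.5), 2, 2),
                         alpha2 = 0.5, alpha3 = 0.5, sigma_e2 = 0.01,
                         mu0 = 3, sigma0 = 0.5,
                         lambda_cens = exp(-0.426),
                         cure_condition = "full") {
  D <- as.matrix(D); A <- as.matrix(A)
  check_psd(D, "D"); check_psd(A, "A")
  if (!identical(dim(D), c(2L, 2L)) || !identical(dim(A), c(2L, 2L)))
    stop("'D' and 'A' must be 2x2", call. = FALSE)
  if (sigma_e2 < 0) stop("'sigma_e2' must be >= 0", call. = FALSE)
  if (meas_times[1] != 0 || is.unsorted(meas_times, strictly = TRUE))
    stop("'meas_times' must be strictly increasing from 0", call. = FALSE)
  if (K < 1 || n_per_study < 2)
    stop("need K >= 1 and n_per_study >= 2", call. = FALSE)
  structure(
    list(K = as.integer(K), n_per_study = as.integer(n_per_study),
         meas_times = meas_times,
         beta10 = beta10, beta11 = beta11, beta12 = beta12, beta21 = beta21,
         D = D, A = A, alpha2 = alpha2, alpha3 = alpha3,
         sigma_e2 = sigma_e2, mu0 = mu0, sigma0 = sigma0,
         lambda_cens = lambda_cens,
         gompertz = gompertz_moments(mu0, sigma0),
         cure_condition = cure_condition),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Joint-data simulation scenario\n")
  cat(sprintf("  %d studies x %d subjects, %d measurement times (0..%g)\n",
              x$K, x$n_per_study, length(x$meas_times), max(x$meas_times)))
  cat(sprintf("  beta = (%g, %g, %g | %g), alpha2 = %g, alpha3 = %g\n",
              x$beta10, x$beta11, x$beta12, x$beta21, x$alpha2, x$alpha3))
  cat(sprintf("  diag(D) = (%g, %g), diag(A) = (%g, %g), sigma_e2 = %g\n",
              x$D[1, 1], x$D[2, 2], x$A[1, 1], x$A[2, 2], x$sigma_e2))
  cat(sprintf("  Gompertz(mu0 = %g, sd0 = %g), lambda_cens = %g\n",
              x$mu0, x$sigma0, x$lambda_cens))
  invisible(x)
}

#' Read a simulation scenario from a YAML configuration file
#'
#' Keys mirror the arguments of \code{\link{sim_scenario}}; \code{D} and
#' \code{A} are given as 4-element row-major vectors.  Preset configurations
#' for the shipped simulation sets live under
#' \code{system.file("extdata", "scenarios", package = "metajoint")}.
#'
#' @param file path to a YAML file.
#' @return a \code{"sim_scenario"} object.
#' @export
read_scenario <- function(file) {
  cfg <- yaml::read_yaml(file)
  cfg <- lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
  for (m in c("D", "A"))
    if (!is.null(cfg[[m]]))
      cfg[[m]] <- matrix(as.numeric(cfg[[m]]), 2, 2, byrow = TRUE)
  if (!is.null(cfg$meas_times)) cfg$meas_times <- as.numeric(cfg$meas_times)
  # allow lambda_cens given as log rate for exactness
  if (!is.null(cfg$log_lambda_cens)) {
    cfg$lambda_cens <- exp(cfg$log_lambda_cens)
    cfg$log_lambda_cens <- NULL
  }
  do.call(sim_scenario, cfg)
}

#' Simulate one multi-study joint dataset
#'
#' Generates study-level random effects (intercept, treatment) from
#' \code{N(0, A)} per study, individual random effects (intercept, slope)
#' from \code{N(0, D)} per subject, longitudinal outcomes on the measurement
#' grid with iid \code{N(0, sigma_e2)} errors, latent Gompertz event times
#' via \code{\link{sim_event_times}}, and exponential censoring.  Survival
#' time is the minimum of the event and censoring times; longitudinal
#' records are kept only at measurement times not exceeding the survival
#' time; treatment is allocated exactly 1:1 within study.
#'
#' @param scenario a \code{"sim_scenario"} object.
#' @param seed integer seed; the generator is fully reproducible given the
#'   scenario and seed.
#' @return list with elements \code{data} (an \code{"mjm_data"} object) and
#'   \code{truth} (a list with per-study random effects \code{b3}, per-subject
#'   random effects \code{b2}, latent event times \code{T_E}, censoring times
#'   \code{T_C}, and the generating scenario).
#' @export
sim_joint_data <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  s <- scenario
  K <- s$K; n <- s$n_per_study
  ntot <- K * n
  study <- rep(sprintf("S%02d", seq_len(K)), each = n)
  subject <- rep(sprintf("id%04d", seq_len(n)), times = K)
  # exact 1:1 allocation within study
  half <- n %/% 2L
  treat <- unlist(lapply(seq_len(K), function(k) {
    tr <- c(rep(1L, half), rep(0L, n - half))
    sample(tr)
  }), use.names = FALSE)

  b3 <- rmvnorm_psd(K, s$A)                     # study: intercept, treatment
  b2 <- rmvnorm_psd(ntot, s$D)                  # subject: intercept, slope
  kk <- rep(seq_len(K), each = n)
  w3 <- b3[kk, 1L] + b3[kk, 2L] * treat         # z3' b3 per subject

  U_e <- stats::runif(ntot)
  U_c <- stats::runif(ntot)
  T_E <- sim_event_times(U_e, treat, b2[, 1L], b2[, 2L], w3,
                         beta21 = s$beta21, alpha2 = s$alpha2,
                         alpha3 = s$alpha3, gompertz = s$gompertz,
                         cure_condition = s$cure_condition)
  T_C <- sim_censoring(U_c, s$lambda_cens)
  T_S <- pmin(T_E, T_C)
  delta <- as.integer(T_E <= T_C)

  m <- length(s$meas_times)
  tmat <- matrix(rep(s$meas_times, each = ntot), ntot, m)
  keep <- tmat <= T_S
  row_i <- rep(seq_len(ntot), times = m)[keep]
  t_l <- tmat[keep]
  eps <- stats::rnorm(length(t_l), 0, sqrt(s$sigma_e2))
  y <- s$beta10 + s$beta11 * t_l + s$beta12 * treat[row_i] +
    b2[row_i, 1L] + b2[row_i, 2L] * t_l + w3[row_i] + eps

  ord <- order(row_i, t_l)
  long <- data.frame(study = study[row_i][ord], subject = subject[row_i][ord],
                     time = t_l[ord], y = y[ord], treat = treat[row_i][ord])
  surv <- data.frame(study = study, subject = subject, survtime = T_S,
                     status = delta, treat = treat)
  list(data = mjm_data(long, surv),
       truth = list(b3 = b3, b2 = b2, T_E = T_E, T_C = T_C,
                    scenario = scenario))
}

# draw from N(0, Sigma) allowing singular / zero Sigma
rmvnorm_psd <- function(n, Sigma) {
  d <- nrow(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, d))
  e <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors %*% (sqrt(ev) * t(e$vectors))
  matrix(stats::rnorm(n * d), n, d) %*% L
}

check_psd <- function(M, name) {
  if (!isSymmetric(unname(M), tol = 1e-8))
    stop("'", name, "' must be symmetric", call. = FALSE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("'", name, "' must be positive semidefinite", call. = FALSE)
  invisible(TRUE)
}
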