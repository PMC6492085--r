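#' Dummy (treatment-contrast) coding of study membership
#'
#' Builds K-1 indicator columns for all non-reference studies, in sorted
#' label order.  A row of all zeros identifies membership of the reference
#' study.
#'
#' @param study character/ factor vector of study labels (one per row).
#' @param labels sorted vector of all study labels.
#' @param reference reference study label; must be one of \code{labels}.
#' @return numeric matrix with \code{length(labels) - 1} columns named
#'   \code{study<label>}.
#' @export
dummy_code <- function(study, labels, reference) {
  if (!reference %in% labels)
    stop("reference study '", reference, "' not present in data",
         call. = FALSE)
  other <- setdiff(labels, reference)
  m <- matrix(0, nrow = length(study), ncol = length(other))
  if (length(other)) {
    colnames(m) <- paste0("study", other)
    for (j in seq_along(other)) m[, j] <- as.numeric(study == other[j])
  }
  m
}

#' Build design matrices for a one-stage joint meta-analysis model
#'
#' Constructs the fixed- and random-effect design matrices of both sub-models
#' and the association design from a validated dataset and a model-group
#' specification.  Column order is fixed: intercept, time, treatment, study
#' dummies, treatment-by-study interactions, extra basis columns.  The
#' individual-level random-effect design is \code{[1, t]}; in the association
#' structure the longitudinal time is replaced by the subject's survival time.
#'
#' @param data an \code{"mjm_data"} object.
#' @param spec an \code{"mjm_spec"} object.
#' @return A list of class \code{"mjm_design"} with elements
#'   \code{X1} (measurement-level longitudinal fixed-effect matrix),
#'   \code{X2} (subject-level survival fixed-effect matrix),
#'   \code{Z3} (subject-level design of the study-level random effects,
#'   0 columns when the spec has none), \code{subj} (row index of each
#'   longitudinal record into the survival table), \code{study} (integer
#'   study code per subject), \code{t} (measurement times), \code{y},
#'   \code{Tsurv}, \code{delta}, \code{treat}, \code{strata} (integer hazard
#'   stratum per subject), \code{studies}, \code{reference}, and \code{spec}.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(data, "mjm_data"), inherits(spec, "mjm_spec"))
  studies <- data$studies
  reference <- spec$reference
  if (is.null(reference)) reference <- studies[1L]
  if (!reference %in% studies)
    stop("reference study '", reference, "' not in data", call. = FALSE)
  if (any(data$n_k == 0L))
    stop("study with zero subjects", call. = FALSE)

  surv <- data$surv
  long <- data$long
  key_s <- paste(surv$study, surv$subject, sep = "\r")
  key_l <- paste(long$study, long$subject, sep = "\r")
  subj <- match(key_l, key_s)

  n <- nrow(surv)
  N <- nrow(long)
  t_l <- long$time
  treat_l <- long$treat
  treat_s <- surv$treat

  # longitudinal fixed effects
  X1 <- cbind(intercept = rep(1, N), time = t_l, treat = treat_l)
  if (spec$fixed_study_long)
    X1 <- cbind(X1, dummy_code(long$study, studies, reference))
  if (spec$fixed_study_interact_long) {
    dd <- dummy_code(long$study, studies, reference) * treat_l
    if (ncol(dd)) colnames(dd) <- paste0("treat:", colnames(dd))
    X1 <- cbind(X1, dd)
  }
  if (!is.null(spec$extra_basis)) {
    eb <- vapply(spec$extra_basis, function(f) f(t_l), numeric(N))
    if (N == 1L) eb <- matrix(eb, nrow = 1L,
                              dimnames = list(NULL, names(spec$extra_basis)))
    X1 <- cbind(X1, eb)
  }

  # survival fixed effects
  X2 <- cbind(treat = treat_s)
  if (spec$fixed_study_surv)
    X2 <- cbind(X2, dummy_code(surv$study, studies, reference))
  if (spec$fixed_study_interact_surv) {
    dd <- dummy_code(surv$study, studies, reference) * treat_s
    if (ncol(dd)) colnames(dd) <- paste0("treat:", colnames(dd))
    X2 <- cbind(X2, dd)
  }

  # study-level random-effect design, per subject
  Z3 <- matrix(numeric(0), nrow = n, ncol = 0)
  if (length(spec$study_re)) {
    cols <- list()
    if ("intercept" %in% spec$study_re) cols$re_intercept <- rep(1, n)
    if ("treatment" %in% spec$study_re) cols$re_treatment <- treat_s
    Z3 <- do.call(cbind, cols)
  }

  study_i <- match(surv$study, studies)
  strata <- if (spec$stratified_hazard) study_i else rep(1L, n)

  structure(
    list(X1 = X1, X2 = X2, Z3 = Z3, subj = subj, study = study_i,
         t = t_l, y = long$y, Tsurv = surv$survtime, delta = surv$status,
         treat = treat_s, strata = strata, studies = studies,
         reference = reference, spec = spec),
    class = "mjm_design"
  )
}
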