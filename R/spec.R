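#' Specify a one-stage joint meta-analysis model group
#'
#' Builds the declarative specification of one of the six model groups used to
#' account for between-study heterogeneity in a one-stage joint model for
#' longitudinal and time-to-event individual participant data.  The groups
#' differ in which fixed study terms enter each sub-model, which study-level
#' random effects are shared between the sub-models through the association
#' structure, and whether the baseline hazard is stratified by study:
#'
#' \describe{
#'   \item{group 0}{no study terms at all (naive pooling).}
#'   \item{group 1}{fixed study main effect and treatment-by-study interaction
#'     in both sub-models.}
#'   \item{group 2}{fixed study main effect in both sub-models plus a
#'     study-level random treatment effect.}
#'   \item{group 3}{study-level random intercept and random treatment effect
#'     only.}
#'   \item{group 4}{longitudinal sub-model as group 1; baseline hazard
#'     stratified by study; survival sub-model contains treatment only.}
#'   \item{group 5}{fixed study main effect in the longitudinal sub-model,
#'     study-level random treatment effect, stratified baseline hazard.}
#' }
#'
#' @param group integer in 0..5 selecting the model group.
#' @param reference optional study label used as the reference (baseline)
#'   study for fixed study effects.  Defaults to the first study in sorted
#'   label order when the design is built.
#' @param extra_basis optional named list of functions of time added as extra
#'   fixed-effect basis columns to the longitudinal sub-model, e.g.
#'   \code{list(exp3t = function(t) exp(-3 * t))}.
#'
#' @return An object of class \code{"mjm_spec"}: a list with elements
#'   \code{group}, \code{fixed_study_long}, \code{fixed_study_interact_long},
#'   \code{fixed_study_surv}, \code{fixed_study_interact_surv},
#'   \code{study_re} (character subset of \code{c("intercept", "treatment")}),
#'   \code{stratified_hazard}, \code{reference}, and \code{extra_basis}.
#' @examples
#' mjm_spec(1)
#' mjm_spec(3)$study_re
#' @export
mjm_spec <- function(group, reference = NULL, extra_basis = NULL) {
  if (length(group) != 1L || is.na(group) || group != as.integer(group) ||
      !(group %in% 0:5)) {
    stop("'group' must be a single integer in 0..5", call. = FALSE)
  }
  group <- as.integer(group)
  flags <- switch(as.character(group),
    "0" = list(fl = FALSE, fi = FALSE, fs = FALSE, fsi = FALSE,
               re = character(0), strat = FALSE),
    "1" = list(fl = TRUE,  fi = TRUE,  fs = TRUE,  fsi = TRUE,
               re = character(0), strat = FALSE),
    "2" = list(fl = TRUE,  fi = FALSE, fs = TRUE,  fsi = FALSE,
               re = "treatment", strat = FALSE),
    "3" = list(fl = FALSE, fi = FALSE, fs = FALSE, fsi = FALSE,
               re = c("intercept", "treatment"), strat = FALSE),
    "4" = list(fl = TRUE,  fi = TRUE,  fs = FALSE, fsi = FALSE,
               re = character(0), strat = TRUE),
    "5" = list(fl = TRUE,  fi = FALSE, fs = FALSE, fsi = FALSE,
               re = "treatment", strat = TRUE)
  )
  if (!is.null(extra_basis)) {
    if (!is.list(extra_basis) || !all(vapply(extra_basis, is.function, TRUE)))
      stop("'extra_basis' must be a list of functions of time", call. = FALSE)
    if (is.null(names(extra_basis)) || any(names(extra_basis) == ""))
      names(extra_basis) <- paste0("basis", seq_along(extra_basis))
  }
  structure(
    list(group = group,
         fixed_study_long = flags$fl,
         fixed_study_interact_long = flags$fi,
         fixed_study_surv = flags$fs,
         fixed_study_interact_surv = flags$fsi,
         study_re = flags$re,
         stratified_hazard = flags$strat,
         reference = reference,
         extra_basis = extra_basis),
    class = "mjm_spec"
  )
}

#' @export
print.mjm_spec <- function(x, ...) {
  cat("One-stage joint meta-analysis model specification (group ",
      x$group, ")\n", sep = "")
  cat("  longitudinal fixed study terms : ",
      if (x$fixed_study_long) "study" else "-",
      if (x$fixed_study_interact_long) " + treat:study" else "", "\n", sep = "")
  cat("  survival fixed study terms     : ",
      if (x$fixed_study_surv) "study" else "-",
      if (x$fixed_study_interact_surv) " + treat:study" else "", "\n", sep = "")
  cat("  study-level random effects     : ",
      if (length(x$study_re)) paste(x$study_re, collapse = ", ") else "none",
      "\n", sep = "")
  cat("  baseline hazard                : ",
      if (x$stratified_hazard) "stratified by study" else "common", "\n",
      sep = "")
  if (!is.null(x$reference))
    cat("  reference study                : ", x$reference, "\n", sep = "")
  if (!is.null(x$extra_basis))
    cat("  extra longitudinal bases       : ",
        paste(names(x$extra_basis), collapse = ", "), "\n", sep = "")
  invisible(x)
}
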