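#' Assemble and validate a multi-study joint dataset
#'
#' Combines a long-format longitudinal table and a one-row-per-subject
#' survival table into a validated container for one-stage joint
#' meta-analysis.  The data have three nested levels: repeated measurements
#' within subjects within studies.
#'
#' Validation enforces: every (study, subject) appearing in the longitudinal
#' table has exactly one survival record; survival times are non-negative;
#' event indicators and treatment arms are 0/1; treatment is constant within
#' subject and consistent between the two tables; and longitudinal
#' measurement times do not exceed the subject's survival time.  Longitudinal
#' records observed after the survival time are dropped with a warning (only
#' measurements recorded prior to a subject's survival time contribute to the
#' analysis).
#'
#' @param long data frame with columns \code{study}, \code{subject},
#'   \code{time}, \code{y}, \code{treat}.
#' @param surv data frame with columns \code{study}, \code{subject},
#'   \code{survtime}, \code{status}, \code{treat}.
#'
#' @return An object of class \code{"mjm_data"}: a list with elements
#'   \code{long}, \code{surv} (cleaned data frames), \code{studies} (sorted
#'   study labels), \code{K}, \code{n_k} (subjects per study) and \code{m_ki}
#'   (measurements per subject, named by \code{study.subject}).
#' @examples
#' sc <- sim_scenario(K = 2, n_per_study = 25)
#' d <- sim_joint_data(sc, seed = 1)$data
#' d
#' @export
mjm_data <- function(long, surv) {
  need_l <- c("study", "subject", "time", "y", "treat")
  need_s <- c("study", "subject", "survtime", "status", "treat")
  if (!all(need_l %in% names(long)))
    stop("'long' must have columns ", paste(need_l, collapse = ", "),
         call. = FALSE)
  if (!all(need_s %in% names(surv)))
    stop("'surv' must have columns ", paste(need_s, collapse = ", "),
         call. = FALSE)
  long <- as.data.frame(long)[need_l]
  surv <- as.data.frame(surv)[need_s]
  if (nrow(long) == 0L)
    stop("empty longitudinal table: nothing to fit", call. = FALSE)
  if (nrow(surv) == 0L)
    stop("empty survival table", call. = FALSE)

  long$study <- as.character(long$study)
  surv$study <- as.character(surv$study)
  long$subject <- as.character(long$subject)
  surv$subject <- as.character(surv$subject)

  key_s <- paste(surv$study, surv$subject, sep = "\r")
  if (anyDuplicated(key_s))
    stop("duplicate survival record(s) for subject(s): ",
         paste(utils::head(unique(sub("\r", ".", key_s[duplicated(key_s)])), 5),
               collapse = ", "), call. = FALSE)
  key_l <- paste(long$study, long$subject, sep = "\r")
  miss <- setdiff(unique(key_l), key_s)
  if (length(miss))
    stop("longitudinal subject(s) missing from survival table: ",
         paste(utils::head(sub("\r", ".", miss), 5), collapse = ", "),
         call. = FALSE)

  if (!all(surv$status %in% c(0, 1)))
    stop("'status' must be 0/1", call. = FALSE)
  if (!all(surv$treat %in% c(0, 1)) || !all(long$treat %in% c(0, 1)))
    stop("'treat' must be 0/1", call. = FALSE)
  if (any(surv$survtime < 0)) stop("negative survival time", call. = FALSE)
  if (any(long$time < 0)) stop("negative measurement time", call. = FALSE)
  if (anyNA(long$y) || anyNA(long$time) || anyNA(surv$survtime))
    stop("missing values in outcome or time columns", call. = FALSE)
  if (anyDuplicated(paste(key_l, long$time, sep = "\r")))
    stop("duplicate (study, subject, time) longitudinal record", call. = FALSE)

  # treatment consistency between tables
  tr_map <- surv$treat
  names(tr_map) <- key_s
  if (any(long$treat != tr_map[key_l]))
    stop("'treat' differs between longitudinal and survival tables",
         call. = FALSE)

  Ts_map <- surv$survtime
  names(Ts_map) <- key_s
  late <- long$time > Ts_map[key_l]
  if (any(late)) {
    warning(sum(late), " longitudinal record(s) after the survival time ",
            "dropped", call. = FALSE)
    long <- long[!late, , drop = FALSE]
    key_l <- key_l[!late]
    if (nrow(long) == 0L)
      stop("no longitudinal records remain after truncation", call. = FALSE)
  }

  studies <- sort(unique(surv$study))
  n_k <- vapply(studies, function(s) sum(surv$study == s), 0L)
  m_tab <- table(factor(key_l, levels = key_s))
  m_ki <- as.integer(m_tab)
  names(m_ki) <- sub("\r", ".", key_s)

  structure(
    list(long = long, surv = surv, studies = studies, K = length(studies),
         n_k = n_k, m_ki = m_ki),
    class = "mjm_data"
  )
}

#' Read a multi-study joint dataset from CSV files
#'
#' Reads the package's delimited-text interchange format: a longitudinal file
#' with header \code{study,subject,time,y,treat} and a survival file with
#' header \code{study,subject,survtime,status,treat}, then validates via
#' \code{\link{mjm_data}}.
#'
#' @param long_file,surv_file paths to the CSV files.
#' @return An \code{"mjm_data"} object.
#' @export
read_mjm_data <- function(long_file, surv_file) {
  long <- utils::read.csv(long_file, stringsAsFactors = FALSE)
  surv <- utils::read.csv(surv_file, stringsAsFactors = FALSE)
  mjm_data(long, surv)
}

#' Write a multi-study joint dataset to CSV files
#'
#' @param data an \code{"mjm_data"} object.
#' @param long_file,surv_file output paths.
#' @return invisibly, \code{data}.
#' @export
write_mjm_data <- function(data, long_file, surv_file) {
  stopifnot(inherits(data, "mjm_data"))
  utils::write.csv(data$long, long_file, row.names = FALSE)
  utils::write.csv(data$surv, surv_file, row.names = FALSE)
  invisible(data)
}

#' @export
print.mjm_data <- function(x, ...) {
  cat("Multi-study joint longitudinal / time-to-event dataset\n")
  cat("  studies      :", x$K, "(", paste(x$studies, collapse = ", "), ")\n")
  cat("  subjects     :", nrow(x$surv),
      sprintf("(%s per study)", paste(x$n_k, collapse = "/")), "\n")
  cat("  measurements :", nrow(x$long), "\n")
  cat("  events       :", sum(x$surv$status),
      sprintf("(%.1f%%)", 100 * mean(x$surv$status)), "\n")
  invisible(x)
}
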