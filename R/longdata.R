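#' Longitudinal dataset with irregular visit times
#'
#' A `longdata` object holds subjects observed at irregular, possibly
#' outcome-dependent visit times: for each subject a vector of time-invariant
#' covariates, an end-of-follow-up (censoring) time `C`, and an ordered set of
#' visits `(time, y)` with a nonnegative outcome recorded at each visit.
#' Subjects with no visits are retained: they still contribute to risk sets
#' when the visit-intensity model is fitted.
#'
#' @param subjects data.frame with columns `id`, `C` (censoring time > 0) and
#'   one numeric column per covariate.
#' @param visits data.frame with columns `id`, `time`, `y`; every `id` must
#'   appear in `subjects`. Visit times must be positive, strictly increasing
#'   within subject, and satisfy `time <= C` and `time < tau`.
#' @param tau maximum observation time; defaults to `max(subjects$C)`.
#' @param covariate_names character vector naming the covariate columns of
#'   `subjects`; defaults to all columns other than `id` and `C`.
#'
#' @return An object of class `longdata`: a list with elements `subjects`
#'   (data.frame `id`, `C`, covariates, `m` = visit count), `visits`
#'   (data.frame `id`, `time`, `y`, sorted by subject then time), `tau`, and
#'   `covariate_names`.
#' @export
longdata <- function(subjects, visits, tau = NULL, covariate_names = NULL) {
  stopifnot(is.data.frame(subjects), is.data.frame(visits))
  if (!all(c("id", "C") %in% names(subjects)))
    stop("subjects must have columns 'id' and 'C'")
  if (!all(c("id", "time", "y") %in% names(visits)))
    stop("visits must have columns 'id', 'time' and 'y'")
  subjects$id <- as.character(subjects$id)
  visits$id <- as.character(visits$id)
  if (anyDuplicated(subjects$id))
    stop("duplicated subject id(s): ",
         paste(unique(subjects$id[duplicated(subjects$id)]), collapse = ", "))
  if (is.null(covariate_names))
    covariate_names <- setdiff(names(subjects), c("id", "C", "m"))
  for (nm in c("C", covariate_names)) {
    if (!is.numeric(subjects[[nm]]) || anyNA(subjects[[nm]]) ||
        any(!is.finite(subjects[[nm]])))
      stop("non-numeric or missing values in subject column '", nm, "'")
  }
  if (any(subjects$C <= 0)) stop("censoring times C must be positive")
  if (!is.numeric(visits$time) || anyNA(visits$time) ||
      any(!is.finite(visits$time)))
    stop("non-numeric or missing values in visit column 'time'")
  # y may be NA: the assessment happened (it counts for the visit-intensity
  # stage) but the outcome was not recorded, so the row is excluded from the
  # outcome estimating equations
  if (!is.numeric(visits$y) || any(!is.finite(visits$y) & !is.na(visits$y)))
    stop("non-numeric values in visit column 'y'")
  if (any(visits$y < 0, na.rm = TRUE)) stop("outcomes y must be nonnegative")
  bad <- setdiff(visits$id, subjects$id)
  if (length(bad))
    stop("visit rows reference unknown subject id(s): ",
         paste(unique(bad), collapse = ", "))
  if (is.null(tau)) tau <- max(subjects$C)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    stop("tau must be a single positive number")

  ord <- order(match(visits$id, subjects$id), visits$time)
  visits <- visits[ord, c("id", "time", "y"), drop = FALSE]
  rownames(visits) <- NULL

  Cmap <- subjects$C[match(visits$id, subjects$id)]
  viol <- which(visits$time > Cmap | visits$time >= tau | visits$time <= 0)
  if (length(viol))
    stop("visit time outside (0, min(C, tau)] for rows: ",
         paste(utils::head(viol, 5), collapse = ", "),
         " (id ", visits$id[viol[1]], ", time ", visits$time[viol[1]], ")")
  dup <- stats::ave(visits$time, visits$id,
                    FUN = function(t) c(1, diff(t)))
  if (any(dup <= 0))
    stop("visit times must be strictly increasing within subject (id ",
         visits$id[which(dup <= 0)[1]], ")")

  subjects$m <- as.integer(table(factor(visits$id, levels = subjects$id)))
  rownames(subjects) <- NULL
  structure(
    list(subjects = subjects[, c("id", "C", covariate_names, "m")],
         visits = visits, tau = tau, covariate_names = covariate_names),
    class = "longdata")
}

#' @export
print.longdata <- function(x, ...) {
  cat("longdata: ", nrow(x$subjects), " subjects, ", nrow(x$visits),
      " visits, ", length(x$covariate_names), " covariate(s) [",
      paste(x$covariate_names, collapse = ", "), "], tau = ",
      format(x$tau), "\n", sep = "")
  invisible(x)
}

#' Number of subjects
#' @param ds a `longdata` object
#' @return integer subject count
#' @export
n_subjects <- function(ds) nrow(ds$subjects)

# covariate matrix (n x p), subjects in dataset order
covariate_matrix <- function(ds) {
  as.matrix(ds$subjects[, ds$covariate_names, drop = FALSE])
}

# index of each visit's subject into ds$subjects
visit_subject_index <- function(ds) {
  match(ds$visits$id, ds$subjects$id)
}

#' Read a longitudinal dataset from delimited text files
#'
#' Reads the two-file long format: a visits file with columns
#' `id, time, y` (one row per visit) and a subjects file with columns
#' `id, C` plus one column per time-invariant covariate. A single denormalized
#' file that repeats the subject columns on every visit row is also accepted:
#' pass it as both paths.
#'
#' @param visits_path CSV file of visits (`id, time, y`).
#' @param subjects_path CSV file of subjects (`id, C, <covariates>`).
#' @param tau maximum observation time; defaults to the largest `C`.
#' @return a [longdata] object
#' @export
read_longdata <- function(visits_path, subjects_path, tau = NULL) {
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE)
  subjects <- utils::read.csv(subjects_path, stringsAsFactors = FALSE)
  if (identical(normalizePath(visits_path), normalizePath(subjects_path))) {
    # denormalized single-file mode: subject columns repeated per visit row
    subjects <- subjects[!duplicated(subjects$id),
                         setdiff(names(subjects), c("time", "y")),
                         drop = FALSE]
  }
  keep <- intersect(c("id", "time", "y"), names(visits))
  if (!all(c("id", "time", "y") %in% keep))
    stop("visits file must have columns id, time, y")
  longdata(subjects, visits[, c("id", "time", "y")], tau = tau)
}

#' Write a longitudinal dataset to delimited text files
#'
#' @param ds a [longdata] object
#' @param visits_path,subjects_path output CSV paths
#' @return invisibly, `ds`
#' @export
write_longdata <- function(ds, visits_path, subjects_path) {
  utils::write.csv(ds$visits, visits_path, row.names = FALSE)
  utils::write.csv(ds$subjects[, c("id", "C", ds$covariate_names)],
                   subjects_path, row.names = FALSE)
  invisible(ds)
}

#' Summarize visit counts, optionally by a grouping covariate
#'
#' Reports the number of subjects and the mean and sample standard deviation
#' of per-subject visit counts, overall or within the levels of a discrete
#' covariate.
#'
#' @param ds a [longdata] object
#' @param group_by optional name of a covariate with finitely many values
#' @return data.frame with columns `group`, `n_subjects`, `mean_m`, `sd_m`
#' @export
summarize_visits <- function(ds, group_by = NULL) {
  m <- ds$subjects$m
  if (is.null(group_by)) {
    return(data.frame(group = "all", n_subjects = length(m),
                      mean_m = mean(m), sd_m = stats::sd(m)))
  }
  if (!group_by %in% ds$covariate_names)
    stop("unknown covariate '", group_by, "'; available: ",
         paste(ds$covariate_names, collapse = ", "))
  g <- ds$subjects[[group_by]]
  out <- do.call(rbind, lapply(sort(unique(g)), function(lev) {
    mm <- m[g == lev]
    data.frame(group = lev, n_subjects = length(mm),
               mean_m = mean(mm),
               sd_m = if (length(mm) > 1) stats::sd(mm) else 0)
  }))
  # single-subject groups report sd 0; all-empty datasets likewise
  out$sd_m[is.na(out$sd_m)] <- 0
  rownames(out) <- NULL
  out
}

#' The bladder-tumor recurrence study as a longdata object
#'
#' Builds the placebo and thiotepa arms of the VA bladder cancer trial
#' (`survival::bladder1`) in the format used by the joint-model estimators:
#' visits are tumor-recurrence assessments (time in months, outcome = number
#' of new tumors found), the censoring time is each subject's end of
#' follow-up, and the covariates are a thiotepa indicator and the initial
#' number of tumors, centered at its mean across the retained subjects.
#'
#' Subjects with zero follow-up time are dropped (one placebo subject),
#' giving 47 placebo and 38 thiotepa subjects. Recurrence visits with an
#' unrecorded tumor count are kept with `y = NA`: they count for the
#' visit-intensity stage but are excluded from the outcome estimating
#' equations.
#'
#' @param center_number center the initial-tumor-count covariate (default TRUE)
#' @return a [longdata] object with covariates `thiotepa` and `number`
#' @export
bladder_longdata <- function(center_number = TRUE) {
  b <- survival::bladder1
  b <- b[b$treatment %in% c("placebo", "thiotepa"), ]
  C <- tapply(b$stop, b$id, max)
  first <- b[!duplicated(b$id), ]
  subjects <- data.frame(
    id = as.character(first$id),
    C = as.numeric(C[as.character(first$id)]),
    thiotepa = as.numeric(first$treatment == "thiotepa"),
    number = as.numeric(first$number))
  subjects <- subjects[subjects$C > 0, ]
  if (center_number) subjects$number <- subjects$number - mean(subjects$number)
  rec <- b[b$status == 1 & b$id %in% subjects$id, ]
  visits <- data.frame(id = as.character(rec$id),
                       time = as.numeric(rec$stop),
                       y = suppressWarnings(as.numeric(rec$rtumor)))
  longdata(subjects, visits, tau = max(subjects$C))
}
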