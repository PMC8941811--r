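#' Assemble a biologic-DMARD course from raw visits
#'
#' Re-anchors a course's clock at its baseline -- the first visit with
#' DAS28 <= 3.2 (low disease activity) reached after at least
#' `min_treatment_weeks` of treatment -- derives per-visit flare flags with
#' [detect_flare()], and records the first-flare and censoring times.
#' Visits before baseline are dropped.  The dose is treated as a step
#' function: the dose recorded at a visit is in force from that visit until
#' the next one.
#'
#' @param visits data frame with columns `week` (time since treatment
#'   start), `das28`, `dose_fraction` (and optionally raw components).
#'   Must be sorted by `week`.
#' @param covariates named list or one-row data frame of per-course
#'   covariates (see [read_cohort()] for the column set).
#' @param course_id,patient_id identifiers.
#' @param min_treatment_weeks minimum treatment duration before a
#'   low-disease-activity visit may serve as baseline (default 24).
#' @return An object of class `patient_course`: a list with `course_id`,
#'   `patient_id`, `visits` (re-anchored, with a logical `flare` column),
#'   `covariates`, `first_flare_week` (`NA` when no flare) and
#'   `censor_week`.
#' @export
assemble_course <- function(visits, covariates, course_id = "c1",
                            patient_id = course_id,
                            min_treatment_weeks = 24) {
  stopifnot(is.data.frame(visits), all(c("week", "das28") %in% names(visits)))
  if (is.unsorted(visits$week, strictly = TRUE))
    stop("visits must be strictly increasing in time")
  if (!"dose_fraction" %in% names(visits)) visits$dose_fraction <- NA_real_
  lda <- which(!is.na(visits$das28) & visits$das28 <= 3.2 &
                 visits$week >= min_treatment_weeks)
  if (length(lda) == 0L)
    stop("ineligible course: no qualifying low-disease-activity visit")
  b <- lda[1L]
  v <- visits[b:nrow(visits), , drop = FALSE]
  v$week <- v$week - visits$week[b]
  v$flare <- c(FALSE, detect_flare(v$das28[-nrow(v)], v$das28[-1L],
                                   v$dose_fraction[-nrow(v)],
                                   v$dose_fraction[-1L]))
  rownames(v) <- NULL
  first_flare <- if (any(v$flare)) v$week[which(v$flare)[1L]] else NA_real_
  structure(list(course_id = course_id, patient_id = patient_id,
                 visits = v, covariates = as.list(covariates),
                 first_flare_week = first_flare,
                 censor_week = v$week[nrow(v)]),
            class = "patient_course")
}

#' @export
print.patient_course <- function(x, ...) {
  cat(sprintf("<patient_course %s (patient %s): %d visits, %s, censored %.1f wk>\n",
              x$course_id, x$patient_id, nrow(x$visits),
              if (is.na(x$first_flare_week)) "no flare"
              else sprintf("first flare %.1f wk", x$first_flare_week),
              x$censor_week))
  invisible(x)
}

# covariate columns required for a complete case, in model order
.covariate_cols <- c("time_to_lda_weeks", "das28_baseline",
                     "dose_fraction_baseline", "sj_increase_baseline",
                     "tj_increase_baseline", "disease_duration_years",
                     "seropositive", "tnfi")

#' Build a cohort object from assembled courses
#'
#' @param courses list of `patient_course` objects.
#' @return An object of class `flare_cohort`: a list with a `visits` data
#'   frame (one row per visit), a `covariates` data frame (one row per
#'   course) and a `courses` data frame holding the event information
#'   (`first_flare_week`, `censor_week`).
#' @export
as_flare_cohort <- function(courses) {
  stopifnot(length(courses) > 0L,
            all(vapply(courses, inherits, TRUE, "patient_course")))
  visits <- do.call(rbind, lapply(courses, function(cr) {
    data.frame(course_id = cr$course_id, patient_id = cr$patient_id,
               cr$visits, stringsAsFactors = FALSE)
  }))
  covariates <- do.call(rbind, lapply(courses, function(cr) {
    cv <- cr$covariates[intersect(.covariate_cols, names(cr$covariates))]
    missing <- setdiff(.covariate_cols, names(cv))
    for (m in missing) cv[[m]] <- NA
    data.frame(course_id = cr$course_id, patient_id = cr$patient_id,
               cv[.covariate_cols], stringsAsFactors = FALSE)
  }))
  course_tab <- data.frame(
    course_id = vapply(courses, `[[`, "", "course_id"),
    patient_id = vapply(courses, `[[`, "", "patient_id"),
    first_flare_week = vapply(courses, `[[`, 0, "first_flare_week"),
    censor_week = vapply(courses, `[[`, 0, "censor_week"),
    stringsAsFactors = FALSE)
  rownames(visits) <- rownames(covariates) <- rownames(course_tab) <- NULL
  structure(list(visits = visits, covariates = covariates,
                 courses = course_tab),
            class = "flare_cohort")
}

#' @export
print.flare_cohort <- function(x, ...) {
  n <- nrow(x$courses)
  yrs <- sum(x$courses$censor_week) / 52
  cat(sprintf("<flare_cohort: %d courses / %d patients, %d visits, %.0f patient-years, %d first flares>\n",
              n, length(unique(x$courses$patient_id)), nrow(x$visits),
              yrs, sum(!is.na(x$courses$first_flare_week))))
  invisible(x)
}

#' Eligibility filter for assembled courses
#'
#' Keeps courses with a complete covariate record and an average DAS28
#' measurement rate of at least `min_rate` per year over follow-up.
#'
#' @param cohort a `flare_cohort`.
#' @param min_rate minimum DAS28 measurements per year (default 2).
#' @param verbose print how many courses were dropped and why.
#' @return The filtered `flare_cohort`.
#' @export
filter_eligible <- function(cohort, min_rate = 2, verbose = FALSE) {
  stopifnot(inherits(cohort, "flare_cohort"))
  cov_ok <- stats::complete.cases(cohort$covariates[.covariate_cols])
  n_das <- vapply(cohort$courses$course_id, function(id) {
    v <- cohort$visits[cohort$visits$course_id == id, ]
    sum(!is.na(v$das28))
  }, 0L)
  fu_years <- pmax(cohort$courses$censor_week, 1e-9) / 52
  rate_ok <- n_das / fu_years >= min_rate
  keep <- cov_ok & rate_ok
  if (verbose) {
    message(sprintf("dropped %d course(s): %d incomplete covariates, %d DAS28 rate < %g/year",
                    sum(!keep), sum(!cov_ok), sum(cov_ok & !rate_ok), min_rate))
  }
  ids <- cohort$courses$course_id[keep]
  subset_cohort(cohort, ids)
}

#' Subset a cohort by course ids
#' @param cohort a `flare_cohort`.
#' @param course_ids character vector of course ids to keep.
#' @export
subset_cohort <- function(cohort, course_ids) {
  structure(list(
    visits = cohort$visits[cohort$visits$course_id %in% course_ids, , drop = FALSE],
    covariates = cohort$covariates[cohort$covariates$course_id %in% course_ids, , drop = FALSE],
    courses = cohort$courses[cohort$courses$course_id %in% course_ids, , drop = FALSE]),
    class = "flare_cohort")
}

#' Read / write a cohort as plain CSV files
#'
#' The visit file has one row per visit (`course_id`, `patient_id`, `week`,
#' `tjc28`, `sjc28`, `esr`, `crp`, `gh`, `das28`, `dose_fraction`, `flare`);
#' the covariate file one row per course.  Empty cells mean "absent".
#'
#' @param visits_file,covariates_file CSV paths.
#' @return A `flare_cohort`.
#' @export
read_cohort <- function(visits_file, covariates_file) {
  v <- utils::read.csv(visits_file, stringsAsFactors = FALSE)
  cv <- utils::read.csv(covariates_file, stringsAsFactors = FALSE)
  v$flare <- as.logical(v$flare)
  for (col in c("sj_increase_baseline", "tj_increase_baseline",
                "seropositive", "tnfi"))
    if (col %in% names(cv)) cv[[col]] <- as.logical(cv[[col]])
  courses <- do.call(rbind, lapply(split(v, v$course_id), function(vi) {
    vi <- vi[order(vi$week), ]
    data.frame(course_id = vi$course_id[1L], patient_id = vi$patient_id[1L],
               first_flare_week = if (any(vi$flare, na.rm = TRUE))
                 vi$week[which(vi$flare)[1L]] else NA_real_,
               censor_week = vi$week[nrow(vi)], stringsAsFactors = FALSE)
  }))
  ord <- match(unique(v$course_id), courses$course_id)
  courses <- courses[ord, , drop = FALSE]
  cv <- cv[match(courses$course_id, cv$course_id), , drop = FALSE]
  rownames(courses) <- rownames(cv) <- NULL
  structure(list(visits = v, covariates = cv, courses = courses),
            class = "flare_cohort")
}

#' @rdname read_cohort
#' @param cohort a `flare_cohort`.
#' @export
write_cohort <- function(cohort, visits_file, covariates_file) {
  utils::write.csv(cohort$visits, visits_file, row.names = FALSE, na = "")
  utils::write.csv(cohort$covariates, covariates_file, row.names = FALSE, na = "")
  invisible(cohort)
}
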