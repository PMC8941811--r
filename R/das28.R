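#' DAS28 variant scores from individual components
#'
#' Computes every validated 28-joint Disease Activity Score variant that the
#' available components allow: the 4- and 3-variable formulae using ESR, and
#' the 4- and 3-variable formulae using CRP.  Variants requiring the patient
#' global health VAS (`gh`) are omitted when `gh` is missing; variants
#' requiring ESR (or CRP) are omitted when that marker is missing.
#'
#' ESR values below 1 mm/h are floored at 1 before taking the logarithm so
#' the score stays finite.
#'
#' @param tjc28 tender joint count, integer in 0--28.
#' @param sjc28 swollen joint count, integer in 0--28.
#' @param esr erythrocyte sedimentation rate in mm/h, or `NA`.
#' @param crp C-reactive protein in mg/L, or `NA`.
#' @param gh patient global health VAS in mm (0--100), or `NA`.
#' @return Named numeric vector with elements among `"esr4"`, `"esr3"`,
#'   `"crp4"`, `"crp3"`.
#' @examples
#' das28_variants(tjc28 = 2, sjc28 = 1, esr = 20, crp = 8, gh = 35)
#' @export
das28_variants <- function(tjc28, sjc28, esr = NA, crp = NA, gh = NA) {
  stopifnot(length(tjc28) == 1L, length(sjc28) == 1L)
  if (is.na(tjc28) || is.na(sjc28) || tjc28 < 0 || tjc28 > 28 ||
      sjc28 < 0 || sjc28 > 28)
    stop("joint counts must be within [0, 28]")
  if (!is.na(gh) && (gh < 0 || gh > 100)) stop("gh must be within [0, 100]")
  if (!is.na(esr) && esr <= 0) esr <- 1
  joints <- 0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28)
  out <- c(
    esr4 = if (!is.na(esr) && !is.na(gh))
      joints + 0.70 * log(esr) + 0.014 * gh else NA_real_,
    esr3 = if (!is.na(esr))
      (joints + 0.70 * log(esr)) * 1.08 + 0.16 else NA_real_,
    crp4 = if (!is.na(crp) && !is.na(gh))
      joints + 0.36 * log(crp + 1) + 0.014 * gh + 0.96 else NA_real_,
    crp3 = if (!is.na(crp))
      (joints + 0.36 * log(crp + 1)) * 1.10 + 1.10 else NA_real_
  )
  out <- out[!is.na(out)]
  if (length(out) == 0L)
    stop("insufficient components: no DAS28 variant computable")
  out
}

#' Composite DAS28 score
#'
#' The composite score used throughout this package is the arithmetic mean of
#' all DAS28 variants computable from the non-missing components (ESR- and
#' CRP-based, 3- and 4-variable).  Averaging the validated formulae makes the
#' score robust to whichever inflammation marker or VAS happens to be
#' recorded at a visit.
#'
#' @inheritParams das28_variants
#' @return A single composite DAS28 value.
#' @seealso [das28_variants()]
#' @export
das28 <- function(tjc28, sjc28, esr = NA, crp = NA, gh = NA) {
  mean(das28_variants(tjc28, sjc28, esr, crp, gh))
}

#' Match time-stamped component measurements to a visit
#'
#' For each DAS28 component, selects the measurement closest in time to the
#' visit within a +/- `window` week tolerance (default 4 weeks = 28 days).
#' Ties in absolute distance are broken toward the earlier measurement.
#' Components with no measurement inside the window come back as `NA`.
#'
#' @param measurements data frame with columns `component` (one of
#'   `"tjc28"`, `"sjc28"`, `"esr"`, `"crp"`, `"gh"`), `week`, `value`.
#' @param visit_week time of the visit, on the same clock as `week`.
#' @param window half-width of the matching window in weeks.
#' @return Named list with elements `tjc28`, `sjc28`, `esr`, `crp`, `gh`.
#' @export
match_components <- function(measurements, visit_week, window = 4) {
  stopifnot(all(c("component", "week", "value") %in% names(measurements)))
  comps <- c("tjc28", "sjc28", "esr", "crp", "gh")
  out <- stats::setNames(as.list(rep(NA_real_, length(comps))), comps)
  for (cmp in comps) {
    m <- measurements[measurements$component == cmp, , drop = FALSE]
    if (nrow(m) == 0L) next
    dt <- abs(m$week - visit_week)
    ok <- dt <= window
    if (!any(ok)) next
    m <- m[ok, , drop = FALSE]
    dt <- dt[ok]
    # nearest; ties toward the earlier measurement
    best <- order(dt, m$week)[1L]
    out[[cmp]] <- m$value[best]
  }
  out
}

#' Flare criterion between two consecutive visits
#'
#' A flare is flagged when the DAS28 rises by more than 1.2 since the
#' previous visit, or rises by more than 0.6 to a value above 3.2, or when
#' the prescribed biologic dose is increased (a dose increase is taken as a
#' flare even when no DAS28 is computable).  The DAS28 clauses are skipped
#' when either score is missing.
#'
#' All arguments are vectorised.
#'
#' @param das28_prev,das28_curr composite DAS28 at the previous/current
#'   visit (`NA` allowed).
#' @param dose_prev,dose_curr dose fraction of the full registered dose at
#'   the previous/current visit (`NA` allowed; the dose clause is skipped
#'   when either is missing).
#' @return Logical vector.
#' @export
detect_flare <- function(das28_prev, das28_curr, dose_prev = NA, dose_curr = NA) {
  n <- max(length(das28_prev), length(das28_curr),
           length(dose_prev), length(dose_curr))
  das28_prev <- rep_len(das28_prev, n); das28_curr <- rep_len(das28_curr, n)
  dose_prev <- rep_len(dose_prev, n);   dose_curr <- rep_len(dose_curr, n)
  delta <- das28_curr - das28_prev
  das_flare <- !is.na(delta) &
    (delta > 1.2 | (delta > 0.6 & das28_curr > 3.2))
  dose_flare <- !is.na(dose_prev) & !is.na(dose_curr) & dose_curr > dose_prev
  das_flare | dose_flare
}
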