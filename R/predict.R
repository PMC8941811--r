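# Landmark ("dynamic") prediction: at landmark s, the class posterior is
#   w_g(s) prop.to  pi_g * f(DAS28 history <= s | class g) * S_g(s | X, dose)
# and the 3-month flare risk is
#   sum_g w_g(s) * [S_g(s) - S_g(s + h)] / S_g(s)
#     = sum_g w_g(s) * (1 - exp(-(Lambda_g(s + h) - Lambda_g(s)))).
# For courses already past a flare (the tapering simulator predicts at every
# 3-monthly visit), the at-risk clock restarts at the last flare: the
# survival factor in the weights then spans [last flare, s] only, while the
# longitudinal history is retained in full.

# per-class longitudinal + survival-factor log terms for one course history
history_logweights <- function(params, X, obs_week, obs_das28,
                               s_week, from_week = 0, dose_week = NULL,
                               dose = NULL) {
  G <- length(params$pi)
  keep <- !is.na(obs_das28) & obs_week <= s_week
  y <- obs_das28[keep]; tw <- obs_week[keep]
  llL <- matrix(0, 1L, G); llS <- matrix(0, 1L, G)
  if (s_week > from_week) {
    sg <- dose_segments(dose_week %||% 0, dose %||% 1, s_week)
    kp <- sg$b > from_week
    a <- pmax(sg$a[kp], from_week) / WEEKS_PER_YEAR
    b <- sg$b[kp] / WEEKS_PER_YEAR
    low <- sg$low[kp]
    cells <- jlcm_cells_cpp(y, tw / WEEKS_PER_YEAR,
                            c(0L, length(y)), matrix(X, 1L),
                            s_week / WEEKS_PER_YEAR, 0L,
                            a, b, low, c(0L, length(a)),
                            params$beta, params$B, params$sigma2,
                            params$kappa, params$rho, params$gamma,
                            params$beta_s, params$delta)
    llL <- cells$ll_long; llS <- cells$ll_surv
  } else if (length(y)) {
    cells <- jlcm_cells_cpp(y, tw / WEEKS_PER_YEAR,
                            c(0L, length(y)), matrix(X, 1L),
                            1, 0L,
                            numeric(0), numeric(0), integer(0), c(0L, 0L),
                            params$beta, params$B, params$sigma2,
                            params$kappa, params$rho, params$gamma,
                            params$beta_s, params$delta)
    llL <- cells$ll_long
  }
  log(params$pi) + llL[1L, ] + llS[1L, ]
}

# class-specific conditional flare probability over (s, s + h] under a
# piecewise-constant future dose path
class_conditional_risk <- function(params, X, s_week, horizon_weeks,
                                   future_dose_week, future_dose) {
  G <- length(params$pi)
  eta <- sum(params$beta_s * X)
  sg <- dose_segments(future_dose_week, future_dose,
                      s_week + horizon_weeks)
  kp <- sg$b > s_week
  a <- pmax(sg$a[kp], s_week) / WEEKS_PER_YEAR
  b <- sg$b[kp] / WEEKS_PER_YEAR
  low <- sg$low[kp]
  vapply(seq_len(G), function(g) {
    dL <- jlcm_cumhaz_cpp(a, b, low, params$kappa, params$rho,
                          params$gamma[1, g], params$gamma[2, g], eta,
                          params$delta)
    1 - exp(-dL)
  }, 0)
}

course_slice <- function(cohort, course_id) {
  v <- cohort$visits[cohort$visits$course_id == course_id, , drop = FALSE]
  if (nrow(v) == 0L) stop("unknown course id: ", course_id)
  v <- v[order(v$week), , drop = FALSE]
  cv <- cohort$covariates[cohort$covariates$course_id == course_id, , drop = FALSE]
  X <- as.numeric(cv[1L, .covariate_cols])
  cr <- cohort$courses[cohort$courses$course_id == course_id, , drop = FALSE]
  list(visits = v, X = X,
       first_flare_week = cr$first_flare_week[1L],
       censor_week = cr$censor_week[1L])
}

#' Posterior class membership at a landmark
#'
#' Bayes weights over the latent classes given the course's DAS28 history up
#' to the landmark, its covariates and its dose path, for a course that is
#' flare-free and in follow-up at the landmark.
#'
#' @param object a fitted `jlcm`.
#' @param cohort the `flare_cohort` holding the course.
#' @param course_id course identifier.
#' @param landmark_week landmark time s in weeks since baseline.
#' @return Numeric vector of length G summing to 1.
#' @export
class_posterior <- function(object, cohort, course_id, landmark_week) {
  cs <- course_slice(cohort, course_id)
  lw <- history_logweights(object$params, cs$X, cs$visits$week,
                           cs$visits$das28, landmark_week,
                           dose_week = cs$visits$week,
                           dose = cs$visits$dose_fraction)
  norm_weights(lw)
}

norm_weights <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) stop("course not at risk at this landmark")
  w <- exp(lw - m)
  w / sum(w)
}

#' Predicted probability of a flare within the horizon
#'
#' Mixes the class-specific conditional flare probabilities over the
#' landmark class posterior.  The future dose defaults to continuing the
#' dose in force at the landmark; pass `future_dose` (a single fraction, or
#' a data frame with `week`/`dose_fraction` describing a planned path) to
#' evaluate a planned taper step.
#'
#' @inheritParams class_posterior
#' @param horizon_weeks prediction horizon (default 13 weeks = 3 months).
#' @param future_dose planned dose over `(s, s + h]`; default: current dose.
#' @return Probability in `[0, 1]`.
#' @export
flare_risk <- function(object, cohort, course_id, landmark_week,
                       horizon_weeks = 13, future_dose = NULL) {
  cs <- course_slice(cohort, course_id)
  w <- class_posterior(object, cohort, course_id, landmark_week)
  fd <- resolve_future_dose(future_dose, cs$visits, landmark_week)
  r <- class_conditional_risk(object$params, cs$X, landmark_week,
                              horizon_weeks, fd$week, fd$dose)
  sum(w * r)
}

resolve_future_dose <- function(future_dose, visits, s_week) {
  if (is.null(future_dose)) {
    # dose in force at the landmark, carried forward
    d <- visits$dose_fraction
    d <- d[!is.na(d) & visits$week <= s_week]
    list(week = s_week, dose = if (length(d)) d[length(d)] else 1)
  } else if (is.data.frame(future_dose)) {
    list(week = future_dose$week, dose = future_dose$dose_fraction)
  } else {
    list(week = s_week, dose = as.numeric(future_dose))
  }
}

#' Landmark flare predictions for every eligible visit
#'
#' Emits one 3-month flare-risk prediction per visit at which a DAS28 was
#' available and the course was still flare-free and in follow-up.  The
#' outcome label is `"flare"` when the first flare falls inside
#' `(s, s + h]`, `"no-flare"` when follow-up covers the full horizon without
#' a flare, and `"indeterminate"` when the course is censored inside the
#' horizon (indeterminate rows are excluded from the performance metrics).
#'
#' @param object a fitted `jlcm`.
#' @param cohort a `flare_cohort` (defaults to the training data).
#' @param horizon_weeks prediction horizon in weeks.
#' @param include_baseline emit predictions at the baseline visit (s = 0)?
#' @param ... ignored.
#' @return Data frame of class `flare_predictions` with columns
#'   `course_id`, `patient_id`, `landmark_week`, `horizon_weeks`, `risk`,
#'   `label`, `at_baseline`.
#' @export
predict.jlcm <- function(object, cohort = NULL, horizon_weeks = 13,
                         include_baseline = TRUE, ...) {
  if (is.null(cohort))
    stop("supply the cohort to predict on (the fit stores only packed data)")
  stopifnot(inherits(cohort, "flare_cohort"))
  rows <- lapply(cohort$courses$course_id, function(id) {
    cs <- course_slice(cohort, id)
    v <- cs$visits
    ff <- cs$first_flare_week; cen <- cs$censor_week
    lm <- v$week[!is.na(v$das28)]
    lm <- lm[lm < cen & (is.na(ff) | lm < ff)]
    if (!include_baseline) lm <- lm[lm > 0]
    if (length(lm) == 0L) return(NULL)
    risk <- vapply(lm, function(s) {
      lw <- history_logweights(object$params, cs$X, v$week, v$das28, s,
                               dose_week = v$week, dose = v$dose_fraction)
      w <- norm_weights(lw)
      fd <- resolve_future_dose(NULL, v, s)
      sum(w * class_conditional_risk(object$params, cs$X, s, horizon_weeks,
                                     fd$week, fd$dose))
    }, 0)
    label <- vapply(lm, function(s) {
      if (!is.na(ff) && ff > s && ff <= s + horizon_weeks) "flare"
      else if (cen >= s + horizon_weeks && (is.na(ff) || ff > s + horizon_weeks))
        "no-flare"
      else "indeterminate"
    }, "")
    data.frame(course_id = id,
               patient_id = cohort$courses$patient_id[
                 cohort$courses$course_id == id][1L],
               landmark_week = lm, horizon_weeks = horizon_weeks,
               risk = risk, label = label, at_baseline = lm == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("flare_predictions", "data.frame")
  out
}

#' Write / read a predictions table as CSV
#' @param predictions a `flare_predictions` data frame.
#' @param path CSV path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE, na = "")
  invisible(predictions)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("flare_predictions", "data.frame")
  out
}
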