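# Prediction-aided disease-activity-guided dose optimisation (DGDO)
# simulator.  Trial courses live on a 3-monthly visit grid over 18 months;
# the dose recorded at a visit is the dose PRESCRIBED there, in force over
# the following 3-month interval; a flare flag at a visit means a flare was
# detected at that visit (it arose during the preceding interval, at the
# dose prescribed at the previous visit).
#
# Decision rules applied at each visit, given a risk cutoff:
#  R1  flares observed in the trial before (or at) the first high-risk
#      prediction are copied and the course follows the trial throughout --
#      the prediction had no impact;
#  R2  at the first high-risk prediction with no prior trial flare, the
#      simulated dose freezes at the prescription current at that visit
#      (at month 0: the pre-taper full dose) and no further simulated
#      flares occur except through R4;
#  R3  if the trial course had fully discontinued when the first high-risk
#      prediction fires, the simulated dose becomes and stays 50% of the
#      full registered dose (the last tapering step);
#  R4  a trial flare after the first high-risk prediction is copied iff the
#      trial dose in force at that flare was at least the simulated dose in
#      force; from then on the simulated course follows the trial.

#' Dichotomise a predicted risk at a cutoff
#'
#' @param risk predicted flare probabilities.
#' @param cutoff decision threshold; `"high"` iff `risk >= cutoff`.
#' @return Character vector of `"high"` / `"low"`.
#' @export
classify_risk <- function(risk, cutoff) {
  ifelse(risk >= cutoff, "high", "low")
}

#' Simulate prediction-aided tapering on a trial cohort
#'
#' Applies the four decision rules above to every course of the DGDO arm of
#' `trial`, using the per-visit predicted risks (see
#' [add_risk_predictions()]).  Missing predictions are treated as low risk
#' with a warning.
#'
#' @param trial a `trial_cohort` whose DGDO-arm visits carry a `risk`
#'   column.
#' @param cutoff risk cutoff; a prediction is high iff `risk >= cutoff`.
#' @param use_baseline honour a high-risk prediction at month 0?  When
#'   `FALSE` the baseline prediction is treated as low risk.
#' @return Object of class `taper_simulation`: the DGDO-arm visits with
#'   added `sim_dose`, `sim_flare` columns and a per-course `rules` table
#'   recording which rule governed each course.
#' @export
simulate_taper <- function(trial, cutoff, use_baseline = TRUE) {
  stopifnot(inherits(trial, "trial_cohort"))
  v <- trial$visits[trial$visits$arm == "dgdo", , drop = FALSE]
  if (nrow(v) == 0L) stop("trial has no DGDO-arm visits")
  if (anyNA(v$risk[v$month < max(v$month)]))
    warning("missing risk predictions treated as low risk")
  out <- lapply(split(v, v$course_id), simulate_taper_course,
                cutoff = cutoff, use_baseline = use_baseline)
  visits <- do.call(rbind, lapply(out, `[[`, "visits"))
  rules <- do.call(rbind, lapply(out, `[[`, "rule"))
  rownames(visits) <- rownames(rules) <- NULL
  structure(list(visits = visits, rules = rules, cutoff = cutoff),
            class = "taper_simulation")
}

simulate_taper_course <- function(cv, cutoff, use_baseline) {
  cv <- cv[order(cv$month), , drop = FALSE]
  m <- cv$month
  dose_obs <- cv$dose_fraction
  flare_obs <- as.logical(cv$flare)
  high <- !is.na(cv$risk) & cv$risk >= cutoff & m < max(m)
  if (!use_baseline) high[m == 0] <- FALSE
  H <- if (any(high)) m[which(high)[1L]] else Inf
  first_flare <- if (any(flare_obs)) m[which(flare_obs)[1L]] else Inf

  sim_dose <- dose_obs
  sim_flare <- flare_obs
  rule <- "follow"
  if (is.finite(H) && first_flare > H) {
    frozen <- dose_obs[m == H]
    if (H == 0) { frozen <- 1; rule <- "freeze" }
    else if (frozen == 0) { frozen <- 0.5; rule <- "half" }
    else rule <- "freeze"
    sim_dose[m >= H] <- frozen
    sim_flare[m > H] <- FALSE
    # R4: copy a later trial flare when it arose at >= the simulated dose
    for (j in which(m > H & flare_obs)) {
      in_force_obs <- if (j > 1L) dose_obs[j - 1L] else dose_obs[j]
      in_force_sim <- if (j > 1L) sim_dose[j - 1L] else sim_dose[j]
      if (in_force_obs >= in_force_sim - 1e-12) {
        sim_dose[m >= m[j]] <- dose_obs[m >= m[j]]
        sim_flare[m >= m[j]] <- flare_obs[m >= m[j]]
        rule <- "copy"
        break
      }
    }
  }
  cv$sim_dose <- sim_dose
  cv$sim_flare <- sim_flare
  list(visits = cv,
       rule = data.frame(course_id = cv$course_id[1L], rule = rule,
                         first_high_month = if (is.finite(H)) H else NA_real_,
                         stringsAsFactors = FALSE))
}

#' Flare and dose outcomes of a (simulated or observed) trial cohort
#'
#' Mean number of flares per course over 18 months, proportion of courses
#' with at least one flare, and the time-weighted mean dose fraction (doses
#' persist over the 3-month interval that follows each visit), each with a
#' patient-level percentile bootstrap confidence interval.
#'
#' @param x a `taper_simulation` (simulated doses/flares are used), a
#'   `trial_cohort` (supply `arm`), or a data frame with columns
#'   `course_id`, `month`, `dose_fraction`, `flare`.
#' @param arm which trial arm when `x` is a `trial_cohort`.
#' @param B bootstrap replicates; `B = 0` skips the CIs.
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @param window_months follow-up window (default 18).
#' @return Object of class `taper_outcomes`.
#' @export
taper_outcomes <- function(x, arm = c("dgdo", "routine"), B = 1000,
                           conf = 0.95, seed = 1, window_months = 18) {
  if (inherits(x, "taper_simulation")) {
    d <- x$visits
    d$dose_fraction <- d$sim_dose
    d$flare <- d$sim_flare
  } else if (inherits(x, "trial_cohort")) {
    arm <- match.arg(arm)
    d <- x$visits[x$visits$arm == arm, , drop = FALSE]
  } else d <- x
  stopifnot(all(c("course_id", "month", "dose_fraction", "flare") %in% names(d)))
  per_course <- do.call(rbind, lapply(split(d, d$course_id), function(cv) {
    cv <- cv[order(cv$month), ]
    w <- cv$month < window_months   # prescription at the last visit has no weight
    data.frame(course_id = cv$course_id[1L],
               patient_id = if ("patient_id" %in% names(cv))
                 cv$patient_id[1L] else cv$course_id[1L],
               n_flares = sum(cv$flare, na.rm = TRUE),
               mean_dose = mean(cv$dose_fraction[w]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_course) <- NULL
  point <- function(pc) c(mean_flares = mean(pc$n_flares),
                          prop_flaring = mean(pc$n_flares >= 1),
                          mean_dose = mean(pc$mean_dose))
  est <- point(per_course)
  ci <- NULL
  if (B > 0) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    pats <- unique(per_course$patient_id)
    boot <- t(vapply(seq_len(B), function(b) {
      take <- sample(pats, length(pats), replace = TRUE)
      point(do.call(rbind, lapply(take, function(id)
        per_course[per_course$patient_id == id, , drop = FALSE])))
    }, est))
    a <- (1 - conf) / 2
    ci <- apply(boot, 2L, stats::quantile, probs = c(a, 1 - a))
  }
  structure(list(mean_flares = est[["mean_flares"]],
                 prop_flaring = est[["prop_flaring"]],
                 mean_dose = est[["mean_dose"]],
                 ci = ci, per_course = per_course, n = nrow(per_course),
                 B = B),
            class = "taper_outcomes")
}

#' @export
print.taper_outcomes <- function(x, ...) {
  fmt <- function(what, v, pct = FALSE) {
    s <- if (pct) sprintf("%.0f%%", 100 * v) else sprintf("%.2f", v)
    if (!is.null(x$ci)) {
      lo <- x$ci[1L, what]; hi <- x$ci[2L, what]
      s <- paste0(s, if (pct) sprintf(" (%.0f-%.0f)", 100 * lo, 100 * hi)
                  else sprintf(" (%.2f-%.2f)", lo, hi))
    }
    s
  }
  cat(sprintf("Outcomes over 18 months (n = %d courses):\n", x$n))
  cat("  mean flares per course: ", fmt("mean_flares", x$mean_flares), "\n", sep = "")
  cat("  courses with >= 1 flare: ", fmt("prop_flaring", x$prop_flaring, TRUE), "\n", sep = "")
  cat("  mean dose (fraction of full): ", fmt("mean_dose", x$mean_dose), "\n", sep = "")
  invisible(x)
}

#' Trade-off metrics between two tapering strategies
#'
#' The extra dose spent per flare prevented,
#' `(dose_a - dose_b) / (flares_b - flares_a)`, and the extra flares
#' incurred per full dose saved, `(flares_a - flares_b) / (dose_b - dose_a)`
#' -- both invariant under swapping the two arms.  A zero denominator is
#' flagged and yields `NA`.
#'
#' @param a,b `taper_outcomes` objects, or numeric vectors
#'   `c(flares = , dose = )` of group means.
#' @return List of class `comparative_metrics` with
#'   `dose_per_flare_prevented` and `flares_per_dose_saved`.
#' @export
comparative_metrics <- function(a, b) {
  get2 <- function(x) {
    if (inherits(x, "taper_outcomes")) c(flares = x$mean_flares, dose = x$mean_dose)
    else c(flares = x[["flares"]], dose = x[["dose"]])
  }
  a <- get2(a); b <- get2(b)
  dflare <- b[["flares"]] - a[["flares"]]
  ddose <- a[["dose"]] - b[["dose"]]
  structure(list(
    dose_per_flare_prevented = if (abs(dflare) < 1e-12) NA_real_ else ddose / dflare,
    flares_per_dose_saved = if (abs(ddose) < 1e-12) NA_real_ else dflare / ddose,
    undefined = abs(dflare) < 1e-12 || abs(ddose) < 1e-12),
    class = "comparative_metrics")
}

#' @export
print.comparative_metrics <- function(x, ...) {
  if (x$undefined) cat("comparative metrics undefined (zero difference)\n")
  cat(sprintf("  dose spent per flare prevented: %.2f\n  flares per full dose saved:     %.2f\n",
              x$dose_per_flare_prevented, x$flares_per_dose_saved))
  invisible(x)
}

#' Sweep the decision cutoff over a grid
#'
#' Runs the prediction-aided simulation at each cutoff and tabulates the
#' cohort outcomes.
#'
#' @inheritParams simulate_taper
#' @param cutoffs cutoff grid (default 15% to 45% in steps of 10%).
#' @param B bootstrap replicates per cutoff (0 = no CIs).
#' @param seed bootstrap seed.
#' @return Data frame with one row per cutoff.
#' @export
cutoff_sweep <- function(trial, cutoffs = c(0.15, 0.25, 0.35, 0.45),
                         use_baseline = TRUE, B = 0, seed = 1) {
  rows <- lapply(cutoffs, function(ct) {
    o <- taper_outcomes(simulate_taper(trial, ct, use_baseline), B = B,
                        seed = seed)
    data.frame(cutoff = ct, mean_flares = o$mean_flares,
               prop_flaring = o$prop_flaring, mean_dose = o$mean_dose)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach model-based risk predictions to a trial cohort
#'
#' Computes the landmark 3-month flare risk at every visit of every trial
#' course from a fitted model: the class posterior combines the DAS28
#' history up to the visit with the survival factor since the last flare
#' (the at-risk clock restarts at a flare; the longitudinal history is kept
#' in full), and the conditional risk is evaluated under the dose prescribed
#' at the visit.
#'
#' @param trial a `trial_cohort`.
#' @param object a fitted `jlcm`.
#' @param horizon_weeks prediction horizon (13 weeks = one visit interval).
#' @return The `trial_cohort` with its `risk` column filled.
#' @export
add_risk_predictions <- function(trial, object, horizon_weeks = 13) {
  stopifnot(inherits(trial, "trial_cohort"), inherits(object, "jlcm"))
  v <- trial$visits
  for (id in unique(v$course_id)) {
    rows <- which(v$course_id == id)
    cv <- v[rows, , drop = FALSE]
    cv <- cv[order(cv$month), , drop = FALSE]
    X <- as.numeric(trial$covariates[
      trial$covariates$course_id == id, .covariate_cols][1L, ])
    # dose in force over (m, m+3] is the prescription at visit m; the dose
    # history for the survival factor therefore steps at the visit times
    risks <- vapply(seq_len(nrow(cv)), function(j) {
      s <- cv$week[j]
      flares_before <- cv$week[cv$flare & cv$week <= s]
      from <- if (length(flares_before)) max(flares_before) else 0
      lw <- history_logweights(object$params, X, cv$week, cv$das28, s,
                               from_week = from, dose_week = cv$week,
                               dose = cv$dose_fraction)
      w <- norm_weights(lw)
      r <- class_conditional_risk(object$params, X, s, horizon_weeks,
                                  future_dose_week = s,
                                  future_dose = cv$dose_fraction[j])
      sum(w * r)
    }, 0)
    v$risk[rows[order(v$month[rows])]] <- risks
  }
  trial$visits <- v
  trial
}
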