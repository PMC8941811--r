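# Shared fixtures: hand-built courses, cohorts, parameter sets, and a
# fit cache so expensive model fits are shared between test blocks.

covariate_cols <- c("time_to_lda_weeks", "das28_baseline",
                    "dose_fraction_baseline", "sj_increase_baseline",
                    "tj_increase_baseline", "disease_duration_years",
                    "seropositive", "tnfi")

zero_covariates <- function() {
  stats::setNames(as.list(c(0, 0, 0, FALSE, FALSE, 0, FALSE, FALSE)),
                  covariate_cols)
}

# a cohort built directly (already re-anchored), bypassing assemble_course
make_cohort <- function(courses) {
  visits <- do.call(rbind, lapply(courses, function(cr) {
    data.frame(course_id = cr$id, patient_id = cr$pid %||% cr$id,
               week = cr$week, das28 = cr$das28,
               dose_fraction = cr$dose %||% rep(1, length(cr$week)),
               flare = cr$flare %||% rep(FALSE, length(cr$week)),
               stringsAsFactors = FALSE)
  }))
  covs <- do.call(rbind, lapply(courses, function(cr) {
    cv <- cr$cov %||% zero_covariates()
    data.frame(course_id = cr$id, patient_id = cr$pid %||% cr$id,
               cv[covariate_cols], stringsAsFactors = FALSE)
  }))
  tab <- do.call(rbind, lapply(courses, function(cr) {
    data.frame(course_id = cr$id, patient_id = cr$pid %||% cr$id,
               first_flare_week = cr$event %||% NA_real_,
               censor_week = cr$censor %||% max(cr$week),
               stringsAsFactors = FALSE)
  }))
  structure(list(visits = visits, covariates = covs, courses = tab),
            class = "flare_cohort")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# simple parameter sets
toy_params <- function(G = 2, q = 1, pi = NULL, kappa = 1, rho = 0.5,
                       gamma = matrix(0, 2, G), beta_s = rep(0, 8),
                       delta = 0, sigma2 = 0.25,
                       B = matrix(c(0.09, 0.01, 0.01, 0.04), 2, 2),
                       beta = NULL) {
  if (is.null(pi)) pi <- rep(1 / G, G)
  if (is.null(beta))
    beta <- sapply(seq_len(G), function(g) c(2 + 0.5 * g, rep(0.2 * g, q)))
  jlcm_params(pi = pi, beta = matrix(beta, q + 1, G), B = B, sigma2 = sigma2,
              kappa = kappa, rho = rho, gamma = gamma, beta_s = beta_s,
              delta = delta)
}

# a trial cohort built by hand: one course per element, 3-monthly grid
make_trial <- function(courses) {
  months <- seq(0, 18, by = 3)
  visits <- do.call(rbind, lapply(courses, function(cr) {
    data.frame(course_id = cr$id, patient_id = cr$id, arm = cr$arm %||% "dgdo",
               month = months, week = months / 3 * 13,
               das28 = cr$das28 %||% rep(2.5, length(months)),
               dose_fraction = cr$dose,
               flare = cr$flare %||% rep(FALSE, length(months)),
               risk = cr$risk %||% rep(0, length(months)),
               stringsAsFactors = FALSE)
  }))
  covs <- do.call(rbind, lapply(courses, function(cr) {
    data.frame(course_id = cr$id, patient_id = cr$id, arm = cr$arm %||% "dgdo",
               zero_covariates()[covariate_cols], stringsAsFactors = FALSE)
  }))
  structure(list(visits = visits, covariates = covs),
            class = "trial_cohort")
}

# well-separated two-class configuration used for recovery studies
well_separated_config <- function() {
  dev_cohort_config(beta = cbind(c(2.45, 0.05, -0.02), c(3.0, 0.8, 0.3)),
                    sigma = 0.45)
}

# cache fits shared across test files (computed at most once per run)
.fit_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fit_cache[[key]])) .fit_cache[[key]] <- force(expr)
  .fit_cache[[key]]
}
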