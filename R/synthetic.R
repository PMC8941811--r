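# Synthetic cohort generators with the statistical structure the analysis
# assumes: latent-class DAS28 trajectories (random intercept + slope,
# Gaussian noise), class-linked flare hazards (Weibull baseline with
# class-specific time effects, fixed covariates, time-varying dichotomised
# dose), covariate marginals matching the published cohort summaries, and
# either an irregular-visit EHR-style visit process or a protocolised
# 3-monthly tapering trial.  Flare events are drawn as an inhomogeneous
# Poisson (renewal) process with the model's intensity, so the first-event
# time has exactly the model's survival function and repeated events give
# per-patient-year flare rates.

#' Configuration of the EHR-style development-cohort generator
#'
#' Defaults emulate the development setting: two latent classes with shares
#' 182/279 and 97/279, a stable and a rising DAS28 trajectory, irregular
#' visits with mean interval 22.3 weeks (SD 12.3), median follow-up 91
#' weeks, covariate marginals from the published cohort table
#' (seropositivity 84.6%, disease duration median 9 years, mean baseline
#' dose about 77% of the full registered dose), published hazard-ratio
#' covariate effects, and a baseline Weibull rate calibrated so the overall
#' flare rate is about 0.47 per patient-year.
#'
#' @param pi class shares.
#' @param beta class trajectory coefficients, DAS28 units per year^k.
#' @param B random intercept/slope covariance (slope per year).
#' @param sigma residual SD of DAS28 measurements.
#' @param kappa,rho Weibull baseline shape and rate scale (per year).
#' @param gamma class-specific log-hazard time coefficients (2 x G).
#' @param beta_s named covariate log-hazard effects.
#' @param delta log-hazard effect of dose <= 50%.
#' @param covariates list of covariate marginal parameters.
#' @param visit_interval_mean,visit_interval_sd gamma visit-interval moments
#'   in weeks.
#' @param followup_median_weeks,followup_sdlog log-normal follow-up length.
#' @param taper_prob share of courses whose dose is tapered during
#'   follow-up (two multiplicative steps to 2/3 and 1/2 of the baseline
#'   dose at random visits).
#' @return A list of class `dev_cohort_config`.
#' @export
dev_cohort_config <- function(
    pi = c(182, 97) / 279,
    beta = cbind(c(2.45, 0.10, -0.05), c(2.75, 0.70, 0.25)),
    B = matrix(c(0.16, 0.01, 0.01, 0.04), 2, 2),
    sigma = 0.55,
    kappa = 1.1,
    rho = 0.112,
    gamma = cbind(c(0, 0), c(1.10, 0.30)),
    beta_s = c(time_to_lda_weeks = log(0.97), das28_baseline = log(1.18),
               dose_fraction_baseline = log(1.21),
               sj_increase_baseline = log(1.72),
               tj_increase_baseline = log(2.07),
               disease_duration_years = log(1.02),
               seropositive = log(2.51), tnfi = log(0.90)),
    delta = log(2.21),
    covariates = list(sero_rate = 0.846, duration_meanlog = log(9),
                      duration_sdlog = 0.7, tta_mean = 30, tta_sd = 15,
                      das28b_mean = 2.79, das28b_sd = 1.34,
                      doseb_shape1 = 4.9, doseb_shape2 = 1.5,
                      tj_rate = 0.176, sj_rate = 0.10, tnfi_rate = 0.799),
    visit_interval_mean = 22.3, visit_interval_sd = 12.3,
    followup_median_weeks = 91, followup_sdlog = 0.25,
    taper_prob = 0.6) {
  cfg <- list(pi = pi, beta = as.matrix(beta), B = B, sigma = sigma,
              kappa = kappa, rho = rho, gamma = as.matrix(gamma),
              beta_s = beta_s, delta = delta, covariates = covariates,
              visit_interval_mean = visit_interval_mean,
              visit_interval_sd = visit_interval_sd,
              followup_median_weeks = followup_median_weeks,
              followup_sdlog = followup_sdlog, taper_prob = taper_prob,
              kind = "development")
  stopifnot(abs(sum(cfg$pi) - 1) < 1e-8, ncol(cfg$beta) == length(cfg$pi))
  class(cfg) <- "dev_cohort_config"
  cfg
}

#' Configuration of the protocolised tapering-trial generator
#'
#' Same disease model as [dev_cohort_config()] but with covariate marginals
#' of a tapering-trial population (seropositivity 85.4%, TNF-inhibitor
#' users at full baseline dose in stable low disease activity, baseline
#' DAS28 mean 2.15), a fixed 3-monthly visit grid over 18 months, the
#' stepwise taper 100% -> 67% -> 50% -> 0% with reinstatement of the last
#' effective dose on flare (full dose on a persistent flare), and a
#' baseline rate calibrated so the tapering arm flares at about 0.62 per
#' patient-year.
#'
#' @inheritParams dev_cohort_config
#' @export
trial_cohort_config <- function(
    pi = c(182, 97) / 279,
    beta = cbind(c(2.45, 0.10, -0.05), c(2.75, 0.70, 0.25)),
    B = matrix(c(0.16, 0.01, 0.01, 0.04), 2, 2),
    sigma = 0.45,
    kappa = 1.1,
    rho = 0.171,
    gamma = cbind(c(0, 0), c(1.10, 0.30)),
    beta_s = c(time_to_lda_weeks = log(0.97), das28_baseline = log(1.18),
               dose_fraction_baseline = log(1.21),
               sj_increase_baseline = log(1.72),
               tj_increase_baseline = log(2.07),
               disease_duration_years = log(1.02),
               seropositive = log(2.51), tnfi = log(0.90)),
    delta = log(2.21),
    covariates = list(sero_rate = 0.854, duration_meanlog = log(6),
                      duration_sdlog = 0.8, tta_mean = 42.1, tta_sd = 29.1,
                      das28b_mean = 2.15, das28b_sd = 0.70)) {
  cfg <- list(pi = pi, beta = as.matrix(beta), B = B, sigma = sigma,
              kappa = kappa, rho = rho, gamma = as.matrix(gamma),
              beta_s = beta_s, delta = delta, covariates = covariates,
              kind = "trial")
  class(cfg) <- "trial_cohort_config"
  cfg
}

rmvn2 <- function(n, B) {
  if (all(B == 0)) return(matrix(0, n, 2L))
  L <- t(chol(B + diag(1e-12, 2L)))
  t(L %*% matrix(stats::rnorm(2L * n), 2L, n))
}

rtruncnorm_upper <- function(n, mean, sd, upper) {
  # inverse-CDF truncated normal on (-Inf, upper], floored at 0.1
  u <- stats::runif(n, 0, stats::pnorm(upper, mean, sd))
  pmax(stats::qnorm(u, mean, sd), 0.1)
}

sample_covariates <- function(n, cfg) {
  cm <- cfg$covariates
  if (cfg$kind == "development") {
    data.frame(
      time_to_lda_weeks = stats::rgamma(n, shape = (cm$tta_mean / cm$tta_sd)^2,
                                        scale = cm$tta_sd^2 / cm$tta_mean),
      das28_baseline = rtruncnorm_upper(n, cm$das28b_mean, cm$das28b_sd, 3.2),
      dose_fraction_baseline = stats::rbeta(n, cm$doseb_shape1, cm$doseb_shape2),
      sj_increase_baseline = stats::runif(n) < cm$sj_rate,
      tj_increase_baseline = stats::runif(n) < cm$tj_rate,
      disease_duration_years = stats::rlnorm(n, cm$duration_meanlog,
                                             cm$duration_sdlog),
      seropositive = stats::runif(n) < cm$sero_rate,
      tnfi = stats::runif(n) < cm$tnfi_rate)
  } else {
    data.frame(
      time_to_lda_weeks = stats::rgamma(n, shape = (cm$tta_mean / cm$tta_sd)^2,
                                        scale = cm$tta_sd^2 / cm$tta_mean),
      das28_baseline = rtruncnorm_upper(n, cm$das28b_mean, cm$das28b_sd, 3.2),
      dose_fraction_baseline = 1,
      sj_increase_baseline = FALSE, tj_increase_baseline = FALSE,
      disease_duration_years = stats::rlnorm(n, cm$duration_meanlog,
                                             cm$duration_sdlog),
      seropositive = stats::runif(n) < cm$sero_rate,
      tnfi = TRUE)
  }
}

# cumulative hazard at `t_yr` for a piecewise-constant dose path (years)
truth_cumhaz <- function(cfg, g, eta, seg_a, seg_b, seg_low, t_yr) {
  kp <- seg_a < t_yr
  jlcm_cumhaz_cpp(seg_a[kp], pmin(seg_b[kp], t_yr), seg_low[kp],
                  cfg$kappa, cfg$rho, cfg$gamma[1, g], cfg$gamma[2, g],
                  eta, cfg$delta)
}

# inhomogeneous-Poisson event times on (0, C_yr] by numerical inversion of
# the cumulative hazard
sample_flare_times <- function(cfg, g, eta, seg_a, seg_b, seg_low, C_yr) {
  Lam_end <- truth_cumhaz(cfg, g, eta, seg_a, seg_b, seg_low, C_yr)
  times <- numeric(0)
  target <- stats::rexp(1)
  while (target < Lam_end) {
    f <- function(u) truth_cumhaz(cfg, g, eta, seg_a, seg_b, seg_low, u) - target
    tt <- stats::uniroot(f, c(1e-8, C_yr), tol = 1e-10)$root
    times <- c(times, tt)
    target <- target + stats::rexp(1)
  }
  times
}

#' Generate an EHR-style development cohort
#'
#' Samples latent classes, covariates, random effects, noisy DAS28 values
#' at irregular visits, a per-course dose path, and flare events from the
#' class-specific hazard.  The first latent flare time (continuous, from
#' numerical inversion of the cumulative hazard) becomes the course's event
#' time; the flare flag is raised at the first visit on or after it.
#'
#' @param n number of courses.
#' @param config a [dev_cohort_config()].
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return A `flare_cohort` with a `truth` attribute (classes, random
#'   effects, latent flare times in weeks, covariate design, config).
#' @export
simulate_dev_cohort <- function(n = 279, config = dev_cohort_config(),
                                seed = 1) {
  stopifnot(inherits(config, "dev_cohort_config"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  G <- length(config$pi); q1 <- nrow(config$beta)
  cls <- sample.int(G, n, replace = TRUE, prob = config$pi)
  cov <- sample_covariates(n, config)
  ranef <- rmvn2(n, config$B)
  Xm <- as.matrix(sapply(cov, as.numeric))
  eta_all <- as.numeric(Xm %*% config$beta_s[colnames(Xm)])
  sh <- (config$visit_interval_mean / config$visit_interval_sd)^2
  sc <- config$visit_interval_sd^2 / config$visit_interval_mean

  visits_list <- vector("list", n); courses_list <- vector("list", n)
  flare_times_wk <- vector("list", n)
  for (i in seq_len(n)) {
    C <- min(stats::rlnorm(1, log(config$followup_median_weeks),
                           config$followup_sdlog), 156)
    wk <- 0
    repeat {
      nxt <- wk[length(wk)] + stats::rgamma(1, shape = sh, scale = sc)
      if (nxt > C) break
      wk <- c(wk, nxt)
    }
    if (length(wk) < 2L) wk <- c(0, C)  # guarantee some follow-up
    dose <- rep(cov$dose_fraction_baseline[i], length(wk))
    if (stats::runif(1) < config$taper_prob && length(wk) >= 3L) {
      ks <- sort(sample(2:length(wk), min(2L, length(wk) - 1L)))
      dose[seq_along(dose) >= ks[1L]] <- cov$dose_fraction_baseline[i] * 2 / 3
      if (length(ks) > 1L)
        dose[seq_along(dose) >= ks[2L]] <- cov$dose_fraction_baseline[i] * 0.5
    }
    cen <- wk[length(wk)]
    sg <- dose_segments(wk, dose, cen)
    ev <- sample_flare_times(config, cls[i], eta_all[i],
                             sg$a / WEEKS_PER_YEAR, sg$b / WEEKS_PER_YEAR,
                             sg$low, cen / WEEKS_PER_YEAR)
    ev_wk <- ev * WEEKS_PER_YEAR
    flare_times_wk[[i]] <- ev_wk
    tyr <- wk / WEEKS_PER_YEAR
    y <- as.numeric(outer(tyr, 0:(q1 - 1L), `^`) %*% config$beta[, cls[i]]) +
      ranef[i, 1L] + ranef[i, 2L] * tyr + stats::rnorm(length(wk), 0, config$sigma)
    flare_flag <- rep(FALSE, length(wk))
    for (e in ev_wk) {
      j <- which(wk >= e)[1L]
      if (!is.na(j)) flare_flag[j] <- TRUE
    }
    id <- sprintf("c%04d", i)
    visits_list[[i]] <- data.frame(
      course_id = id, patient_id = sprintf("p%04d", i), week = wk,
      das28 = y, dose_fraction = dose, flare = flare_flag,
      stringsAsFactors = FALSE)
    courses_list[[i]] <- data.frame(
      course_id = id, patient_id = sprintf("p%04d", i),
      first_flare_week = if (length(ev_wk)) ev_wk[1L] else NA_real_,
      censor_week = cen, stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, visits_list)
  courses <- do.call(rbind, courses_list)
  covariates <- data.frame(course_id = courses$course_id,
                           patient_id = courses$patient_id, cov,
                           stringsAsFactors = FALSE)
  rownames(visits) <- rownames(courses) <- rownames(covariates) <- NULL
  out <- structure(list(visits = visits, covariates = covariates,
                        courses = courses),
                   class = "flare_cohort")
  attr(out, "truth") <- list(class = cls, ranef = ranef,
                             flare_times_week = flare_times_wk,
                             X = Xm, eta = eta_all, config = config)
  out
}

#' Generate a protocolised tapering-trial cohort
#'
#' The tapering (DGDO) arm follows the dose steps 100% -> 67% -> 50% -> 0%
#' prescribed at months 0/3/6 on a 3-monthly grid over 18 months; on a
#' flare the last effective dose is reinstated and tapering stops; a
#' persistent flare escalates to the full dose.  The routine-care arm keeps
#' the full dose.  Flares arise from the class-specific hazard (the
#' dose <= 50% indicator raises it) and are detected at the following
#' visit; DAS28 values at flare visits jump so the visit-to-visit flare
#' criterion fires there too.
#'
#' @param n_dgdo,n_routine arm sizes.
#' @param config a [trial_cohort_config()].
#' @param seed integer seed.
#' @return An object of class `trial_cohort`: `visits` (one row per
#'   course-visit: `month`, `week`, `das28`, `dose_fraction` = dose
#'   prescribed at the visit, `flare`, `risk` (`NA` until
#'   [add_risk_predictions()]), `arm`) and `covariates`; plus a `truth`
#'   attribute.
#' @export
simulate_trial_cohort <- function(n_dgdo = 121, n_routine = 59,
                                  config = trial_cohort_config(), seed = 1) {
  stopifnot(inherits(config, "trial_cohort_config"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- n_dgdo + n_routine
  arm <- rep(c("dgdo", "routine"), c(n_dgdo, n_routine))
  G <- length(config$pi); q1 <- nrow(config$beta)
  cls <- sample.int(G, n, replace = TRUE, prob = config$pi)
  cov <- sample_covariates(n, config)
  ranef <- rmvn2(n, config$B)
  Xm <- as.matrix(sapply(cov, as.numeric))
  eta_all <- as.numeric(Xm %*% config$beta_s[colnames(Xm)])
  months <- seq(0, 18, by = 3)
  weeks <- months / 3 * 13
  taper_steps <- c(2 / 3, 0.5, 0)   # prescriptions at months 0, 3, >= 6

  visits_list <- vector("list", n)
  for (i in seq_len(n)) {
    nv <- length(months)
    dose <- numeric(nv); flare <- logical(nv)
    # state: index into the taper schedule; flare handling per protocol
    step <- 0L; flared_once <- FALSE; in_force_prev <- 1
    for (j in seq_len(nv)) {
      if (j > 1L) {
        # did a flare arise during (week[j-1], week[j]] at the in-force dose?
        low <- dose[j - 1L] <= 0.5
        a <- weeks[j - 1L] / WEEKS_PER_YEAR; b <- weeks[j] / WEEKS_PER_YEAR
        dLam <- jlcm_cumhaz_cpp(a, b, as.integer(low), config$kappa,
                                config$rho, config$gamma[1, cls[i]],
                                config$gamma[2, cls[i]], eta_all[i],
                                config$delta)
        flare[j] <- stats::runif(1) < 1 - exp(-dLam)
      }
      # prescription at visit j
      if (arm[i] == "routine") {
        dose[j] <- 1
      } else if (j > 1L && flare[j]) {
        if (!flared_once) {
          # reinstate the last effective dose: the level before the one
          # the patient flared on
          flared_once <- TRUE
          lvl <- c(1, taper_steps)
          pos <- which.min(abs(lvl - dose[j - 1L]))
          dose[j] <- lvl[max(pos - 1L, 1L)]
        } else {
          dose[j] <- 1  # persistent flare: full dose
        }
      } else if (flared_once) {
        dose[j] <- dose[j - 1L]
      } else {
        step <- min(step + 1L, length(taper_steps))
        dose[j] <- taper_steps[step]
      }
    }
    tyr <- weeks / WEEKS_PER_YEAR
    y <- as.numeric(outer(tyr, 0:(q1 - 1L), `^`) %*% config$beta[, cls[i]]) +
      ranef[i, 1L] + ranef[i, 2L] * tyr + stats::rnorm(nv, 0, config$sigma)
    for (j in which(flare)) # DAS28 jump so the flare criterion fires
      y[j] <- max(y[j], y[j - 1L] + 1.25, 3.25)
    visits_list[[i]] <- data.frame(
      course_id = sprintf("t%04d", i), patient_id = sprintf("tp%04d", i),
      arm = arm[i], month = months, week = weeks, das28 = y,
      dose_fraction = dose, flare = flare, risk = NA_real_,
      stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, visits_list)
  covariates <- data.frame(course_id = sprintf("t%04d", seq_len(n)),
                           patient_id = sprintf("tp%04d", seq_len(n)),
                           arm = arm, cov, stringsAsFactors = FALSE)
  rownames(visits) <- rownames(covariates) <- NULL
  out <- structure(list(visits = visits, covariates = covariates),
                   class = "trial_cohort")
  attr(out, "truth") <- list(class = cls, ranef = ranef, X = Xm,
                             eta = eta_all, config = config)
  out
}

#' @export
print.trial_cohort <- function(x, ...) {
  n <- length(unique(x$visits$course_id))
  nd <- length(unique(x$visits$course_id[x$visits$arm == "dgdo"]))
  cat(sprintf("<trial_cohort: %d courses (%d tapering / %d routine care), 18-month 3-monthly grid>\n",
              n, nd, n - nd))
  invisible(x)
}

#' Exact flare risk under the generating model
#'
#' The generating-model probability of a flare in `(s, s + h]` for a course
#' with known latent class, covariates and planned dose -- the oracle the
#' fitted landmark predictions are benchmarked against.
#'
#' @param config generator configuration (or any list with `kappa`, `rho`,
#'   `gamma`, `beta_s`, `delta`).
#' @param class latent class index.
#' @param X named covariate vector (model order).
#' @param s_week landmark in weeks.
#' @param horizon_weeks horizon (default 13).
#' @param dose dose fraction in force over the horizon, or a data frame
#'   `week`/`dose_fraction` path.
#' @export
true_flare_risk <- function(config, class, X, s_week, horizon_weeks = 13,
                            dose = 1) {
  eta <- sum(config$beta_s * as.numeric(X))
  fd <- if (is.data.frame(dose)) list(week = dose$week, dose = dose$dose_fraction)
        else list(week = s_week, dose = dose)
  sg <- dose_segments(fd$week, fd$dose, s_week + horizon_weeks)
  kp <- sg$b > s_week
  dL <- jlcm_cumhaz_cpp(pmax(sg$a[kp], s_week) / WEEKS_PER_YEAR,
                        sg$b[kp] / WEEKS_PER_YEAR, sg$low[kp],
                        config$kappa, config$rho, config$gamma[1, class],
                        config$gamma[2, class], eta, config$delta)
  1 - exp(-dL)
}

#' Generating-model risks for a table of landmark predictions
#'
#' @param cohort a synthetic `flare_cohort` carrying its `truth` attribute.
#' @param predictions a `flare_predictions` frame (e.g. from
#'   [predict.jlcm()] or [jlcm_cv()]).
#' @return Numeric vector of oracle risks aligned with `predictions` rows.
#' @export
oracle_risks <- function(cohort, predictions) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop("cohort carries no ground truth")
  idx <- match(predictions$course_id, cohort$courses$course_id)
  vapply(seq_len(nrow(predictions)), function(r) {
    i <- idx[r]
    v <- cohort$visits[cohort$visits$course_id == predictions$course_id[r], ]
    s <- predictions$landmark_week[r]
    d <- v$dose_fraction[!is.na(v$dose_fraction) & v$week <= s]
    true_flare_risk(truth$config, truth$class[i], truth$X[i, ], s,
                    predictions$horizon_weeks[r],
                    dose = if (length(d)) d[length(d)] else 1)
  }, 0)
}

#' Empirical flare rate per patient-year
#'
#' For a development cohort: all latent flare events over total follow-up.
#' For a trial cohort: flare visits in the requested arm over the 18-month
#' window.
#'
#' @param x a synthetic `flare_cohort` or `trial_cohort`.
#' @param arm trial arm (trial cohorts only).
#' @export
empirical_flare_rate <- function(x, arm = "dgdo") {
  if (inherits(x, "flare_cohort")) {
    sum(x$visits$flare, na.rm = TRUE) / (sum(x$courses$censor_week) / 52)
  } else if (inherits(x, "trial_cohort")) {
    v <- x$visits[x$visits$arm == arm, ]
    sum(v$flare) / (length(unique(v$course_id)) * 1.5)
  } else stop("unsupported input")
}

#' Calibrate the baseline hazard rate to a target flare rate
#'
#' Bisection over `log(rho)` so that the generator's empirical flare rate
#' (per patient-year, under common random numbers) matches `target`.  Used
#' once to fix the package defaults; exported so the calibration is
#' reproducible.
#'
#' @param config a [dev_cohort_config()] or [trial_cohort_config()].
#' @param target flares per patient-year (0.47 development, 0.62 trial arm).
#' @param n cohort size per evaluation.
#' @param seed common-random-number seed.
#' @param interval search interval for `log(rho)`.
#' @return The config with `rho` replaced by the calibrated value.
#' @export
calibrate_flare_rate <- function(config, target, n = 1000, seed = 1,
                                 interval = c(-4, 1.5)) {
  rate <- function(lr) {
    cfg <- config; cfg$rho <- exp(lr)
    if (cfg$kind == "development")
      empirical_flare_rate(simulate_dev_cohort(n, cfg, seed))
    else
      empirical_flare_rate(simulate_trial_cohort(n, 0, cfg, seed), "dgdo")
  }
  sol <- stats::uniroot(function(lr) rate(lr) - target, interval, tol = 1e-4)
  config$rho <- exp(sol$root)
  config
}
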