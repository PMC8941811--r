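#' @export
print.jlcm <- function(x, ...) {
  cat(sprintf("Joint latent class mixed model: %d class(es), order-%d trajectories\n",
              x$spec$classes, x$spec$poly))
  cat(sprintf("  %d courses, logLik %.2f, %d parameters, BIC %.2f%s\n",
              x$data$n, x$loglik, x$n_params, x$bic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  class shares (prior): ",
      paste(sprintf("%.3f", x$params$pi), collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.jlcm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$data$n,
            class = "logLik")
}

#' @export
coef.jlcm <- function(object, ...) {
  p <- object$params
  G <- length(p$pi)
  out <- c(stats::setNames(p$pi, paste0("class_prob_", seq_len(G))))
  for (g in seq_len(G))
    out <- c(out, stats::setNames(p$beta[, g],
             paste0("traj_class", g, "_t", seq_len(nrow(p$beta)) - 1L)))
  out <- c(out,
           re_var_intercept = p$B[1, 1], re_cov = p$B[1, 2],
           re_var_slope = p$B[2, 2], sigma2 = p$sigma2,
           weibull_shape = p$kappa, weibull_scale = p$rho)
  for (g in seq_len(G))
    out <- c(out, stats::setNames(p$gamma[, g],
             paste0(c("loghaz_time_class", "loghaz_time2_class"), g)))
  c(out, p$beta_s, loghaz_low_dose = p$delta)
}

#' @export
summary.jlcm <- function(object, ...) {
  p <- object$params
  G <- length(p$pi)
  hr <- exp(c(stats::setNames(as.numeric(p$gamma),
                              paste0(rep(c("time_class", "time2_class"), G),
                                     rep(seq_len(G), each = 2L))),
              p$beta_s, dose_le_50pct = p$delta))
  modal <- apply(object$posterior, 1L, which.max)
  structure(list(fit = object,
                 hazard_ratios = hr,
                 class_sizes = tabulate(modal, G),
                 mean_posterior = colMeans(object$posterior)),
            class = "summary.jlcm")
}

#' @export
print.summary.jlcm <- function(x, ...) {
  print(x$fit)
  cat("  modal class sizes: ", paste(x$class_sizes, collapse = " / "), "\n",
      sep = "")
  cat("\nHazard ratios (survival submodel, time effects per year):\n")
  print(round(x$hazard_ratios, 3))
  invisible(x)
}

#' Posterior class membership probabilities
#' @param object a fitted `jlcm`.
#' @return Matrix (courses x classes), rows summing to 1.
#' @export
posterior_classes <- function(object) {
  stopifnot(inherits(object, "jlcm"))
  object$posterior
}

#' @export
residuals.jlcm <- function(object, type = c("marginal", "class"), ...) {
  type <- match.arg(type)
  d <- object$data; p <- object$params
  G <- length(p$pi)
  out <- numeric(length(d$y))
  for (i in seq_len(d$n)) {
    if (d$long_ptr[i + 1L] == d$long_ptr[i]) next
    idx <- (d$long_ptr[i] + 1L):d$long_ptr[i + 1L]
    Pm <- outer(d$t[idx], 0:(nrow(p$beta) - 1L), `^`)
    mu <- Pm %*% p$beta           # m x G class means
    w <- if (type == "marginal") object$posterior[i, ]
         else as.numeric(seq_len(G) == which.max(object$posterior[i, ]))
    out[idx] <- d$y[idx] - as.numeric(mu %*% w)
  }
  out
}

#' Draw new cohorts from a fitted model
#'
#' Uses the fitted parameters as the generating truth of
#' [simulate_dev_cohort()] and draws `nsim` fresh cohorts.
#'
#' @param object a fitted `jlcm`.
#' @param nsim,seed standard [stats::simulate()] arguments.
#' @param n courses per cohort (default: the training size).
#' @param ... ignored.
#' @export
simulate.jlcm <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  cfg <- dev_cohort_config(
    pi = object$params$pi, beta = object$params$beta, B = object$params$B,
    sigma = sqrt(object$params$sigma2), kappa = object$params$kappa,
    rho = object$params$rho, gamma = object$params$gamma,
    beta_s = object$params$beta_s, delta = object$params$delta)
  n <- n %||% object$data$n
  seeds <- if (is.null(seed)) sample.int(2^31 - 2L, nsim) else seed + seq_len(nsim) - 1L
  out <- lapply(seeds, function(s) simulate_dev_cohort(n = n, config = cfg, seed = s))
  if (nsim == 1L) out[[1L]] else out
}

#' Plot class mean trajectories and flare-free survival
#'
#' Left panel: class-specific mean DAS28 trajectories over follow-up.
#' Right panel: class-specific probability of remaining flare-free for a
#' course at the average covariate values, full dose.
#'
#' @param x a fitted `jlcm`.
#' @param upto_weeks time axis limit (default: the observed maximum).
#' @param ... ignored.
#' @export
plot.jlcm <- function(x, upto_weeks = NULL, ...) {
  p <- x$params; G <- length(p$pi)
  tmax <- (upto_weeks %||% (max(x$data$t) * WEEKS_PER_YEAR)) / WEEKS_PER_YEAR
  tt <- seq(1e-6, tmax, length.out = 80L)
  Pm <- outer(tt, 0:(nrow(p$beta) - 1L), `^`)
  mu <- Pm %*% p$beta
  xbar <- colMeans(x$data$X)
  eta <- sum(p$beta_s * xbar)
  S <- sapply(seq_len(G), function(g) {
    Lam <- vapply(tt, function(u)
      jlcm_cumhaz_cpp(0, u, 0L, p$kappa, p$rho, p$gamma[1, g], p$gamma[2, g],
                      eta, p$delta), 0)
    exp(-Lam)
  })
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(tt * WEEKS_PER_YEAR, mu, type = "l", lty = 1, lwd = 2,
                    xlab = "weeks since baseline", ylab = "mean DAS28",
                    main = "latent class trajectories")
  graphics::legend("topleft", bty = "n", lwd = 2, col = seq_len(G),
                   legend = sprintf("class %d (pi=%.2f)", seq_len(G), p$pi))
  graphics::matplot(tt * WEEKS_PER_YEAR, S, type = "l", lty = 1, lwd = 2,
                    ylim = c(0, 1), xlab = "weeks since baseline",
                    ylab = "P(flare-free)", main = "time to first flare")
  invisible(x)
}

#' Serialise a fitted model to JSON (and back)
#'
#' Writes the model specification, the full named parameter vector, the fit
#' statistics and convergence metadata as flat JSON; `read_jlcm()`
#' reconstructs a `jlcm` object usable for prediction (the training data and
#' posterior memberships are not stored).
#'
#' @param object a fitted `jlcm`.
#' @param path file path.
#' @export
write_jlcm <- function(object, path) {
  p <- object$params
  payload <- list(
    spec = object$spec,
    pi = p$pi, beta = as.numeric(p$beta), B = as.numeric(p$B),
    sigma2 = p$sigma2, kappa = p$kappa, rho = p$rho,
    gamma = as.numeric(p$gamma), beta_s = as.list(p$beta_s), delta = p$delta,
    loglik = object$loglik, n_params = object$n_params, bic = object$bic,
    converged = object$converged, n_starts_used = object$n_starts_used,
    n_courses = object$data$n)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(object)
}

#' @rdname write_jlcm
#' @export
read_jlcm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  G <- j$spec$classes; q <- j$spec$poly
  params <- jlcm_params(
    pi = j$pi, beta = matrix(j$beta, q + 1L, G), B = matrix(j$B, 2L, 2L),
    sigma2 = j$sigma2, kappa = j$kappa, rho = j$rho,
    gamma = matrix(j$gamma, 2L, G), beta_s = unlist(j$beta_s),
    delta = j$delta)
  structure(list(spec = j$spec, params = params, loglik = j$loglik,
                 n_params = j$n_params, bic = j$bic, converged = j$converged,
                 n_starts_used = j$n_starts_used,
                 data = list(n = j$n_courses)),
            class = "jlcm")
}
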