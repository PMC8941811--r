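# Likelihood kernels: longitudinal marginal density, survival submodel,
# joint mixture, and the analytic gradient.

test_that("single observation with no random effects reduces to a normal density", {
  p <- toy_params(G = 1, q = 1, B = matrix(0, 2, 2), sigma2 = 0.49,
                  beta = c(2.5, 0.3), rho = 0.2)
  coh <- make_cohort(list(list(id = "a", week = 26, das28 = 3.1, censor = 26)))
  cells <- jlcm_cells(coh, p)
  mu <- 2.5 + 0.3 * 0.5   # week 26 = 0.5 years
  expect_equal(cells$ll_long[1, 1], dnorm(3.1, mu, 0.7, log = TRUE),
               tolerance = 1e-12)
})

test_that("independent observations sum when the random effects vanish", {
  p <- toy_params(G = 1, q = 1, B = matrix(0, 2, 2), sigma2 = 1,
                  beta = c(2, 0.5))
  coh <- make_cohort(list(list(id = "a", week = c(0, 52), das28 = c(2.2, 2.9))))
  cells <- jlcm_cells(coh, p)
  expect_equal(cells$ll_long[1, 1],
               dnorm(2.2, 2, 1, log = TRUE) + dnorm(2.9, 2.5, 1, log = TRUE),
               tolerance = 1e-12)
})

test_that("marginal longitudinal density matches Monte-Carlo integration over random effects", {
  p <- toy_params(G = 1, q = 2, B = matrix(c(0.2, 0.05, 0.05, 0.1), 2, 2),
                  sigma2 = 0.3, beta = c(2.4, 0.6, 0.2))
  wk <- c(0, 30, 70); y <- c(2.6, 3.4, 3.1)
  coh <- make_cohort(list(list(id = "a", week = wk, das28 = y)))
  got <- jlcm_cells(coh, p)$ll_long[1, 1]
  set.seed(1)
  ndraw <- 2e5
  L <- t(chol(p$B)); b <- t(L %*% matrix(rnorm(2 * ndraw), 2))
  tyr <- wk / 52
  mu0 <- 2.4 + 0.6 * tyr + 0.2 * tyr^2
  dens <- rep(1, ndraw)
  for (j in seq_along(wk))
    dens <- dens * dnorm(y[j], mu0[j] + b[, 1] + b[, 2] * tyr[j], sqrt(0.3))
  mc <- mean(dens); se <- sd(dens) / sqrt(ndraw)
  expect_lt(abs(exp(got) - mc), 3 * se)
})

test_that("survival submodel reproduces the exponential special case exactly", {
  # kappa = 1, no time effects, no covariates: constant hazard rho
  rho <- 0.8
  p <- toy_params(G = 1, q = 1, kappa = 1, rho = rho)
  cen <- make_cohort(list(list(id = "a", week = 52, das28 = 2.5, censor = 52)))
  expect_equal(jlcm_cells(cen, p)$ll_surv[1, 1], -rho * 1, tolerance = 1e-12)
  ev <- make_cohort(list(list(id = "a", week = 52, das28 = 2.5,
                              event = 26, censor = 52)))
  expect_equal(jlcm_cells(ev, p)$ll_surv[1, 1], log(rho) - rho * 0.5,
               tolerance = 1e-12)
})

test_that("cumulative hazard with a time-varying dose matches a dense Riemann sum", {
  kappa <- 1.3; rho <- 0.4; g1 <- 0.5; g2 <- 0.3; eta <- 0.2; delta <- 0.7
  # dose drops below 50% at 0.6 years; evaluate up to 1.4 years
  seg_a <- c(0, 0.6); seg_b <- c(0.6, 1.4); seg_low <- c(0L, 1L)
  got <- flaretaper:::jlcm_cumhaz_cpp(seg_a, seg_b, seg_low, kappa, rho,
                                      g1, g2, eta, delta)
  tt <- seq(0, 1.4, length.out = 1e5 + 1); mid <- (tt[-1] + tt[-length(tt)]) / 2
  h <- kappa * rho^kappa * mid^(kappa - 1) * exp(g1 * mid + g2 * mid^2) *
    exp(eta + delta * (mid > 0.6))
  riemann <- sum(h) * diff(tt)[1]
  expect_equal(got, riemann, tolerance = 1e-6)
})

test_that("joint likelihood reduces correctly for one class and collapses for equal classes", {
  coh <- simulate_dev_cohort(n = 25, seed = 2)
  p1 <- toy_params(G = 1, q = 2, beta = c(2.5, 0.3, 0.1), rho = 0.3)
  cells <- jlcm_cells(coh, p1)
  expect_equal(jlcm_loglik(coh, p1), sum(cells$ll_long + cells$ll_surv),
               tolerance = 1e-10)
  # two identical classes: the mixture collapses to the one-class value
  p2 <- toy_params(G = 2, q = 2, beta = cbind(c(2.5, 0.3, 0.1), c(2.5, 0.3, 0.1)),
                   rho = 0.3)
  expect_equal(jlcm_loglik(coh, p2), jlcm_loglik(coh, p1), tolerance = 1e-10)
})

test_that("joint mixture equals a direct per-course two-term sum computed independently", {
  coh <- simulate_dev_cohort(n = 5, seed = 9)
  p <- toy_params(G = 2, q = 1, pi = c(0.3, 0.7),
                  beta = cbind(c(2.3, 0.1), c(3.0, 0.8)),
                  gamma = cbind(c(0, 0), c(0.5, 0.2)), rho = 0.4)
  # independent route: dense MVN via determinant/solve, R quadrature hazard
  d <- pack_jlcm_data(coh)
  ll_direct <- 0
  for (i in 1:5) {
    idx <- seq(d$long_ptr[i] + 1, d$long_ptr[i + 1])
    tyr <- d$t[idx]; y <- d$y[idx]
    terms <- numeric(2)
    for (g in 1:2) {
      mu <- p$beta[1, g] + p$beta[2, g] * tyr
      Z <- cbind(1, tyr)
      V <- Z %*% p$B %*% t(Z) + diag(p$sigma2, length(tyr))
      llL <- -0.5 * (length(y) * log(2 * pi) +
                       determinant(V)$modulus[1] +
                       drop(t(y - mu) %*% solve(V, y - mu)))
      lam <- function(u) p$kappa * p$rho^p$kappa * u^(p$kappa - 1) *
        exp(p$gamma[1, g] * u + p$gamma[2, g] * u^2)
      Lam <- integrate(lam, 0, d$Tev[i], rel.tol = 1e-12)$value
      llS <- -Lam + if (d$d[i] == 1) log(lam(d$Tev[i])) else 0
      terms[g] <- log(p$pi[g]) + llL + llS
    }
    ll_direct <- ll_direct + log(sum(exp(terms)))
  }
  expect_equal(jlcm_loglik(coh, p), ll_direct, tolerance = 1e-8)
})

test_that("joint likelihood is invariant under permutation of class labels", {
  coh <- simulate_dev_cohort(n = 30, seed = 4)
  p <- toy_params(G = 2, q = 1, pi = c(0.4, 0.6),
                  beta = cbind(c(2.2, 0.2), c(3.1, 0.7)),
                  gamma = cbind(c(0.1, 0), c(0.6, 0.3)), rho = 0.35)
  pswap <- p
  pswap$pi <- rev(p$pi)
  pswap$beta <- p$beta[, 2:1]
  pswap$gamma <- p$gamma[, 2:1]
  expect_equal(jlcm_loglik(coh, p), jlcm_loglik(coh, pswap), tolerance = 1e-10)
})

test_that("analytic gradient agrees with central differences", {
  coh <- simulate_dev_cohort(n = 40, seed = 6)
  d <- pack_jlcm_data(coh)
  p <- toy_params(G = 2, q = 2, pi = c(0.55, 0.45),
                  beta = cbind(c(2.4, 0.2, 0), c(2.9, 0.6, 0.2)),
                  gamma = cbind(c(0.1, 0.05), c(0.8, 0.3)),
                  beta_s = c(-0.02, 0.1, 0.2, 0.5, 0.7, 0.02, 0.9, -0.1),
                  delta = 0.6, rho = 0.3, kappa = 1.2)
  th <- flaretaper:::pack_theta(p)
  ng <- flaretaper:::nll_grad_natural(d, p)
  ga <- flaretaper:::chain_gradient(ng$grad, p, 2L, 3L, 8L)
  fn <- function(t) flaretaper:::nll_grad_natural(
    d, flaretaper:::unpack_theta(t, 2L, 2L, 8L))$loglik
  for (j in seq_along(th)) {
    h <- 1e-6 * max(1, abs(th[j]))
    e1 <- th; e1[j] <- e1[j] + h
    e2 <- th; e2[j] <- e2[j] - h
    expect_equal(ga[j], (fn(e1) - fn(e2)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("non-positive-definite covariance inputs are rejected", {
  expect_error(jlcm_params(1, matrix(c(2, 0.1), 2, 1),
                           matrix(c(1, 2, 2, 1), 2, 2), 0.3, 1, 0.5,
                           matrix(0, 2, 1), rep(0, 8), 0),
               "positive semi-definite")
})
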