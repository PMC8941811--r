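# Landmark prediction: class posterior, conditional risk, labels.

# a fitted-object shell around known parameters (no optimisation)
fake_fit <- function(params) {
  structure(list(spec = list(classes = length(params$pi),
                             poly = nrow(params$beta) - 1L,
                             horizon_weeks = 13,
                             covariates = covariate_cols,
                             time_varying_dose = TRUE),
                 params = params),
            class = "jlcm")
}

test_that("one-class exponential risk equals the closed form at every landmark", {
  rho <- 0.9
  p <- toy_params(G = 1, q = 1, kappa = 1, rho = rho, beta = c(2.5, 0.2))
  f <- fake_fit(p)
  coh <- make_cohort(list(list(id = "a", week = c(0, 20, 40, 80),
                               das28 = c(2.4, 2.6, 2.5, 2.7))))
  for (s in c(0, 20, 40)) {
    r <- flare_risk(f, coh, "a", s, horizon_weeks = 13)
    expect_equal(r, 1 - exp(-rho * 13 / 52), tolerance = 1e-10)
  }
})

test_that("class posterior is trivial for one class and excludes impossible classes", {
  p1 <- toy_params(G = 1, q = 1)
  f1 <- fake_fit(p1)
  coh <- make_cohort(list(list(id = "a", week = c(0, 26), das28 = c(2.5, 2.6))))
  expect_equal(class_posterior(f1, coh, "a", 26), 1)
  # class 2 mean far away with tiny variance: posterior collapses to class 1
  p2 <- toy_params(G = 2, q = 1, sigma2 = 0.01, B = matrix(0, 2, 2),
                   beta = cbind(c(2.5, 0), c(8, 0)))
  w <- class_posterior(fake_fit(p2), coh, "a", 26)
  expect_equal(w[1], 1, tolerance = 1e-10)
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("two-class posterior matches a hand-coded Bayes computation", {
  p <- toy_params(G = 2, q = 1, pi = c(0.35, 0.65),
                  beta = cbind(c(2.3, 0.1), c(3.0, 0.9)),
                  gamma = cbind(c(0, 0), c(0.6, 0.2)), rho = 0.5)
  f <- fake_fit(p)
  wk <- c(0, 15, 30); y <- c(2.6, 3.1, 3.0)
  coh <- make_cohort(list(list(id = "a", week = wk, das28 = y)))
  got <- class_posterior(f, coh, "a", 30)
  # independent route: dense MVN density x Weibull survival, two terms
  tyr <- wk / 52
  Z <- cbind(1, tyr)
  V <- Z %*% p$B %*% t(Z) + diag(p$sigma2, 3)
  terms <- sapply(1:2, function(g) {
    mu <- p$beta[1, g] + p$beta[2, g] * tyr
    dens <- exp(-0.5 * (3 * log(2 * pi) + determinant(V)$modulus[1] +
                          drop(t(y - mu) %*% solve(V, y - mu))))
    lam <- function(u) p$rho * exp(p$gamma[1, g] * u + p$gamma[2, g] * u^2)
    S <- exp(-integrate(lam, 0, 30 / 52, rel.tol = 1e-12)$value)
    p$pi[g] * dens * S
  })
  expect_equal(got, terms / sum(terms), tolerance = 1e-7)
})

test_that("risk grows with the horizon and vanishes as the horizon shrinks", {
  p <- toy_params(G = 2, q = 1, kappa = 1.2, rho = 0.4,
                  gamma = cbind(c(0.2, 0.1), c(0.7, 0.3)))
  f <- fake_fit(p)
  coh <- make_cohort(list(list(id = "a", week = c(0, 26), das28 = c(2.5, 3.0))))
  risks <- sapply(c(0.01, 4, 13, 26, 52),
                  function(h) flare_risk(f, coh, "a", 26, horizon_weeks = h))
  expect_true(all(diff(risks) > 0))
  expect_lt(risks[1], 1e-3)
})

test_that("a positive low-dose effect never decreases predicted risk", {
  p <- toy_params(G = 2, q = 1, rho = 0.4, delta = 0.8)
  f <- fake_fit(p)
  coh <- make_cohort(list(list(id = "a", week = c(0, 26), das28 = c(2.5, 2.8),
                               dose = c(1, 1))))
  r_full <- flare_risk(f, coh, "a", 26, future_dose = 1)
  r_low <- flare_risk(f, coh, "a", 26, future_dose = 0.4)
  expect_gte(r_low, r_full)
  # boundary: 0.5 counts as low dose, 0.51 does not
  expect_gt(flare_risk(f, coh, "a", 26, future_dose = 0.5), r_full)
  expect_equal(flare_risk(f, coh, "a", 26, future_dose = 0.51), r_full,
               tolerance = 1e-12)
})

test_that("landmark predictions carry the outcome labels the follow-up supports", {
  p <- toy_params(G = 1, q = 1, rho = 0.4)
  f <- fake_fit(p)
  coh <- make_cohort(list(
    list(id = "flare10", week = c(0, 5), das28 = c(2.5, 2.6),
         event = 10, censor = 20),
    list(id = "cens8", week = 0, das28 = 2.5, censor = 8),
    list(id = "clean", week = c(0, 20, 40), das28 = c(2.5, 2.6, 2.4),
         censor = 60)))
  pr <- predict(f, coh)
  expect_equal(pr$label[pr$course_id == "flare10" & pr$landmark_week == 0],
               "flare")   # flare at week 10 inside (0, 13]
  expect_equal(pr$label[pr$course_id == "cens8"], "indeterminate")
  expect_equal(pr$label[pr$course_id == "clean" & pr$landmark_week == 20],
               "no-flare")
  # no predictions at or after the first flare, none at censoring
  expect_true(all(pr$landmark_week[pr$course_id == "flare10"] < 10))
  expect_false(any(pr$landmark_week[pr$course_id == "clean"] == 60))
  # baseline rows flagged and removable
  expect_true(all(pr$at_baseline == (pr$landmark_week == 0)))
  pr2 <- predict(f, coh, include_baseline = FALSE)
  expect_false(any(pr2$at_baseline))
})

test_that("prediction risks lie in [0, 1] across a simulated cohort", {
  fs <- cached("fit_small", {
    coh <- simulate_dev_cohort(n = 150, seed = 21)
    list(cohort = coh,
         fit = suppressWarnings(
           jlcm(coh, classes = 2, poly = 2,
                control = jlcm_control(starts = 2, maxit = 400), seed = 1)))
  })
  pr <- predict(fs$fit, fs$cohort)
  expect_true(all(pr$risk >= 0 & pr$risk <= 1))
  expect_true(all(pr$label %in% c("flare", "no-flare", "indeterminate")))
})
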