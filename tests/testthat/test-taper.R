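# Decision-rule simulator, cohort outcomes, comparative metrics, sweeps.

test_that("risk classification is exact at the boundary", {
  expect_equal(classify_risk(c(0.35, 0.349, 0), 0.35),
               c("high", "low", "low"))
  expect_true(all(classify_risk(runif(20), 0) == "high"))
})

# taper path helper: prescriptions at months 0..18
dgdo_dose <- c(2/3, 1/2, 0, 0, 0, 0, 0)

test_that("a flare before the first high-risk prediction leaves the course untouched", {
  tr <- make_trial(list(list(
    id = "r1", dose = c(2/3, 1/2, 1/2, 1/2, 1/2, 1/2, 1/2),
    flare = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),  # flare month 6
    risk = c(0, 0, 0, 0.9, 0, 0, 0))))                          # high month 9
  sim <- simulate_taper(tr, 0.35)
  expect_equal(sim$visits$sim_dose, tr$visits$dose_fraction)
  expect_equal(sim$visits$sim_flare, tr$visits$flare)
  expect_equal(sim$rules$rule, "follow")
})

test_that("the first high-risk prediction freezes the dose and suppresses later flares", {
  tr <- make_trial(list(list(
    id = "r2", dose = dgdo_dose,
    flare = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),  # month 12
    risk = c(0, 0.5, 0, 0, 0, 0, 0))))                          # high month 3
  sim <- simulate_taper(tr, 0.35)
  v <- sim$visits
  expect_equal(v$sim_dose, c(2/3, rep(1/2, 6)))  # frozen at the month-3 step
  expect_false(any(v$sim_flare))                 # month-12 flare (at dose 0) suppressed
  expect_equal(sim$rules$rule, "freeze")
})

test_that("a course already discontinued gets the 50% last-step dose", {
  tr <- make_trial(list(list(
    id = "r3", dose = dgdo_dose,
    risk = c(0, 0, 0, 0.9, 0, 0, 0))))           # high month 9, dose 0
  sim <- simulate_taper(tr, 0.35)
  v <- sim$visits
  expect_equal(v$sim_dose, c(2/3, 1/2, 0, rep(0.5, 4)))
  expect_equal(sim$rules$rule, "half")
})

test_that("a later flare at a dose at least the frozen dose is copied, then the course follows the trial", {
  tr <- make_trial(list(list(
    id = "r4",
    dose = c(2/3, 1/2, 0, 0, 1/2, 1/2, 1/2),
    # flare at month 12 arose at the in-force dose 0 (prescribed month 9):
    # below the frozen 1/2, so NOT copied; the month-15 flare arose at 1/2
    # (prescribed month 12 after reinstatement): copied, then follow trial
    flare = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    risk = c(0, 0.5, 0, 0, 0, 0, 0))))
  sim <- simulate_taper(tr, 0.35)
  v <- sim$visits
  expect_equal(v$sim_flare, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(v$sim_dose, c(2/3, rep(1/2, 3), 1/2, 1/2, 1/2))
  expect_equal(sim$rules$rule, "copy")
})

test_that("a high-risk baseline prediction freezes at the pre-taper full dose", {
  tr <- make_trial(list(list(id = "b", dose = dgdo_dose,
                             risk = c(0.5, 0, 0, 0, 0, 0, 0))))
  sim <- simulate_taper(tr, 0.35)
  expect_true(all(sim$visits$sim_dose == 1))
  # and ignoring baseline predictions restores the trial course
  sim2 <- simulate_taper(tr, 0.35, use_baseline = FALSE)
  expect_equal(sim2$visits$sim_dose, tr$visits$dose_fraction)
})

test_that("simulator invariants hold on randomly generated trial courses", {
  dev <- cached("fit_small", {
    coh <- simulate_dev_cohort(n = 150, seed = 21)
    list(cohort = coh,
         fit = suppressWarnings(
           jlcm(coh, classes = 2, poly = 2,
                control = jlcm_control(starts = 2, maxit = 400), seed = 1)))
  })
  tr <- simulate_trial_cohort(150, 0, seed = 33)
  tr <- add_risk_predictions(tr, dev$fit)
  for (ct in c(0.15, 0.35)) {
    sim <- simulate_taper(tr, ct)
    v <- sim$visits
    expect_true(all(v$sim_dose >= v$dose_fraction - 1e-9))
    expect_false(any(v$sim_flare & !v$flare))
    per <- tapply(v$sim_flare, v$course_id, sum) -
      tapply(v$flare, v$course_id, sum)
    expect_true(all(per <= 0))
  }
})

test_that("cohort outcomes reproduce direct arithmetic", {
  tr <- make_trial(list(
    list(id = "a", dose = rep(1, 7),
         flare = c(FALSE, TRUE, rep(FALSE, 5))),
    list(id = "b", dose = rep(0.5, 7))))
  o <- taper_outcomes(tr, arm = "dgdo", B = 0)
  expect_equal(o$mean_flares, 0.5)
  expect_equal(o$prop_flaring, 0.5)
  expect_equal(o$mean_dose, 0.75)
  # time weighting: 1.0 for 9 months then 0.5 for 9 months
  tw <- make_trial(list(list(id = "c", dose = c(1, 1, 1, 0.5, 0.5, 0.5, 0.5))))
  expect_equal(taper_outcomes(tw, arm = "dgdo", B = 0)$mean_dose, 0.75)
  # identical courses give zero-width bootstrap intervals
  same <- make_trial(list(list(id = "s1", dose = rep(1, 7)),
                          list(id = "s2", dose = rep(1, 7))))
  os <- taper_outcomes(same, arm = "dgdo", B = 25, seed = 4)
  expect_equal(os$ci[1, "mean_dose"], os$ci[2, "mean_dose"])
})

test_that("comparative metrics reproduce ratio arithmetic and swap-invariance", {
  a <- c(flares = 0.5, dose = 0.9); b <- c(flares = 1.5, dose = 0.4)
  m <- comparative_metrics(a, b)
  expect_equal(m$dose_per_flare_prevented, 0.5)
  expect_equal(m$flares_per_dose_saved, 2)
  m2 <- comparative_metrics(b, a)
  expect_equal(m2$dose_per_flare_prevented, m$dose_per_flare_prevented)
  expect_equal(m2$flares_per_dose_saved, m$flares_per_dose_saved)
  same <- comparative_metrics(a, a)
  expect_true(same$undefined)
  expect_true(is.na(same$dose_per_flare_prevented))
})

test_that("an unreachable cutoff reproduces the observed arm; lowering it never adds flares", {
  tr <- make_trial(list(
    list(id = "a", dose = dgdo_dose,
         flare = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
         risk = c(0.1, 0.2, 0.4, 0.1, 0.1, 0.1, 0.1)),
    list(id = "b", dose = dgdo_dose,
         risk = c(0.05, 0.15, 0.25, 0.3, 0.1, 0.1, 0.1))))
  never <- simulate_taper(tr, 1.01)
  expect_equal(never$visits$sim_dose, tr$visits$dose_fraction)
  expect_equal(never$visits$sim_flare, as.logical(tr$visits$flare))
  sw <- cutoff_sweep(tr, cutoffs = c(0.45, 0.35, 0.25, 0.15, 0.05))
  expect_true(all(diff(sw$mean_flares) <= 1e-12))  # ordered high -> low cutoff
  expect_true(all(diff(sw$mean_dose) >= -1e-12))
})
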