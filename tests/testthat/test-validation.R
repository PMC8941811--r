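# Discrimination, cutoff selection, classification performance,
# calibration, cross-validation plumbing.

pred_frame <- function(risk, label, patient = seq_along(risk)) {
  structure(data.frame(course_id = paste0("c", seq_along(risk)),
                       patient_id = paste0("p", patient),
                       landmark_week = 0, horizon_weeks = 13,
                       risk = risk, label = label, at_baseline = FALSE,
                       stringsAsFactors = FALSE),
            class = c("flare_predictions", "data.frame"))
}

brute_auc <- function(risk, label) {
  pos <- risk[label == "flare"]; neg <- risk[label == "no-flare"]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

brute_youden <- function(risk, label) {
  cand <- sort(unique(risk)); best <- -Inf; arg <- cand[1]
  for (ct in cand) {
    J <- mean(risk[label == "flare"] >= ct) +
      mean(risk[label == "no-flare"] < ct) - 1
    if (J > best + 1e-12) { best <- J; arg <- ct }
  }
  arg
}

test_that("AUC handles separation, ties, and degenerate label sets", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.1, 0.2), c("flare", "flare", "no-flare", "no-flare")), 1)
  expect_equal(auc_roc(rep(0.3, 6), rep(c("flare", "no-flare"), 3)), 0.5)
  r <- c(0.2, 0.2, 0.5, 0.5, 0.7, 0.1)
  l <- c("flare", "no-flare", "flare", "no-flare", "flare", "no-flare")
  expect_equal(auc_roc(r, l), brute_auc(r, l))
  expect_error(auc_roc(c(0.1, 0.2), c("flare", "flare")), "undefined AUC")
})

test_that("AUC and Youden cutoff match brute force on random instances", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    risk <- round(runif(n), sample(c(1, 2, 3), 1))  # force ties
    label <- ifelse(runif(n) < plogis(4 * risk - 2), "flare", "no-flare")
    if (length(unique(label)) < 2) next
    expect_equal(auc_roc(risk, label), brute_auc(risk, label))
    expect_equal(youden_cutoff(risk, label), brute_youden(risk, label))
  }
})

test_that("Youden cutoff honours its tie-breaking conventions", {
  # perfectly separated: the lowest flare-labelled risk attains J = 1
  r <- c(0.1, 0.2, 0.6, 0.9); l <- c("no-flare", "no-flare", "flare", "flare")
  expect_equal(youden_cutoff(r, l), 0.6)
  # all risks identical: J = 0 everywhere, the common value is returned
  expect_equal(youden_cutoff(rep(0.4, 4), c("flare", "no-flare", "flare", "no-flare")),
               0.4)
})

test_that("performance table reproduces direct 2x2 arithmetic", {
  # TP = 3, FP = 1, FN = 1, TN = 5 at cutoff 0.5
  risk <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.1, 0.2, 0.3, 0.35, 0.05)
  label <- c("flare", "flare", "flare", "no-flare", "flare",
             rep("no-flare", 5))
  perf <- performance_at_cutoff(pred_frame(risk, label), 0.5, B = 50, seed = 1)
  expect_equal(unname(perf$estimate["sensitivity"]), 0.75)
  expect_equal(unname(perf$estimate["specificity"]), 5 / 6)
  expect_equal(unname(perf$estimate["ppv"]), 0.75)
  expect_equal(unname(perf$estimate["npv"]), 5 / 6)
  expect_equal(unname(perf$estimate["accuracy"]), 0.8)
  expect_true(all(perf$ci_lower <= perf$estimate + 1e-12, na.rm = TRUE))
  expect_true(all(perf$ci_upper >= perf$estimate - 1e-12, na.rm = TRUE))
  # cutoff below every risk: everything called positive
  p0 <- performance_at_cutoff(pred_frame(risk, label), 0, B = 0)
  expect_equal(unname(p0$estimate["sensitivity"]), 1)
  expect_equal(unname(p0$estimate["specificity"]), 0)
})

test_that("bootstrap over identical patients is degenerate", {
  risk <- rep(c(0.8, 0.2), 10); label <- rep(c("flare", "no-flare"), 10)
  perf <- performance_at_cutoff(pred_frame(risk, label, patient = rep(1, 20)),
                                0.5, B = 30, seed = 2)
  expect_equal(unname(perf$ci_lower["sensitivity"]),
               unname(perf$ci_upper["sensitivity"]))
})

test_that("calibration groups by risk quartile and flags degenerate input", {
  risk <- (1:8) / 10
  label <- c(rep("no-flare", 5), rep("flare", 3))
  cal <- calibration(pred_frame(risk, label))
  expect_equal(cal$n, rep(2, 4))
  expect_equal(sum(cal$n), 8)
  expect_true(all(diff(cal$mean_predicted) > 0))
  expect_false(attr(cal, "degenerate"))
  cal2 <- calibration(pred_frame(rep(0.3, 6), rep(c("flare", "no-flare"), 3)))
  expect_true(attr(cal2, "degenerate"))
  expect_equal(nrow(cal2), 1L)
})

test_that("cross-validation predicts every course exactly once, folds split by patient", {
  coh <- simulate_dev_cohort(n = 60, seed = 31)
  # give some patients two courses
  coh$courses$patient_id[1:10] <- coh$courses$patient_id[11:20]
  coh$covariates$patient_id <- coh$courses$patient_id
  map <- setNames(coh$courses$patient_id, coh$courses$course_id)
  coh$visits$patient_id <- unname(map[coh$visits$course_id])
  cv <- suppressWarnings(
    jlcm_cv(coh, classes = 1, poly = 1, k = 3,
            control = jlcm_control(starts = 1, maxit = 150), seed = 2))
  per_course_folds <- tapply(cv$fold, cv$course_id, function(x) length(unique(x)))
  expect_true(all(per_course_folds == 1))
  # courses sharing a patient land in the same fold
  fold_of <- tapply(cv$fold, cv$course_id, unique)
  pat_of <- map[names(fold_of)]
  expect_true(all(tapply(unlist(fold_of), pat_of,
                         function(x) length(unique(x))) == 1))
  # most courses produce at least one prediction
  expect_gt(length(unique(cv$course_id)), 45)
})
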