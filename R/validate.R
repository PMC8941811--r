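# Discrimination, cutoff selection, classification performance, calibration
# and patient-level cross-validation for the landmark flare predictions.
# Indeterminate outcome labels are excluded from all metrics.

drop_indeterminate <- function(predictions) {
  predictions[predictions$label %in% c("flare", "no-flare"), , drop = FALSE]
}

#' Area under the ROC curve, pooled over all landmarks
#'
#' Mann-Whitney form: the probability that a randomly chosen flare-labelled
#' prediction carries a higher risk than a randomly chosen no-flare one,
#' ties counted one half.
#'
#' @param risk numeric risks, or a `flare_predictions` data frame.
#' @param label `"flare"`/`"no-flare"` labels (ignored when `risk` is a
#'   predictions frame).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(risk, label = NULL) {
  if (is.data.frame(risk)) {
    p <- drop_indeterminate(risk); label <- p$label; risk <- p$risk
  }
  pos <- label == "flare"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("undefined AUC: need at least one flare and one no-flare label")
  r <- rank(risk)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimal classification cutoff by Youden's index
#'
#' Scans the observed risk values as candidate cutoffs for the rule
#' `risk >= cutoff` and returns the one maximising
#' sensitivity + specificity - 1; ties are broken toward the lower cutoff.
#'
#' @inheritParams auc_roc
#' @export
youden_cutoff <- function(risk, label = NULL) {
  if (is.data.frame(risk)) {
    p <- drop_indeterminate(risk); label <- p$label; risk <- p$risk
  }
  pos <- label == "flare"
  if (!any(pos) || all(pos)) stop("both labels needed for a cutoff")
  cand <- sort(unique(risk))
  J <- vapply(cand, function(cut) {
    mean(risk[pos] >= cut) + mean(risk[!pos] < cut) - 1
  }, 0)
  # ties (within float noise) break toward the lower cutoff
  cand[which(J >= max(J) - 1e-9)[1L]]
}

#' Classification performance at a fixed cutoff
#'
#' Builds the 2x2 table of `risk >= cutoff` against the observed labels and
#' reports sensitivity, specificity, predictive values and accuracy with
#' patient-level percentile bootstrap confidence intervals.
#'
#' @param predictions a `flare_predictions` data frame.
#' @param cutoff classification threshold (rule: `risk >= cutoff`).
#' @param B bootstrap replicates (patients resampled with replacement).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return Object of class `performance_table`.
#' @export
performance_at_cutoff <- function(predictions, cutoff, B = 1000,
                                  conf = 0.95, seed = 1) {
  p <- drop_indeterminate(predictions)
  stats_fun <- function(d) {
    pred_pos <- d$risk >= cutoff
    obs_pos <- d$label == "flare"
    tp <- sum(pred_pos & obs_pos); fp <- sum(pred_pos & !obs_pos)
    fn <- sum(!pred_pos & obs_pos); tn <- sum(!pred_pos & !obs_pos)
    c(auc = tryCatch(auc_roc(d$risk, d$label), error = function(e) NA_real_),
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
      accuracy = (tp + tn) / nrow(d))
  }
  est <- stats_fun(p)
  pid <- if ("patient_id" %in% names(p)) p$patient_id else p$course_id
  pats <- unique(pid)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  boot <- t(vapply(seq_len(B), function(b) {
    take <- sample(pats, length(pats), replace = TRUE)
    d <- do.call(rbind, lapply(take, function(id) p[pid == id, , drop = FALSE]))
    stats_fun(d)
  }, est))
  a <- (1 - conf) / 2
  ci <- apply(boot, 2L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  structure(list(estimate = est, ci_lower = ci[1L, ], ci_upper = ci[2L, ],
                 cutoff = cutoff, B = B, n = nrow(p),
                 ppv_undefined = is.na(est["ppv"])),
            class = "performance_table")
}

#' @export
print.performance_table <- function(x, ...) {
  cat(sprintf("Performance at cutoff %.3f (n = %d predictions, %d bootstrap reps)\n",
              x$cutoff, x$n, x$B))
  tab <- data.frame(estimate = round(x$estimate, 3),
                    lower = round(x$ci_lower, 3),
                    upper = round(x$ci_upper, 3))
  print(tab)
  if (isTRUE(x$ppv_undefined))
    cat("note: no predicted positives; PPV undefined\n")
  invisible(x)
}

#' Calibration by quartile of predicted risk
#'
#' Groups predictions into four bins bounded by the 25th, 50th and 75th
#' percentiles of predicted risk and compares the mean predicted risk with
#' the observed flare frequency per bin.
#'
#' @param predictions a `flare_predictions` data frame.
#' @return Object of class `calibration_groups`: a data frame with one row
#'   per group (`n`, `mean_predicted`, `observed_frequency`) plus a
#'   `degenerate` attribute flagging an all-identical risk vector.
#' @export
calibration <- function(predictions) {
  p <- drop_indeterminate(predictions)
  if (nrow(p) < 4L) stop("need at least 4 labelled predictions")
  qs <- stats::quantile(p$risk, c(0.25, 0.5, 0.75))
  degenerate <- length(unique(p$risk)) == 1L
  breaks <- unique(c(-Inf, qs, Inf))
  grp <- cut(p$risk, breaks = breaks, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    d <- p[grp == g, ]
    data.frame(group = g, n = nrow(d), mean_predicted = mean(d$risk),
               observed_frequency = mean(d$label == "flare"))
  }))
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  class(out) <- c("calibration_groups", "data.frame")
  out
}

#' Patient-level k-fold cross-validated landmark predictions
#'
#' Partitions patients (not courses) into `k` seeded folds, stratified by
#' whether any of the patient's courses flared; fits the model on the
#' remaining folds and predicts the held-out patients' visits; returns the
#' pooled out-of-fold predictions.
#'
#' @inheritParams jlcm
#' @param k number of folds.
#' @param horizon_weeks,include_baseline passed to [predict.jlcm()].
#' @return A `flare_predictions` data frame with an extra `fold` column.
#' @export
jlcm_cv <- function(cohort, classes = 2, poly = 2, k = 5,
                    control = jlcm_control(), seed = 1,
                    horizon_weeks = 13, include_baseline = TRUE) {
  stopifnot(inherits(cohort, "flare_cohort"))
  pats <- unique(cohort$courses$patient_id)
  if (length(pats) < k) stop("need at least k patients")
  flared <- vapply(pats, function(pid) {
    any(!is.na(cohort$courses$first_flare_week[
      cohort$courses$patient_id == pid]))
  }, TRUE)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fold <- integer(length(pats))
  for (str in c(TRUE, FALSE)) {
    idx <- which(flared == str)
    if (length(idx)) fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  out <- lapply(seq_len(k), function(f) {
    test_p <- pats[fold == f]
    train_ids <- cohort$courses$course_id[!cohort$courses$patient_id %in% test_p]
    test_ids <- cohort$courses$course_id[cohort$courses$patient_id %in% test_p]
    fit <- tryCatch(
      suppressWarnings(jlcm(subset_cohort(cohort, train_ids),
                            classes = classes, poly = poly,
                            control = control, seed = seed + f)),
      error = function(e) stop("cross-validation fit failed in fold ", f,
                               ": ", conditionMessage(e)))
    pr <- predict(fit, subset_cohort(cohort, test_ids),
                  horizon_weeks = horizon_weeks,
                  include_baseline = include_baseline)
    if (!is.null(pr) && nrow(pr)) pr$fold <- f
    pr
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("flare_predictions", "data.frame")
  out
}
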