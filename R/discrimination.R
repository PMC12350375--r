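# Score-comparison statistics: AUROC, the DeLong paired test, logistic
# risk calibration, continuous NRI, IDI, bootstrap percentile intervals,
# and Youden-index operating points.

.check_binary_labels <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) stop("labels must not contain NA", call. = FALSE)
  if (!any(labels) || all(labels)) {
    stop("labels must contain at least one event and one nonevent",
         call. = FALSE)
  }
  labels
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: over all (event, nonevent) pairs, the fraction
#' with the event scored higher, counting ties as one half.  Computed from
#' midranks in O(N log N).
#'
#' @param scores Numeric predictor (higher = more likely event).
#' @param labels Binary outcome (logical or 0/1); both classes required.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- .check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  r <- rank(scores, ties.method = "average")
  m <- sum(labels)
  n <- sum(!labels)
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

# Placement values (structural components) for one score vector:
# V10[i] = fraction of nonevents scored below event i (ties half),
# V01[j] = fraction of events scored above nonevent j (ties half).
# Midrank identity: V10_i = (R_i - RX_i)/n, V01_j = 1 - (R_j - RY_j)/m,
# with R the combined midranks and RX/RY the within-class midranks.
.placements <- function(scores, labels) {
  m <- sum(labels)
  n <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  rx <- rank(scores[labels], ties.method = "average")
  ry <- rank(scores[!labels], ties.method = "average")
  list(v10 = (r[labels] - rx) / n,
       v01 = 1 - (r[!labels] - ry) / m,
       m = m, n = n)
}

#' DeLong variance of a single AUROC
#'
#' @inheritParams auroc
#' @return Estimated variance of the AUROC estimate.
#' @export
auroc_variance <- function(scores, labels) {
  labels <- .check_binary_labels(labels)
  p <- .placements(scores, labels)
  var(p$v10) / p$m + var(p$v01) / p$n
}

#' DeLong paired comparison of two correlated AUROCs
#'
#' Computes placement values for each score on the same patients, the
#' structural-component variance/covariance estimates, and the two-sided
#' normal test of equal AUROCs.  When the variance of the AUROC difference
#' is numerically zero the comparison is degenerate: a zero AUROC
#' difference yields `z = 0, p = 1`; a nonzero difference with zero
#' variance is an error.
#'
#' @param scores_new,scores_old Numeric score vectors aligned with
#'   `labels`.
#' @param labels Binary outcome; at least 2 events and 2 nonevents.
#' @param conf Confidence level for the per-score Wald intervals.
#' @return A list of class `roc_comparison`: `auc_new`, `auc_old`,
#'   `var_new`, `var_old`, `cov`, `z`, `p`, `ci_new`, `ci_old`.
#' @export
delong_compare <- function(scores_new, scores_old, labels, conf = 0.95) {
  labels <- .check_binary_labels(labels)
  stopifnot(length(scores_new) == length(labels),
            length(scores_old) == length(labels))
  if (sum(labels) < 2 || sum(!labels) < 2) {
    stop("need at least 2 events and 2 nonevents", call. = FALSE)
  }
  pn <- .placements(scores_new, labels)
  po <- .placements(scores_old, labels)
  auc_new <- mean(pn$v10)
  auc_old <- mean(po$v10)
  var_new <- var(pn$v10) / pn$m + var(pn$v01) / pn$n
  var_old <- var(po$v10) / po$m + var(po$v01) / po$n
  cv <- cov(pn$v10, po$v10) / pn$m + cov(pn$v01, po$v01) / pn$n
  vdiff <- var_new + var_old - 2 * cv
  if (vdiff <= .Machine$double.eps^0.5 * max(1, var_new + var_old)) {
    if (abs(auc_new - auc_old) < 1e-12) {
      z <- 0
      p <- 1
    } else {
      stop("degenerate DeLong comparison: zero variance of the AUROC difference with unequal AUROCs",
           call. = FALSE)
    }
  } else {
    z <- (auc_new - auc_old) / sqrt(vdiff)
    p <- 2 * pnorm(-abs(z))
  }
  zq <- qnorm(1 - (1 - conf) / 2)
  structure(list(
    auc_new = auc_new, auc_old = auc_old,
    var_new = var_new, var_old = var_old, cov = cv,
    z = z, p = p,
    ci_new = pmin(1, pmax(0, auc_new + c(-1, 1) * zq * sqrt(var_new))),
    ci_old = pmin(1, pmax(0, auc_old + c(-1, 1) * zq * sqrt(var_old)))
  ), class = "roc_comparison")
}

#' Calibrate a severity score to predicted risks
#'
#' Univariate logistic regression of the outcome on the score, fitted by
#' maximum likelihood.  NRI and IDI operate on these calibrated risks
#' rather than on the raw scores: when one score dominates the other
#' pointwise (the combined score is never below its parent), raw-score
#' up/down movement is degenerate.
#'
#' @inheritParams auroc
#' @return A list: `intercept`, `slope`, and `risk` (per-patient fitted
#'   probabilities).
#' @export
fit_score_risk <- function(scores, labels) {
  labels <- .check_binary_labels(labels)
  if (length(unique(scores)) < 2) {
    stop("scores must take at least 2 distinct values", call. = FALSE)
  }
  fit <- suppressWarnings(glm(labels ~ scores, family = binomial()))
  b <- coef(fit)
  fitted_p <- fit$fitted.values
  sep <- !fit$converged || abs(b[2]) > 20 ||
    all(fitted_p[labels] > 1 - 1e-8) && all(fitted_p[!labels] < 1e-8)
  if (sep) {
    stop("complete separation in logistic calibration; collapse score categories",
         call. = FALSE)
  }
  list(intercept = unname(b[1]), slope = unname(b[2]),
       risk = unname(fitted_p))
}

#' Continuous net reclassification improvement
#'
#' A patient moves "up" when the new risk exceeds the old, "down" when it
#' is lower; ties move neither way.  The event component is
#' `P(up | event) - P(down | event)`, the nonevent component
#' `P(down | nonevent) - P(up | nonevent)`; the NRI is their sum
#' (range -2..2).
#'
#' @param risk_old,risk_new Predicted risks under the old and new model.
#' @param labels Binary outcome; both classes required.
#' @return A list: `nri`, `nri_events`, `nri_nonevents`.
#' @export
continuous_nri <- function(risk_old, risk_new, labels) {
  labels <- .check_binary_labels(labels)
  stopifnot(length(risk_old) == length(labels),
            length(risk_new) == length(labels))
  up <- risk_new > risk_old
  down <- risk_new < risk_old
  nri_events <- mean(up[labels]) - mean(down[labels])
  nri_nonevents <- mean(down[!labels]) - mean(up[!labels])
  list(nri = nri_events + nri_nonevents,
       nri_events = nri_events, nri_nonevents = nri_nonevents)
}

#' Integrated discrimination improvement
#'
#' The change in discrimination slope: `[mean risk in events - mean risk
#' in nonevents]` under the new model minus the same quantity under the
#' old.
#'
#' @inheritParams continuous_nri
#' @return IDI (numeric scalar in -1..1).
#' @export
idi <- function(risk_old, risk_new, labels) {
  labels <- .check_binary_labels(labels)
  stopifnot(length(risk_old) == length(labels),
            length(risk_new) == length(labels))
  slope_new <- mean(risk_new[labels]) - mean(risk_new[!labels])
  slope_old <- mean(risk_old[labels]) - mean(risk_old[!labels])
  slope_new - slope_old
}

#' Bootstrap percentile confidence interval
#'
#' Patient-level resampling with replacement; the interval is the 2.5/97.5
#' percentile of the replicate statistics (for `conf = 0.95`).  If
#' `labels` is supplied, resamples containing a single outcome class are
#' redrawn (and counted); replicates on which the statistic fails are
#' dropped, and more than 10% failures is an error.
#'
#' @param data A data frame (resampled by row) or vector.
#' @param statistic Function of the resampled `data` returning a scalar.
#' @param b Number of replicates (>= 100; study default 1000).
#' @param seed Integer seed; required for a reproducible interval.
#' @param labels Optional binary outcome aligned with `data`, used to
#'   redraw single-class resamples.
#' @param conf Confidence level.
#' @return A list: `lower`, `upper`, `b` (replicates used), `redrawn`,
#'   `failed`.
#' @export
bootstrap_ci <- function(data, statistic, b = 1000, seed = NULL,
                         labels = NULL, conf = 0.95) {
  if (b < 100) stop("b must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- function(idx) {
    if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
  }
  stats_out <- numeric(b)
  redrawn <- 0L
  failed <- 0L
  for (i in seq_len(b)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (is.null(labels)) break
      cls <- labels[idx]
      if (any(cls) && !all(cls)) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * b) {
        stop("could not draw two-class resamples", call. = FALSE)
      }
    }
    val <- tryCatch(statistic(take(idx)), error = function(e) NA_real_)
    if (is.na(val)) failed <- failed + 1L
    stats_out[i] <- val
  }
  if (failed > 0.1 * b) {
    stop(sprintf("statistic failed on %d of %d resamples", failed, b),
         call. = FALSE)
  }
  qs <- quantile(stats_out, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 na.rm = TRUE, names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], b = b, redrawn = redrawn,
       failed = failed)
}

#' Compare two scores with reclassification indices
#'
#' Convenience wrapper: calibrates each score with [fit_score_risk()],
#' computes the continuous NRI and IDI, and bootstrap percentile intervals
#' for both (recalibrating inside every resample).
#'
#' @inheritParams delong_compare
#' @param b Bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `reclassification_result`: `nri`, `nri_events`,
#'   `nri_nonevents`, `idi`, `ci_nri`, `ci_idi`, `b_replicates`.
#' @export
reclassification <- function(scores_new, scores_old, labels, b = 1000,
                             seed = NULL) {
  labels <- .check_binary_labels(labels)
  risk_new <- fit_score_risk(scores_new, labels)$risk
  risk_old <- fit_score_risk(scores_old, labels)$risk
  nri_pt <- continuous_nri(risk_old, risk_new, labels)
  idi_pt <- idi(risk_old, risk_new, labels)
  dat <- data.frame(new = scores_new, old = scores_old, y = labels)
  stat_nri <- function(d) {
    rn <- fit_score_risk(d$new, d$y)$risk
    ro <- fit_score_risk(d$old, d$y)$risk
    continuous_nri(ro, rn, d$y)$nri
  }
  stat_idi <- function(d) {
    rn <- fit_score_risk(d$new, d$y)$risk
    ro <- fit_score_risk(d$old, d$y)$risk
    idi(ro, rn, d$y)
  }
  ci_nri <- bootstrap_ci(dat, stat_nri, b = b, seed = seed,
                         labels = labels)
  ci_idi <- bootstrap_ci(dat, stat_idi, b = b,
                         seed = if (is.null(seed)) NULL else seed + 1L,
                         labels = labels)
  structure(list(
    nri = nri_pt$nri, nri_events = nri_pt$nri_events,
    nri_nonevents = nri_pt$nri_nonevents, idi = idi_pt,
    ci_nri = c(ci_nri$lower, ci_nri$upper),
    ci_idi = c(ci_idi$lower, ci_idi$upper),
    b_replicates = b
  ), class = "reclassification_result")
}

#' Operating point of a score
#'
#' Scans the observed score values as candidate thresholds (predicted
#' positive when `score >= threshold`), selects the one maximising
#' Youden's J (`sensitivity + specificity - 1`; ties broken by the lowest
#' threshold), and reports the 2x2-table metrics at that cut.
#'
#' @inheritParams auroc
#' @param criterion Threshold selection rule; only `"youden"` is
#'   implemented.
#' @return A list of class `operating_point`: `threshold`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `plr`, `nlr` (likelihood ratios are
#'   `NA` when their denominator is zero).
#' @export
operating_point <- function(scores, labels, criterion = "youden") {
  labels <- .check_binary_labels(labels)
  criterion <- match.arg(criterion, "youden")
  thresholds <- sort(unique(scores))
  m <- sum(labels)
  n <- sum(!labels)
  sens <- vapply(thresholds, function(t) sum(labels & scores >= t) / m,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(!labels & scores < t) / n,
                 numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]
  t <- thresholds[best]
  tp <- sum(labels & scores >= t)
  fp <- sum(!labels & scores >= t)
  fn <- m - tp
  tn <- n - fp
  se <- sens[best]
  sp <- spec[best]
  structure(list(
    threshold = t,
    sensitivity = se, specificity = sp,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    plr = if (sp < 1) se / (1 - sp) else NA_real_,
    nlr = if (sp > 0) (1 - se) / sp else NA_real_
  ), class = "operating_point")
}
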