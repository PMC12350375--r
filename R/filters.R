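# Cohort exclusion cascade with attrition logging.
#
# Rules are applied sequentially, in the fixed study order; the Tukey
# fences for ALC outliers are computed on the patients remaining after the
# earlier exclusions, so the cascade is order-sensitive by design and the
# log records every step.

#' Tukey's fences
#'
#' Outlier bounds `Q1 - k*IQR` and `Q3 + k*IQR`, with the quartiles
#' computed by linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param values Numeric vector, at least 4 finite values.
#' @param k Fence multiplier (default 1.5).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
tukey_fences <- function(values, k = 1.5) {
  if (any(!is.finite(values))) {
    stop("tukey_fences: values must all be finite", call. = FALSE)
  }
  if (length(values) < 4) {
    stop("tukey_fences: need at least 4 values", call. = FALSE)
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

.exclusion_rules <- c(
  "repeat_admission",
  "missing_28d_status",
  "under_18",
  "icu_stay_le_24h",
  "missing_alc",
  "alc_outlier"
)

#' Apply the cohort exclusion cascade
#'
#' Sequentially excludes: (1) repeat hospital admissions; (2) patients
#' whose 28-day survival status is undeterminable (neither death within 28
#' days nor follow-up reaching 28 days); (3) age under 18; (4) ICU stay of
#' 24 hours or less; (5) missing first-day ALC; (6) ALC outside Tukey's
#' fences, with the fences computed on the ALC values of the patients
#' surviving steps 1-5.  Missing values never trigger an exclusion except
#' through their own dedicated rule.
#'
#' @param cohort A cohort data frame.
#' @param tukey_k Fence multiplier passed to [tukey_fences()].
#' @return A list with `cohort` (the kept records), `attrition` (a data
#'   frame with columns `rule`, `n_excluded`, `n_remaining`, one row per
#'   rule in application order), and `fences` (the ALC fences used, or
#'   `NULL` if fewer than 4 ALC values remained).
#' @export
apply_exclusions <- function(cohort, tukey_k = 1.5) {
  validate_cohort(cohort)
  kept <- cohort
  log <- data.frame(rule = character(0), n_excluded = integer(0),
                    n_remaining = integer(0), stringsAsFactors = FALSE)
  drop_step <- function(kept, rule, drop) {
    drop[is.na(drop)] <- FALSE
    list(kept = kept[!drop, , drop = FALSE], n = sum(drop))
  }
  fences <- NULL
  for (rule in .exclusion_rules) {
    drop <- switch(rule,
      repeat_admission = kept$repeat_admission,
      missing_28d_status = is.na(horizon_label(kept$time_days, kept$event, 28)),
      under_18 = kept$age < 18,
      icu_stay_le_24h = kept$icu_los_hours <= 24,
      missing_alc = is.na(kept$alc),
      alc_outlier = {
        if (sum(is.finite(kept$alc)) >= 4) {
          fences <- tukey_fences(kept$alc, k = tukey_k)
          kept$alc < fences["lower"] | kept$alc > fences["upper"]
        } else {
          rep(FALSE, nrow(kept))
        }
      }
    )
    step <- drop_step(kept, rule, drop)
    kept <- step$kept
    log <- rbind(log, data.frame(rule = rule, n_excluded = step$n,
                                 n_remaining = nrow(kept),
                                 stringsAsFactors = FALSE))
  }
  rownames(kept) <- NULL
  list(cohort = kept, attrition = log, fences = fences)
}

#' Audit a filtered cohort against the exclusion rules
#'
#' Post-hoc check that no kept record violates any exclusion rule (the
#' ALC-outlier rule is checked against the fences recorded by
#' [apply_exclusions()]).
#'
#' @param filtered The list returned by [apply_exclusions()].
#' @return `TRUE` if clean, otherwise an error naming the violated rule.
#' @export
audit_exclusions <- function(filtered) {
  k <- filtered$cohort
  viol <- c(
    repeat_admission = any(k$repeat_admission, na.rm = TRUE),
    missing_28d_status = any(is.na(horizon_label(k$time_days, k$event, 28))),
    under_18 = any(k$age < 18, na.rm = TRUE),
    icu_stay_le_24h = any(k$icu_los_hours <= 24, na.rm = TRUE),
    missing_alc = any(is.na(k$alc)),
    alc_outlier = !is.null(filtered$fences) && nrow(k) > 0 &&
      any(k$alc < filtered$fences["lower"] | k$alc > filtered$fences["upper"])
  )
  if (any(viol)) {
    stop("kept records violate rule(s): ",
         paste(names(viol)[viol], collapse = ", "), call. = FALSE)
  }
  TRUE
}
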