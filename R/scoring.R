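# SOFA component scorers, the ALC bin score, and the combined ALC-SOFA total.
#
# All scorers are vectorised over patients.  Band edges follow the standard
# six-system grid with these closures where the printed bands leave gaps:
#   - bilirubin / creatinine bands are right-open on the worst axis
#     ([1.2, 2.0) -> 1, ..., >= 12.0 -> 4 for bilirubin);
#   - dopamine exactly 5.0 ug/kg/min scores 2;
#   - PaO2/FiO2 < 200 without respiratory support caps at 2 (scores 3-4
#     require support);
#   - ALC exactly 1.0 x10^9/L scores 0 (lymphopenia is strictly below 1.0).
# Missing non-ALC inputs contribute 0 points and are flagged (configurable
# to strict mode); missing ALC is an error because it is an exclusion
# criterion, not a zero.

.check_nonneg <- function(x, what) {
  if (any(!is.na(x) & x < 0)) stop(what, " must be >= 0", call. = FALSE)
}

#' Respiratory SOFA component
#'
#' Scores the worst (lowest) first-day PaO2/FiO2 ratio.  Scores 3 and 4
#' additionally require respiratory support (mechanical ventilation);
#' without support a ratio below 200 caps at 2.
#'
#' @param pf_ratio PaO2/FiO2 in mmHg (> 0), `NA` if not measured.
#' @param respiratory_support Logical, respiratory support present.
#' @return Integer score 0-4 per patient (`NA` input scores 0).
#' @export
score_respiratory <- function(pf_ratio, respiratory_support) {
  if (any(!is.na(pf_ratio) & pf_ratio <= 0)) {
    stop("pf_ratio must be > 0", call. = FALSE)
  }
  support <- !is.na(respiratory_support) & respiratory_support
  s <- ifelse(is.na(pf_ratio), 0L,
       ifelse(pf_ratio >= 400, 0L,
       ifelse(pf_ratio >= 300, 1L,
       ifelse(pf_ratio >= 200, 2L,
       ifelse(!support, 2L,
       ifelse(pf_ratio >= 100, 3L, 4L))))))
  as.integer(s)
}

#' Coagulation SOFA component
#'
#' @param platelets Platelet count, x10^3/uL (worst = lowest), `NA` if not
#'   measured.
#' @return Integer score 0-4 (`NA` input scores 0).
#' @export
score_coagulation <- function(platelets) {
  .check_nonneg(platelets, "platelets")
  s <- ifelse(is.na(platelets), 0L,
       ifelse(platelets >= 150, 0L,
       ifelse(platelets >= 100, 1L,
       ifelse(platelets >= 50, 2L,
       ifelse(platelets >= 20, 3L, 4L)))))
  as.integer(s)
}

#' Hepatic SOFA component
#'
#' Bands are right-open: `[1.2, 2.0)` scores 1, `[2.0, 6.0)` scores 2,
#' `[6.0, 12.0)` scores 3, `>= 12.0` scores 4.
#'
#' @param bilirubin Total bilirubin, mg/dL (worst = highest), `NA` if not
#'   measured.
#' @return Integer score 0-4 (`NA` input scores 0).
#' @export
score_hepatic <- function(bilirubin) {
  .check_nonneg(bilirubin, "bilirubin")
  s <- ifelse(is.na(bilirubin), 0L,
       ifelse(bilirubin < 1.2, 0L,
       ifelse(bilirubin < 2.0, 1L,
       ifelse(bilirubin < 6.0, 2L,
       ifelse(bilirubin < 12.0, 3L, 4L)))))
  as.integer(s)
}

#' Cardiovascular SOFA component
#'
#' The highest applicable category wins.  Catecholamine doses are
#' ug/kg/min, counted only when administered for at least one hour; a
#' missing duration flag is treated as qualifying (permissive default,
#' flagged upstream).  Dopamine exactly 5.0 scores 2.
#'
#' @param map Mean arterial pressure, mmHg (worst = lowest), `NA` allowed.
#' @param dopamine,dobutamine,epinephrine,norepinephrine Max sustained dose
#'   over day 1 in ug/kg/min; 0 or `NA` if not given.
#' @param dopamine_ge_1h,dobutamine_ge_1h,epinephrine_ge_1h,norepinephrine_ge_1h
#'   Logical, agent given for >= 1 h (`NA` treated as `TRUE`).
#' @return Integer score 0-4.
#' @export
score_cardiovascular <- function(map, dopamine = 0, dobutamine = 0,
                                 epinephrine = 0, norepinephrine = 0,
                                 dopamine_ge_1h = NA, dobutamine_ge_1h = NA,
                                 epinephrine_ge_1h = NA,
                                 norepinephrine_ge_1h = NA) {
  for (d in list(dopamine, dobutamine, epinephrine, norepinephrine)) {
    .check_nonneg(d, "vasopressor dose")
  }
  .check_nonneg(map, "map")
  n <- max(length(map), length(dopamine), length(dobutamine),
           length(epinephrine), length(norepinephrine))
  qualify <- function(dose, flag) {
    dose <- rep_len(ifelse(is.na(dose), 0, dose), n)
    flag <- rep_len(flag, n)
    ifelse(is.na(flag) | flag, dose, 0)
  }
  dop <- qualify(dopamine, dopamine_ge_1h)
  dob <- qualify(dobutamine, dobutamine_ge_1h)
  epi <- qualify(epinephrine, epinephrine_ge_1h)
  nor <- qualify(norepinephrine, norepinephrine_ge_1h)
  map <- rep_len(map, n)
  s <- ifelse(dop > 15 | epi > 0.1 | nor > 0.1, 4L,
       ifelse(dop > 5 | epi > 0 | nor > 0, 3L,
       ifelse(dop > 0 | dob > 0, 2L,
       ifelse(!is.na(map) & map < 70, 1L, 0L))))
  as.integer(s)
}

#' Central nervous system SOFA component
#'
#' @param gcs Glasgow Coma Scale, integer 3-15 (worst = lowest), `NA` if
#'   not assessed.
#' @return Integer score 0-4 (`NA` input scores 0).
#' @export
score_cns <- function(gcs) {
  if (any(!is.na(gcs) & (gcs < 3 | gcs > 15))) {
    stop("gcs must be within 3..15", call. = FALSE)
  }
  s <- ifelse(is.na(gcs), 0L,
       ifelse(gcs >= 15, 0L,
       ifelse(gcs >= 13, 1L,
       ifelse(gcs >= 10, 2L,
       ifelse(gcs >= 6, 3L, 4L)))))
  as.integer(s)
}

#' Renal SOFA component
#'
#' Score is the worse of the creatinine band (right-open: `[1.2, 2.0)` 1,
#' `[2.0, 3.5)` 2, `[3.5, 5.0)` 3, `>= 5.0` 4) and the urine-output band
#' (`< 500` mL/day at least 3, `< 200` mL/day 4).
#'
#' @param creatinine Serum creatinine, mg/dL (worst = highest).
#' @param urine_output_24h Total urine output, mL/day.
#' @return Integer score 0-4 (both inputs `NA` scores 0).
#' @export
score_renal <- function(creatinine, urine_output_24h = NA) {
  .check_nonneg(creatinine, "creatinine")
  .check_nonneg(urine_output_24h, "urine_output_24h")
  n <- max(length(creatinine), length(urine_output_24h))
  creatinine <- rep_len(creatinine, n)
  urine_output_24h <- rep_len(urine_output_24h, n)
  s_cr <- ifelse(is.na(creatinine), 0L,
          ifelse(creatinine < 1.2, 0L,
          ifelse(creatinine < 2.0, 1L,
          ifelse(creatinine < 3.5, 2L,
          ifelse(creatinine < 5.0, 3L, 4L)))))
  s_uo <- ifelse(is.na(urine_output_24h), 0L,
          ifelse(urine_output_24h < 200, 4L,
          ifelse(urine_output_24h < 500, 3L, 0L)))
  as.integer(pmax(s_cr, s_uo))
}

#' Lymphocyte-count (immune) score
#'
#' Bins the first-day minimum absolute lymphocyte count: `>= 1.0` scores 0
#' (lymphopenia is strictly below 1.0 x10^9/L), `[0.78, 1.0)` 1,
#' `[0.58, 0.78)` 2, `[0.36, 0.58)` 3, `< 0.36` 4.  Unlike the organ
#' components, a missing ALC is an error: it is a cohort exclusion
#' criterion, never a zero.
#'
#' @param alc Absolute lymphocyte count, x10^9/L (first-day minimum).
#' @return Integer score 0-4.
#' @export
score_alc <- function(alc) {
  if (any(is.na(alc))) {
    stop("alc is missing; patients without a first-day ALC must be excluded upstream",
         call. = FALSE)
  }
  .check_nonneg(alc, "alc")
  s <- ifelse(alc >= 1.0, 0L,
       ifelse(alc >= 0.78, 1L,
       ifelse(alc >= 0.58, 2L,
       ifelse(alc >= 0.36, 3L, 4L))))
  as.integer(s)
}

.missing_flags <- function(cohort) {
  parts <- list(
    respiratory   = is.na(cohort$pf_ratio),
    coagulation   = is.na(cohort$platelets),
    hepatic       = is.na(cohort$bilirubin),
    cardiovascular = is.na(cohort$map) &
      (is.na(cohort$dopamine) | cohort$dopamine == 0) &
      (is.na(cohort$dobutamine) | cohort$dobutamine == 0) &
      (is.na(cohort$epinephrine) | cohort$epinephrine == 0) &
      (is.na(cohort$norepinephrine) | cohort$norepinephrine == 0),
    renal         = is.na(cohort$creatinine) & is.na(cohort$urine_output_24h),
    cns           = is.na(cohort$gcs)
  )
  flags <- character(nrow(cohort))
  for (comp in names(parts)) {
    hit <- parts[[comp]]
    flags[hit] <- paste0(flags[hit],
                         ifelse(nzchar(flags[hit]), ";", ""),
                         comp, " missing -> 0")
  }
  uo_used <- !is.na(cohort$urine_output_24h) & cohort$urine_output_24h < 500
  flags[uo_used] <- paste0(flags[uo_used],
                           ifelse(nzchar(flags[uo_used]), ";", ""),
                           "renal scored on urine output")
  flags
}

.opt_col <- function(cohort, name) {
  if (name %in% names(cohort)) cohort[[name]] else rep(NA, nrow(cohort))
}

#' Compute the six-system SOFA breakdown for a cohort
#'
#' @param cohort A cohort data frame (see [cohort_columns()]).
#' @param strict_missing If `TRUE`, any missing organ-component input is an
#'   error; by default missing components contribute 0 points and are
#'   recorded in the `flags` column.
#' @return A data frame with one row per patient: the six component scores
#'   (`respiratory`, `coagulation`, `hepatic`, `cardiovascular`, `cns`,
#'   `renal`, each 0-4), `sofa_total` (0-24), and a `flags` character
#'   column noting missing components and urine-output-driven renal scores.
#' @export
compute_sofa <- function(cohort, strict_missing = FALSE) {
  validate_cohort(cohort)
  flags <- .missing_flags(cohort)
  if (strict_missing && any(grepl("missing", flags))) {
    bad <- which(grepl("missing", flags))[1]
    stop(sprintf("strict_missing: row %d has missing component inputs (%s)",
                 bad, flags[bad]), call. = FALSE)
  }
  out <- data.frame(
    respiratory = score_respiratory(cohort$pf_ratio, cohort$respiratory_support),
    coagulation = score_coagulation(cohort$platelets),
    hepatic = score_hepatic(cohort$bilirubin),
    cardiovascular = score_cardiovascular(
      cohort$map, cohort$dopamine, cohort$dobutamine,
      cohort$epinephrine, cohort$norepinephrine,
      .opt_col(cohort, "dopamine_ge_1h"), .opt_col(cohort, "dobutamine_ge_1h"),
      .opt_col(cohort, "epinephrine_ge_1h"),
      .opt_col(cohort, "norepinephrine_ge_1h")),
    cns = score_cns(cohort$gcs),
    renal = score_renal(cohort$creatinine, cohort$urine_output_24h),
    stringsAsFactors = FALSE
  )
  out$sofa_total <- as.integer(out$respiratory + out$coagulation +
                                 out$hepatic + out$cardiovascular +
                                 out$cns + out$renal)
  out$flags <- flags
  out
}

#' Compute the combined ALC-SOFA breakdown for a cohort
#'
#' Adds the 0-4 lymphocyte-count score to the six-system SOFA total,
#' giving the combined score on 0-28.
#'
#' @inheritParams compute_sofa
#' @return The [compute_sofa()] data frame with two extra integer columns:
#'   `alc_score` (0-4) and `alc_sofa_total` (0-28).
#' @export
compute_alc_sofa <- function(cohort, strict_missing = FALSE) {
  if (any(is.na(cohort$alc))) {
    stop("alc is missing for some patients; apply the exclusion cascade first",
         call. = FALSE)
  }
  out <- compute_sofa(cohort, strict_missing = strict_missing)
  out$alc_score <- score_alc(cohort$alc)
  out$alc_sofa_total <- as.integer(out$sofa_total + out$alc_score)
  out
}

#' Append score columns to a cohort
#'
#' Convenience wrapper binding the [compute_alc_sofa()] breakdown columns
#' onto the cohort, for writing a scored CSV.
#'
#' @inheritParams compute_sofa
#' @return The cohort with the nine breakdown columns and `flags` appended.
#' @export
score_cohort <- function(cohort, strict_missing = FALSE) {
  br <- compute_alc_sofa(cohort, strict_missing = strict_missing)
  clash <- intersect(names(br), names(cohort))
  if (length(clash) > 0) cohort[clash] <- NULL
  cbind(cohort, br)
}
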