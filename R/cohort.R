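# Patient-level cohort container and CSV interchange.
#
# A cohort is a plain data.frame (class "alcsofa_cohort") with one row per
# patient and a fixed set of canonical columns holding the first-day worst
# clinical measurements, the first-day minimum absolute lymphocyte count,
# and the survival outcome.  Units are fixed and never auto-converted:
# bilirubin/creatinine mg/dL, platelets x10^3/uL, ALC x10^9/L, vasopressor
# doses ug/kg/min, MAP mmHg, urine output mL/day, ICU stay hours, follow-up
# time days.

.core_numeric <- c(
  "age", "pf_ratio", "platelets", "bilirubin", "map",
  "dopamine", "dobutamine", "epinephrine", "norepinephrine",
  "gcs", "creatinine", "urine_output_24h", "alc", "icu_los_hours",
  "time_days"
)

.core_logical <- c("respiratory_support", "repeat_admission", "event")

.optional_logical <- c(
  "any_other_vasopressor",
  "dopamine_ge_1h", "dobutamine_ge_1h", "epinephrine_ge_1h",
  "norepinephrine_ge_1h"
)

#' Canonical cohort column names
#'
#' The required and optional canonical columns of a cohort data frame.
#' Any further columns are carried along as analysis covariates.
#'
#' @return A list with elements `required` and `optional`, each a character
#'   vector of column names.
#' @export
cohort_columns <- function() {
  list(
    required = c("patient_id", "sex", .core_numeric, .core_logical),
    optional = .optional_logical
  )
}

# Fields that may never be negative when present.
.nonneg_fields <- c(
  "age", "pf_ratio", "platelets", "bilirubin", "map",
  "dopamine", "dobutamine", "epinephrine", "norepinephrine",
  "creatinine", "urine_output_24h", "alc", "icu_los_hours", "time_days"
)

.parse_logical <- function(x, column) {
  out <- rep(NA, length(x))
  x_lower <- tolower(trimws(x))
  out[x_lower %in% c("true", "t", "1", "yes")] <- TRUE
  out[x_lower %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(x) & nzchar(trimws(x)) & is.na(out)
  if (any(bad)) {
    stop(sprintf("column '%s': unparsable logical value '%s' in row %d",
                 column, x[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  out
}

.parse_numeric <- function(x, column) {
  blank <- is.na(x) | !nzchar(trimws(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- !blank & is.na(out)
  if (any(bad)) {
    stop(sprintf("column '%s': unparsable numeric value '%s' in row %d",
                 column, x[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  out[blank] <- NA_real_
  out
}

#' Validate a cohort data frame
#'
#' Checks the structural invariants of a cohort: required columns present,
#' value-range constraints (non-negative counts and doses, GCS in 3..15,
#' positive PaO2/FiO2, sex coded `male`/`female`), and non-negative
#' follow-up time.  Missing values are permitted everywhere; they are
#' handled downstream (scoring flags, exclusion cascade).
#'
#' @param cohort A data frame with the canonical columns (see
#'   [cohort_columns()]).
#' @return The validated cohort, invisibly, with class `alcsofa_cohort`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_columns()$required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in .nonneg_fields) {
    v <- cohort[[col]]
    if (any(!is.na(v) & v < 0)) {
      stop(sprintf("column '%s': negative value in row %d", col,
                   which(!is.na(v) & v < 0)[1]), call. = FALSE)
    }
  }
  sx <- cohort$sex
  bad_sex <- !is.na(sx) & !(sx %in% c("male", "female"))
  if (any(bad_sex)) {
    stop(sprintf("column 'sex': unknown code '%s' in row %d (expected male/female)",
                 sx[which(bad_sex)[1]], which(bad_sex)[1]), call. = FALSE)
  }
  g <- cohort$gcs
  if (any(!is.na(g) & (g < 3 | g > 15))) {
    stop(sprintf("column 'gcs': value outside 3..15 in row %d",
                 which(!is.na(g) & (g < 3 | g > 15))[1]), call. = FALSE)
  }
  pf <- cohort$pf_ratio
  if (any(!is.na(pf) & pf <= 0)) {
    stop(sprintf("column 'pf_ratio': non-positive value in row %d",
                 which(!is.na(pf) & pf <= 0)[1]), call. = FALSE)
  }
  for (col in intersect(.optional_logical, names(cohort))) {
    if (!is.logical(cohort[[col]])) {
      stop(sprintf("column '%s' must be logical", col), call. = FALSE)
    }
  }
  class(cohort) <- unique(c("alcsofa_cohort", class(cohort)))
  invisible(cohort)
}

#' Read a patient-level cohort from CSV
#'
#' Reads a UTF-8, comma-separated, headered CSV into a cohort data frame.
#' Empty cells become `NA` (never silently 0).  A schema map can rename
#' source columns onto the canonical field names.  Extra columns are kept
#' as covariates: numeric where fully parseable, otherwise character.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical field
#'   names to source column names, e.g. `c(alc = "lymph_min")`.
#' @return A validated cohort data frame of class `alcsofa_cohort`.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(!nzchar(names(schema)))) {
      stop("schema must be a named character vector (canonical = source)",
           call. = FALSE)
    }
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent) > 0) {
      stop("schema maps to column(s) absent from file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    idx <- match(unname(schema), names(raw))
    names(raw)[idx] <- names(schema)
  }
  required <- cohort_columns()$required
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  sx <- trimws(raw$sex)
  sx[!nzchar(sx)] <- NA_character_
  out$sex <- tolower(sx)
  for (col in .core_numeric) out[[col]] <- .parse_numeric(raw[[col]], col)
  for (col in .core_logical) out[[col]] <- .parse_logical(raw[[col]], col)
  for (col in intersect(.optional_logical, names(raw))) {
    out[[col]] <- .parse_logical(raw[[col]], col)
  }
  extras <- setdiff(names(raw), c(names(out)))
  for (col in extras) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    blank <- !nzchar(trimws(v))
    if (all(blank | !is.na(num))) {
      num[blank] <- NA_real_
      out[[col]] <- num
    } else {
      v[blank] <- NA_character_
      out[[col]] <- v
    }
  }
  validate_cohort(out)
  class(out) <- unique(c("alcsofa_cohort", class(out)))
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' every field including the missingness pattern.  Missing values are
#' written as empty cells.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  df <- as.data.frame(cohort)
  class(df) <- "data.frame"
  write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
            quote = TRUE)
  invisible(path)
}

#' Binary mortality label at a follow-up horizon
#'
#' The label at horizon `h` days is defined only when the outcome
#' determines it: `TRUE` (died within `h` days) when the event occurred at
#' or before `h`; `FALSE` (survived `h` days) when follow-up reached `h`;
#' otherwise `NA` (censored before the horizon).  Labels are always derived
#' from `(time_days, event)`, never stored.
#'
#' @param time_days Follow-up time in days.
#' @param event Logical, death observed.
#' @param horizon Horizon in days (> 0).
#' @return Logical vector, `NA` where the label is undefined.
#' @export
horizon_label <- function(time_days, event, horizon) {
  stopifnot(length(horizon) == 1, horizon > 0)
  died <- !is.na(event) & event & !is.na(time_days) & time_days <= horizon
  survived <- !is.na(time_days) & time_days >= horizon & !died
  out <- rep(NA, length(time_days))
  out[died] <- TRUE
  out[survived] <- FALSE
  out
}
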