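# Orchestration: filter -> score -> evaluate, with a machine-readable
# report.  Every number in the report is recomputable from the input CSV
# plus the seed; the report carries a config echo and a schema version so
# downstream consumers can pin the layout.

REPORT_SCHEMA_VERSION <- "1.0"

.horizon_block <- function(scored, horizon, boot, seed, min_events = 10) {
  lab <- horizon_label(scored$time_days, scored$event, horizon)
  keep <- !is.na(lab)
  y <- lab[keep]
  s_new <- scored$alc_sofa_total[keep]
  s_old <- scored$sofa_total[keep]
  if (sum(y) < min_events || sum(!y) < min_events) {
    return(list(horizon_days = horizon, status = "insufficient data",
                n = sum(keep), n_events = sum(y)))
  }
  dl <- delong_compare(s_new, s_old, y)
  rc <- reclassification(s_new, s_old, y, b = boot, seed = seed)
  op_new <- operating_point(s_new, y)
  op_old <- operating_point(s_old, y)
  mort <- mortality_at(scored$time_days, scored$event, horizon)
  list(
    horizon_days = horizon, status = "ok",
    n = sum(keep), n_events = sum(y),
    mortality = mort$proportion,
    auc_new = dl$auc_new, auc_old = dl$auc_old,
    ci_auc_new = dl$ci_new, ci_auc_old = dl$ci_old,
    delong_z = dl$z, delong_p = dl$p,
    nri = rc$nri, nri_events = rc$nri_events,
    nri_nonevents = rc$nri_nonevents, ci_nri = rc$ci_nri,
    idi = rc$idi, ci_idi = rc$ci_idi,
    b_replicates = rc$b_replicates,
    operating_point_new = unclass(op_new),
    operating_point_old = unclass(op_old)
  )
}

#' Discrimination evaluation of a scored cohort
#'
#' For each horizon, compares the combined score against the organ score:
#' paired AUROCs with the DeLong test, continuous NRI and IDI with
#' bootstrap percentile intervals, Youden operating points for both
#' scores, and the horizon mortality.  Optionally repeats the analysis
#' within levels of a subgroup column.
#'
#' @param scored A scored cohort (output of [score_cohort()]).
#' @param horizons Follow-up horizons in days.
#' @param boot Bootstrap replicates for the NRI/IDI intervals.
#' @param seed Integer seed driving the bootstrap.
#' @param subgroup_col Optional name of a column in `scored` defining
#'   subgroups.
#' @param min_events Minimum events (and nonevents) for a block to be
#'   evaluated; smaller blocks are marked `"insufficient data"`.
#' @return A list with one `h<days>` element per horizon, plus
#'   `subgroups` when requested.
#' @export
evaluate_cohort <- function(scored, horizons = c(7, 28, 90), boot = 1000,
                            seed = NULL, subgroup_col = NULL,
                            min_events = 10) {
  stopifnot(all(c("sofa_total", "alc_sofa_total", "time_days", "event")
                %in% names(scored)))
  out <- list()
  for (h in horizons) {
    out[[paste0("h", h)]] <- .horizon_block(scored, h, boot, seed,
                                            min_events)
  }
  if (!is.null(subgroup_col)) {
    stopifnot(subgroup_col %in% names(scored))
    levels_sg <- sort(unique(as.character(scored[[subgroup_col]])))
    sg <- list()
    for (lv in levels_sg) {
      sel <- !is.na(scored[[subgroup_col]]) &
        as.character(scored[[subgroup_col]]) == lv
      sub <- scored[sel, , drop = FALSE]
      sg[[lv]] <- lapply(setNames(horizons, paste0("h", horizons)),
                         function(h) .horizon_block(sub, h, boot, seed,
                                                    min_events))
    }
    out$subgroups <- sg
  }
  out
}

#' Subgroup discrimination comparison
#'
#' Runs [delong_compare()] within each level of a subgroup label;
#' levels with fewer than `min_events` events (or nonevents) at the
#' horizon are skipped with a log entry.
#'
#' @param scored A scored cohort.
#' @param subgroup Vector of subgroup labels aligned with `scored`.
#' @param horizon Horizon in days.
#' @param min_events Minimum events and nonevents per level.
#' @return A list with `blocks` (named per level) and `skipped`.
#' @export
subgroup_evaluate <- function(scored, subgroup, horizon = 28,
                              min_events = 10) {
  stopifnot(length(subgroup) == nrow(scored))
  lab <- horizon_label(scored$time_days, scored$event, horizon)
  blocks <- list()
  skipped <- character(0)
  for (lv in sort(unique(as.character(subgroup[!is.na(subgroup)])))) {
    sel <- !is.na(subgroup) & as.character(subgroup) == lv & !is.na(lab)
    y <- lab[sel]
    if (sum(y) < min_events || sum(!y) < min_events) {
      skipped <- c(skipped, lv)
      next
    }
    blocks[[lv]] <- delong_compare(scored$alc_sofa_total[sel],
                                   scored$sofa_total[sel], y)
  }
  list(blocks = blocks, skipped = skipped)
}

#' Default pipeline configuration
#'
#' @param input Path to the raw cohort CSV.
#' @param output_dir Directory for artifacts (created if absent).
#' @param horizons Follow-up horizons in days.
#' @param boot Bootstrap replicates.
#' @param seed Top-level seed; all pipeline randomness flows from it.
#' @param subgroup_col Optional subgroup column name.
#' @param strict_missing Passed to [score_cohort()].
#' @param tukey_k Fence multiplier for the ALC outlier rule.
#' @return A config list.
#' @export
pipeline_config <- function(input, output_dir = ".", horizons = c(7, 28, 90),
                            boot = 1000, seed = 1, subgroup_col = NULL,
                            strict_missing = FALSE, tukey_k = 1.5) {
  list(input = input, output_dir = output_dir, horizons = horizons,
       boot = boot, seed = seed, subgroup_col = subgroup_col,
       strict_missing = strict_missing, tukey_k = tukey_k)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys fall back to
#' [pipeline_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A config list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    raw <- yaml::read_yaml(path)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- formals(pipeline_config)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$input)) stop("config must set 'input'", call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Run the full validation pipeline
#'
#' Executes filter -> score -> evaluate on a raw cohort CSV and writes the
#' artifacts: the scored cohort (`scored.csv`), tidy per-class
#' Kaplan-Meier curves (`km_curves.csv`), the attrition log
#' (`attrition.json`), and the evaluation report (`report.json`).  The
#' report echoes the config and seed, so identical config plus seed yields
#' a byte-identical report.
#'
#' @param config A config list from [pipeline_config()] or
#'   [read_config()].
#' @return The report, invisibly (also written to
#'   `<output_dir>/report.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(config$input)
  filtered <- apply_exclusions(cohort, tukey_k = config$tukey_k)
  audit_exclusions(filtered)
  if (nrow(filtered$cohort) == 0) {
    stop("filter stage: no records remain after exclusions", call. = FALSE)
  }
  scored <- tryCatch(
    score_cohort(filtered$cohort, strict_missing = config$strict_missing),
    error = function(e) stop("score stage: ", conditionMessage(e),
                             call. = FALSE)
  )
  write_cohort(scored, file.path(config$output_dir, "scored.csv"))
  cc <- class_curves(scored$alc_sofa_total, scored$time_days, scored$event)
  km_df <- km_tidy(cc$curves)
  write.csv(km_df, file.path(config$output_dir, "km_curves.csv"),
            row.names = FALSE)
  evaluation <- tryCatch(
    evaluate_cohort(scored, horizons = config$horizons, boot = config$boot,
                    seed = config$seed, subgroup_col = config$subgroup_col),
    error = function(e) stop("evaluate stage: ", conditionMessage(e),
                             call. = FALSE)
  )
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    config = config[setdiff(names(config), "output_dir")],
    seed = config$seed,
    attrition = filtered$attrition,
    n_analyzed = nrow(scored),
    alc_sofa_classes = list(
      classes = cc$classes, dropped = cc$dropped,
      logrank = cc$logrank
    ),
    evaluation = evaluation
  )
  jsonlite::write_json(report,
                       file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  jsonlite::write_json(filtered$attrition,
                       file.path(config$output_dir, "attrition.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Check a report against the pinned schema
#'
#' Verifies the schema version and the presence and types of the required
#' top-level and per-horizon fields (the schema itself ships as
#' `inst/schema/report-schema.json`).
#'
#' @param report A report list (from [run_pipeline()]) or a path to a
#'   report JSON file.
#' @return `TRUE` if valid, otherwise an error naming the first problem.
#' @export
validate_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  }
  required_top <- c("schema_version", "config", "seed", "attrition",
                    "n_analyzed", "alc_sofa_classes", "evaluation")
  missing <- setdiff(required_top, names(report))
  if (length(missing) > 0) {
    stop("report missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.character(report$schema_version),
                 REPORT_SCHEMA_VERSION)) {
    stop("report schema version mismatch: ", report$schema_version,
         call. = FALSE)
  }
  for (nm in names(report$evaluation)) {
    if (!grepl("^h[0-9]+$", nm)) next
    block <- report$evaluation[[nm]]
    if (identical(block$status, "ok")) {
      need <- c("auc_new", "auc_old", "delong_p", "nri", "idi",
                "operating_point_new", "operating_point_old")
      gone <- setdiff(need, names(block))
      if (length(gone) > 0) {
        stop("horizon block ", nm, " missing: ",
             paste(gone, collapse = ", "), call. = FALSE)
      }
    }
  }
  TRUE
}
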