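# Monthly orchestration: iterate censuses, produce cohort / completion /
# reverse-check tables and the main + sensitivity trend series, compare the
# algorithm variants at one census, and render team feedback reports.

spec_for <- function(census, config = list()) {
  census_spec(
    census,
    window_days = config$window_days %||% 183L,
    algorithm_version = config$algorithm_version %||% "v2",
    sensitivity_mode = config$sensitivity_mode %||% FALSE,
    form_validity_days = config$form_validity_days %||%
      (config$window_days %||% 183L),
    min_references_v2 = config$min_references_v2 %||% 2L,
    rule1_scope = config$rule1_scope %||% "pooled",
    setting_specific_validity = config$setting_specific_validity %||% FALSE
  )
}

as_bundle <- function(bundle) {
  if (inherits(bundle, "ehr_bundle")) bundle
  else if (is.character(bundle) && length(bundle) == 1) read_bundle(bundle)
  else stopf("expected an ehr_bundle or a bundle directory path")
}

#' Build the event stream for a bundle
#'
#' Convenience wrapper: extraction plus merge with the structured tables,
#' with the patient registry enforced.
#'
#' @param bundle an `ehr_bundle` or a bundle directory path.
#' @param lexicons an `apm_lexicons`.
#' @return an `event_stream`.
#' @export
bundle_event_stream <- function(bundle, lexicons = default_lexicons()) {
  b <- as_bundle(bundle)
  build_event_stream(b$structured_diagnoses, b$notes, b$forms, b$episodes,
                     lexicons, patients = b$patients)
}

#' Run the monthly monitoring pipeline over all censuses
#'
#' Iterates every census (28th of each month in the configured span),
#' ascertaining the cohort under the configured algorithm, linking forms,
#' running the reverse check, and assembling the main and sensitivity trend
#' series.  Fully deterministic given the bundle.
#'
#' @param bundle an `ehr_bundle` or bundle directory path.
#' @param config list of overrides: `census_start` / `census_end`
#'   ("YYYY-MM", default from the bundle config), plus any [census_spec()]
#'   parameter (`window_days`, `algorithm_version`, `min_references_v2`,
#'   `rule1_scope`, `form_validity_days`, ...).
#' @param out_dir when given, writes `cohort.csv`, `completion.csv`,
#'   `reverse_check.csv`, `trend.csv` there.
#' @param lexicons an `apm_lexicons`.
#' @param quiet suppress per-census log lines.
#' @return invisible list of data.tables: cohort, completion, reverse_check,
#'   trend.
#' @export
run_monthly <- function(bundle, config = list(), out_dir = NULL,
                        lexicons = default_lexicons(), quiet = TRUE) {
  b <- as_bundle(bundle)
  censuses <- monthly_censuses(config$census_start %||% b$config$census_start,
                               config$census_end %||% b$config$census_end)
  stream <- bundle_event_stream(b, lexicons)
  cohort_l <- list(); comp_l <- list(); rev_l <- list(); trend_l <- list()
  n_processed <- 0L
  for (cen in as.list(censuses)) {
    spec_main <- spec_for(cen, config)
    cohort <- build_cohort(stream, b$episodes, spec_main)
    if (!nrow(cohort)) next
    n_processed <- n_processed + 1L
    comp <- completion_rate(cohort, b$forms, spec_main, b$episodes,
                            group_by_team = TRUE)
    rev <- reverse_check(stream, b$episodes, b$forms, spec_main)

    cfg_sens <- config; cfg_sens$sensitivity_mode <- TRUE
    cohort_s <- build_cohort(stream, b$episodes, spec_for(cen, cfg_sens))
    spec_sens <- spec_for(cen, cfg_sens)
    comp_s <- completion_rate(cohort_s, b$forms, spec_sens)

    pooled <- comp[team_id == "ALL"]
    trend_l[[length(trend_l) + 1L]] <- data.table::data.table(
      census_date = spec_main$census_date,
      pct_main = pooled$pct_complete, pct_sensitivity = comp_s$pct_complete,
      n_main = pooled$n_eligible, n_sensitivity = comp_s$n_eligible)
    cohort_l[[length(cohort_l) + 1L]] <- cohort
    comp_l[[length(comp_l) + 1L]] <- comp
    rev_l[[length(rev_l) + 1L]] <- rev
    if (!quiet) {
      message(sprintf("[%s] caseload evaluated: %d; included: %d; reasons: %s",
                      format(spec_main$census_date), nrow(cohort),
                      sum(cohort$included),
                      paste(sprintf("%s=%d",
                                    names(table(cohort$exclusion_reason)),
                                    table(cohort$exclusion_reason)),
                            collapse = " ")))
    }
  }
  empty_trend <- data.table::data.table(census_date = as.Date(character()),
                                        pct_main = numeric(),
                                        pct_sensitivity = numeric(),
                                        n_main = integer(),
                                        n_sensitivity = integer())
  res <- list(
    cohort = if (length(cohort_l)) data.table::rbindlist(cohort_l) else
      build_cohort(stream, b$episodes, spec_for(censuses[1], config))[0],
    completion = if (length(comp_l)) data.table::rbindlist(comp_l) else
      completion_rate(data.table::data.table(included = logical(),
                                             patient_id = character()),
                      b$forms, spec_for(censuses[1], config))[0],
    reverse_check = if (length(rev_l)) data.table::rbindlist(rev_l) else
      reverse_check(stream, b$episodes, b$forms, spec_for(censuses[1], config))[0],
    trend = if (length(trend_l)) data.table::rbindlist(trend_l) else empty_trend
  )
  if (!quiet) message(sprintf("censuses processed: %d", n_processed))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(res)) {
      data.table::fwrite(date_cols_to_char(res[[nm]]),
                         file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  invisible(res)
}

#' Compare algorithm variants at one census (the refinement cascade)
#'
#' Three stages at a single census: (1) baseline v1 (any reference in
#' window); (2) the refined filter (minimum reference count, stop-reference
#' exclusion); (3) stage 2 plus the sensitivity exclusions.  Denominators
#' are non-increasing across stages by construction; completion percentages
#' may move either way.
#'
#' @param bundle an `ehr_bundle` or bundle directory path.
#' @param census_date the census to evaluate.
#' @param config overrides as in [run_monthly()].
#' @param lexicons an `apm_lexicons`.
#' @return list with `summary` (one row per stage: stage, n_cohort,
#'   n_with_form, pct_complete) and `exclusions` (tallies by reason at each
#'   stage).
#' @export
compare_variants <- function(bundle, census_date, config = list(),
                             lexicons = default_lexicons()) {
  b <- as_bundle(bundle)
  stream <- bundle_event_stream(b, lexicons)
  stage_cfgs <- list(
    v1 = c(config, list(algorithm_version = "v1", sensitivity_mode = FALSE)),
    v2_filters = c(config, list(algorithm_version = "v2", sensitivity_mode = FALSE)),
    v2_sensitivity = c(config, list(algorithm_version = "v2", sensitivity_mode = TRUE))
  )
  # explicit stage settings must override caller-supplied ones: keep the
  # last of any duplicated name
  stage_cfgs <- lapply(stage_cfgs, function(cf) cf[!duplicated(names(cf), fromLast = TRUE)])
  rows <- list(); excl <- list()
  for (nm in names(stage_cfgs)) {
    spec <- spec_for(census_date, stage_cfgs[[nm]])
    cohort <- build_cohort(stream, b$episodes, spec)
    comp <- completion_rate(cohort, b$forms, spec)
    rows[[nm]] <- data.table::data.table(
      census_date = spec$census_date, stage = nm,
      n_cohort = comp$n_eligible, n_with_form = comp$n_with_form,
      pct_complete = comp$pct_complete)
    tab <- cohort[included == FALSE, .N, by = exclusion_reason]
    tab[, stage := nm]
    excl[[nm]] <- tab
  }
  list(summary = data.table::rbindlist(rows),
       exclusions = data.table::rbindlist(excl))
}

#' Render a plain-text team feedback report
#'
#' One line per team with eligible count, completed forms and percentage,
#' under a header stating the census, algorithm version and window settings.
#' Formatting is stable for snapshot testing.
#'
#' @param completion per-team output of [completion_rate()].
#' @param spec the `census_spec` the completion table was computed under.
#' @return character vector of report lines.
#' @export
render_report <- function(completion, spec) {
  comp <- data.table::as.data.table(completion)
  hdr <- c(
    sprintf("Antipsychotic monitoring report — census %s",
            format(spec$census_date)),
    sprintf("algorithm %s | lookback window %d days | form validity %d days | sensitivity %s",
            spec$algorithm_version, spec$window_days, spec$form_validity_days,
            if (spec$sensitivity_mode) "on" else "off"),
    strrep("-", 72))
  teams <- comp[team_id != "ALL"][order(team_id)]
  body <- if (nrow(teams)) {
    vapply(seq_len(nrow(teams)), function(i) {
      r <- teams[i]
      if (r$n_eligible == 0) {
        sprintf("%-10s no eligible patients", r$team_id)
      } else {
        sprintf("%-10s eligible %4d | forms completed %4d | completion %5.1f%%",
                r$team_id, r$n_eligible, r$n_with_form, r$pct_complete)
      }
    }, "")
  } else character()
  pooled <- comp[team_id == "ALL"]
  foot <- if (nrow(pooled)) {
    if (pooled$n_eligible == 0) {
      "ALL        no eligible patients"
    } else {
      sprintf("%-10s eligible %4d | forms completed %4d | completion %5.1f%%",
              "ALL", pooled$n_eligible, pooled$n_with_form, pooled$pct_complete)
    }
  } else character()
  c(hdr, body, strrep("-", 72), foot)
}
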