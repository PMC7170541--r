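# Monitoring-form completion metrics and the PDSA-style reverse check.

#' Has a patient a completed monitoring form at a census?
#'
#' TRUE iff at least one form of either type is dated in the closed interval
#' `[census - validity, census]`, where validity is
#' `spec$form_validity_days`, or 28 days for inpatients when
#' `spec$setting_specific_validity` is set.
#'
#' @param forms data.table of forms (patient_id, date, ...).
#' @param patient_id one patient id.
#' @param spec a `census_spec`.
#' @param setting optional care setting for the setting-specific mode
#'   (`"inpatient"` shortens validity to 28 days).
#' @return logical flag.
#' @export
form_completed <- function(forms, patient_id, spec, setting = NULL) {
  validity <- spec$form_validity_days
  if (spec$setting_specific_validity && identical(setting, "inpatient")) {
    validity <- 28L
  }
  lo <- spec$census_date - validity
  pid <- patient_id
  f <- data.table::as.data.table(forms)
  nrow(f[f$patient_id == pid & date >= lo & date <= spec$census_date]) > 0
}

# patient -> teams with an active episode at the census (a patient counts in
# each such team)
teams_at_census <- function(episodes, census_date) {
  ep <- data.table::as.data.table(episodes)
  act <- ep[start_date <= census_date & (is.na(end_date) | end_date >= census_date)]
  unique(act[, .(patient_id, team_id, setting)])
}

form_flags <- function(members, forms, episodes, spec) {
  f <- data.table::as.data.table(forms)
  lo_default <- spec$census_date - spec$form_validity_days
  with_form_default <- unique(f[date >= lo_default & date <= spec$census_date,
                                patient_id])
  if (!spec$setting_specific_validity) {
    return(members$patient_id %in% with_form_default)
  }
  tm <- teams_at_census(episodes, spec$census_date)
  inpat <- unique(tm[setting == "inpatient", patient_id])
  lo_inpat <- spec$census_date - 28L
  with_form_inpat <- unique(f[date >= lo_inpat & date <= spec$census_date,
                              patient_id])
  ifelse(members$patient_id %in% inpat,
         members$patient_id %in% with_form_inpat,
         members$patient_id %in% with_form_default)
}

#' Form-completion rate for cohort members
#'
#' Numerator: included members with a form inside the validity window;
#' denominator: included members.  Percentages are rounded half away from
#' zero to one decimal; with an empty denominator the percentage is reported
#' absent (NA), not zero.  With `group_by_team`, a patient counts in every
#' team holding an active episode at the census, plus the pooled `ALL` row
#' (where each patient counts once).
#'
#' @param members cohort table from [build_cohort()] (only `included` rows
#'   enter the denominator).
#' @param forms data.table of monitoring forms.
#' @param spec a `census_spec`.
#' @param episodes care episodes; required when `group_by_team = TRUE`.
#' @param group_by_team emit per-team rows in addition to the pooled row.
#' @return data.table: census_date, team_id ("ALL" = pooled), n_eligible,
#'   n_with_form, pct_complete.
#' @export
completion_rate <- function(members, forms, spec, episodes = NULL,
                            group_by_team = FALSE) {
  m <- data.table::as.data.table(members)[included == TRUE]
  flags <- if (nrow(m)) form_flags(m, forms, episodes, spec) else logical()
  pooled <- data.table::data.table(
    census_date = spec$census_date, team_id = "ALL",
    n_eligible = nrow(m), n_with_form = sum(flags),
    pct_complete = completion_pct(sum(flags), nrow(m))
  )
  if (!group_by_team) return(pooled)
  if (is.null(episodes)) stopf("episodes are required for per-team grouping")
  tm <- teams_at_census(episodes, spec$census_date)
  mt <- merge(m[, .(patient_id, has_form = flags)], tm, by = "patient_id",
              allow.cartesian = TRUE)
  per_team <- mt[, .(n_eligible = .N, n_with_form = sum(has_form)),
                 by = .(team_id)][order(team_id)]
  per_team[, `:=`(census_date = spec$census_date,
                  pct_complete = completion_pct(n_with_form, n_eligible))]
  data.table::rbindlist(list(
    per_team[, .(census_date, team_id, n_eligible, n_with_form, pct_complete)],
    pooled))
}

#' Reverse check: forms for dementia patients the algorithm did not flag
#'
#' Denominator: active-caseload patients with a dementia diagnosis on or
#' before the census whom the recent-use algorithm (version per `spec`) did
#' NOT flag; numerator: those with a completed form.  Detects algorithm
#' false negatives (forms completed for patients the exposure algorithm
#' missed).
#'
#' @param stream an `event_stream`.
#' @param episodes care episodes.
#' @param forms data.table of monitoring forms.
#' @param spec a `census_spec`.
#' @return one-row data.table: census_date,
#'   n_dementia_without_algorithm_use, n_with_form, pct.
#' @export
reverse_check <- function(stream, episodes = stream$episodes,
                          forms = stream$forms, spec) {
  cohort <- build_cohort(stream, episodes, spec)
  denom <- cohort[exclusion_reason %in%
                    c("no_recent_use", "single_reference", "stopped")]
  flags <- if (nrow(denom)) form_flags(denom, forms, episodes, spec) else logical()
  data.table::data.table(
    census_date = spec$census_date,
    n_dementia_without_algorithm_use = nrow(denom),
    n_with_form = sum(flags),
    pct = completion_pct(sum(flags), nrow(denom))
  )
}
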