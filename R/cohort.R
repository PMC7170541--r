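# Census-date cohort ascertainment.
#
# At each monthly census (28th), the cohort is: patients on the active
# caseload, with a dementia diagnosis (F00-F03, structured or text) dated on
# or before the census, and evidence of recent antipsychotic use inside a
# closed lookback window [census - window_days, census].  v1 admits any
# single reference; v2 (the refined algorithm) requires at least
# `min_references_v2` references and drops every medication carrying a stop
# reference in the window.  Sensitivity mode further excludes ever-psychosis
# (F20-F29) and a different psychiatric diagnosis after the index dementia
# diagnosis.

#' Census specification
#'
#' All tunable ascertainment parameters for one census evaluation.
#'
#' @param census_date census date (by convention the 28th of a month).
#' @param window_days lookback for "recent" use; closed interval
#'   `[census - window_days, census]`.  Default 183 (about 6 months, the
#'   community review cadence).
#' @param algorithm_version `"v1"` (any reference) or `"v2"` (refined:
#'   minimum reference count, stop-reference filter).
#' @param sensitivity_mode apply the psychosis / superseding-diagnosis
#'   exclusions.
#' @param form_validity_days lookback for counting a monitoring form;
#'   defaults to `window_days`.
#' @param min_references_v2 minimum in-window reference count for v2.
#' @param rule1_scope `"pooled"` (reference count pooled across drugs at
#'   patient level, the default reading) or `"per_drug"` (each drug must
#'   individually carry the minimum count).
#' @param setting_specific_validity when TRUE, inpatient form validity is 28
#'   days (review cadence every 2-4 weeks) instead of `form_validity_days`.
#' @return a `census_spec` list.
#' @export
census_spec <- function(census_date,
                        window_days = 183L,
                        algorithm_version = c("v2", "v1"),
                        sensitivity_mode = FALSE,
                        form_validity_days = window_days,
                        min_references_v2 = 2L,
                        rule1_scope = c("pooled", "per_drug"),
                        setting_specific_validity = FALSE) {
  spec <- list(
    census_date = as_iso_date(census_date, "census_date"),
    window_days = as.integer(window_days),
    algorithm_version = match.arg(algorithm_version),
    sensitivity_mode = isTRUE(sensitivity_mode),
    form_validity_days = as.integer(form_validity_days),
    min_references_v2 = as.integer(min_references_v2),
    rule1_scope = match.arg(rule1_scope),
    setting_specific_validity = isTRUE(setting_specific_validity)
  )
  if (is.na(spec$census_date)) stopf("census_date is invalid")
  if (spec$window_days <= 0) stopf("window_days must be > 0")
  if (spec$min_references_v2 < 2) stopf("min_references_v2 must be >= 2")
  structure(spec, class = "census_spec")
}

#' Active caseload at a census date
#'
#' Patients with at least one care episode whose closed interval contains the
#' census date; an open end date means the episode is ongoing.
#'
#' @param episodes data.table: patient_id, start_date, end_date (NA = open).
#' @param census_date census date.
#' @return character vector of patient ids (sorted, unique).
#' @export
active_caseload <- function(episodes, census_date) {
  census_date <- as_iso_date(census_date)
  ep <- data.table::as.data.table(episodes)
  if (!nrow(ep)) return(character())
  act <- ep[start_date <= census_date &
              (is.na(end_date) | end_date >= census_date)]
  sort(unique(act$patient_id))
}

#' Index dementia diagnosis date
#'
#' Earliest F00-F03 event (structured or text) on or before the census date;
#' NA if there is none.
#'
#' @param stream an `event_stream`.
#' @param patient_id one patient id.
#' @param census_date census date.
#' @return Date or NA.
#' @export
dementia_index <- function(stream, patient_id, census_date) {
  census_date <- as_iso_date(census_date)
  pid <- patient_id
  ev <- stream$events
  d <- ev[ev$patient_id == pid & event_class == "diagnosis" &
            detail == "F00-F03" & date <= census_date, date]
  if (length(d)) min(d) else as.Date(NA)
}

window_references <- function(stream, patient_id, spec) {
  lo <- spec$census_date - spec$window_days
  pid <- patient_id
  ev <- stream$events
  ev[ev$patient_id == pid & event_class == "medication" &
       date >= lo & date <= spec$census_date,
     .(patient_id, date, drug_name = detail, kind, note_id = provenance_id)]
}

#' Recent antipsychotic use, baseline algorithm (v1)
#'
#' TRUE iff at least one medication reference of any kind (stop references
#' included) falls in the closed window `[census - window_days, census]`.
#'
#' @param stream an `event_stream`.
#' @param patient_id one patient id.
#' @param spec a `census_spec`.
#' @return list(flag, evidence, reason): reason is `"none"` when flagged,
#'   `"no_recent_use"` otherwise.
#' @export
recent_use_v1 <- function(stream, patient_id, spec) {
  refs <- window_references(stream, patient_id, spec)
  list(flag = nrow(refs) > 0, evidence = refs,
       reason = if (nrow(refs) > 0) "none" else "no_recent_use")
}

#' Recent antipsychotic use, refined algorithm (v2)
#'
#' Two filters on the in-window references: (1) the reference count (pooled
#' across drugs by default) must reach `min_references_v2`, otherwise the
#' patient is excluded as a single-reference case; (2) every medication with
#' at least one stop reference in the window is dropped, and the patient is
#' flagged only if a surviving medication retains at least one reference.
#' Stop references count toward the step-1 tally (they are still references)
#' before step 2 removes their drug.
#'
#' @inheritParams recent_use_v1
#' @return list(flag, evidence, reason): reason one of `"none"`,
#'   `"no_recent_use"`, `"single_reference"`, `"stopped"`.
#' @export
recent_use_v2 <- function(stream, patient_id, spec) {
  refs <- window_references(stream, patient_id, spec)
  if (nrow(refs) == 0) {
    return(list(flag = FALSE, evidence = refs, reason = "no_recent_use"))
  }
  if (spec$rule1_scope == "pooled") {
    if (nrow(refs) < spec$min_references_v2) {
      return(list(flag = FALSE, evidence = refs, reason = "single_reference"))
    }
    surviving <- refs[, if (!any(kind == "stop")) .SD, by = drug_name]
  } else {
    counts <- refs[, .N, by = drug_name]
    eligible <- counts[N >= spec$min_references_v2, drug_name]
    if (!length(eligible)) {
      return(list(flag = FALSE, evidence = refs, reason = "single_reference"))
    }
    surviving <- refs[drug_name %in% eligible][, if (!any(kind == "stop")) .SD,
                                               by = drug_name]
  }
  if (nrow(surviving) == 0) {
    return(list(flag = FALSE, evidence = refs, reason = "stopped"))
  }
  list(flag = TRUE, evidence = refs, reason = "none")
}

recent_use <- function(stream, patient_id, spec) {
  if (spec$algorithm_version == "v1") recent_use_v1(stream, patient_id, spec)
  else recent_use_v2(stream, patient_id, spec)
}

#' Sensitivity-output exclusions
#'
#' Applied to included members, in order: (1) exclude anyone with an F20-F29
#' event dated on or before the census ("ever" psychosis, as knowable at the
#' census); (2) exclude anyone with an F-chapter event outside F00-F03 dated
#' strictly after their index dementia date and on or before the census.
#'
#' @param members data.table of cohort members (see [build_cohort()]).
#' @param stream an `event_stream`.
#' @param spec a `census_spec`.
#' @return `members` with `included` / `exclusion_reason` updated.
#' @export
apply_sensitivity_exclusions <- function(members, stream, spec) {
  m <- data.table::copy(members)
  ev <- stream$events[event_class == "diagnosis" & date <= spec$census_date]
  psych <- unique(ev[detail == "F20-F29", patient_id])
  idx <- which(m$included & m$patient_id %in% psych)
  if (length(idx)) {
    m[idx, `:=`(included = FALSE, exclusion_reason = "psychosis_ever")]
  }
  other <- ev[detail != "F00-F03"]
  for (i in which(m$included)) {
    d0 <- m$dementia_index_date[i]
    if (is.na(d0)) next
    hit <- other[patient_id == m$patient_id[i] & date > d0]
    if (nrow(hit)) {
      m[i, `:=`(included = FALSE, exclusion_reason = "other_dx_after_index")]
    }
  }
  m
}

#' Ascertain the cohort at one census
#'
#' Composes active caseload, dementia index, recent-use (v1 or v2 per the
#' spec) and, when `sensitivity_mode` is set, the sensitivity exclusions.
#' Every patient on the active caseload (plus any patient with events) is
#' evaluated exactly once; the result records the first failing rule.
#'
#' @param stream an `event_stream`.
#' @param episodes care episodes (defaults to those carried in the stream).
#' @param spec a `census_spec`.
#' @return data.table sorted by patient_id: patient_id, census_date,
#'   included, exclusion_reason, dementia_index_date, n_references_in_window,
#'   algorithm_version, sensitivity_mode, window_days.
#' @export
build_cohort <- function(stream, episodes = stream$episodes, spec) {
  active <- active_caseload(episodes, spec$census_date)
  universe <- sort(unique(c(stream$patients, episodes$patient_id)))
  out <- data.table::data.table(
    patient_id = universe,
    census_date = spec$census_date,
    included = FALSE,
    exclusion_reason = "not_active",
    dementia_index_date = as.Date(NA),
    n_references_in_window = 0L
  )
  ev <- stream$events
  # earliest dementia event per patient, and in-window reference summaries,
  # computed set-at-a-time; equivalent to the per-patient operations
  dem <- if (nrow(ev)) {
    ev[event_class == "diagnosis" & detail == "F00-F03" &
         date <= spec$census_date, .(d_idx = min(date)), by = patient_id]
  } else {
    data.table::data.table(patient_id = character(), d_idx = as.Date(character()))
  }
  lo <- spec$census_date - spec$window_days
  refs <- ev[event_class == "medication" & date >= lo & date <= spec$census_date]
  per_drug <- refs[, .(n = .N, any_stop = any(kind == "stop")), by = .(patient_id, detail)]
  if (spec$algorithm_version == "v1") {
    med <- per_drug[, .(n_refs = sum(n), flag = sum(n) > 0), by = patient_id]
    med[, reason := "none"]
  } else if (spec$rule1_scope == "pooled") {
    med <- per_drug[, .(n_refs = sum(n),
                        survives = any(!any_stop),
                        all_stop = all(any_stop)), by = patient_id]
    med[, flag := n_refs >= spec$min_references_v2 & survives]
    med[, reason := ifelse(flag, "none",
                           ifelse(n_refs < spec$min_references_v2,
                                  "single_reference", "stopped"))]
  } else {
    med <- per_drug[, .(n_refs = sum(n),
                        any_eligible = any(n >= spec$min_references_v2),
                        survives_big = any(n >= spec$min_references_v2 & !any_stop)),
                    by = patient_id]
    med[, flag := any_eligible & survives_big]
    med[, reason := ifelse(flag, "none",
                           ifelse(!any_eligible, "single_reference", "stopped"))]
  }

  out[dem, dementia_index_date := i.d_idx, on = "patient_id"]
  is_active <- out$patient_id %in% active
  out[is_active, exclusion_reason := ifelse(is.na(dementia_index_date),
                                            "no_dementia", "no_recent_use")]
  dem_active <- is_active & !is.na(out$dementia_index_date)
  out[med, `:=`(n_refs_tmp = i.n_refs, flag_tmp = i.flag, reason_tmp = i.reason),
      on = "patient_id"]
  sel <- dem_active & !is.na(out$flag_tmp)
  out[sel, `:=`(included = flag_tmp, exclusion_reason = reason_tmp,
                n_references_in_window = as.integer(n_refs_tmp))]
  out[, c("n_refs_tmp", "flag_tmp", "reason_tmp") := NULL]
  if (spec$sensitivity_mode) {
    out <- apply_sensitivity_exclusions(out, stream, spec)
  }
  out[, `:=`(algorithm_version = spec$algorithm_version,
             sensitivity_mode = spec$sensitivity_mode,
             window_days = spec$window_days)]
  data.table::setorder(out, patient_id)
  out[]
}
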