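#' Configuration for the synthetic EHR generator
#'
#' The defaults describe the emulated service: a mental-health-of-older-adults
#' dementia caseload observed over a 16-census span (October 2017 to January
#' 2019 analogue), with roughly 32% of the caseload on an antipsychotic, 19%
#' carrying a comorbid psychosis diagnosis, and monitoring-form completion
#' ramping linearly from 22% at the first census to 58% at the last.
#'
#' @param n_patients number of patients (all carry a dementia diagnosis: the
#'   bundle models the dementia caseload).
#' @param start_date,end_date record bounds (ISO dates); every generated event
#'   falls inside them.
#' @param census_start,census_end "YYYY-MM" bounds of the monthly census span
#'   (28th of each month).
#' @param antipsychotic_prevalence probability a patient is truly exposed.
#' @param psychosis_comorbidity probability of an ever-psychosis (F20-F29)
#'   diagnosis.
#' @param other_dx_rate probability of a non-dementia psychiatric diagnosis
#'   recorded strictly after the index dementia diagnosis.
#' @param form_completion_start,form_completion_end endpoints of the linear
#'   form-adoption ramp across the census span.
#' @param offlabel_form_rate probability a non-exposed patient has a stray
#'   monitoring form (feeds the reverse check).
#' @param note_rate mean background (distractor) notes per patient-month.
#' @param mention_noise probability a truly exposed patient is a sparse
#'   documenter, leaving typically a single medication reference per lookback
#'   window.
#' @param stop_rate probability an exposed patient's treatment truly ends
#'   inside the record with a documented 'stop' reference; otherwise exposure
#'   is ongoing to the end of the record.
#' @param text_only_dx_frac fraction of dementia diagnoses recorded only in
#'   free text (never as a structured code), forcing the NLP pathway.
#' @param negation_rate rate of negated psychosis-screen sentences per
#'   patient-month (extraction must not count them).
#' @param n_teams number of teams (split across community, care-home and
#'   inpatient settings).
#' @param active_frac fraction of patients whose care episode spans the whole
#'   record; the rest have a shorter random episode, so the active caseload
#'   varies between censuses.
#' @param seed integer RNG seed; identical configs (including seed) produce
#'   byte-identical bundles.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_patients = 660L,
                             start_date = "2017-01-01",
                             end_date = "2019-01-31",
                             census_start = "2017-10",
                             census_end = "2019-01",
                             antipsychotic_prevalence = 0.321,
                             psychosis_comorbidity = 0.19,
                             other_dx_rate = 0.15,
                             form_completion_start = 0.22,
                             form_completion_end = 0.58,
                             offlabel_form_rate = 0.04,
                             note_rate = 1.0,
                             mention_noise = 0.1,
                             stop_rate = 0.1,
                             text_only_dx_frac = 0.3,
                             negation_rate = 0.05,
                             n_teams = 10L,
                             active_frac = 0.85,
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    start_date = as_iso_date(start_date, "start_date"),
    end_date = as_iso_date(end_date, "end_date"),
    census_start = census_start,
    census_end = census_end,
    antipsychotic_prevalence = antipsychotic_prevalence,
    psychosis_comorbidity = psychosis_comorbidity,
    other_dx_rate = other_dx_rate,
    form_completion_start = form_completion_start,
    form_completion_end = form_completion_end,
    offlabel_form_rate = offlabel_form_rate,
    note_rate = note_rate,
    mention_noise = mention_noise,
    stop_rate = stop_rate,
    text_only_dx_frac = text_only_dx_frac,
    negation_rate = negation_rate,
    n_teams = as.integer(n_teams),
    active_frac = active_frac,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  probs <- c("antipsychotic_prevalence", "psychosis_comorbidity",
             "other_dx_rate", "form_completion_start", "form_completion_end",
             "offlabel_form_rate", "mention_noise", "stop_rate",
             "text_only_dx_frac", "active_frac")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stopf("configuration error: '%s' must be a probability in [0,1]", p)
    }
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 0) {
    stopf("configuration error: 'n_patients' must be >= 0")
  }
  if (!(cfg$start_date < cfg$end_date)) {
    stopf("configuration error: 'start_date' must be before 'end_date'")
  }
  if (cfg$note_rate < 0) stopf("configuration error: 'note_rate' must be >= 0")
  if (cfg$negation_rate < 0) stopf("configuration error: 'negation_rate' must be >= 0")
  if (cfg$n_teams < 1) stopf("configuration error: 'n_teams' must be >= 1")
  cen <- monthly_censuses(cfg$census_start, cfg$census_end)
  if (cen[1] <= cfg$start_date || cen[length(cen)] > cfg$end_date) {
    stopf("configuration error: census span must lie inside (start_date, end_date]")
  }
  invisible(cfg)
}

#' Read a generator config from a flat-key file
#'
#' The file holds one `key = value` pair per line, keys matching
#' [generator_config()] argument names; `#` lines are comments.  Unknown keys
#' raise a configuration error.
#'
#' @param path file path.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  kv <- read_lexicon_file(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(kv), known)
  if (length(unknown)) stopf("configuration error: unknown key '%s'", unknown[1])
  args <- lapply(seq_along(kv), function(i) {
    v <- kv[[i]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(args) <- names(kv)
  do.call(generator_config, args)
}

#' Write a generator config as a flat-key file
#'
#' @param cfg a `generator_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(cfg, path) {
  vals <- vapply(unclass(cfg), function(v) {
    if (inherits(v, "Date")) format(v) else as.character(v)
  }, "")
  writeLines(paste(names(vals), "=", vals), path)
  invisible(path)
}
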