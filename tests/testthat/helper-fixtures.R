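# Shared fixtures: lexicons loaded once; constructors for hand-built event
# streams and notes.

LEX <- default_lexicons()

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_patients = 50L, note_rate = 0.3, seed = 101L)
  do.call(generator_config, utils::modifyList(defaults, args))
}

note_row <- function(text, note_id = "N000001", patient_id = "P0001",
                     date = "2018-06-01", team_id = "CMHT-01") {
  data.table::data.table(note_id = note_id, patient_id = patient_id,
                         date = as.Date(date), team_id = team_id, text = text)
}

events_dt <- function(patient_id = character(), date = character(),
                      event_class = character(), detail = character(),
                      kind = NA_character_, source = "structured",
                      provenance_id = NA_character_) {
  n <- length(patient_id)
  prov <- if (all(is.na(provenance_id))) sprintf("ev%03d", seq_len(n)) else
    rep_len(provenance_id, n)
  dt <- data.table::data.table(
    patient_id = patient_id, date = as.Date(date),
    event_class = rep_len(event_class, n), detail = rep_len(detail, n),
    kind = rep_len(kind, n), source = rep_len(source, n),
    provenance_id = prov,
    matched_term = NA_character_)
  data.table::setorder(dt, patient_id, date, source, provenance_id)
  dt
}

episodes_dt <- function(patient_id, start_date, end_date = NA,
                        team_id = "CMHT-01", setting = "community") {
  n <- length(patient_id)
  data.table::data.table(
    patient_id = patient_id, team_id = rep_len(team_id, n),
    setting = rep_len(setting, n), start_date = as.Date(start_date),
    end_date = as.Date(rep_len(end_date, n)))
}

forms_dt <- function(patient_id = character(), date = character(),
                     form_type = "review", team_id = "CMHT-01") {
  n <- length(patient_id)
  data.table::data.table(form_id = sprintf("FRM%03d", seq_len(n)),
                         patient_id = patient_id, date = as.Date(date),
                         form_type = rep_len(form_type, n),
                         team_id = rep_len(team_id, n))
}

manual_stream <- function(events = events_dt(), forms = forms_dt(),
                          episodes = episodes_dt(character(), character()),
                          patients = NULL) {
  structure(list(events = events, forms = forms, episodes = episodes,
                 patients = patients %||% sort(unique(c(events$patient_id,
                                                        episodes$patient_id)))),
            class = "event_stream")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
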