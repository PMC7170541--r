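# Deterministic lexicon/pattern extraction: a deliberately simple, exactly
# analysable stand-in for the NLP applications that real mental-health EHR
# research platforms run over free text.  Matching is case-insensitive,
# whole-word, no stemming.  A start/stop/negation cue attributes to a drug or
# diagnosis term in the same sentence within 5 tokens; the nearest cue wins,
# with ties broken stop > start (conservative for exposure).

tokenize <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9']+")[[1]]
  toks[nzchar(toks)]
}

split_sentences <- function(x) {
  s <- strsplit(x, "[.;!?\n]+")[[1]]
  s[nzchar(trimws(s))]
}

# start indices (first token) of a phrase within a token vector
find_phrase <- function(toks, ptoks) {
  n <- length(toks); k <- length(ptoks)
  if (n < k) return(integer())
  cand <- which(toks == ptoks[1])
  if (k == 1L) return(cand)
  cand <- cand[cand + k - 1L <= n]
  cand[vapply(cand, function(i) all(toks[i:(i + k - 1L)] == ptoks), TRUE)]
}

compile_lexicons <- function(lex) {
  validate_lexicons(lex)
  toks_of <- function(x) lapply(x, tokenize)
  cues <- data.table::data.table(
    surface = c(lex$stop, lex$start, lex$negation),
    type = c(rep("stop", length(lex$stop)), rep("start", length(lex$start)),
             rep("negation", length(lex$negation)))
  )
  list(
    drug_surface = names(lex$drugs), drug_generic = unname(lex$drugs),
    drug_tokens = toks_of(names(lex$drugs)),
    dx_surface = names(lex$diagnoses), dx_category = unname(lex$diagnoses),
    dx_tokens = toks_of(names(lex$diagnoses)),
    cue_surface = cues$surface, cue_type = cues$type,
    cue_tokens = toks_of(cues$surface)
  )
}

# cue-type priority at equal distance; smaller is stronger
cue_priority <- c(stop = 1L, start = 2L, negation = 3L)

# Resolve the nearest cue (within `span` tokens, same sentence) for each
# target position.  Returns the winning cue type or NA.
attribute_cues <- function(target_pos, cue_pos, cue_type, span = 5L) {
  vapply(target_pos, function(p) {
    if (!length(cue_pos)) return(NA_character_)
    d <- abs(cue_pos - p)
    ok <- d <= span
    if (!any(ok)) return(NA_character_)
    d <- d[ok]; ty <- cue_type[ok]
    o <- order(d, cue_priority[ty])
    ty[o[1]]
  }, NA_character_)
}

# Extract diagnosis assertions and medication references from note texts.
# Returns list(dx = per-note diagnosis events, med = per-note references).
extract_all <- function(notes, clex) {
  n <- nrow(notes)
  if (n == 0L) {
    return(list(
      dx = data.table::data.table(patient_id = character(), date = as.Date(character()),
                                  icd10_category = character(), source = character(),
                                  matched_term = character(), note_id = character()),
      med = data.table::data.table(patient_id = character(), date = as.Date(character()),
                                   drug_name = character(), kind = character(),
                                   note_id = character())
    ))
  }
  lower <- tolower(notes$text)
  # vectorised prefilter: which notes contain each target surface as a
  # substring (whole-word status is confirmed during token matching)
  target_surface <- c(clex$drug_surface, clex$dx_surface)
  hit_mat <- vapply(target_surface, function(s) grepl(s, lower, fixed = TRUE),
                    logical(n))
  if (n == 1L) hit_mat <- matrix(hit_mat, nrow = 1L)
  any_hit <- rowSums(hit_mat) > 0
  n_drug <- length(clex$drug_surface)

  dx_out <- vector("list", n)
  med_out <- vector("list", n)
  for (i in which(any_hit)) {
    drug_idx <- which(hit_mat[i, seq_len(n_drug)])
    dx_idx <- which(hit_mat[i, -seq_len(n_drug)])
    dx_rows <- list(); med_rows <- list()
    for (s in split_sentences(lower[i])) {
      toks <- tokenize(s)
      if (!length(toks)) next
      cpos <- integer(); ctype <- character()
      for (j in seq_along(clex$cue_surface)) {
        p <- find_phrase(toks, clex$cue_tokens[[j]])
        if (length(p)) {
          cpos <- c(cpos, p)
          ctype <- c(ctype, rep(clex$cue_type[j], length(p)))
        }
      }
      for (j in drug_idx) {
        p <- find_phrase(toks, clex$drug_tokens[[j]])
        if (!length(p)) next
        cue <- attribute_cues(p, cpos, ctype)
        kind <- ifelse(is.na(cue), "mention",
                       ifelse(cue == "negation", NA_character_, cue))
        keep <- !is.na(kind)
        if (any(keep)) {
          med_rows[[length(med_rows) + 1L]] <- data.table::data.table(
            drug_name = clex$drug_generic[j], kind = kind[keep])
        }
      }
      for (j in dx_idx) {
        p <- find_phrase(toks, clex$dx_tokens[[j]])
        if (!length(p)) next
        cue <- attribute_cues(p, cpos, ctype)
        asserted <- is.na(cue) | cue != "negation"
        if (any(asserted)) {
          dx_rows[[length(dx_rows) + 1L]] <- data.table::data.table(
            icd10_category = clex$dx_category[j],
            matched_term = clex$dx_surface[j])
        }
      }
    }
    if (length(med_rows)) med_out[[i]] <- data.table::rbindlist(med_rows)
    if (length(dx_rows)) dx_out[[i]] <- data.table::rbindlist(dx_rows)
  }

  bind_with_note <- function(lst) {
    keep <- which(!vapply(lst, is.null, TRUE))
    if (!length(keep)) return(NULL)
    dt <- data.table::rbindlist(lapply(keep, function(i) {
      cbind(lst[[i]],
            data.table::data.table(patient_id = notes$patient_id[i],
                                   date = notes$date[i],
                                   note_id = notes$note_id[i]))
    }))
    dt
  }

  med <- bind_with_note(med_out)
  if (is.null(med)) {
    med <- data.table::data.table(patient_id = character(), date = as.Date(character()),
                                  drug_name = character(), kind = character(),
                                  note_id = character())
  } else {
    # one reference per (drug, note); stop outranks start outranks mention
    pr <- c(stop = 1L, start = 2L, mention = 3L)
    med[, .p := pr[kind]]
    med <- med[order(.p), .SD[1], by = .(note_id, drug_name)]
    med[, .p := NULL]
    med <- med[, .(patient_id, date, drug_name, kind, note_id)]
  }

  dx <- bind_with_note(dx_out)
  if (is.null(dx)) {
    dx <- data.table::data.table(patient_id = character(), date = as.Date(character()),
                                 icd10_category = character(), source = character(),
                                 matched_term = character(), note_id = character())
  } else {
    # one event per (category, note)
    dx <- dx[, .SD[1], by = .(note_id, icd10_category)]
    dx[, source := "text"]
    dx <- dx[, .(patient_id, date, icd10_category, source, matched_term, note_id)]
  }
  list(dx = dx, med = med)
}

#' Extract diagnosis assertions from clinical notes
#'
#' One event per asserted (non-negated) ICD-10 category per note; a term with
#' a negation cue within five tokens in the same sentence is suppressed.
#'
#' @param notes data.table of notes (`note_id`, `patient_id`, `date`, `text`).
#' @param lexicons an `apm_lexicons`.
#' @return data.table: patient_id, date, icd10_category, source ("text"),
#'   matched_term, note_id.
#' @export
extract_diagnoses <- function(notes, lexicons) {
  extract_all(notes, compile_lexicons(lexicons))$dx
}

#' Extract medication references from clinical notes
#'
#' Each antipsychotic hit yields exactly one reference per (drug, note), of
#' kind `stop` if a stop phrase is the nearest cue within five tokens in the
#' sentence, `start` for a start phrase, else `mention`.  Brand names are
#' normalized to generics.
#'
#' @inheritParams extract_diagnoses
#' @return data.table: patient_id, date, drug_name, kind, note_id.
#' @export
extract_medication_references <- function(notes, lexicons) {
  extract_all(notes, compile_lexicons(lexicons))$med
}

icd10_category_of <- function(code) {
  up <- toupper(code)
  ifelse(grepl("^F0[0-3]", up), "F00-F03",
         ifelse(grepl("^F2[0-9]", up), "F20-F29",
                ifelse(grepl("^F", up), "other-F", NA_character_)))
}

check_universe <- function(dt, table_name, universe) {
  if (is.null(universe) || !nrow(dt)) return(invisible())
  bad <- which(!(dt$patient_id %in% universe))
  if (length(bad)) {
    stopf("referential-integrity error: unknown patient_id '%s' in table '%s' (row %d)",
          dt$patient_id[bad[1]], table_name, bad[1])
  }
}

#' Build the unified per-patient event stream
#'
#' Merges structured-field diagnoses with text-derived diagnosis assertions
#' and medication references into one date-sorted stream; duplicates across
#' sources are retained with distinct `source` values.  Forms and episodes
#' are carried through unchanged.  Structured codes outside the ICD-10
#' F chapter are inert and dropped.
#'
#' @param structured_diagnoses data.table: patient_id, date, icd10_code.
#' @param notes data.table of clinical notes.
#' @param forms data.table of monitoring-form records.
#' @param episodes data.table of care episodes.
#' @param lexicons an `apm_lexicons`.
#' @param patients optional patient registry (data.table with `patient_id`);
#'   when supplied, an unknown patient_id in any table is a
#'   referential-integrity error naming the table and row.
#' @return an `event_stream`: list with `events` (patient_id, date,
#'   event_class, detail, kind, source, provenance_id, matched_term), plus
#'   `forms`, `episodes` and the patient universe.
#' @export
build_event_stream <- function(structured_diagnoses, notes, forms, episodes,
                               lexicons = default_lexicons(), patients = NULL) {
  universe <- if (!is.null(patients)) patients$patient_id else NULL
  check_universe(structured_diagnoses, "diagnoses_structured", universe)
  check_universe(notes, "notes", universe)
  check_universe(forms, "forms", universe)
  check_universe(episodes, "episodes", universe)

  sd <- data.table::as.data.table(structured_diagnoses)
  if (nrow(sd)) {
    sd <- sd[, .(patient_id, date, icd10_category = icd10_category_of(icd10_code),
                 provenance_id = sprintf("structured:%06d", .I))]
    sd <- sd[!is.na(icd10_category)]
    sd_ev <- sd[, .(patient_id, date, event_class = "diagnosis",
                    detail = icd10_category, kind = NA_character_,
                    source = "structured", provenance_id,
                    matched_term = NA_character_)]
  } else {
    sd_ev <- NULL
  }

  ex <- extract_all(data.table::as.data.table(notes), compile_lexicons(lexicons))
  dx_ev <- if (nrow(ex$dx)) ex$dx[, .(patient_id, date, event_class = "diagnosis",
                                      detail = icd10_category, kind = NA_character_,
                                      source = "text", provenance_id = note_id,
                                      matched_term)] else NULL
  med_ev <- if (nrow(ex$med)) ex$med[, .(patient_id, date, event_class = "medication",
                                         detail = drug_name, kind,
                                         source = "text", provenance_id = note_id,
                                         matched_term = NA_character_)] else NULL

  events <- data.table::rbindlist(Filter(Negate(is.null), list(sd_ev, dx_ev, med_ev)))
  if (!nrow(events)) {
    events <- data.table::data.table(
      patient_id = character(), date = as.Date(character()),
      event_class = character(), detail = character(), kind = character(),
      source = character(), provenance_id = character(), matched_term = character())
  }
  data.table::setorder(events, patient_id, date, source, provenance_id)
  structure(list(events = events,
                 forms = data.table::as.data.table(forms),
                 episodes = data.table::as.data.table(episodes),
                 patients = universe %||% unique(events$patient_id)),
            class = "event_stream")
}

#' Export an event stream's events table to CSV
#'
#' @param stream an `event_stream`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_events <- function(stream, path) {
  data.table::fwrite(date_cols_to_char(stream$events), path)
  invisible(path)
}
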