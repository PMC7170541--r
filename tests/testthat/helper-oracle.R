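# Independent brute-force re-implementations of every ascertainment rule,
# written as plain row-by-row loops with no shared code with the package
# internals.  Deliberately slow and literal.

oracle_active <- function(episodes, census) {
  out <- character()
  for (i in seq_len(nrow(episodes))) {
    s <- episodes$start_date[i]; e <- episodes$end_date[i]
    if (s <= census && (is.na(e) || e >= census)) {
      out <- c(out, episodes$patient_id[i])
    }
  }
  sort(unique(out))
}

oracle_dementia_index <- function(events, pid, census) {
  best <- as.Date(NA)
  for (i in seq_len(nrow(events))) {
    if (events$patient_id[i] == pid &&
        events$event_class[i] == "diagnosis" &&
        events$detail[i] == "F00-F03" &&
        events$date[i] <= census) {
      if (is.na(best) || events$date[i] < best) best <- events$date[i]
    }
  }
  best
}

oracle_window_refs <- function(events, pid, census, window_days) {
  keep <- integer()
  for (i in seq_len(nrow(events))) {
    if (events$patient_id[i] == pid &&
        events$event_class[i] == "medication" &&
        events$date[i] >= census - window_days &&
        events$date[i] <= census) {
      keep <- c(keep, i)
    }
  }
  events[keep, ]
}

oracle_recent <- function(events, pid, census, window_days, version,
                          min_refs = 2L) {
  refs <- oracle_window_refs(events, pid, census, window_days)
  if (version == "v1") {
    if (nrow(refs) > 0) return(list(flag = TRUE, reason = "none"))
    return(list(flag = FALSE, reason = "no_recent_use"))
  }
  if (nrow(refs) == 0) return(list(flag = FALSE, reason = "no_recent_use"))
  if (nrow(refs) < min_refs) return(list(flag = FALSE, reason = "single_reference"))
  ok <- FALSE
  for (d in unique(refs$detail)) {
    dref <- refs[refs$detail == d, ]
    if (!any(dref$kind == "stop")) ok <- TRUE
  }
  if (ok) list(flag = TRUE, reason = "none") else list(flag = FALSE, reason = "stopped")
}

oracle_cohort <- function(events, episodes, spec_list) {
  census <- spec_list$census_date
  universe <- sort(unique(c(events$patient_id, episodes$patient_id)))
  active <- oracle_active(episodes, census)
  out <- data.frame(patient_id = universe, included = FALSE,
                    exclusion_reason = "not_active",
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    pid <- out$patient_id[r]
    if (!(pid %in% active)) next
    d_idx <- oracle_dementia_index(events, pid, census)
    if (is.na(d_idx)) {
      out$exclusion_reason[r] <- "no_dementia"
      next
    }
    ru <- oracle_recent(events, pid, census, spec_list$window_days,
                        spec_list$algorithm_version,
                        spec_list$min_references_v2)
    out$included[r] <- ru$flag
    out$exclusion_reason[r] <- ru$reason
    if (!ru$flag) next
    if (isTRUE(spec_list$sensitivity_mode)) {
      psych <- FALSE; other <- FALSE
      for (i in seq_len(nrow(events))) {
        if (events$patient_id[i] != pid) next
        if (events$event_class[i] != "diagnosis") next
        if (events$date[i] > census) next
        if (events$detail[i] == "F20-F29") psych <- TRUE
        if (events$detail[i] != "F00-F03" && events$date[i] > d_idx) other <- TRUE
      }
      if (psych) {
        out$included[r] <- FALSE; out$exclusion_reason[r] <- "psychosis_ever"
      } else if (other) {
        out$included[r] <- FALSE; out$exclusion_reason[r] <- "other_dx_after_index"
      }
    }
  }
  out
}

oracle_form_flag <- function(forms, pid, census, validity) {
  for (i in seq_len(nrow(forms))) {
    if (forms$patient_id[i] == pid &&
        forms$date[i] >= census - validity &&
        forms$date[i] <= census) return(TRUE)
  }
  FALSE
}

oracle_reverse <- function(events, episodes, forms, spec_list) {
  census <- spec_list$census_date
  active <- oracle_active(episodes, census)
  denom <- character()
  for (pid in active) {
    d_idx <- oracle_dementia_index(events, pid, census)
    if (is.na(d_idx)) next
    ru <- oracle_recent(events, pid, census, spec_list$window_days,
                        spec_list$algorithm_version,
                        spec_list$min_references_v2)
    if (!ru$flag) denom <- c(denom, pid)
  }
  numer <- 0L
  for (pid in denom) {
    if (oracle_form_flag(forms, pid, census, spec_list$form_validity_days)) {
      numer <- numer + 1L
    }
  }
  list(n_denom = length(denom), n_numer = numer)
}

# Exhaustive span-attribution oracle for one note text: cues attribute only
# within the same sentence (split at . ; ! ?) and within 5 tokens; for every
# drug occurrence, enumerate all cue occurrences and distances and apply the
# nearest-cue rule with the stop > start priority at ties.  Per-note dedup
# keeps one row per drug, stop outranking start outranking mention.
oracle_attribution <- function(text, lex) {
  hits <- list()
  for (sent in strsplit(tolower(text), "[.;!?\n]+")[[1]]) {
    toks <- strsplit(sent, "[^a-z0-9']+")[[1]]
    toks <- toks[nzchar(toks)]
    cues <- list()
    for (s in lex$stop) if (s %in% toks) {
      for (p in which(toks == s)) cues[[length(cues) + 1]] <- list(pos = p, type = "stop")
    }
    for (s in lex$start) if (s %in% toks) {
      for (p in which(toks == s)) cues[[length(cues) + 1]] <- list(pos = p, type = "start")
    }
    for (i in seq_along(lex$drugs)) {
      surf <- names(lex$drugs)[i]
      for (p in which(toks == surf)) {
        best_d <- Inf; best_type <- "mention"
        for (cue in cues) {
          d <- abs(cue$pos - p)
          if (d > 5) next
          better <- d < best_d ||
            (d == best_d && cue$type == "stop" && best_type != "stop")
          if (better) { best_d <- d; best_type <- cue$type }
        }
        hits[[length(hits) + 1]] <- data.frame(drug = unname(lex$drugs[i]),
                                               kind = best_type,
                                               stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(data.frame(drug = character(), kind = character()))
  all_hits <- do.call(rbind, hits)
  pr <- c(stop = 1, start = 2, mention = 3)
  out <- do.call(rbind, lapply(split(all_hits, all_hits$drug), function(g) {
    g[order(pr[g$kind]), , drop = FALSE][1, ]
  }))
  rownames(out) <- NULL
  out
}
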