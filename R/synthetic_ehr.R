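# Synthetic EHR generator.
#
# The bundle models a dementia caseload under monthly census surveillance.
# Every patient carries a dementia diagnosis (structured F00-F03 code and/or
# a free-text assertion); a configured fraction is truly exposed to one
# antipsychotic over one interval; notes document exposure via templated
# sentences so that downstream lexicon extraction is exactly analysable.
# Ground truth (latent exposure intervals, comorbidity flags) is carried
# separately and is never read by the pipeline proper.

dx_structured_codes <- c("F00.1", "F01.9", "F02.8", "F03")
psychosis_codes <- c("F20.0", "F22", "F25.1", "F29")
other_dx_codes <- c("F32.1", "F31.9", "F41.1")

note_templates <- list(
  dx_assert = c(
    "Diagnosis of %s confirmed at memory clinic.",
    "Assessment today consistent with %s.",
    "He has an established diagnosis of %s."
  ),
  dx_negated = c(
    "No evidence of %s at review today.",
    "Denies hallucinations; %s not suspected."
  ),
  med_mention = c(
    "Remains on %s at night with good effect.",
    "%s 0.5mg continues, tolerated well.",
    "Medication reviewed; continues %s at current dose."
  ),
  med_start = c(
    "Started %s for distressing agitation.",
    "%s commenced after discussion with family.",
    "Plan: initiated %s at low dose."
  ),
  med_stop = c(
    "%s stopped due to sedation.",
    "%s discontinued following review.",
    "Review outcome: %s to be ceased this week."
  ),
  distractor = c(
    "Home visit completed, patient settled.",
    "Routine physical health checks arranged.",
    "Continues donepezil 10mg each morning.",
    "Family meeting held to discuss care plan.",
    "Sleep chart reviewed, appetite fair.",
    "Carer reports a quiet week at the placement."
  )
)

cap_first <- function(x) {
  substr(x, 1, 1) <- toupper(substr(x, 1, 1))
  x
}

# Vectorised note text rendering from a facts table.  `fact_class` selects the
# template family; `term` is the surface form substituted into the template.
render_note_text <- function(fact_class, term) {
  fam <- c(dx_assert = "dx_assert", dx_negated = "dx_negated",
           mention = "med_mention", start = "med_start", stop = "med_stop",
           distractor = "distractor")[fact_class]
  if (anyNA(fam)) stopf("unknown fact class '%s'", fact_class[is.na(fam)][1])
  out <- character(length(fact_class))
  for (f in unique(fam)) {
    i <- which(fam == f)
    tpl <- note_templates[[f]]
    pick <- tpl[sample.int(length(tpl), length(i), replace = TRUE)]
    if (f == "distractor") {
      out[i] <- pick
    } else {
      starts_with_term <- startsWith(pick, "%s")
      txt <- sprintf(pick, term[i])
      txt[starts_with_term] <- cap_first(txt[starts_with_term])
      out[i] <- txt
    }
  }
  out
}

#' Render a single clinical note from a planned fact
#'
#' One templated sentence embedding the planted fact, plus the plant record
#' that downstream extraction is scored against.  The bulk generator uses the
#' same template tables vectorised; this is the one-note API.  Draws from the
#' current RNG stream.
#'
#' @param patient_state list with `patient_id`, `team_id`, and `fact`: a list
#'   with `class` (one of `dx_assert`, `dx_negated`, `mention`, `start`,
#'   `stop`, `distractor`), `term` (surface form to embed; ignored for
#'   distractors) and `detail` (ICD-10 block or generic drug name recorded in
#'   the plant).
#' @param date note date.
#' @param lexicons an `apm_lexicons` object (validated; the templates only
#'   embed terms drawn from it).
#' @return list with `note` (one-row data.table: note_id, patient_id, date,
#'   team_id, text) and `plant` (one-row data.table of the planted fact;
#'   empty for distractors).
#' @export
render_note <- function(patient_state, date, lexicons) {
  validate_lexicons(lexicons)
  fact <- patient_state$fact
  text <- render_note_text(fact$class, fact$term %||% "")
  note <- data.table::data.table(
    note_id = patient_state$note_id %||% "N000001",
    patient_id = patient_state$patient_id,
    date = as_iso_date(date),
    team_id = patient_state$team_id %||% "T-01",
    text = text
  )
  plant <- if (fact$class == "distractor") {
    empty_plants()
  } else {
    data.table::data.table(
      note_id = note$note_id, patient_id = note$patient_id, date = note$date,
      fact_class = if (fact$class %in% c("dx_assert", "dx_negated")) "diagnosis" else "medication",
      detail = fact$detail,
      kind = switch(fact$class, dx_assert = "assert", dx_negated = "negated",
                    fact$class)
    )
  }
  list(note = note, plant = plant)
}

empty_plants <- function() {
  data.table::data.table(note_id = character(), patient_id = character(),
                         date = as.Date(character()), fact_class = character(),
                         detail = character(), kind = character())
}

empty_bundle <- function(config) {
  structure(list(
    patients = data.table::data.table(patient_id = character(), birth_year = integer()),
    episodes = data.table::data.table(patient_id = character(), team_id = character(),
                                      setting = character(),
                                      start_date = as.Date(character()),
                                      end_date = as.Date(character())),
    notes = data.table::data.table(note_id = character(), patient_id = character(),
                                   date = as.Date(character()), team_id = character(),
                                   text = character()),
    structured_diagnoses = data.table::data.table(patient_id = character(),
                                                  date = as.Date(character()),
                                                  icd10_code = character()),
    forms = data.table::data.table(form_id = character(), patient_id = character(),
                                   date = as.Date(character()), form_type = character(),
                                   team_id = character()),
    ground_truth = list(
      patients = data.table::data.table(patient_id = character(), has_dementia = logical(),
                                        dementia_onset = as.Date(character()),
                                        has_psychosis = logical(),
                                        post_index_other_dx = logical(),
                                        exposed = logical(), sparse_documenter = logical()),
      exposures = data.table::data.table(patient_id = character(), drug_name = character(),
                                         start = as.Date(character()),
                                         end = as.Date(character()))
    ),
    plants = empty_plants(),
    config = config
  ), class = "ehr_bundle")
}

make_teams <- function(n_teams) {
  n_com <- max(1L, ceiling(n_teams * 0.6))
  n_ch <- max(0L, floor((n_teams - n_com) / 2))
  n_in <- n_teams - n_com - n_ch
  data.table::data.table(
    team_id = c(sprintf("CMHT-%02d", seq_len(n_com)),
                if (n_ch > 0) sprintf("CHIT-%02d", seq_len(n_ch)),
                if (n_in > 0) sprintf("WARD-%02d", seq_len(n_in))),
    setting = c(rep("community", n_com), rep("care_home", n_ch),
                rep("inpatient", n_in))
  )
}

#' Generate a synthetic EHR bundle
#'
#' Deterministic for a fixed config (including seed).  See
#' [generator_config()] for the stated population: exposure prevalence,
#' psychosis comorbidity, the form-adoption ramp, and the documentation-noise
#' knobs.  Ground truth is returned alongside the observable tables but is
#' intended only for scoring, never as pipeline input.
#'
#' @param config a `generator_config`.
#' @param lexicons an `apm_lexicons`; the generator only embeds terms the
#'   extractor knows.
#' @return an `ehr_bundle`: list with data.tables `patients`, `episodes`,
#'   `notes`, `structured_diagnoses`, `forms`, the `ground_truth` list
#'   (`patients`, `exposures`), the note-level `plants` table, and `config`.
#' @export
generate_bundle <- function(config, lexicons = default_lexicons()) {
  validate_generator_config(config)
  validate_lexicons(lexicons)
  if (config$n_patients == 0L) return(empty_bundle(config))
  set.seed(config$seed)

  n <- config$n_patients
  d0 <- config$start_date
  d1 <- config$end_date
  span <- as.integer(d1 - d0)
  censuses <- monthly_censuses(config$census_start, config$census_end)
  months <- seq(as.Date(format(d0, "%Y-%m-01")), d1, by = "1 month")

  teams <- make_teams(config$n_teams)
  patients <- data.table::data.table(
    patient_id = sprintf("P%04d", seq_len(n)),
    birth_year = sample(1925:1950, n, replace = TRUE)
  )
  team_of <- teams[sample.int(nrow(teams), n, replace = TRUE)]

  # one care episode per patient; most span the whole record (open-ended)
  full <- runif(n) < config$active_frac
  ep_start <- rep(d0, n)
  ep_end <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  short_start <- d0 + floor(runif(n, 0, max(span - 60, 1)))
  short_end <- pmin(short_start + 60 + floor(runif(n, 0, 340)), d1)
  ep_start[!full] <- short_start[!full]
  ep_end[!full] <- short_end[!full]
  episodes <- data.table::data.table(
    patient_id = patients$patient_id, team_id = team_of$team_id,
    setting = team_of$setting, start_date = ep_start, end_date = ep_end
  )

  ## ground-truth latent state ------------------------------------------------
  onset <- d0 + floor(runif(n, 0, 180))
  text_only <- runif(n) < config$text_only_dx_frac
  has_psy <- runif(n) < config$psychosis_comorbidity
  has_other <- runif(n) < config$other_dx_rate
  exposed <- runif(n) < config$antipsychotic_prevalence
  sparse <- exposed & (runif(n) < config$mention_noise)
  stopped <- exposed & (runif(n) < config$stop_rate)

  generics <- antipsychotic_generics(lexicons)
  common <- c("risperidone", "quetiapine", "olanzapine", "haloperidol")
  wts <- ifelse(generics %in% common, 5, 1)
  drug <- sample(generics, n, replace = TRUE, prob = wts)

  exp_start <- d0 + floor(runif(n, 0, max(span - 120, 1)))
  exp_end <- rep(d1, n)
  if (any(stopped)) {
    idx <- which(stopped)
    dur <- 60 + floor(runif(length(idx), 0, 340))
    ee <- pmin(exp_start[idx] + dur, d1 - 7)
    # if capping squeezes the interval away, treat as ongoing instead
    ok <- ee > exp_start[idx]
    stopped[idx[!ok]] <- FALSE
    exp_end[idx[ok]] <- ee[ok]
  }

  gt_patients <- data.table::data.table(
    patient_id = patients$patient_id, has_dementia = TRUE,
    dementia_onset = onset, has_psychosis = has_psy,
    post_index_other_dx = has_other, exposed = exposed,
    sparse_documenter = sparse
  )
  gt_exposures <- data.table::data.table(
    patient_id = patients$patient_id[exposed], drug_name = drug[exposed],
    start = exp_start[exposed], end = exp_end[exposed]
  )

  ## structured diagnoses -----------------------------------------------------
  sd_list <- list(
    data.table::data.table(
      patient_id = patients$patient_id[!text_only], date = onset[!text_only],
      icd10_code = sample(dx_structured_codes, sum(!text_only), replace = TRUE)
    ),
    data.table::data.table(
      patient_id = patients$patient_id[has_psy],
      date = d0 + floor(runif(sum(has_psy), 0, 90)),
      icd10_code = sample(psychosis_codes, sum(has_psy), replace = TRUE)
    ),
    data.table::data.table(
      patient_id = patients$patient_id[has_other],
      date = pmin(onset[has_other] + 30 + floor(runif(sum(has_other), 0, 270)), d1),
      icd10_code = sample(other_dx_codes, sum(has_other), replace = TRUE)
    )
  )
  structured_diagnoses <- data.table::rbindlist(sd_list)

  ## planned note facts -------------------------------------------------------
  dementia_terms <- names(lexicons$diagnoses)[lexicons$diagnoses == "F00-F03"]
  psychosis_terms <- names(lexicons$diagnoses)[lexicons$diagnoses == "F20-F29"]

  facts <- list()
  # every patient gets a diagnosis assertion note at onset (the text pathway;
  # for text_only patients it is the only record of dementia)
  facts$dx <- data.table::data.table(
    patient_id = patients$patient_id, team_id = team_of$team_id, date = onset,
    fact_class = "dx_assert",
    term = sample(dementia_terms, n, replace = TRUE),
    detail = "F00-F03", kind = "assert"
  )

  # medication notes: a same-day pair at exposure start (start phrase +
  # plain mention), then a 28-day mention cadence; sparse documenters get a
  # 150-day cadence and no pair.  A documented stop closes the interval.
  med_facts <- function(i) {
    pid <- patients$patient_id[i]; tid <- team_of$team_id[i]
    dg <- drug[i]; es <- exp_start[i]; ee <- exp_end[i]
    if (sparse[i]) {
      dts <- seq(es, ee, by = 150)
      kinds <- rep("mention", length(dts))
    } else {
      dts <- c(es, es, if (es + 28 <= ee) seq(es + 28, ee, by = 28))
      kinds <- c("start", rep("mention", length(dts) - 1L))
    }
    if (stopped[i]) {
      dts <- c(dts, ee)
      kinds <- c(kinds, "stop")
    }
    data.table::data.table(patient_id = pid, team_id = tid, date = dts,
                           fact_class = kinds, term = dg, detail = dg,
                           kind = kinds)
  }
  if (any(exposed)) {
    facts$med <- data.table::rbindlist(lapply(which(exposed), med_facts))
  }

  # negated psychosis screens: per patient-month with prob negation_rate
  if (config$negation_rate > 0) {
    grid <- data.table::CJ(i = seq_len(n), m = seq_along(months))
    grid <- grid[runif(nrow(grid)) < config$negation_rate]
    if (nrow(grid)) {
      facts$neg <- data.table::data.table(
        patient_id = patients$patient_id[grid$i],
        team_id = team_of$team_id[grid$i],
        date = pmin(months[grid$m] + sample(0:27, nrow(grid), replace = TRUE), d1),
        fact_class = "dx_negated",
        term = sample(psychosis_terms, nrow(grid), replace = TRUE),
        detail = "F20-F29", kind = "negated"
      )
    }
  }

  # background distractor notes
  if (config$note_rate > 0) {
    k <- stats::rpois(n * length(months), config$note_rate)
    idx <- rep(seq_len(n * length(months)), k)
    if (length(idx)) {
      i <- ((idx - 1L) %% n) + 1L
      m <- ((idx - 1L) %/% n) + 1L
      facts$bg <- data.table::data.table(
        patient_id = patients$patient_id[i], team_id = team_of$team_id[i],
        date = pmin(months[m] + sample(0:27, length(idx), replace = TRUE), d1),
        fact_class = "distractor", term = "", detail = "", kind = ""
      )
    }
  }

  facts <- data.table::rbindlist(facts, use.names = TRUE)
  facts <- facts[date >= d0 & date <= d1]
  data.table::setorder(facts, patient_id, date, fact_class, term)
  facts[, note_id := sprintf("N%06d", .I)]
  facts[, text := render_note_text(fact_class, term)]

  notes <- facts[, .(note_id, patient_id, date, team_id, text)]
  plants <- facts[fact_class != "distractor",
                  .(note_id, patient_id, date,
                    fact_class = ifelse(fact_class %in% c("dx_assert", "dx_negated"),
                                        "diagnosis", "medication"),
                    detail,
                    kind = ifelse(fact_class == "dx_assert", "assert",
                                  ifelse(fact_class == "dx_negated", "negated", kind)))]

  ## monitoring forms: latent adoption-threshold ramp -------------------------
  # a patient starts completing monthly forms once the ramp probability
  # passes their latent uniform, so the measured per-census completion
  # fraction tracks the configured ramp under any validity lookback >= 1 month
  n_cen <- length(censuses)
  ramp <- seq(config$form_completion_start, config$form_completion_end,
              length.out = n_cen)
  u <- runif(n)
  forms_list <- list()
  for (i in which(exposed)) {
    from <- which(ramp >= u[i])[1]
    if (is.na(from)) next
    cen_months <- censuses[from:n_cen]
    dts <- as.Date(format(cen_months, "%Y-%m-01")) +
      sample(0:27, length(cen_months), replace = TRUE)
    forms_list[[length(forms_list) + 1L]] <- data.table::data.table(
      patient_id = patients$patient_id[i], date = dts,
      form_type = c("initiation", rep("review", length(dts) - 1L)),
      team_id = team_of$team_id[i]
    )
  }
  # stray forms for non-exposed patients (algorithm false-negative fodder
  # for the reverse check)
  stray <- which(!exposed & runif(n) < config$offlabel_form_rate)
  for (i in stray) {
    m <- sample.int(n_cen, 1L)
    forms_list[[length(forms_list) + 1L]] <- data.table::data.table(
      patient_id = patients$patient_id[i],
      date = as.Date(format(censuses[m], "%Y-%m-01")) + sample(0:27, 1L),
      form_type = "review", team_id = team_of$team_id[i]
    )
  }
  if (length(forms_list)) {
    forms <- data.table::rbindlist(forms_list)
    data.table::setorder(forms, patient_id, date)
    forms[, form_id := sprintf("FRM%06d", .I)]
    data.table::setcolorder(forms, c("form_id", "patient_id", "date",
                                     "form_type", "team_id"))
  } else {
    forms <- empty_bundle(config)$forms
  }

  structure(list(
    patients = patients, episodes = episodes, notes = notes,
    structured_diagnoses = structured_diagnoses, forms = forms,
    ground_truth = list(patients = gt_patients, exposures = gt_exposures),
    plants = plants, config = config
  ), class = "ehr_bundle")
}
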