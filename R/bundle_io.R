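# Bundle serialization: one CSV per tabular entity, notes as JSON-lines,
# ground truth as JSON.  Re-reading reproduces the bundle exactly.

bundle_files <- c(patients = "patients.csv", episodes = "episodes.csv",
                  diagnoses = "diagnoses_structured.csv", notes = "notes.jsonl",
                  forms = "forms.csv", ground_truth = "ground_truth.json",
                  plants = "plants.csv", config = "config.txt")

validate_bundle <- function(bundle) {
  cfg <- bundle$config
  d0 <- cfg$start_date; d1 <- cfg$end_date
  chk <- function(dates, what) {
    dates <- dates[!is.na(dates)]
    if (length(dates) && (min(dates) < d0 || max(dates) > d1)) {
      stopf("bundle validation error: %s date outside config bounds [%s, %s]",
            what, d0, d1)
    }
  }
  chk(bundle$notes$date, "note")
  chk(bundle$forms$date, "form")
  chk(bundle$structured_diagnoses$date, "structured diagnosis")
  ep <- bundle$episodes
  if (nrow(ep)) {
    bad <- !is.na(ep$end_date) & ep$start_date > ep$end_date
    if (any(bad)) stopf("bundle validation error: episode start after end (row %d)",
                        which(bad)[1])
  }
  if (anyDuplicated(bundle$patients$patient_id)) {
    stopf("bundle validation error: duplicate patient_id")
  }
  invisible(bundle)
}

date_cols_to_char <- function(dt) {
  dt <- data.table::copy(dt)
  for (col in names(dt)) {
    if (inherits(dt[[col]], "Date")) data.table::set(dt, j = col, value = format(dt[[col]]))
  }
  dt
}

#' Write an EHR bundle to a directory
#'
#' Tabular entities as CSV, notes as JSON-lines, ground truth and plants in
#' separate files that the pipeline proper never reads, and the generator
#' config as a flat-key file.  The bundle is validated (dates within config
#' bounds, episode intervals well formed) before anything is written.
#'
#' @param bundle an `ehr_bundle`.
#' @param output_dir directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_bundle <- function(bundle, output_dir) {
  validate_bundle(bundle)
  if (!dir.exists(output_dir) && !dir.create(output_dir, recursive = TRUE)) {
    stopf("cannot create output directory '%s'", output_dir)
  }
  p <- function(f) file.path(output_dir, bundle_files[[f]])
  data.table::fwrite(date_cols_to_char(bundle$patients), p("patients"))
  data.table::fwrite(date_cols_to_char(bundle$episodes), p("episodes"))
  data.table::fwrite(date_cols_to_char(bundle$structured_diagnoses), p("diagnoses"))
  data.table::fwrite(date_cols_to_char(bundle$forms), p("forms"))
  data.table::fwrite(date_cols_to_char(bundle$plants), p("plants"))
  con <- file(p("notes"), open = "wb")
  on.exit(close(con))
  if (nrow(bundle$notes)) {
    jsonlite::stream_out(as.data.frame(date_cols_to_char(bundle$notes)), con,
                         verbose = FALSE)
  }
  gt <- list(patients = as.data.frame(date_cols_to_char(bundle$ground_truth$patients)),
             exposures = as.data.frame(date_cols_to_char(bundle$ground_truth$exposures)))
  jsonlite::write_json(gt, p("ground_truth"), dataframe = "rows", digits = NA)
  write_generator_config(bundle$config, p("config"))
  invisible(output_dir)
}

read_csv_dates <- function(path, date_cols) {
  dt <- data.table::fread(path, colClasses = "character")
  for (col in intersect(date_cols, names(dt))) {
    data.table::set(dt, j = col,
                    value = as.Date(ifelse(nzchar(dt[[col]]), dt[[col]], NA)))
  }
  dt
}

#' Read an EHR bundle from a directory
#'
#' Inverse of [write_bundle()]: field-for-field equal to the written bundle.
#'
#' @param dir directory written by [write_bundle()].
#' @return an `ehr_bundle`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) {
    fp <- file.path(dir, bundle_files[[f]])
    if (!file.exists(fp)) stopf("missing bundle file '%s' in '%s'",
                                bundle_files[[f]], dir)
    fp
  }
  cfg <- read_generator_config(p("config"))
  patients <- read_csv_dates(p("patients"), character())
  patients[, birth_year := as.integer(birth_year)]
  notes_path <- p("notes")
  notes <- if (file.size(notes_path) > 0) {
    nd <- jsonlite::stream_in(file(notes_path), verbose = FALSE)
    nd <- data.table::as.data.table(nd)
    nd[, date := as.Date(date)]
    nd
  } else empty_bundle(cfg)$notes
  gt_raw <- jsonlite::read_json(p("ground_truth"), simplifyVector = TRUE)
  gt_p <- data.table::as.data.table(gt_raw$patients)
  gt_e <- data.table::as.data.table(gt_raw$exposures)
  if (nrow(gt_p)) gt_p[, dementia_onset := as.Date(dementia_onset)] else
    gt_p <- empty_bundle(cfg)$ground_truth$patients
  if (nrow(gt_e)) {
    gt_e[, start := as.Date(start)][, end := as.Date(end)]
  } else gt_e <- empty_bundle(cfg)$ground_truth$exposures
  structure(list(
    patients = patients,
    episodes = read_csv_dates(p("episodes"), c("start_date", "end_date")),
    notes = notes,
    structured_diagnoses = read_csv_dates(p("diagnoses"), "date"),
    forms = read_csv_dates(p("forms"), "date"),
    ground_truth = list(patients = gt_p, exposures = gt_e),
    plants = read_csv_dates(p("plants"), "date"),
    config = cfg
  ), class = "ehr_bundle")
}

#' Hash a bundle's serialized form
#'
#' Writes the bundle to a temporary directory and returns the md5 of every
#' file; used to assert byte-identical seeded determinism.
#'
#' @param bundle an `ehr_bundle`.
#' @return named character vector of md5 digests.
#' @export
bundle_hash <- function(bundle) {
  td <- tempfile("bundlehash")
  on.exit(unlink(td, recursive = TRUE))
  write_bundle(bundle, td)
  files <- sort(list.files(td, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- basename(names(h))
  h
}
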