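# Lexicons are shipped as editable plain-text "surface = value" files under
# inst/extdata/lexicons and loaded into named character vectors.

read_lexicon_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^(.*?)\\s*=\\s*(.*)$", lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stopf("malformed lexicon line in %s: '%s'", path, lines[bad][1])
  vals <- vapply(m, `[`, "", 3L)
  names(vals) <- tolower(vapply(m, `[`, "", 2L))
  vals
}

#' Load the extraction lexicons
#'
#' Reads the antipsychotic dictionary (surface -> generic), the diagnosis
#' lexicon (surface -> ICD-10 category block) and the context cues
#' (start / stop / negation phrases) from plain-text files.  Defaults to the
#' files shipped with the package; point `dir` at a copy to customise.
#'
#' @param dir directory holding `drugs.txt`, `diagnoses.txt`, `context.txt`.
#' @return an object of class `apm_lexicons`: a list with elements `drugs`,
#'   `diagnoses` (named character vectors, names are lower-case surface
#'   forms), and `start`, `stop`, `negation` (character vectors of phrases).
#' @export
default_lexicons <- function(dir = system.file("extdata", "lexicons",
                                               package = "apmonitor")) {
  drugs <- read_lexicon_file(file.path(dir, "drugs.txt"))
  dx <- read_lexicon_file(file.path(dir, "diagnoses.txt"))
  ctx <- read_lexicon_file(file.path(dir, "context.txt"))
  lex <- list(
    drugs = drugs,
    diagnoses = dx,
    start = names(ctx)[ctx == "start"],
    stop = names(ctx)[ctx == "stop"],
    negation = names(ctx)[ctx == "negation"]
  )
  validate_lexicons(lex)
  structure(lex, class = "apm_lexicons")
}

validate_lexicons <- function(lex) {
  for (f in c("drugs", "diagnoses", "start", "stop", "negation")) {
    if (is.null(lex[[f]]) || length(lex[[f]]) == 0) {
      stopf("lexicon '%s' is empty", f)
    }
  }
  blocks <- unique(unname(lex$diagnoses))
  ok <- blocks %in% c("F00-F03", "F20-F29", "other-F")
  if (!all(ok)) stopf("unknown diagnosis block '%s'", blocks[!ok][1])
  invisible(lex)
}

# generic names only (deduplicated), used by the generator
antipsychotic_generics <- function(lex) sort(unique(unname(lex$drugs)))
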