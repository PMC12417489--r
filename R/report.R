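#' Canonical clinical report sections
#'
#' The 15 section headers used in the clinical EEG report corpus this
#' pipeline targets, in their conventional order of appearance. Keys are
#' snake_case identifiers; the display form is the upper-case header with
#' underscores replaced by spaces (e.g. `description_of_the_record` ->
#' `"DESCRIPTION OF THE RECORD:"`).
#'
#' @return named character vector mapping canonical keys to display headers.
#' @export
report_sections <- function() {
  keys <- c("clinical_history", "medications", "introduction",
            "description_of_the_record", "impression",
            "clinical_correlation", "heart_rate", "findings",
            "reason_for_study", "technical_difficulties", "events",
            "condition_of_the_recording", "past_medical_history",
            "type_of_study", "activation_procedures")
  stats::setNames(gsub("_", " ", toupper(keys)), keys)
}

# Default header alias table: maps upper-case header text (without the
# trailing colon) to a canonical key. Real-world headers vary; the alias
# table is configurable through parse_report(aliases = ...).
default_section_aliases <- function() {
  c("DESCRIPTION" = "description_of_the_record",
    "HISTORY" = "clinical_history",
    "CORRELATION" = "clinical_correlation",
    "MEDICATION" = "medications",
    "HR" = "heart_rate",
    "TECHNICAL DIFFICULTY" = "technical_difficulties",
    "CONDITION OF THE RECORD" = "condition_of_the_recording")
}

#' Clinical report container
#'
#' An ordered map from the 15 canonical section keys (see
#' [report_sections()]) to text, plus a reserved `preamble` slot for text
#' appearing before any recognized header.
#'
#' @param sections named list/character of section texts; names must be
#'   canonical keys (or `preamble`). Missing sections are filled empty.
#' @return object of class `clinical_report`.
#' @export
new_clinical_report <- function(sections = list()) {
  keys <- names(report_sections())
  out <- stats::setNames(as.list(rep("", length(keys) + 1L)),
                         c("preamble", keys))
  if (length(sections)) {
    bad <- setdiff(names(sections), names(out))
    if (length(bad)) stop("unknown section key(s): ", paste(bad, collapse = ", "))
    out[names(sections)] <- lapply(sections, as.character)
  }
  structure(list(sections = out), class = "clinical_report")
}

#' @export
print.clinical_report <- function(x, ...) {
  nonempty <- names(x$sections)[nzchar(trimws(unlist(x$sections)))]
  cat("<clinical_report: ", length(nonempty), " non-empty section(s): ",
      paste(nonempty, collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Parse raw report text into sections
#'
#' Scans the text for canonical headers (case-insensitive, colon-terminated,
#' at the start of a line); the text between one header and the next is
#' assigned to that header's section. Text before the first header goes to
#' the reserved `preamble` slot; headerless text is therefore all preamble.
#' A header appearing twice has its contents concatenated in order.
#'
#' @param raw plain-text report string.
#' @param aliases named character vector mapping extra upper-case header
#'   spellings (no colon) to canonical keys, merged over
#'   the built-in alias table.
#' @return a `clinical_report`.
#' @export
parse_report <- function(raw, aliases = character()) {
  stopifnot(is.character(raw), length(raw) == 1L)
  canon <- report_sections()
  amap <- c(stats::setNames(names(canon), unname(canon)),
            default_section_aliases())
  if (length(aliases)) amap[names(aliases)] <- aliases
  headers <- names(amap)
  # longest-first so e.g. "DESCRIPTION OF THE RECORD" wins over "DESCRIPTION"
  headers <- headers[order(-nchar(headers))]
  pat <- paste0("(?mi)^[ \\t]*(",
                paste(gsub("([][{}()+*^$|?.\\\\])", "\\\\\\1", headers,
                           perl = TRUE),
                      collapse = "|"),
                ")[ \\t]*:")
  m <- gregexpr(pat, raw, perl = TRUE)[[1]]
  rep_out <- new_clinical_report()
  if (m[1] == -1) {
    rep_out$sections$preamble <- trimws(raw)
    return(rep_out)
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  pre <- trimws(substr(raw, 1L, starts[1] - 1L))
  if (nzchar(pre)) rep_out$sections$preamble <- pre
  bounds <- c(starts, nchar(raw) + 1L)
  for (i in seq_along(starts)) {
    hdr_txt <- substr(raw, starts[i], starts[i] + lens[i] - 1L)
    hdr_key <- amap[[toupper(trimws(sub(":[ \\t]*$", "", trimws(hdr_txt))))]]
    body <- trimws(substr(raw, starts[i] + lens[i], bounds[i + 1L] - 1L))
    cur <- rep_out$sections[[hdr_key]]
    rep_out$sections[[hdr_key]] <-
      if (nzchar(cur)) paste(cur, body, sep = " ") else body
  }
  rep_out
}

#' Render a clinical report back to text
#'
#' Inverse of [parse_report()]: writes each non-empty section as its display
#' header followed by the section text, one section per paragraph. The
#' round-trip `parse_report(render_report(x))` is the identity on section
#' contents.
#'
#' @param rep a `clinical_report`.
#' @return a single string.
#' @export
render_report <- function(rep) {
  canon <- report_sections()
  parts <- character(0)
  pre <- rep$sections$preamble
  if (nzchar(trimws(pre))) parts <- c(parts, trimws(pre))
  for (key in names(canon)) {
    txt <- trimws(rep$sections[[key]])
    if (nzchar(txt)) parts <- c(parts, paste0(canon[[key]], ": ", txt))
  }
  paste(parts, collapse = "\n")
}

#' Select and concatenate report sections
#'
#' Joins the non-empty selected sections with single blank lines, preserving
#' the canonical section order. With `names = "all"` every section
#' (including the preamble) is used. The result may be the empty string if
#' all selected sections are empty; callers pairing text with EEG windows
#' must drop such recordings.
#'
#' @param rep a `clinical_report`.
#' @param names character vector of canonical keys, or `"all"`.
#' @return a single string.
#' @export
select_sections <- function(rep, names = "all") {
  keys <- base::names(report_sections())
  if (identical(names, "all")) {
    sel <- c("preamble", keys)
  } else {
    bad <- setdiff(names, keys)
    if (length(bad)) stop("unknown section key(s): ", paste(bad, collapse = ", "))
    sel <- keys[keys %in% names]   # canonical order regardless of input order
  }
  txt <- trimws(unlist(rep$sections[sel]))
  paste(txt[nzchar(txt)], collapse = "\n\n")
}

#' Anticonvulsant keywords used for the medication label
#' @return lower-case character vector.
#' @export
medication_keywords <- function() c("keppra", "dilantin", "depakote")

#' Derive the four decoding-task labels
#'
#' Builds the binary label set used throughout evaluation:
#' * `pathological` — copied from metadata.
#' * `age_over_50` — `TRUE` iff `age > 50` (age exactly 50 falls in the
#'   "under or equal" class).
#' * `gender` — `"M"`/`"F"` from metadata.
#' * `medication` — `TRUE` iff the report contains at least one of the three
#'   common anticonvulsants (`keppra`, `dilantin`, `depakote`),
#'   case-insensitive substring match anywhere in the report text.
#'
#' Missing metadata fields propagate as `NA`; they are never guessed.
#'
#' @param meta list with `age`, `gender`, `pathological` (any may be `NA`).
#' @param rep a `clinical_report`, raw report string, or `NULL` (no report:
#'   `medication` is `NA`).
#' @return list of class `task_labels` with elements `pathological`,
#'   `age_over_50`, `gender`, `medication`.
#' @export
derive_labels <- function(meta, rep = NULL) {
  age <- meta$age
  if (!is.null(age) && !is.na(age)) {
    age <- as.integer(age)
    if (age < 0) stop("age must be a nonnegative integer")
  } else age <- NA_integer_
  gender <- if (is.null(meta$gender)) NA_character_ else as.character(meta$gender)
  if (!is.na(gender) && !gender %in% c("M", "F")) {
    stop("gender must be \"M\" or \"F\" (got ", gender, ")")
  }
  patho <- if (is.null(meta$pathological)) NA else as.logical(meta$pathological)
  med <- NA
  if (!is.null(rep)) {
    txt <- if (inherits(rep, "clinical_report")) render_report(rep) else as.character(rep)
    med <- any(vapply(medication_keywords(), grepl, TRUE,
                      x = tolower(txt), fixed = TRUE))
  }
  structure(list(pathological = patho,
                 age_over_50 = if (is.na(age)) NA else age > 50,
                 gender = gender,
                 medication = med),
            class = "task_labels")
}

#' Zero-shot prompt pairs for the four decoding tasks
#'
#' Returns the fixed two-class natural-language prompts used as class
#' prototypes for zero-shot classification. Class `A` is the negative /
#' reference class of the task label (`FALSE`, `"M"`), class `B` the
#' positive one. Note the prompts are class *handles* for the embedding
#' space; the label rule itself is [derive_labels()] (age exactly 50 is
#' class A even though the prompt says "under 50").
#'
#' @param task one of `"pathological"`, `"age"`, `"gender"`, `"medication"`.
#' @return named character vector with elements `A` and `B`.
#' @export
build_prompts <- function(task) {
  prompts <- list(
    pathological = c(A = "This is a normal recording",
                     B = "This is an abnormal recording"),
    age = c(A = "The patient is under 50 years old",
            B = "The patient is over 50 years old"),
    gender = c(A = "The patient is male",
               B = "The patient is female"),
    medication = c(A = "No anti-epileptic drugs were prescribed to the patient",
                   B = "Anti-epileptic drugs were prescribed to the patient")
  )
  if (!task %in% names(prompts)) {
    stop("unknown task \"", task, "\"; expected one of ",
         paste(names(prompts), collapse = ", "))
  }
  prompts[[task]]
}

#' Task label as a logical for a task name
#'
#' Maps a `task_labels` object and task name to the binary target used by
#' probes and zero-shot scoring (`TRUE` corresponds to prompt class B).
#'
#' @param labels a `task_labels` (or plain list with the same fields).
#' @param task one of `"pathological"`, `"age"`, `"gender"`, `"medication"`.
#' @return logical scalar (possibly `NA`).
#' @export
task_target <- function(labels, task) {
  switch(task,
         pathological = as.logical(labels$pathological),
         age = as.logical(labels$age_over_50),
         gender = if (is.na(labels$gender)) NA else labels$gender == "F",
         medication = as.logical(labels$medication),
         stop("unknown task \"", task, "\""))
}
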