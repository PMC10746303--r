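# Deterministic serialization of profiles to reviewer-facing (markdown/html)
# and machine-facing (json/csv) forms.

SECTION_LABELS <- c(
  presentation = "Presentation",
  demographics = "Demographics",
  prior_history = "Prior conditions, symptoms and treatment",
  comorbidities_risk_factors = "Comorbidities and risk factors",
  competing_diagnoses = "Competing diagnoses",
  diagnostic_procedures = "Diagnostic procedures",
  lab_tests = "Laboratory tests",
  visit_context = "Visit context",
  treatment_procedures = "Treatment procedures",
  medications = "Medications",
  followup = "Follow-up care",
  complications = "Complications"
)

QUALIFIER_TEXT <- c(abnormal_high = "abnormal, high",
                    abnormal_low = "abnormal, low",
                    normal = "normal",
                    unknown = "unknown")

#' Rendering options
#'
#' @param format One of `"json"`, `"csv"`, `"markdown"`, `"html"`.
#' @param include_blinding_map Write the study-id/person-id map alongside a
#'   batch (never embedded in reviewer-facing markdown/html).
#' @param overwrite Allow [render_batch()] to replace existing files.
#' @return An object of class `render_options`.
#' @export
render_options <- function(format = c("markdown", "json", "csv", "html"),
                           include_blinding_map = FALSE, overwrite = FALSE) {
  format <- match.arg(format)
  structure(list(format = format,
                 include_blinding_map = isTRUE(include_blinding_map),
                 overwrite = isTRUE(overwrite)),
            class = "render_options")
}

#' One summary rendered as profile text
#'
#' Drug summaries print the exposure duration (`metronidazole (3 days)`),
#' measurement summaries the qualifier and day set
#' (`leukocytes (abnormal, high, day 0/1/2/5)`), other domains the day set
#' (`appendectomy (day 25)`).
#'
#' @param s An `event_summary`.
#' @return Character string.
#' @export
summary_text <- function(s) {
  stopifnot(inherits(s, "event_summary"))
  if (!is.null(s$duration_days)) {
    sprintf("%s (%d day%s)", s$concept_name, s$duration_days,
            if (s$duration_days == 1L) "" else "s")
  } else if (s$qualifier != "none") {
    sprintf("%s (%s, %s)", s$concept_name, QUALIFIER_TEXT[[s$qualifier]],
            format_days(s$day_offsets))
  } else {
    sprintf("%s (%s)", s$concept_name, format_days(s$day_offsets))
  }
}

#' Render one profile to text
#'
#' Sections are emitted in the fixed conceptual-element order; within a
#' section, summaries keep their grouping order. Output is byte-stable across
#' runs. Reviewer-facing formats (markdown, html, csv) identify the patient
#' only by study id; the json machine form carries the full structure
#' including the person id.
#'
#' @param profile A `keeper_profile`.
#' @param options A [render_options()].
#' @return A single character string.
#' @export
render_profile <- function(profile, options = render_options()) {
  stopifnot(inherits(profile, "keeper_profile"),
            inherits(options, "render_options"))
  switch(options$format,
         markdown = render_profile_md(profile),
         html = render_profile_html(profile),
         csv = df_to_csv_string(profile_to_rows(profile)),
         json = paste0(as.character(
           jsonlite::toJSON(profile_to_list(profile), auto_unbox = TRUE,
                            pretty = TRUE, null = "null")), "\n"),
         stop("unsupported format: ", options$format, call. = FALSE))
}

profile_header <- function(profile) {
  demo <- c(profile$gender,
            paste0(profile$age_years, " yo"),
            if (!is.na(profile$race)) profile$race,
            if (!is.na(profile$ethnicity)) profile$ethnicity)
  paste0(paste(demo[!is.na(demo)], collapse = ", "),
         "; visit: ", profile$visit_summary)
}

render_profile_md <- function(profile) {
  lines <- c(
    paste0("# KEEPER profile ", profile$study_id,
           " [", profile$phenotype_name, "]"),
    "",
    paste0("**Demographics and details about the visit:** ",
           profile_header(profile)),
    "")
  for (el in keeper_elements()) {
    if (el %in% c("demographics", "visit_context")) next
    lines <- c(lines, paste0("## ", SECTION_LABELS[[el]]))
    entries <- profile$sections[[el]]
    if (length(entries) == 0L) {
      lines <- c(lines, "- (none)")
    } else {
      lines <- c(lines, vapply(entries, function(s) paste0("- ",
                                                           summary_text(s)),
                               character(1)))
    }
    lines <- c(lines, "")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

render_profile_html <- function(profile) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c("<!DOCTYPE html>", "<html><body>",
             paste0("<h1>KEEPER profile ", esc(profile$study_id), " [",
                    esc(profile$phenotype_name), "]</h1>"),
             paste0("<p><b>Demographics and details about the visit:</b> ",
                    esc(profile_header(profile)), "</p>"))
  for (el in keeper_elements()) {
    if (el %in% c("demographics", "visit_context")) next
    lines <- c(lines, paste0("<h2>", SECTION_LABELS[[el]], "</h2>"), "<ul>")
    entries <- profile$sections[[el]]
    if (length(entries) == 0L) {
      lines <- c(lines, "<li>(none)</li>")
    } else {
      lines <- c(lines, vapply(entries, function(s) {
        paste0("<li>", esc(summary_text(s)), "</li>")
      }, character(1)))
    }
    lines <- c(lines, "</ul>")
  }
  paste0(paste(c(lines, "</body></html>"), collapse = "\n"), "\n")
}

profile_to_rows <- function(profile) {
  rows <- list(data.frame(study_id = profile$study_id,
                          section = "header",
                          concept_id = NA_integer_,
                          concept_name = NA_character_,
                          qualifier = NA_character_,
                          days = NA_character_,
                          duration_days = NA_integer_,
                          text = profile_header(profile)))
  for (el in keeper_elements()) {
    for (s in profile$sections[[el]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = profile$study_id,
        section = el,
        concept_id = s$concept_id,
        concept_name = s$concept_name,
        qualifier = s$qualifier,
        days = format_days(s$day_offsets),
        duration_days = if (is.null(s$duration_days)) NA_integer_ else
          s$duration_days,
        text = summary_text(s))
    }
  }
  do.call(rbind, rows)
}

df_to_csv_string <- function(df) {
  con <- textConnection("csv_out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  close(con)
  paste0(paste(csv_out, collapse = "\n"), "\n")
}

profile_to_list <- function(profile) {
  list(
    study_id = profile$study_id,
    person_id = profile$person_id,
    phenotype_name = profile$phenotype_name,
    index_date = as.character(profile$index_date),
    age_years = profile$age_years,
    gender = profile$gender,
    race = profile$race,
    ethnicity = profile$ethnicity,
    visit_summary = profile$visit_summary,
    sections = lapply(profile$sections, function(entries) {
      lapply(entries, function(s) {
        list(concept_id = s$concept_id,
             concept_name = s$concept_name,
             qualifier = s$qualifier,
             day_offsets = as.list(s$day_offsets),
             duration_days = s$duration_days)
      })
    })
  )
}

#' Parse a json-rendered profile back into a `keeper_profile`
#'
#' Inverse of the json form of [render_profile()]: the round trip reproduces
#' the profile structure exactly.
#'
#' @param json A json string (or path to a json file).
#' @return A `keeper_profile`.
#' @export
profile_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  sections <- stats::setNames(
    lapply(keeper_elements(), function(el) {
      lapply(raw$sections[[el]], function(s) {
        event_summary(concept_id = s$concept_id,
                      concept_name = s$concept_name,
                      day_offsets = unlist(s$day_offsets),
                      qualifier = s$qualifier,
                      duration_days = s$duration_days)
      })
    }), keeper_elements())
  structure(list(
    study_id = raw$study_id,
    person_id = as.integer(raw$person_id),
    phenotype_name = raw$phenotype_name,
    index_date = as.Date(raw$index_date),
    age_years = as.integer(raw$age_years),
    gender = null_to_na(raw$gender),
    race = null_to_na(raw$race),
    ethnicity = null_to_na(raw$ethnicity),
    visit_summary = raw$visit_summary,
    sections = sections),
    class = "keeper_profile")
}

null_to_na <- function(x) if (is.null(x)) NA_character_ else x

#' Render a blinded batch to a directory
#'
#' Writes one file per profile (named by study id), an `index.csv` listing
#' the files, and — only when requested — `blinding_map.csv` with the
#' study-id/person-id correspondence.
#'
#' @param batch A `keeper_batch`.
#' @param directory Output directory (created if absent).
#' @param options A [render_options()]; existing files are an error unless
#'   `overwrite` is set.
#' @return Invisible character vector of the files written.
#' @export
render_batch <- function(batch, directory, options = render_options()) {
  stopifnot(inherits(batch, "keeper_batch"),
            inherits(options, "render_options"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ext <- switch(options$format, markdown = "md", json = "json", csv = "csv",
                html = "html")
  files <- file.path(directory, paste0(
    vapply(batch$profiles, `[[`, character(1), "study_id"), ".", ext))
  index_file <- file.path(directory, "index.csv")
  targets <- c(files, index_file)
  existing <- targets[file.exists(targets)]
  if (length(existing) && !options$overwrite) {
    stop("output file(s) already exist (set overwrite): ",
         paste(basename(existing), collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(batch$profiles)) {
    writeLines(render_profile(batch$profiles[[i]], options), files[i],
               sep = "")
  }
  idx <- data.frame(
    study_id = vapply(batch$profiles, `[[`, character(1), "study_id"),
    file = basename(files))
  utils::write.csv(idx, index_file, row.names = FALSE)
  written <- c(files, index_file)
  if (options$include_blinding_map) {
    map_file <- file.path(directory, "blinding_map.csv")
    utils::write.csv(batch$blinding_map, map_file, row.names = FALSE)
    written <- c(written, map_file)
  }
  invisible(written)
}
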