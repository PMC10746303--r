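# OMOP-CDM-shaped CSV loading into a uniform event model, plus windowed,
# concept-filtered per-patient queries anchored on an index date.

EVENT_TABLE_SPECS <- list(
  condition_occurrence = list(domain = "condition",
                              concept = "condition_concept_id",
                              start = "condition_start_date",
                              end = "condition_end_date"),
  drug_exposure = list(domain = "drug",
                       concept = "drug_concept_id",
                       start = "drug_exposure_start_date",
                       end = "drug_exposure_end_date"),
  procedure_occurrence = list(domain = "procedure",
                              concept = "procedure_concept_id",
                              start = "procedure_date",
                              end = NULL),
  measurement = list(domain = "measurement",
                     concept = "measurement_concept_id",
                     start = "measurement_date",
                     end = NULL),
  observation = list(domain = "observation",
                     concept = "observation_concept_id",
                     start = "observation_date",
                     end = NULL)
)

#' Load a directory of OMOP-CDM-shaped CSV tables
#'
#' Parses `person.csv` plus any of `condition_occurrence.csv`,
#' `drug_exposure.csv`, `procedure_occurrence.csv`, `measurement.csv`,
#' `observation.csv` and `visit_occurrence.csv` into a uniform clinical event
#' model: one row per dated, concept-coded fact with optional value, reference
#' range, unit, days supply and visit linkage. Absent optional tables yield
#' empty collections. Dates are calendar dates; events are assumed to carry
#' standard concept ids (source-to-standard mapping happens upstream).
#'
#' @param directory Path containing the CSV tables.
#' @param quiet Suppress the per-table row-count messages.
#' @return An object of class `cdm_store` with components `person`, `events`,
#'   `visits` and `table_counts`.
#' @export
load_cdm <- function(directory, quiet = FALSE) {
  person_path <- file.path(directory, "person.csv")
  if (!file.exists(person_path)) {
    stop("missing required table person.csv in ", directory, call. = FALSE)
  }
  person <- read_person_table(person_path)

  events <- list()
  counts <- c(person = nrow(person))
  for (tbl in names(EVENT_TABLE_SPECS)) {
    path <- file.path(directory, paste0(tbl, ".csv"))
    if (!file.exists(path)) next
    ev <- read_event_table(path, tbl, EVENT_TABLE_SPECS[[tbl]])
    counts[tbl] <- nrow(ev)
    events[[tbl]] <- ev
  }
  if (length(events) == 0L && !quiet) {
    message("no event tables found in ", directory)
  }
  events <- if (length(events)) do.call(rbind, events) else empty_events()
  rownames(events) <- NULL

  visit_path <- file.path(directory, "visit_occurrence.csv")
  visits <- if (file.exists(visit_path)) {
    read_visit_table(visit_path)
  } else {
    data.frame(visit_id = integer(), person_id = integer(),
               visit_kind = character(),
               start_date = as.Date(character()),
               end_date = as.Date(character()))
  }
  if (nrow(visits)) counts["visit_occurrence"] <- nrow(visits)

  unknown <- setdiff(unique(events$person_id), person$person_id)
  if (length(unknown)) {
    stop("event rows reference person_id(s) absent from person.csv: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  # birth date after an observed event is suspicious but tolerated
  bd <- person$birth_date[match(events$person_id, person$person_id)]
  late <- !is.na(bd) & events$start_date < bd
  if (any(late)) {
    warning(sum(late), " event(s) dated before the person's birth date",
            call. = FALSE)
  }
  if (!quiet) {
    for (nm in names(counts)) message(nm, ": ", counts[[nm]], " rows")
  }
  structure(list(person = person, events = events, visits = visits,
                 table_counts = counts),
            class = "cdm_store")
}

#' @export
print.cdm_store <- function(x, ...) {
  cat("<cdm_store>", nrow(x$person), "persons,", nrow(x$events), "events,",
      nrow(x$visits), "visits\n")
  if (nrow(x$events)) {
    tab <- table(x$events$domain)
    cat("  events by domain:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a cohort CSV (subject id + index date)
#'
#' @param path CSV with columns `subject_id` and `cohort_start_date`
#'   (ISO-8601 dates).
#' @param store Optional `cdm_store`; when given, entries are checked against
#'   its person table (unknown person is an error; an index date outside the
#'   person's observed event range only warns).
#' @return Data frame with columns `person_id`, `index_date`.
#' @export
read_cohort <- function(path, store = NULL) {
  df <- read_keeper_csv(path)
  require_columns(df, c("subject_id", "cohort_start_date"), basename(path))
  out <- data.frame(person_id = as.integer(df$subject_id),
                    index_date = parse_dates(df$cohort_start_date,
                                             basename(path)))
  if (!is.null(store)) {
    unknown <- setdiff(out$person_id, store$person$person_id)
    if (length(unknown)) {
      stop("cohort references unknown person_id(s): ",
           paste(sort(unknown), collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(out))) {
      ev <- store$events[store$events$person_id == out$person_id[i], ]
      if (nrow(ev) && (out$index_date[i] < min(ev$start_date) ||
                       out$index_date[i] > max(ev$start_date))) {
        warning("index date for person ", out$person_id[i],
                " lies outside that person's event date range", call. = FALSE)
      }
    }
  }
  out
}

#' Windowed, concept-filtered event query for one patient
#'
#' Returns exactly the events whose domain is in `domains`, whose concept id
#' is in `concept_ids`, and whose start-date offset from `index_date` lies in
#' `window` (bounds inclusive). Window membership uses the start date only;
#' end dates are carried through for duration computation. Results are sorted
#' by start date then concept id, so queries are order-deterministic.
#'
#' @param store A `cdm_store`.
#' @param person_id Single person id (must exist in the store).
#' @param domains Character vector of domains, or `NULL` for all.
#' @param concept_ids Integer vector of concept ids, or `NULL` for all;
#'   an empty vector selects nothing.
#' @param window A [temporal_window()], or `NULL` for all time.
#' @param index_date The day-0 anchor (required when `window` is given).
#' @return Data frame of events in the uniform model, plus a `day_offset`
#'   column when `index_date` is supplied.
#' @export
events_for <- function(store, person_id, domains = NULL, concept_ids = NULL,
                       window = NULL, index_date = NULL) {
  stopifnot(inherits(store, "cdm_store"), length(person_id) == 1L)
  person_id <- as.integer(person_id)
  if (!person_id %in% store$person$person_id) {
    stop("unknown person_id: ", person_id, call. = FALSE)
  }
  ev <- store$events[store$events$person_id == person_id, , drop = FALSE]
  if (!is.null(domains)) ev <- ev[ev$domain %in% domains, , drop = FALSE]
  if (!is.null(concept_ids)) {
    ev <- ev[ev$concept_id %in% as.integer(concept_ids), , drop = FALSE]
  }
  if (!is.null(index_date)) {
    ev$day_offset <- day_offset(ev$start_date, index_date)
  }
  if (!is.null(window)) {
    if (is.null(index_date)) {
      stop("index_date is required when a window is given", call. = FALSE)
    }
    ev <- ev[ev$day_offset >= window$lo & ev$day_offset <= window$hi, ,
             drop = FALSE]
  }
  ev <- ev[order(ev$start_date, ev$concept_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Visits for one patient
#'
#' @inheritParams events_for
#' @return The visit rows for `person_id`, sorted by start date.
#' @export
visits_for <- function(store, person_id) {
  stopifnot(inherits(store, "cdm_store"))
  v <- store$visits[store$visits$person_id == as.integer(person_id), ,
                    drop = FALSE]
  v <- v[order(v$start_date, v$visit_kind), , drop = FALSE]
  rownames(v) <- NULL
  v
}

# -- internal parsers ---------------------------------------------------------

empty_events <- function() {
  data.frame(person_id = integer(), domain = character(),
             concept_id = integer(),
             start_date = as.Date(character()), end_date = as.Date(character()),
             value_as_number = numeric(), range_low = numeric(),
             range_high = numeric(), unit = character(),
             days_supply = integer(), visit_id = integer())
}

parse_dates <- function(x, where) {
  out <- as.Date(rep(NA_character_, length(x)))
  nonblank <- !is.na(x) & nzchar(trimws(as.character(x)))
  parsed <- suppressWarnings(
    as.Date(substr(trimws(as.character(x[nonblank])), 1, 10),
            format = "%Y-%m-%d"))
  bad <- which(nonblank)[is.na(parsed)]
  if (length(bad)) {
    stop(where, ": unparseable date(s) at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (expected ISO-8601 YYYY-MM-DD): ",
         paste(utils::head(x[bad], 5L), collapse = ", "), call. = FALSE)
  }
  out[nonblank] <- parsed
  out
}

read_person_table <- function(path) {
  df <- read_keeper_csv(path)
  require_columns(df, "person_id", basename(path))
  person_id <- as.integer(df$person_id)
  if (anyNA(person_id) || any(duplicated(person_id))) {
    stop("person.csv: person_id must be unique positive integers",
         call. = FALSE)
  }
  birth_date <- if ("birth_datetime" %in% names(df)) {
    parse_dates(df$birth_datetime, "person.csv")
  } else if ("year_of_birth" %in% names(df)) {
    y <- as.integer(df$year_of_birth)
    m <- if ("month_of_birth" %in% names(df)) as.integer(df$month_of_birth) else 6L
    d <- if ("day_of_birth" %in% names(df)) as.integer(df$day_of_birth) else 15L
    m[is.na(m)] <- 6L
    d[is.na(d)] <- 15L
    parse_dates(sprintf("%04d-%02d-%02d", y, m, d), "person.csv")
  } else {
    stop("person.csv: need birth_datetime or year_of_birth", call. = FALSE)
  }
  pick <- function(col) {
    if (col %in% names(df)) as.character(df[[col]]) else
      rep(NA_character_, nrow(df))
  }
  data.frame(person_id = person_id,
             birth_date = birth_date,
             gender = pick("gender"),
             race = pick("race"),
             ethnicity = pick("ethnicity"))
}

read_event_table <- function(path, tbl, spec) {
  df <- read_keeper_csv(path)
  require_columns(df, c("person_id", spec$concept, spec$start), basename(path))
  n <- nrow(df)
  start_date <- parse_dates(df[[spec$start]], basename(path))
  end_date <- if (!is.null(spec$end) && spec$end %in% names(df)) {
    parse_dates(df[[spec$end]], basename(path))
  } else {
    as.Date(rep(NA_character_, n))
  }
  bad <- which(!is.na(end_date) & end_date < start_date)
  if (length(bad)) {
    stop(basename(path), ": end date before start date at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  num <- function(col) {
    if (col %in% names(df)) as.numeric(df[[col]]) else rep(NA_real_, n)
  }
  out <- data.frame(
    person_id = as.integer(df$person_id),
    domain = rep(spec$domain, n),
    concept_id = as.integer(df[[spec$concept]]),
    start_date = start_date,
    end_date = end_date,
    value_as_number = if (spec$domain == "measurement") num("value_as_number")
      else rep(NA_real_, n),
    range_low = if (spec$domain == "measurement") num("range_low")
      else rep(NA_real_, n),
    range_high = if (spec$domain == "measurement") num("range_high")
      else rep(NA_real_, n),
    unit = if (spec$domain == "measurement" && "unit" %in% names(df))
      as.character(df$unit) else rep(NA_character_, n),
    days_supply = if (spec$domain == "drug" && "days_supply" %in% names(df))
      as.integer(df$days_supply) else rep(NA_integer_, n),
    visit_id = if ("visit_occurrence_id" %in% names(df))
      as.integer(df$visit_occurrence_id) else rep(NA_integer_, n)
  )
  if (any(!is.na(out$days_supply) & out$days_supply < 0)) {
    stop(basename(path), ": days_supply must be non-negative", call. = FALSE)
  }
  out
}

read_visit_table <- function(path) {
  df <- read_keeper_csv(path)
  require_columns(df, c("visit_occurrence_id", "person_id", "visit_kind",
                        "visit_start_date", "visit_end_date"), basename(path))
  start_date <- parse_dates(df$visit_start_date, basename(path))
  end_date <- parse_dates(df$visit_end_date, basename(path))
  bad <- which(!is.na(end_date) & end_date < start_date)
  if (length(bad)) {
    stop(basename(path), ": visit end before start at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  data.frame(visit_id = as.integer(df$visit_occurrence_id),
             person_id = as.integer(df$person_id),
             visit_kind = tolower(as.character(df$visit_kind)),
             start_date = start_date,
             end_date = end_date)
}
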