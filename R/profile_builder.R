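# Core profile construction: one cohort entry + phenotype config + CDM store
# -> a sectioned, summarized, blinded patient profile.

#' Signed day offset of an event relative to the index date
#'
#' @param event_date,index_date Calendar dates (`Date` or ISO-8601 strings).
#' @return Integer day difference; 0 on the index date, negative before it.
#' @export
day_offset <- function(event_date, index_date) {
  as.integer(as.Date(event_date) - as.Date(index_date))
}

#' Completed age in years at the index date
#'
#' Birthday-aware floor: the age increments on the birthday itself.
#'
#' @param index_date,birth_date Calendar dates.
#' @return Integer completed years.
#' @export
age_at <- function(index_date, birth_date) {
  index_date <- as.Date(index_date)
  birth_date <- as.Date(birth_date)
  if (any(birth_date > index_date)) {
    stop("birth_date after index_date", call. = FALSE)
  }
  iy <- as.integer(format(index_date, "%Y"))
  by <- as.integer(format(birth_date, "%Y"))
  imd <- format(index_date, "%m%d")
  bmd <- format(birth_date, "%m%d")
  iy - by - as.integer(imd < bmd)
}

#' Classify a measurement value against its reference range
#'
#' @param value Numeric value or `NA`.
#' @param range_low,range_high Reference-range bounds (either may be `NA`).
#' @return One of `"abnormal_high"`, `"abnormal_low"`, `"normal"`,
#'   `"unknown"`. Boundary values are normal (inclusive range); one-sided
#'   ranges are classified against the available bound; a missing value or a
#'   fully missing range is `"unknown"`.
#' @export
classify_measurement <- function(value, range_low = NA, range_high = NA) {
  if (!is.na(range_low) && !is.na(range_high) && range_low > range_high) {
    stop("range_low (", range_low, ") exceeds range_high (", range_high, ")",
         call. = FALSE)
  }
  if (is.na(value) || (is.na(range_low) && is.na(range_high))) {
    return("unknown")
  }
  if (!is.na(range_high) && value > range_high) return("abnormal_high")
  if (!is.na(range_low) && value < range_low) return("abnormal_low")
  "normal"
}

#' Render a sorted day-offset set as compact profile text
#'
#' Maximal consecutive runs of length >= 4 are dashed (`day 1-5`); everything
#' else is slash-separated (`day 0/1/2/5`).
#'
#' @param day_offsets Sorted, deduplicated integer day offsets.
#' @return A string like `"day 1-5"` or `"day 0/1/2/5"`.
#' @seealso [parse_days()] for the inverse.
#' @export
format_days <- function(day_offsets) {
  if (length(day_offsets) == 0L) stop("empty day-offset set", call. = FALSE)
  day_offsets <- as.integer(day_offsets)
  if (is.unsorted(day_offsets, strictly = TRUE)) {
    stop("day offsets must be strictly increasing", call. = FALSE)
  }
  runs <- split(day_offsets, cumsum(c(1L, diff(day_offsets) != 1L)))
  tokens <- unlist(lapply(runs, function(r) {
    if (length(r) >= 4L) paste0(r[1L], "-", r[length(r)]) else as.character(r)
  }), use.names = FALSE)
  paste0("day ", paste(tokens, collapse = "/"))
}

#' Parse profile day text back into day offsets
#'
#' Inverse of [format_days()]: `parse_days(format_days(x))` recovers `x`.
#'
#' @param text A string such as `"day 0/1/2/5"` or `"day 1-5"`.
#' @return Sorted integer vector of day offsets.
#' @export
parse_days <- function(text) {
  body <- sub("^day ", "", text)
  tokens <- strsplit(body, "/", fixed = TRUE)[[1L]]
  out <- unlist(lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^(-?[0-9]+)-(-?[0-9]+)$", tok))[[1L]]
    if (length(m) == 3L) {
      seq.int(as.integer(m[2L]), as.integer(m[3L]))
    } else {
      as.integer(tok)
    }
  }))
  sort(unique(out))
}

# one summarized line of evidence in a profile section
event_summary <- function(concept_id, concept_name, day_offsets,
                          qualifier = "none", duration_days = NULL) {
  day_offsets <- sort(unique(as.integer(day_offsets)))
  if (length(day_offsets) == 0L) stop("empty day_offsets", call. = FALSE)
  structure(list(concept_id = as.integer(concept_id),
                 concept_name = tolower(concept_name),
                 qualifier = qualifier,
                 day_offsets = day_offsets,
                 duration_days = if (is.null(duration_days)) NULL else
                   as.integer(duration_days)),
            class = "event_summary")
}

#' Summarize drug exposures at the ingredient level with days supply
#'
#' Exposures are grouped by [ingredient_of()] (falling back to the recorded
#' drug concept when no ingredient ancestor exists). Each exposure contributes
#' the day interval from its start offset spanning `days_supply` days (the
#' recorded start-to-end span when days supply is absent, a single day when
#' both are absent); per-ingredient intervals are unioned, the summary
#' duration is the size of that union, and the day offsets are the exposure
#' start offsets.
#'
#' @param exposures Drug-domain event rows (uniform model) for one patient.
#' @param vocab A `keeper_vocabulary`.
#' @param index_date Day-0 anchor.
#' @return List of `event_summary` objects sorted by first day offset then
#'   ingredient name.
#' @export
summarize_drugs <- function(exposures, vocab, index_date) {
  if (nrow(exposures) == 0L) return(list())
  if (any(exposures$domain != "drug")) {
    stop("summarize_drugs expects drug-domain events only", call. = FALSE)
  }
  ing <- vapply(exposures$concept_id, function(id) {
    i <- ingredient_of(id, vocab)
    if (is.na(i)) id else i
  }, integer(1))
  summaries <- lapply(split(seq_len(nrow(exposures)), ing), function(idx) {
    rows <- exposures[idx, , drop = FALSE]
    starts <- day_offset(rows$start_date, index_date)
    ends <- mapply(function(s, ds, ed, sd) {
      if (!is.na(ds)) s + max(ds, 1L) - 1L
      else if (!is.na(ed)) s + as.integer(as.Date(ed) - as.Date(sd))
      else s
    }, starts, rows$days_supply, as.character(rows$end_date),
       as.character(rows$start_date))
    covered <- sort(unique(unlist(mapply(seq.int, starts, ends,
                                         SIMPLIFY = FALSE))))
    ing_id <- ing[idx[1L]]
    event_summary(
      concept_id = ing_id,
      concept_name = concept_info(vocab, ing_id)$concept_name,
      day_offsets = starts,
      duration_days = length(covered))
  })
  sort_summaries(unname(summaries))
}

#' Group non-drug events into profile summaries
#'
#' Measurements are grouped by concept and reference-range qualifier (a lab
#' that is high on day 1 and normal on day 3 yields two lines); other domains
#' are grouped by concept. Same-day duplicate codes collapse to a single day
#' entry.
#'
#' @param events Non-drug event rows (uniform model) for one patient.
#' @param index_date Day-0 anchor.
#' @param vocab A `keeper_vocabulary`.
#' @return List of `event_summary` objects sorted by first day offset then
#'   concept name.
#' @export
group_events <- function(events, index_date, vocab) {
  if (nrow(events) == 0L) return(list())
  if (any(events$domain == "drug")) {
    stop("group_events expects non-drug events; use summarize_drugs",
         call. = FALSE)
  }
  qual <- ifelse(events$domain == "measurement",
                 mapply(classify_measurement, events$value_as_number,
                        events$range_low, events$range_high),
                 "none")
  key <- paste(events$concept_id, qual, sep = "|")
  summaries <- lapply(split(seq_len(nrow(events)), key), function(idx) {
    rows <- events[idx, , drop = FALSE]
    event_summary(
      concept_id = rows$concept_id[1L],
      concept_name = concept_info(vocab, rows$concept_id[1L])$concept_name,
      day_offsets = day_offset(rows$start_date, index_date),
      qualifier = qual[idx[1L]])
  })
  sort_summaries(unname(summaries))
}

sort_summaries <- function(summaries) {
  if (length(summaries) <= 1L) return(summaries)
  first_day <- vapply(summaries, function(s) s$day_offsets[1L], integer(1))
  nm <- vapply(summaries, `[[`, character(1), "concept_name")
  summaries[order(first_day, nm)]
}

#' Summarize the visit context around the index date
#'
#' Selects visits whose span contains day 0 or that start on day 0, ordered
#' by start date (emergency room before inpatient on same-day ties), and
#' renders inpatient stays as `hospitalization (N days)` with length of stay
#' = end minus start.
#'
#' @param visits Visit rows for one patient.
#' @param index_date Day-0 anchor.
#' @return Text like `"emergency room followed by hospitalization (3 days)"`,
#'   or `"none recorded"`.
#' @export
summarize_index_visit <- function(visits, index_date) {
  if (nrow(visits) == 0L) return("none recorded")
  s <- day_offset(visits$start_date, index_date)
  e <- ifelse(is.na(visits$end_date), s,
              day_offset(visits$end_date, index_date))
  keep <- (s <= 0L & e >= 0L) | s == 0L
  visits <- visits[keep, , drop = FALSE]
  if (nrow(visits) == 0L) return("none recorded")
  s <- s[keep]; e <- e[keep]
  precedence <- match(visits$visit_kind,
                      c("emergency room", "outpatient", "inpatient"),
                      nomatch = 4L)
  ord <- order(s, precedence, visits$visit_kind)
  parts <- vapply(ord, function(i) {
    kind <- visits$visit_kind[i]
    if (kind == "inpatient") {
      los <- e[i] - s[i]
      sprintf("hospitalization (%d day%s)", los, if (los == 1L) "" else "s")
    } else {
      kind
    }
  }, character(1))
  paste(parts, collapse = " followed by ")
}

#' Build one patient's profile
#'
#' For every data-element spec in the config, fetches the windowed,
#' concept-filtered events, summarizes them (ingredient/days-supply rule for
#' medications, reference-range rule for measurements, concept grouping
#' otherwise) and places them in the spec's section. Demographics and the
#' index-visit summary are always populated. Every summary is re-verified
#' against its spec's window and resolved concept set before the profile is
#' returned.
#'
#' @param entry A single cohort row (`person_id`, `index_date`) as produced
#'   by [read_cohort()], or a list with those fields.
#' @param config A `keeper_config`.
#' @param store A `cdm_store`.
#' @param vocab A `keeper_vocabulary`.
#' @return An object of class `keeper_profile`.
#' @export
build_profile <- function(entry, config, store, vocab) {
  stopifnot(inherits(config, "keeper_config"), inherits(store, "cdm_store"))
  person_id <- as.integer(entry$person_id)
  index_date <- as.Date(entry$index_date)
  prow <- store$person[store$person$person_id == person_id, , drop = FALSE]
  if (nrow(prow) == 0L) stop("unknown person_id: ", person_id, call. = FALSE)

  sections <- stats::setNames(
    vector("list", length(keeper_elements())), keeper_elements())
  for (el in keeper_elements()) sections[[el]] <- list()

  for (spec in config$specs) {
    if (spec$element %in% c("demographics", "visit_context")) next
    ev <- events_for(store, person_id,
                     domains = setdiff(spec$domains, "visit"),
                     concept_ids = spec$resolved_ids,
                     window = spec$window, index_date = index_date)
    if (nrow(ev) == 0L) next
    summaries <- if (spec$element == "medications") {
      summarize_drugs(ev[ev$domain == "drug", , drop = FALSE], vocab,
                      index_date)
    } else {
      c(group_events(ev[ev$domain != "drug", , drop = FALSE], index_date,
                     vocab),
        summarize_drugs(ev[ev$domain == "drug", , drop = FALSE], vocab,
                        index_date))
    }
    verify_summaries(summaries, spec, store, vocab, person_id, index_date)
    sections[[spec$element]] <- c(sections[[spec$element]], summaries)
  }
  sections <- lapply(sections, sort_summaries)

  profile <- structure(list(
    study_id = as.character(person_id),
    person_id = person_id,
    phenotype_name = config$phenotype_name,
    index_date = index_date,
    age_years = age_at(index_date, prow$birth_date),
    gender = tolower(prow$gender),
    race = tolower(prow$race),
    ethnicity = tolower(prow$ethnicity),
    visit_summary = summarize_index_visit(visits_for(store, person_id),
                                          index_date),
    sections = sections),
    class = "keeper_profile")
  profile
}

# brute-force re-check: every summarized day offset traces back to a store
# event whose concept lies in the spec's resolved set and window
verify_summaries <- function(summaries, spec, store, vocab, person_id,
                             index_date) {
  ev <- store$events[store$events$person_id == person_id, , drop = FALSE]
  ev <- ev[ev$concept_id %in% spec$resolved_ids &
             ev$domain %in% spec$domains, , drop = FALSE]
  off <- day_offset(ev$start_date, index_date)
  ev <- ev[off >= spec$window$lo & off <= spec$window$hi, , drop = FALSE]
  off <- off[off >= spec$window$lo & off <= spec$window$hi]
  grouping_id <- vapply(seq_len(nrow(ev)), function(i) {
    if (ev$domain[i] == "drug") {
      ing <- ingredient_of(ev$concept_id[i], vocab)
      if (is.na(ing)) ev$concept_id[i] else ing
    } else {
      ev$concept_id[i]
    }
  }, integer(1))
  for (s in summaries) {
    ok <- all(s$day_offsets %in% off[grouping_id == s$concept_id])
    if (!ok) {
      stop("internal consistency failure: summary '", s$concept_name,
           "' in section ", spec$element,
           " is not backed by an in-window store event", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.keeper_profile <- function(x, ...) {
  cat(render_profile(x, render_options(format = "markdown")))
  invisible(x)
}

#' Build a blinded batch of profiles
#'
#' Profiles are built for every cohort entry and relabeled with opaque study
#' identifiers via a seeded random permutation, so study ids carry no
#' ordering information about person ids. The same seed reproduces the batch
#' exactly.
#'
#' @param entries Cohort data frame (`person_id`, `index_date`) with distinct
#'   person ids.
#' @param config A `keeper_config`.
#' @param store A `cdm_store`.
#' @param vocab A `keeper_vocabulary`.
#' @param seed Integer RNG seed for the blinding permutation.
#' @return An object of class `keeper_batch` with components `profiles`
#'   (ordered by study id), `blinding_map` (study_id/person_id bijection) and
#'   `seed`.
#' @export
build_batch <- function(entries, config, store, vocab, seed) {
  entries <- as.data.frame(entries)
  if (nrow(entries) == 0L) stop("no cohort entries", call. = FALSE)
  if (anyDuplicated(entries$person_id)) {
    stop("duplicate person_id in cohort: ",
         paste(unique(entries$person_id[duplicated(entries$person_id)]),
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(entries)
  perm <- with_seed(seed, sample.int(n))
  width <- max(3L, nchar(n))
  study_ids <- sprintf(paste0("ID-%0", width, "d"), seq_len(n))
  # study id i goes to the person at permuted position i
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    entry <- entries[perm[i], , drop = FALSE]
    pr <- build_profile(entry, config, store, vocab)
    pr$study_id <- study_ids[i]
    profiles[[i]] <- pr
  }
  blinding_map <- data.frame(study_id = study_ids,
                             person_id = as.integer(entries$person_id[perm]))
  structure(list(profiles = profiles, blinding_map = blinding_map,
                 seed = as.integer(seed)),
            class = "keeper_batch")
}

#' @export
print.keeper_batch <- function(x, ...) {
  cat("<keeper_batch>", length(x$profiles), "blinded profiles (seed",
      x$seed, ")\n")
  invisible(x)
}

# evaluate expr under a temporary RNG state; the seed promise must be forced
# before the ambient state is saved, or a caller drawing its seed from the
# ambient stream would be rolled back on exit
with_seed <- function(seed, expr) {
  force(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
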