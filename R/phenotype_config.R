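# Phenotype knowledge input: the conceptual elements of diagnostic reasoning,
# each bound to concept sets, domains and temporal windows around day 0.

#' Conceptual elements of a profile, in fixed rendering order
#'
#' The closed enumeration of diagnostic-reasoning stages used to organize a
#' profile: presentation on the index day, demographics, prior history,
#' comorbidities and risk factors, competing diagnoses, diagnostic procedures,
#' laboratory tests, visit context, treatment procedures, medications,
#' follow-up care and complications.
#'
#' @return Character vector of element names in rendering order.
#' @export
keeper_elements <- function() {
  c("presentation", "demographics", "prior_history",
    "comorbidities_risk_factors", "competing_diagnoses",
    "diagnostic_procedures", "lab_tests", "visit_context",
    "treatment_procedures", "medications", "followup", "complications")
}

# domains each element may draw from
ELEMENT_DOMAINS <- list(
  presentation = c("condition", "observation", "measurement"),
  demographics = "demographic",
  prior_history = c("condition", "drug", "observation", "procedure"),
  comorbidities_risk_factors = c("condition", "observation"),
  competing_diagnoses = c("condition", "procedure", "measurement", "drug"),
  diagnostic_procedures = "procedure",
  lab_tests = "measurement",
  visit_context = "visit",
  treatment_procedures = "procedure",
  medications = "drug",
  followup = c("visit", "procedure"),
  complications = "condition"
)

#' An inclusive temporal window of day offsets around the index date
#'
#' @param lo,hi Integer day offsets (day 0 = index date), or `-Inf`/`+Inf`.
#'   Bounds are inclusive; `lo` must not exceed `hi`.
#' @return An object of class `temporal_window`.
#' @export
temporal_window <- function(lo, hi) {
  lo <- parse_window_bound(lo)
  hi <- parse_window_bound(hi)
  if (lo > hi) stop("window lo (", lo, ") exceeds hi (", hi, ")", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "temporal_window")
}

parse_window_bound <- function(x) {
  if (is.character(x)) {
    x <- trimws(x)
    if (x %in% c("-inf", "-Inf")) return(-Inf)
    if (x %in% c("+inf", "inf", "+Inf", "Inf")) return(Inf)
    xn <- suppressWarnings(as.numeric(x))
    if (is.na(xn)) stop("malformed window bound: '", x, "'", call. = FALSE)
    x <- xn
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("malformed window bound", call. = FALSE)
  }
  if (is.finite(x) && x != round(x)) {
    stop("window bound must be an integer day offset: ", x, call. = FALSE)
  }
  as.numeric(x)
}

#' @export
print.temporal_window <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) ifelse(v < 0, "-inf", "+inf") else
    format(as.integer(v))
  cat("[", fmt(x$lo), ", ", fmt(x$hi), "] days from index\n", sep = "")
  invisible(x)
}

#' Default temporal window for a conceptual element
#'
#' Presentation is the index day itself; history and comorbidities end the day
#' before the index; competing diagnoses, complications and follow-up start
#' the day after it; treatment (procedures and medications) starts on the
#' index day; diagnostics, laboratory tests and visit context are unbounded
#' (overridable per element in the config).
#'
#' @param element One of [keeper_elements()].
#' @return A [temporal_window()].
#' @export
default_window <- function(element) {
  element <- match.arg(element, keeper_elements())
  switch(element,
         presentation = ,
         demographics = temporal_window(0, 0),
         prior_history = ,
         comorbidities_risk_factors = temporal_window(-Inf, -1),
         competing_diagnoses = ,
         complications = ,
         followup = temporal_window(1, Inf),
         treatment_procedures = ,
         medications = temporal_window(0, Inf),
         temporal_window(-Inf, Inf))
}

#' Parse a phenotype definition config (YAML or JSON)
#'
#' The config names the phenotype, defines seed-based concept sets, and binds
#' conceptual elements to domains, concept sets and temporal windows.
#' Unspecified windows are filled from [default_window()]; all concept sets
#' are resolved against the vocabulary so the returned object is
#' self-contained and can be serialized back to an equivalent file with
#' [write_config()].
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` config file.
#' @param vocab A `keeper_vocabulary` used to resolve concept sets.
#' @return An object of class `keeper_config`.
#' @export
parse_config <- function(file, vocab) {
  stopifnot(inherits(vocab, "keeper_vocabulary"))
  raw <- if (tolower(tools::file_ext(file)) == "json") {
    jsonlite::fromJSON(file, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(file)
  }
  config_from_list(raw, vocab, where = basename(file))
}

config_from_list <- function(raw, vocab, where = "config") {
  if (is.null(raw$phenotype_name)) {
    stop(where, ": missing phenotype_name", call. = FALSE)
  }
  if (is.null(raw$concept_sets) || !length(raw$concept_sets)) {
    stop(where, ": missing concept_sets", call. = FALSE)
  }
  sets <- list()
  for (nm in names(raw$concept_sets)) {
    seeds <- raw$concept_sets[[nm]]
    seeds <- do.call(rbind, lapply(seeds, function(s) {
      data.frame(
        concept_id = as.integer(s$concept_id),
        include_descendants = isTRUE(s$include_descendants) ||
          is.null(s$include_descendants),
        excluded = isTRUE(s$excluded))
    }))
    cs <- concept_set(nm, seeds)
    cs$resolved_ids <- resolve_concept_set(cs, vocab)
    sets[[nm]] <- cs
  }
  if (is.null(raw$elements) || !length(raw$elements)) {
    stop(where, ": missing elements", call. = FALSE)
  }
  specs <- lapply(seq_along(raw$elements), function(i) {
    el <- raw$elements[[i]]
    loc <- paste0(where, ": elements[", i, "]")
    if (is.null(el$element) || !el$element %in% keeper_elements()) {
      stop(loc, ": unknown element name '", el$element, "'", call. = FALSE)
    }
    if (is.null(el$concept_set) || !el$concept_set %in% names(sets)) {
      stop(loc, ": references undefined concept set '", el$concept_set, "'",
           call. = FALSE)
    }
    domains <- unlist(el$domains)
    if (is.null(domains)) domains <- ELEMENT_DOMAINS[[el$element]]
    bad <- setdiff(domains, ELEMENT_DOMAINS[[el$element]])
    if (length(bad)) {
      stop(loc, ": domain(s) ", paste(bad, collapse = ", "),
           " incompatible with element '", el$element, "'", call. = FALSE)
    }
    window <- if (is.null(el$window)) default_window(el$element) else {
      if (is.null(el$window$lo) || is.null(el$window$hi)) {
        stop(loc, ": malformed window (need lo and hi)", call. = FALSE)
      }
      temporal_window(el$window$lo, el$window$hi)
    }
    list(element = el$element, domains = domains,
         concept_set = el$concept_set, window = window,
         resolved_ids = sets[[el$concept_set]]$resolved_ids)
  })
  keys <- vapply(specs, function(s) paste(s$element, s$concept_set, sep = "|"),
                 character(1))
  if (anyDuplicated(keys)) {
    stop(where, ": duplicate (element, concept_set) pair(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "), call. = FALSE)
  }
  structure(list(phenotype_name = as.character(raw$phenotype_name),
                 concept_sets = sets, specs = specs),
            class = "keeper_config")
}

#' Serialize a parsed config back to YAML or JSON
#'
#' Writing then re-parsing a config is a fixed point: windows and flags are
#' emitted explicitly, so the round trip reproduces the same object.
#'
#' @param config A `keeper_config`.
#' @param file Output path; format chosen by extension (`.json` vs yaml).
#' @return `file`, invisibly.
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "keeper_config"))
  bound_out <- function(v) {
    if (is.infinite(v)) ifelse(v < 0, "-inf", "+inf") else as.integer(v)
  }
  raw <- list(
    phenotype_name = config$phenotype_name,
    concept_sets = lapply(config$concept_sets, function(cs) {
      lapply(seq_len(nrow(cs$seeds)), function(i) {
        list(concept_id = cs$seeds$concept_id[i],
             include_descendants = cs$seeds$include_descendants[i],
             excluded = cs$seeds$excluded[i])
      })
    }),
    elements = lapply(config$specs, function(s) {
      list(element = s$element,
           domains = as.list(s$domains),
           concept_set = s$concept_set,
           window = list(lo = bound_out(s$window$lo),
                         hi = bound_out(s$window$hi)))
    })
  )
  if (tolower(tools::file_ext(file)) == "json") {
    jsonlite::write_json(raw, file, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(raw, file)
  }
  invisible(file)
}

#' @export
print.keeper_config <- function(x, ...) {
  cat("<keeper_config> phenotype:", x$phenotype_name, "\n")
  cat("  concept sets:", paste(names(x$concept_sets), collapse = ", "), "\n")
  for (s in x$specs) {
    fmt <- function(v) if (is.infinite(v)) ifelse(v < 0, "-inf", "+inf") else
      format(as.integer(v))
    cat(sprintf("  %-26s %-30s [%s, %s]  (%d concepts)\n", s$element,
                s$concept_set, fmt(s$window$lo), fmt(s$window$hi),
                length(s$resolved_ids)))
  }
  invisible(x)
}
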