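# Concept dictionary + ancestry relation: hierarchy-guided concept-set
# resolution and drug -> ingredient rollup.

KEEPER_DOMAINS <- c("condition", "drug", "procedure", "measurement",
                    "observation", "visit", "demographic")

#' Load an OMOP-style concept vocabulary with its ancestry relation
#'
#' Reads a concept dictionary and a (transitively closed) concept-ancestor
#' relation and builds an index supporting constant-time concept lookup,
#' descendant enumeration and ancestor enumeration. Per OMOP convention the
#' ancestry relation is reflexive: every concept is its own ancestor. Missing
#' reflexive edges are added by the loader so that "descendants of X" always
#' includes X itself.
#'
#' @param concept_file Path to a CSV with columns `concept_id`,
#'   `concept_name`, `domain_id`, `vocabulary_id`, `concept_class_id`.
#' @param ancestry_file Path to a CSV with columns `ancestor_concept_id`,
#'   `descendant_concept_id`, or `NULL` for a vocabulary with no hierarchy
#'   (the reflexive closure is still constructed).
#' @return An object of class `keeper_vocabulary`.
#' @export
load_vocabulary <- function(concept_file, ancestry_file = NULL) {
  concepts <- read_keeper_csv(concept_file)
  require_columns(concepts, c("concept_id", "concept_name", "domain_id",
                              "vocabulary_id", "concept_class_id"),
                  basename(concept_file))
  if (is.null(ancestry_file)) {
    ancestry <- data.frame(ancestor_concept_id = integer(),
                           descendant_concept_id = integer())
  } else {
    ancestry <- read_keeper_csv(ancestry_file)
    require_columns(ancestry, c("ancestor_concept_id", "descendant_concept_id"),
                    basename(ancestry_file))
  }
  vocabulary_index(concepts, ancestry)
}

#' Build a vocabulary index from in-memory tables
#'
#' @param concepts Data frame in the `concept.csv` column contract.
#' @param ancestry Data frame in the `concept_ancestor.csv` column contract.
#' @return An object of class `keeper_vocabulary` with components `concepts`
#'   (validated concept table, `domain_id` normalized to lower case),
#'   `ancestry` (reflexively closed edge table) and internal lookup maps.
#' @export
vocabulary_index <- function(concepts, ancestry) {
  concepts$concept_id <- as.integer(concepts$concept_id)
  if (anyNA(concepts$concept_id) || any(concepts$concept_id <= 0)) {
    stop("concept_id must be a positive integer", call. = FALSE)
  }
  dup <- unique(concepts$concept_id[duplicated(concepts$concept_id)])
  if (length(dup)) {
    stop("duplicated concept_id in concept table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  concepts$domain_id <- tolower(as.character(concepts$domain_id))
  bad <- setdiff(unique(concepts$domain_id), KEEPER_DOMAINS)
  if (length(bad)) {
    stop("unknown domain_id value(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(KEEPER_DOMAINS, collapse = ", "),
         call. = FALSE)
  }
  ancestry <- data.frame(
    ancestor_concept_id = as.integer(ancestry$ancestor_concept_id),
    descendant_concept_id = as.integer(ancestry$descendant_concept_id)
  )
  known <- concepts$concept_id
  dangling <- setdiff(
    unique(c(ancestry$ancestor_concept_id, ancestry$descendant_concept_id)),
    known)
  if (length(dangling)) {
    stop("ancestry edges reference unknown concept id(s): ",
         paste(sort(dangling), collapse = ", "), call. = FALSE)
  }
  # reflexive-transitive closure: OMOP's concept_ancestor is a precomputed
  # closure, but fixtures may supply direct parent-child edges only; both
  # normalize here, and every concept becomes its own ancestor
  adj <- split(ancestry$descendant_concept_id,
               as.character(ancestry$ancestor_concept_id))
  closure <- lapply(known, function(id) {
    seen <- id
    frontier <- id
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[as.character(frontier)],
                                   use.names = FALSE)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    sort(seen)
  })
  ancestry <- data.frame(
    ancestor_concept_id = rep(known, lengths(closure)),
    descendant_concept_id = unlist(closure))
  ancestry <- ancestry[order(ancestry$ancestor_concept_id,
                             ancestry$descendant_concept_id), , drop = FALSE]
  rownames(ancestry) <- NULL

  vocab <- list(
    concepts = concepts,
    ancestry = ancestry,
    desc_map = split(ancestry$descendant_concept_id,
                     as.character(ancestry$ancestor_concept_id)),
    anc_map = split(ancestry$ancestor_concept_id,
                    as.character(ancestry$descendant_concept_id))
  )
  class(vocab) <- "keeper_vocabulary"
  vocab
}

#' @export
print.keeper_vocabulary <- function(x, ...) {
  cat("<keeper_vocabulary>", nrow(x$concepts), "concepts,",
      nrow(x$ancestry), "ancestry edges (reflexive closure included)\n")
  cat("  domains:", paste(sort(unique(x$concepts$domain_id)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Look up concepts by id
#'
#' @param vocab A `keeper_vocabulary`.
#' @param concept_ids Integer vector of concept ids.
#' @param strict Error on unknown ids (default) or drop them.
#' @return The concept table rows for `concept_ids`, in input order.
#' @export
concept_info <- function(vocab, concept_ids, strict = TRUE) {
  stopifnot(inherits(vocab, "keeper_vocabulary"))
  idx <- match(as.integer(concept_ids), vocab$concepts$concept_id)
  if (strict && anyNA(idx)) {
    stop("unknown concept id(s): ",
         paste(concept_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  vocab$concepts[idx[!is.na(idx)], , drop = FALSE]
}

#' Enumerate the descendants of a concept (including itself)
#'
#' @inheritParams concept_info
#' @param concept_id A single concept id.
#' @return Sorted integer vector of descendant concept ids.
#' @export
descendants_of <- function(vocab, concept_id) {
  stopifnot(inherits(vocab, "keeper_vocabulary"))
  ids <- vocab$desc_map[[as.character(as.integer(concept_id))]]
  if (is.null(ids)) {
    stop("unknown concept id: ", concept_id, call. = FALSE)
  }
  sort(unique(ids))
}

#' Define a seed-based concept set
#'
#' A concept set is a named list of seed concepts, each optionally expanded to
#' its descendants and optionally excluded. Resolution takes the union of the
#' non-excluded seeds' subtrees (the seed alone when `include_descendants` is
#' off) and removes the excluded seeds' subtrees (the excluded seed alone when
#' its `include_descendants` flag is off).
#'
#' @param name Concept-set name.
#' @param seeds Data frame with columns `concept_id`, `include_descendants`
#'   (logical), `excluded` (logical); missing flag columns default to
#'   `TRUE`/`FALSE` respectively.
#' @return An object of class `keeper_concept_set`.
#' @export
concept_set <- function(name, seeds) {
  seeds <- as.data.frame(seeds)
  if (!"concept_id" %in% names(seeds)) {
    stop("seeds must have a concept_id column", call. = FALSE)
  }
  if (is.null(seeds$include_descendants)) {
    seeds$include_descendants <- rep(TRUE, nrow(seeds))
  }
  if (is.null(seeds$excluded)) seeds$excluded <- rep(FALSE, nrow(seeds))
  seeds$concept_id <- as.integer(seeds$concept_id)
  seeds$include_descendants <- as.logical(seeds$include_descendants)
  seeds$excluded <- as.logical(seeds$excluded)
  structure(list(name = name,
                 seeds = seeds[, c("concept_id", "include_descendants",
                                   "excluded")],
                 resolved_ids = NULL),
            class = "keeper_concept_set")
}

#' Resolve a concept set against a vocabulary
#'
#' @param definition A `keeper_concept_set`.
#' @param vocab A `keeper_vocabulary`.
#' @return Sorted integer vector of resolved concept ids (deterministic).
#' @export
resolve_concept_set <- function(definition, vocab) {
  stopifnot(inherits(definition, "keeper_concept_set"),
            inherits(vocab, "keeper_vocabulary"))
  seeds <- definition$seeds
  if (nrow(seeds) == 0L) return(integer())
  unknown <- setdiff(seeds$concept_id, vocab$concepts$concept_id)
  if (length(unknown)) {
    stop("concept set '", definition$name, "': unknown seed id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  expand <- function(row) {
    if (row$include_descendants) descendants_of(vocab, row$concept_id)
    else row$concept_id
  }
  included <- excluded <- integer()
  for (i in seq_len(nrow(seeds))) {
    ids <- expand(seeds[i, ])
    if (seeds$excluded[i]) excluded <- c(excluded, ids)
    else included <- c(included, ids)
  }
  sort(unique(setdiff(included, excluded)))
}

#' Roll a drug concept up to its active ingredient
#'
#' Walks the ancestry relation to find the unique ancestor whose concept class
#' is `Ingredient`. A concept that is itself an ingredient rolls up to itself
#' (reflexive ancestry). Combination products with multiple ingredient
#' ancestors are an error rather than a silent pick.
#'
#' @param drug_concept_id A single drug-domain concept id.
#' @param vocab A `keeper_vocabulary`.
#' @return The ingredient concept id, or `NA_integer_` when the concept has no
#'   ingredient ancestor.
#' @export
ingredient_of <- function(drug_concept_id, vocab) {
  stopifnot(inherits(vocab, "keeper_vocabulary"))
  drug_concept_id <- as.integer(drug_concept_id)
  info <- concept_info(vocab, drug_concept_id)
  if (info$domain_id != "drug") {
    stop("concept ", drug_concept_id, " has domain '", info$domain_id,
         "', expected drug", call. = FALSE)
  }
  anc <- vocab$anc_map[[as.character(drug_concept_id)]]
  anc_info <- concept_info(vocab, sort(unique(anc)))
  ing <- anc_info$concept_id[anc_info$concept_class_id == "Ingredient"]
  if (length(ing) > 1L) {
    stop("concept ", drug_concept_id, " has multiple ingredient ancestors: ",
         paste(ing, collapse = ", "), call. = FALSE)
  }
  if (length(ing) == 0L) return(NA_integer_)
  ing
}

#' Tabulate how often concepts occur in an event collection
#'
#' Used when refining concept sets iteratively against the observed
#' distribution of codes. Returns one row per requested id (zero counts
#' included), sorted by patient count descending then concept id ascending.
#'
#' @param ids Integer vector of concept ids.
#' @param events Data frame with at least `person_id` and `concept_id`
#'   columns (e.g. the `events` component of a [load_cdm()] store).
#' @param vocab Optional `keeper_vocabulary` used to attach concept names.
#' @return Data frame with columns `concept_id`, `concept_name`,
#'   `event_count`, `person_count`.
#' @export
concept_prevalence_report <- function(ids, events, vocab = NULL) {
  ids <- sort(unique(as.integer(ids)))
  if (length(ids) == 0L) {
    return(data.frame(concept_id = integer(), concept_name = character(),
                      event_count = integer(), person_count = integer()))
  }
  sub <- events[events$concept_id %in% ids, c("person_id", "concept_id")]
  ev <- table(factor(sub$concept_id, levels = ids))
  pat <- table(factor(unique(sub)[["concept_id"]], levels = ids))
  nm <- if (is.null(vocab)) rep(NA_character_, length(ids)) else
    vocab$concepts$concept_name[match(ids, vocab$concepts$concept_id)]
  out <- data.frame(concept_id = ids,
                    concept_name = nm,
                    event_count = as.integer(ev),
                    person_count = as.integer(pat))
  out <- out[order(-out$person_count, out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- shared CSV helpers -------------------------------------------------------

read_keeper_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
}

require_columns <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(where, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
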