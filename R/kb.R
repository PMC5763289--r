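#' Create an empty knowledge base
#'
#' The store keeps entities (id-keyed), facts (subject–predicate–object
#' triples with per-source provenance) and the declared property vocabulary.
#' It enforces referential integrity and rejects undeclared predicates; it
#' never merges — duplicate ids are an error, de-duplication is the fusion
#' step's job.
#'
#' @param schema property vocabulary, as from [kb_schema()].
#' @return an object of class `symkb_kb`.
#' @export
kb_new <- function(schema = kb_schema()) {
  structure(
    list(entities = list(),
         facts = empty_facts(),
         schema = schema),
    class = "symkb_kb"
  )
}

empty_facts <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), object_kind = character(),
             source = character(), stringsAsFactors = FALSE)
}

#' Construct an entity record
#'
#' @param name non-empty Unicode surface name.
#' @param types character vector of concept types (implied parents are
#'   added automatically, e.g. `TCMSymptom` brings in `Symptom`).
#' @param sources character vector of source identifiers.
#' @param attributes named list mapping attribute names (schema datatype
#'   properties) to character vectors of literal values.
#' @param id stable identifier; defaults to a hash of the first source and
#'   the name (see [entity_id()]).
#' @return an object of class `symkb_entity`.
#' @export
new_entity <- function(name, types, sources, attributes = list(), id = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("entity name must be a non-empty string")
  types <- expand_types(types)
  sources <- unique(as.character(sources))
  if (is.null(id)) {
    if (!length(sources)) stop("an entity needs a source or an explicit id")
    id <- entity_id(sources[[1L]], name)
  }
  if (length(attributes)) {
    if (is.null(names(attributes)) || any(!nzchar(names(attributes))))
      stop("attributes must be a named list")
    attributes <- lapply(attributes, as.character)
  }
  structure(list(id = id, name = name, types = types,
                 sources = sources, attributes = attributes),
            class = "symkb_entity")
}

#' @export
print.symkb_entity <- function(x, ...) {
  cat(sprintf("<entity %s> %s [%s] sources: %s; %d attribute(s)\n",
              x$id, x$name, paste(x$types, collapse = ","),
              paste(x$sources, collapse = ","), length(x$attributes)))
  invisible(x)
}

#' @export
print.symkb_kb <- function(x, ...) {
  cat(sprintf("<symkb knowledge base> %d entities, %d facts\n",
              length(x$entities), nrow(x$facts)))
  invisible(x)
}

#' Add an entity to a knowledge base
#'
#' @param kb a `symkb_kb`.
#' @param entity a `symkb_entity`.
#' @return the updated knowledge base.
#' @export
kb_add_entity <- function(kb, entity) {
  stopifnot(inherits(kb, "symkb_kb"), inherits(entity, "symkb_entity"))
  if (!nzchar(entity$name)) stop("entity name must be non-empty")
  if (!is.null(kb$entities[[entity$id]]))
    stop("duplicate entity id: ", entity$id)
  kb$entities[[entity$id]] <- entity
  kb
}

#' Add entity/literal facts to a knowledge base
#'
#' Each fact is validated: the subject must be a stored entity, an entity
#' object must resolve, and the predicate must be declared in the schema
#' with a compatible range kind.
#'
#' @param kb a `symkb_kb`.
#' @param subject,predicate,object,source character vectors (recycled to a
#'   common length).
#' @param object_kind `"entity"` or `"literal"`, per fact.
#' @return the updated knowledge base.
#' @export
kb_add_facts <- function(kb, subject, predicate, object,
                         object_kind = "literal", source = NA_character_) {
  stopifnot(inherits(kb, "symkb_kb"))
  df <- data.frame(subject = as.character(subject),
                   predicate = as.character(predicate),
                   object = as.character(object),
                   object_kind = as.character(object_kind),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  if (!nrow(df)) return(kb)
  bad_pred <- setdiff(unique(df$predicate), kb$schema$property)
  if (length(bad_pred))
    stop("predicate(s) not in declared schema: ", paste(bad_pred, collapse = ", "))
  if (!all(df$object_kind %in% c("entity", "literal")))
    stop("object_kind must be 'entity' or 'literal'")
  kinds <- kb$schema$range_kind[match(df$predicate, kb$schema$property)]
  mism <- kinds != "any" & kinds != df$object_kind
  if (any(mism))
    stop("object kind incompatible with declared range for: ",
         paste(unique(df$predicate[mism]), collapse = ", "))
  missing_subj <- setdiff(unique(df$subject), names(kb$entities))
  if (length(missing_subj))
    stop("fact subject(s) not in KB: ", paste(missing_subj, collapse = ", "))
  ent_obj <- df$object[df$object_kind == "entity"]
  missing_obj <- setdiff(unique(ent_obj), names(kb$entities))
  if (length(missing_obj))
    stop("fact entity object(s) not in KB: ", paste(missing_obj, collapse = ", "))
  kb$facts <- rbind(kb$facts, df)
  rownames(kb$facts) <- NULL
  kb
}

#' Knowledge-base statistics
#'
#' Per-type entity counts (an entity carrying several types is counted once
#' per type, so type columns can sum to more than the distinct total), the
#' distinct entity total, per-predicate fact counts and a per-source entity
#' contribution table.
#'
#' @param kb a `symkb_kb`.
#' @return a list with elements `n_entities`, `n_facts`,
#'   `n_attribute_values`, `entities_by_type`, `facts_by_predicate`,
#'   `entities_by_source`.
#' @export
kb_statistics <- function(kb) {
  stopifnot(inherits(kb, "symkb_kb"))
  all_types <- concept_types()
  by_type <- stats::setNames(integer(length(all_types)), all_types)
  by_source <- integer(0)
  for (e in kb$entities) {
    for (tp in e$types) by_type[[tp]] <- by_type[[tp]] + 1L
    for (s in e$sources) by_source[[s]] <- (if (s %in% names(by_source)) by_source[[s]] else 0L) + 1L
  }
  by_pred <- if (nrow(kb$facts)) table(kb$facts$predicate) else table(character())
  n_attr <- sum(vapply(kb$entities, function(e)
    sum(lengths(e$attributes)), integer(1)))
  list(n_entities = length(kb$entities),
       n_facts = nrow(kb$facts),
       n_attribute_values = n_attr,
       entities_by_type = by_type,
       facts_by_predicate = stats::setNames(as.integer(by_pred), names(by_pred)),
       entities_by_source = by_source)
}

#' Write knowledge-base statistics as JSON
#'
#' @param kb a `symkb_kb`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
kb_statistics_json <- function(kb, path = NULL) {
  st <- kb_statistics(kb)
  st <- lapply(st, function(x)
    if (!is.null(names(x))) as.list(x) else x)
  js <- jsonlite::toJSON(st, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}

#' Simple random sample of facts
#'
#' Uniform sampling without replacement, used to draw evaluation samples
#' from a large fact set.  The caller's RNG state is left untouched.
#'
#' @param kb a `symkb_kb`.
#' @param n sample size; must not exceed the number of facts.
#' @param seed integer seed; identical `(kb, n, seed)` give identical samples.
#' @return a data.frame of sampled fact rows.
#' @export
kb_sample_facts <- function(kb, n, seed) {
  stopifnot(inherits(kb, "symkb_kb"))
  pop <- nrow(kb$facts)
  if (n > pop) stop("sample size ", n, " exceeds fact population ", pop)
  idx <- with_seed(seed, sample.int(pop, n))
  out <- kb$facts[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate human correctness judgments by majority vote
#'
#' Each sampled fact is judged by a panel; the verdict is the strictly most
#' frequent label.  Ties (possible only with an even panel) resolve to
#' `"incorrect"`, the conservative choice for correctness-ratio estimation.
#'
#' @param judgments character vector over `{"correct", "incorrect"}`.
#' @return `"correct"` or `"incorrect"`.
#' @export
majority_vote <- function(judgments) {
  judgments <- as.character(judgments)
  if (!length(judgments)) stop("empty judgment list")
  if (!all(judgments %in% c("correct", "incorrect")))
    stop("judgments must be 'correct' or 'incorrect'")
  n_ok <- sum(judgments == "correct")
  if (n_ok * 2L > length(judgments)) "correct" else "incorrect"
}

#' Correctness ratio of a judged sample
#'
#' @param verdicts character vector of per-fact verdicts
#'   (`"correct"`/`"incorrect"`), e.g. from [majority_vote()] per fact.
#' @return fraction of `"correct"` verdicts.
#' @export
correctness_ratio <- function(verdicts) {
  if (!length(verdicts)) stop("no verdicts")
  mean(verdicts == "correct")
}
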