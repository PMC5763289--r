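#' Concept types of the knowledge-base schema
#'
#' The schema centres on Symptom and adds the four concepts directly related
#' to it in clinical practice (Disease, Medicine, Department, Examination),
#' plus Other for entities outside the medical scope.  Symptom is subdivided
#' into a traditional-Chinese-medicine (TCM) subtype and a Western-medicine
#' subtype, and Medicine likewise; an entity may carry both subtypes at once.
#'
#' @return character vector of all valid type labels.
#' @export
concept_types <- function() {
  c("Symptom", "TCMSymptom", "WesternSymptom",
    "Disease", "Medicine", "TCMMedicine", "WesternMedicine",
    "Department", "Examination", "Other")
}

#' Coarse (top-level) concept types
#' @return character vector of the six top-level types.
#' @export
coarse_types <- function() {
  c("Symptom", "Disease", "Medicine", "Department", "Examination", "Other")
}

# subtype -> implied parent
.type_parent <- c(TCMSymptom = "Symptom", WesternSymptom = "Symptom",
                  TCMMedicine = "Medicine", WesternMedicine = "Medicine")

#' Expand a type set with its implied parents
#'
#' `TCMSymptom`/`WesternSymptom` imply `Symptom`; `TCMMedicine`/
#' `WesternMedicine` imply `Medicine`.  Unknown labels are an error.
#'
#' @param types character vector of type labels.
#' @return the closed type set (unique, in canonical order).
#' @export
expand_types <- function(types) {
  types <- unique(as.character(types))
  bad <- setdiff(types, concept_types())
  if (length(bad)) stop("unknown concept type(s): ", paste(bad, collapse = ", "))
  parents <- unname(.type_parent[intersect(types, names(.type_parent))])
  out <- unique(c(types, parents))
  intersect(concept_types(), out)
}

# project a type set onto its coarse types
coarse_of <- function(types) {
  types <- expand_types(types)
  intersect(coarse_types(), types)
}

#' Declared property vocabulary of the knowledge base
#'
#' Unlike terminologies whose relations carry no fixed interpretation, every
#' predicate here has a declared kind: `"entity"` objects must resolve to a
#' stored entity, `"literal"` objects are plain values, `"any"` admits both.
#' Facts using predicates outside this table are rejected at add time.
#'
#' @return data.frame with columns `property` and `range_kind`.
#' @export
kb_schema <- function() {
  data.frame(
    property = c("relevant_disease", "relevant_department", "relevant_medicine",
                 "relevant_examination", "symptom_related_symptom",
                 "location", "description", "cause", "treatment",
                 "sameAs", "exactMatch"),
    range_kind = c("any", "any", "any",
                   "any", "any",
                   "literal", "literal", "literal", "literal",
                   "entity", "literal"),
    stringsAsFactors = FALSE
  )
}
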