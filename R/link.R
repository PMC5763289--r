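#' Reduce an English phrase to a normalized bag of words
#'
#' Lowercases, strips punctuation, splits on whitespace and collapses
#' duplicates (set semantics).  The same normalization is applied to
#' translated symptom names and to concept-table terms — the exact-match
#' linking rule makes this symmetry essential.
#'
#' @param phrase a string.
#' @return sorted character vector of tokens (possibly empty).
#' @export
bag_of_words <- function(phrase) {
  x <- tolower(paste(as.character(phrase), collapse = " "))
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  sort(unique(toks[nzchar(toks)]))
}

#' Jaccard similarity of two word bags
#'
#' `|A intersect B| / |A union B|`; symmetric, 1 iff the sets are equal.
#' Two empty bags are an error (0/0 undefined).
#'
#' @param a,b character vectors (sets of tokens).
#' @return numeric in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) stop("Jaccard of two empty bags is undefined")
  length(intersect(a, b)) / length(union(a, b))
}

#' Build a deterministic translator from a bilingual lexicon
#'
#' The translation service is an injected interface; this adapter answers
#' from a fixed Chinese-to-English lexicon and is therefore deterministic
#' and reproducible offline.
#'
#' @param lexicon data.frame with columns `chinese`, `english`.
#' @return a function `chinese string -> English phrase or NA`.
#' @export
make_lexicon_translator <- function(lexicon) {
  stopifnot(all(c("chinese", "english") %in% names(lexicon)))
  map <- stats::setNames(as.character(lexicon$english),
                         as.character(lexicon$chinese))
  function(x) {
    out <- map[as.character(x)]
    unname(out)
  }
}

#' Read / write the bilingual lexicon and the concept table as TSV
#'
#' The concept table is a projection of a terminology release: one row per
#' (concept id, preferred term) with the concept's semantic type.
#'
#' @param path TSV file.
#' @param x data.frame to write.
#' @return the data.frame (readers) or the path, invisibly (writers).
#' @export
read_concept_table <- function(path) {
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  stopifnot(all(c("cui", "term", "semantic_type") %in% names(df)))
  df
}

#' @rdname read_concept_table
#' @export
write_concept_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_concept_table
#' @export
read_lexicon <- function(path) {
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  stopifnot(all(c("chinese", "english") %in% names(df)))
  df
}

#' @rdname read_concept_table
#' @export
write_lexicon <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

bag_key <- function(bag) paste(bag, collapse = " ")

#' Link symptoms to English concepts by translation and exact Jaccard match
#'
#' Each symptom name is translated, reduced to a bag of words and linked to
#' every concept row whose term yields an identical bag — i.e. a Jaccard
#' similarity of exactly 1; anything less is not a link.  Untranslatable
#' symptoms are skipped with a log; a symptom may link to several concepts
#' sharing one bag.
#'
#' @param symptoms data.frame with columns `id`, `name`, or a list of
#'   `symkb_entity`.
#' @param translator a function as from [make_lexicon_translator()].
#' @param concepts concept table data.frame (`cui`, `term`,
#'   `semantic_type`).
#' @return data.frame with columns `symptom_id`, `symptom_name`,
#'   `translation`, `cui`, `term`, `semantic_type`, `jaccard`.
#' @export
link_symptoms <- function(symptoms, translator, concepts) {
  if (is.list(symptoms) && !is.data.frame(symptoms))
    symptoms <- data.frame(
      id = vapply(symptoms, `[[`, character(1), "id"),
      name = vapply(symptoms, `[[`, character(1), "name"),
      stringsAsFactors = FALSE)
  concept_keys <- vapply(concepts$term, function(t)
    bag_key(bag_of_words(t)), character(1))
  out <- list()
  for (i in seq_len(nrow(symptoms))) {
    en <- translator(symptoms$name[[i]])
    if (is.na(en) || !nzchar(en)) {
      symkb_log("no translation for symptom: ", symptoms$name[[i]])
      next
    }
    bag <- bag_of_words(en)
    if (!length(bag)) next
    hits <- which(concept_keys == bag_key(bag))
    for (h in hits)
      out[[length(out) + 1L]] <- data.frame(
        symptom_id = symptoms$id[[i]], symptom_name = symptoms$name[[i]],
        translation = en, cui = concepts$cui[[h]], term = concepts$term[[h]],
        semantic_type = concepts$semantic_type[[h]], jaccard = 1,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(symptom_id = character(), symptom_name = character(),
                      translation = character(), cui = character(),
                      term = character(), semantic_type = character(),
                      jaccard = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Re-verify stored links from scratch
#'
#' Recomputes the Jaccard similarity of every stored link from its
#' translation and concept term; all must be exactly 1.
#'
#' @param links data.frame from [link_symptoms()].
#' @return logical vector, one per link.
#' @export
audit_links <- function(links) {
  vapply(seq_len(nrow(links)), function(i)
    jaccard(bag_of_words(links$translation[[i]]),
            bag_of_words(links$term[[i]])) == 1, logical(1))
}

#' Semantic-type distribution over symptom links
#'
#' @param links data.frame from [link_symptoms()].
#' @param concepts concept table; every linked cui must appear in it.
#' @return data.frame with columns `semantic_type`, `count`, `fraction`
#'   (fractions sum to 1 on a non-empty link set).
#' @export
semantic_type_distribution <- function(links, concepts) {
  if (!nrow(links))
    return(data.frame(semantic_type = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  unknown <- setdiff(links$cui, concepts$cui)
  if (length(unknown))
    stop("link(s) reference unknown concept id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  st <- concepts$semantic_type[match(links$cui, concepts$cui)]
  tab <- table(st)
  data.frame(semantic_type = names(tab),
             count = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Add symptom links to a knowledge base as exact-match facts
#'
#' @param kb a `symkb_kb`; link subjects must already be entities in it.
#' @param links data.frame from [link_symptoms()].
#' @param source provenance tag for the link facts.
#' @return the updated knowledge base.
#' @export
kb_add_links <- function(kb, links, source = "umls_link") {
  if (!nrow(links)) return(kb)
  kb_add_facts(kb, links$symptom_id, "exactMatch", links$cui,
               "literal", source)
}
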