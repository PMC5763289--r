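#' Default extraction heuristics for healthcare-site pages
#'
#' Keyword configuration for the symptom and medicine subtype heuristics and
#' the synonym pattern inventory.  A symptom related to a department whose
#' name carries a TCM marker is a TCM symptom; one related to a department
#' without the marker is a Western-medicine symptom (both can co-occur).  A
#' medicine whose description mentions patent/herbal-medicine keywords is
#' TCM, pharmaceuticals/chemicals keywords mark Western medicine.
#'
#' @return a nested list of keyword vectors and synonym pattern templates.
#' @export
default_heuristics <- function() {
  list(
    tcm_markers = c("中医", "TCM", "Traditional Chinese"),  # 中医
    medicine = list(
      tcm = c("中成药", "中草药",      # 中成药 中草药
              "草药", "Chinese patent medicine", "herbal medicine"),
      western = c("化学药品", "化学制剂", # 化学药品 化学制剂
                  "西药", "pharmaceuticals", "chemicals")
    ),
    # two-slot templates; {1}/{2} mark the entity slots
    synonym_patterns = c("{1}又称{2}",                 # 又称
                         "{1}俗称{2}",                 # 俗称
                         "{1}也叫{2}",                 # 也叫
                         "{1} is known as {2}")
  )
}

#' Load per-site wrapper configurations from YAML
#'
#' Wrappers are configuration, not code: each site entry declares the
#' structural locators of its pages (property box, rows, name/value cells,
#' entity name, abstract, list pages) and the map from the site's attribute
#' names to schema properties.  Adding a ninth site is a YAML edit.
#'
#' @param path YAML file with one entry per site id.
#' @return named list of wrapper configs.
#' @export
load_wrappers <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (site in names(cfg)) cfg[[site]]$site_id <- site
  cfg
}

#' Extract attribute-value pairs from a detail page's property box
#'
#' Finds the property box via the wrapper's locator and walks its rows in
#' document order.  Only rows whose attribute name appears in the wrapper's
#' attribute map are emitted, already renamed to schema properties; values
#' are whitespace-normalized.  A page without the box yields an empty result
#' with a log line, never an error, so one malformed page cannot halt a batch.
#'
#' @param html page HTML (string or `xml2` document).
#' @param wrapper one site's wrapper config (see [load_wrappers()]).
#' @return data.frame with columns `property`, `value`, `raw_name`, in order
#'   of appearance.
#' @export
parse_property_box <- function(html, wrapper) {
  doc <- if (inherits(html, "xml_document")) html else xml2::read_html(html)
  empty <- data.frame(property = character(), value = character(),
                      raw_name = character(), stringsAsFactors = FALSE)
  box <- xml2::xml_find_first(doc, wrapper$property_box)
  if (inherits(box, "xml_missing")) {
    symkb_log("no property box found (site ", wrapper$site_id %||% "?", ")")
    return(empty)
  }
  rows <- xml2::xml_find_all(box, wrapper$row)
  out <- empty
  for (r in rows) {
    nm <- xml2::xml_find_first(r, wrapper$name_cell)
    vl <- xml2::xml_find_first(r, wrapper$value_cell)
    if (inherits(nm, "xml_missing") || inherits(vl, "xml_missing")) next
    raw <- squish(xml2::xml_text(nm))
    target <- wrapper$attribute_map[[raw]]
    if (is.null(target)) next
    out <- rbind(out, data.frame(property = target,
                                 value = squish(xml2::xml_text(vl)),
                                 raw_name = raw, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Classify a symptom into TCM / Western-medicine subtypes
#'
#' Pure function of the related-department names: any department containing
#' a TCM marker contributes `TCMSymptom`, any department without one
#' contributes `WesternSymptom`; both labels can co-occur.
#'
#' @param departments character vector of related-department names (possibly
#'   empty; a single string with separators is split on `,`/`、`/`;`).
#' @param markers TCM marker strings.
#' @return character subset of `c("TCMSymptom", "WesternSymptom")`.
#' @export
classify_symptom_subtype <- function(departments,
                                     markers = default_heuristics()$tcm_markers) {
  departments <- unlist(strsplit(as.character(departments),
                                 "[,;、，；]"))
  departments <- trimws(departments)
  departments <- departments[nzchar(departments)]
  if (!length(departments)) return(character(0))
  has_marker <- vapply(departments, function(d)
    any(vapply(markers, function(m) grepl(m, d, fixed = TRUE), logical(1))),
    logical(1))
  out <- character(0)
  if (any(has_marker)) out <- c(out, "TCMSymptom")
  if (any(!has_marker)) out <- c(out, "WesternSymptom")
  out
}

#' Classify a medicine into TCM / Western subtypes by description keywords
#'
#' @param description free-text description from the detail page.
#' @param keywords list with `tcm` and `western` keyword vectors.
#' @return character subset of `c("TCMMedicine", "WesternMedicine")`; empty
#'   when no keyword hits (the entity stays a plain Medicine).
#' @export
classify_medicine_subtype <- function(description,
                                      keywords = default_heuristics()$medicine) {
  description <- paste(as.character(description), collapse = " ")
  hit <- function(words) any(vapply(words, function(w)
    grepl(w, description, fixed = TRUE), logical(1)))
  out <- character(0)
  if (hit(keywords$tcm)) out <- c(out, "TCMMedicine")
  if (hit(keywords$western)) out <- c(out, "WesternMedicine")
  out
}

# compile a two-slot template into a regex with two capture groups,
# anchored to the sentence
compile_pattern <- function(template) {
  if (lengths(regmatches(template, gregexpr("\\{1\\}", template))) != 1L ||
      lengths(regmatches(template, gregexpr("\\{2\\}", template))) != 1L)
    stop("synonym pattern must contain exactly one {1} and one {2} slot: ",
         template)
  parts <- strsplit(template, "\\{[12]\\}")[[1]]
  parts <- vapply(parts, function(p)
    gsub("([][.\\\\+*?^$(){}=!<>|:#-])", "\\\\\\1", p, perl = TRUE),
    character(1))
  while (length(parts) < 3L) parts <- c(parts, "")
  paste0("^", parts[[1]], "(.+?)", parts[[2]], "(.+?)", parts[[3]], "$")
}

split_zh_sentences <- function(text) {
  text <- gsub("\n", "。", text)
  out <- unlist(strsplit(text, "(?<=[。！？；.!?;])",
                         perl = TRUE))
  out <- gsub("[。！？；.!?;]+$", "", out)
  out <- trimws(out)
  out[nzchar(out)]
}

trim_entity_slot <- function(x) {
  x <- gsub("^[[:punct:]、，：“”\\s]+|[[:punct:]、，：“”\\s]+$",
            "", x, perl = TRUE)
  trimws(x)
}

#' Extract synonym (sameAs) pairs from an abstract with two-slot patterns
#'
#' Applies each lexico-syntactic template sentence-by-sentence; slot fillers
#' are trimmed of surrounding punctuation and self-pairs are suppressed.
#' The pair is symmetric: callers adding it to a knowledge base should
#' assert `sameAs` in both directions.
#'
#' @param abstract free text (the abstract of an entity page).
#' @param patterns character vector of two-slot templates, e.g.
#'   `"{1} is known as {2}"`.
#' @return data.frame with columns `entity1`, `entity2`.
#' @export
extract_synonyms <- function(abstract,
                             patterns = default_heuristics()$synonym_patterns) {
  if (!length(patterns)) stop("patterns must be non-empty")
  sentences <- split_zh_sentences(paste(abstract, collapse = "\n"))
  out <- data.frame(entity1 = character(), entity2 = character(),
                    stringsAsFactors = FALSE)
  for (pat in patterns) {
    rx <- compile_pattern(pat)
    for (s in sentences) {
      m <- regmatches(s, regexec(rx, s, perl = TRUE))[[1]]
      if (length(m) != 3L) next
      e1 <- trim_entity_slot(m[[2]])
      e2 <- trim_entity_slot(m[[3]])
      if (!nzchar(e1) || !nzchar(e2) || identical(e1, e2)) next
      out <- rbind(out, data.frame(entity1 = e1, entity2 = e2,
                                   stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

#' Extract a whole pseudo-site into a knowledge base
#'
#' Reads the site's list pages to learn which detail page holds which entity
#' type, then parses every detail page: entity name, property-box attributes
#' (via the wrapper's map), subtype heuristics for symptoms and medicines,
#' and synonym pairs from the abstract.
#'
#' @param site_dir directory holding the site's HTML files.
#' @param wrapper this site's wrapper config.
#' @param kb knowledge base to extend (default: a fresh one).
#' @param heuristics keyword config, see [default_heuristics()].
#' @return the updated `symkb_kb`.
#' @export
extract_website <- function(site_dir, wrapper, kb = kb_new(),
                            heuristics = default_heuristics()) {
  site <- wrapper$site_id
  roster <- data.frame(file = character(), type = character(),
                       stringsAsFactors = FALSE)
  for (type in names(wrapper$list_pages)) {
    lp <- file.path(site_dir, wrapper$list_pages[[type]])
    if (!file.exists(lp)) next
    doc <- xml2::read_html(lp)
    links <- xml2::xml_find_all(doc, wrapper$list_link)
    roster <- rbind(roster, data.frame(
      file = xml2::xml_attr(links, "href"),
      type = type, stringsAsFactors = FALSE))
  }
  syn_buf <- list()
  for (i in seq_len(nrow(roster))) {
    path <- file.path(site_dir, roster$file[[i]])
    if (!file.exists(path)) { symkb_log("missing detail page ", path); next }
    doc <- xml2::read_html(path)
    name_node <- xml2::xml_find_first(doc, wrapper$entity_name)
    if (inherits(name_node, "xml_missing")) next
    name <- squish(xml2::xml_text(name_node))
    attrs_df <- parse_property_box(doc, wrapper)
    type <- type_label_to_concept(roster$type[[i]])
    types <- type
    if (type == "Symptom") {
      dep <- attrs_df$value[attrs_df$property == "relevant_department"]
      types <- c(type, classify_symptom_subtype(dep, heuristics$tcm_markers))
    } else if (type == "Medicine") {
      desc <- attrs_df$value[attrs_df$property == "description"]
      types <- c(type, classify_medicine_subtype(desc, heuristics$medicine))
    }
    attrs <- split(attrs_df$value, attrs_df$property)
    ent <- new_entity(name, types, site, attrs)
    if (is.null(kb$entities[[ent$id]])) kb <- kb_add_entity(kb, ent)
    abs_node <- xml2::xml_find_first(doc, wrapper$abstract)
    if (!inherits(abs_node, "xml_missing")) {
      syn <- extract_synonyms(xml2::xml_text(abs_node),
                              heuristics$synonym_patterns)
      if (nrow(syn)) syn_buf[[length(syn_buf) + 1L]] <-
          cbind(syn, anchor = ent$id, stringsAsFactors = FALSE)
    }
  }
  # synonym pairs become symmetric sameAs facts between entities the KB knows
  if (length(syn_buf)) {
    syn <- unique(do.call(rbind, syn_buf))
    name_to_id <- stats::setNames(
      vapply(kb$entities, `[[`, character(1), "id"),
      vapply(kb$entities, `[[`, character(1), "name"))
    for (i in seq_len(nrow(syn))) {
      a <- name_to_id[[syn$entity1[[i]]]] %||% NA_character_
      b <- name_to_id[[syn$entity2[[i]]]] %||% NA_character_
      if (is.na(a) || is.na(b) || identical(a, b)) next
      kb <- kb_add_facts(kb, c(a, b), "sameAs", c(b, a), "entity", site)
    }
  }
  kb
}

# list-page type slug -> concept type
type_label_to_concept <- function(x) {
  map <- c(symptom = "Symptom", disease = "Disease", medicine = "Medicine",
           department = "Department", examination = "Examination",
           other = "Other")
  out <- map[[tolower(x)]]
  if (is.null(out)) stop("unknown entity type slug: ", x)
  out
}
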