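# Namespaces.  Entities get opaque hashed ids as IRI local parts (Chinese
# surface names are kept in rdfs:label literals), so every minted IRI is
# ASCII-safe and stable across runs.
.ns <- list(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  skos = "http://www.w3.org/2004/02/skos/core#",
  sym  = "http://example.org/symkb/vocab#",
  ent  = "http://example.org/symkb/entity/"
)

.iri <- function(prefix, local) paste0(.ns[[prefix]], local)

fact_predicate_iri <- function(p) {
  if (p == "sameAs") .iri("owl", "sameAs")
  else if (p == "exactMatch") .iri("skos", "exactMatch")
  else .iri("sym", p)
}

iri_to_predicate <- function(iri) {
  if (iri == .iri("owl", "sameAs")) return("sameAs")
  if (iri == .iri("skos", "exactMatch")) return("exactMatch")
  if (startsWith(iri, .ns$sym)) return(substring(iri, nchar(.ns$sym) + 1L))
  NA_character_
}

#' Flatten a knowledge base into RDF triples
#'
#' Every entity becomes a subject IRI with class assertions for its types,
#' an `rdfs:label` carrying the Chinese name, one `sym:fromSource` literal
#' per source and one literal triple per attribute value.  Facts become
#' plain triples; a fact with a source additionally gets a standard RDF
#' reification block (deterministic blank-node label) recording that source,
#' which is what makes `parse(serialize(kb))` restore provenance.
#'
#' @param kb a `symkb_kb`.
#' @return data.frame with columns `s`, `p`, `o`, `o_kind`
#'   (`"iri"`/`"literal"`/`"blank"`), `lang`.
#' @export
kb_to_triples <- function(kb) {
  stopifnot(inherits(kb, "symkb_kb"))
  rows <- list()
  add <- function(s, p, o, o_kind, lang = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      s = s, p = p, o = o, o_kind = o_kind, lang = lang,
      stringsAsFactors = FALSE)
  }
  for (e in kb$entities) {
    s <- .iri("ent", e$id)
    for (tp in e$types) add(s, .iri("rdf", "type"), .iri("sym", tp), "iri")
    add(s, .iri("rdfs", "label"), e$name, "literal", "zh")
    for (src in e$sources) add(s, .iri("sym", "fromSource"), src, "literal")
    for (an in names(e$attributes))
      for (v in e$attributes[[an]]) add(s, .iri("sym", an), v, "literal")
  }
  if (nrow(kb$facts)) {
    for (i in seq_len(nrow(kb$facts))) {
      f <- kb$facts[i, ]
      s <- .iri("ent", f$subject)
      p <- fact_predicate_iri(f$predicate)
      if (f$object_kind == "entity") {
        o <- .iri("ent", f$object); ok <- "iri"
      } else {
        o <- f$object; ok <- "literal"
      }
      add(s, p, o, ok)
      if (!is.na(f$source)) {
        bn <- paste0("_:f", str_hash(paste(s, p, o, ok, f$source, sep = "")))
        add(bn, .iri("rdf", "type"), .iri("rdf", "Statement"), "iri")
        add(bn, .iri("rdf", "subject"), s, "iri")
        add(bn, .iri("rdf", "predicate"), p, "iri")
        add(bn, .iri("rdf", "object"), o, ok)
        add(bn, .iri("sym", "factSource"), f$source, "literal")
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(s = character(), p = character(), o = character(),
                      o_kind = character(), lang = character(),
                      stringsAsFactors = FALSE))
  }
  tr <- do.call(rbind, rows)
  unique(tr)
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[[j]]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

format_term <- function(value, kind, lang, prefixed) {
  if (kind == "blank") return(value)
  if (kind == "iri") {
    if (prefixed) {
      for (pre in names(.ns)) {
        ns <- .ns[[pre]]
        if (startsWith(value, ns)) {
          local <- substring(value, nchar(ns) + 1L)
          if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local))
            return(paste0(pre, ":", local))
        }
      }
    }
    return(paste0("<", value, ">"))
  }
  lit <- paste0("\"", escape_literal(value), "\"")
  if (!is.na(lang) && nzchar(lang)) lit <- paste0(lit, "@", lang)
  lit
}

term_kind <- function(value) {
  if (startsWith(value, "_:")) "blank" else "iri"
}

#' Serialize a knowledge base as RDF
#'
#' Turtle output carries a prefix block and uses prefixed names where the
#' local part is ASCII-safe; N-Triples output uses full IRIs throughout.
#' Both emit one triple per line in a canonical sort order, so serialization
#' is deterministic.
#'
#' @param kb a `symkb_kb`.
#' @param dialect `"turtle"` or `"ntriples"`.
#' @return a single UTF-8 string.
#' @export
serialize_rdf <- function(kb, dialect = c("turtle", "ntriples")) {
  dialect <- match.arg(dialect)
  tr <- kb_to_triples(kb)
  prefixed <- dialect == "turtle"
  lines <- character(nrow(tr))
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      lines[[i]] <- paste(
        format_term(tr$s[[i]], term_kind(tr$s[[i]]), NA, prefixed),
        format_term(tr$p[[i]], "iri", NA, prefixed),
        format_term(tr$o[[i]], tr$o_kind[[i]], tr$lang[[i]], prefixed),
        ".")
    }
    lines <- sort(lines, method = "radix")
  }
  header <- if (prefixed)
    vapply(names(.ns), function(p) sprintf("@prefix %s: <%s> .", p, .ns[[p]]),
           character(1))
  else character(0)
  paste0(paste(c(header, lines), collapse = "\n"), "\n")
}

# scan one term starting at position i of a character vector of single chars;
# returns list(value, kind, lang, next_i)
scan_term <- function(chars, i, prefixes) {
  n <- length(chars)
  while (i <= n && chars[[i]] %in% c(" ", "\t")) i <- i + 1L
  if (i > n) stop("unexpected end of triple line")
  ch <- chars[[i]]
  if (ch == "<") {
    j <- i + 1L
    while (j <= n && chars[[j]] != ">") j <- j + 1L
    if (j > n) stop("unterminated IRI")
    return(list(value = paste(chars[(i + 1L):(j - 1L)], collapse = ""),
                kind = "iri", lang = NA_character_, next_i = j + 1L))
  }
  if (ch == "_") {
    j <- i
    while (j <= n && !chars[[j]] %in% c(" ", "\t")) j <- j + 1L
    return(list(value = paste(chars[i:(j - 1L)], collapse = ""),
                kind = "blank", lang = NA_character_, next_i = j))
  }
  if (ch == "\"") {
    j <- i + 1L
    while (j <= n) {
      if (chars[[j]] == "\\") { j <- j + 2L; next }
      if (chars[[j]] == "\"") break
      j <- j + 1L
    }
    if (j > n) stop("unterminated literal")
    raw <- if (j > i + 1L) paste(chars[(i + 1L):(j - 1L)], collapse = "") else ""
    value <- unescape_literal(raw)
    lang <- NA_character_
    k <- j + 1L
    if (k <= n && chars[[k]] == "@") {
      m <- k + 1L
      while (m <= n && grepl("[A-Za-z-]", chars[[m]])) m <- m + 1L
      lang <- paste(chars[(k + 1L):(m - 1L)], collapse = "")
      k <- m
    }
    return(list(value = value, kind = "literal", lang = lang, next_i = k))
  }
  # prefixed name (turtle)
  j <- i
  while (j <= n && !chars[[j]] %in% c(" ", "\t")) j <- j + 1L
  tok <- paste(chars[i:(j - 1L)], collapse = "")
  parts <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", tok))[[1]]
  if (length(parts) != 3L || !parts[[2]] %in% names(prefixes))
    stop("cannot parse RDF term: ", tok)
  list(value = paste0(prefixes[[parts[[2]]]], parts[[3]]),
       kind = "iri", lang = NA_character_, next_i = j)
}

#' Parse RDF produced by [serialize_rdf()]
#'
#' Reads the one-triple-per-line Turtle/N-Triples subset this package emits
#' (`@prefix` declarations, IRIs, blank nodes, language-tagged literals).
#'
#' @param text RDF string or character vector of lines.
#' @param dialect `"turtle"` or `"ntriples"`.
#' @return a triple data.frame as from [kb_to_triples()].
#' @export
parse_rdf_triples <- function(text, dialect = c("turtle", "ntriples")) {
  dialect <- match.arg(dialect)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  prefixes <- character(0)
  out <- vector("list", length(lines))
  k <- 0L
  for (ln in lines) {
    if (startsWith(ln, "@prefix")) {
      m <- regmatches(ln, regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9]*):\\s+<([^>]*)>\\s+\\.$", ln))[[1]]
      if (length(m) == 3L) prefixes[[m[[2]]]] <- m[[3]]
      next
    }
    chars <- strsplit(ln, "", fixed = TRUE)[[1]]
    s <- scan_term(chars, 1L, prefixes)
    p <- scan_term(chars, s$next_i, prefixes)
    o <- scan_term(chars, p$next_i, prefixes)
    rest <- if (o$next_i <= length(chars))
      trimws(paste(chars[o$next_i:length(chars)], collapse = "")) else ""
    if (rest != ".") stop("malformed triple line: ", ln)
    k <- k + 1L
    out[[k]] <- data.frame(s = s$value, p = p$value, o = o$value,
                           o_kind = o$kind, lang = o$lang,
                           stringsAsFactors = FALSE)
  }
  if (!k) {
    return(data.frame(s = character(), p = character(), o = character(),
                      o_kind = character(), lang = character(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out[seq_len(k)]))
}

#' Rebuild a knowledge base from RDF triples
#'
#' Inverse of [kb_to_triples()].  Reified statements restore fact sources;
#' literal triples without a reification are read back as entity attributes,
#' entity-object triples without one as facts with unknown source.
#'
#' @param triples triple data.frame.
#' @param schema property vocabulary.
#' @return a `symkb_kb`.
#' @export
triples_to_kb <- function(triples, schema = kb_schema()) {
  kb <- kb_new(schema)
  is_ent <- startsWith(triples$s, .ns$ent)
  is_blank <- startsWith(triples$s, "_:")

  # reified provenance: blank-node statements
  reif <- triples[is_blank, , drop = FALSE]
  facts_prov <- NULL
  if (nrow(reif)) {
    by_bn <- split(reif, reif$s)
    facts_prov <- do.call(rbind, lapply(by_bn, function(g) {
      gets <- function(p) {
        i <- which(g$p == .iri("rdf", p))
        if (length(i)) g[i[[1L]], c("o", "o_kind")] else NULL
      }
      su <- gets("subject"); pr <- gets("predicate"); ob <- gets("object")
      src <- g$o[g$p == .iri("sym", "factSource")]
      if (is.null(su) || is.null(pr) || is.null(ob) || !length(src)) return(NULL)
      data.frame(s = su$o, p = pr$o, o = ob$o, o_kind = ob$o_kind,
                 source = src[[1L]], stringsAsFactors = FALSE)
    }))
  }

  ent_tr <- triples[is_ent, , drop = FALSE]
  subjects <- unique(ent_tr$s)
  fact_rows <- list()
  for (s in subjects) {
    g <- ent_tr[ent_tr$s == s, , drop = FALSE]
    id <- substring(s, nchar(.ns$ent) + 1L)
    type_o <- g$o[g$p == .iri("rdf", "type") & startsWith(g$o, .ns$sym)]
    types <- substring(type_o, nchar(.ns$sym) + 1L)
    name <- g$o[g$p == .iri("rdfs", "label")]
    sources <- g$o[g$p == .iri("sym", "fromSource")]
    attrs <- list()
    for (i in seq_len(nrow(g))) {
      p <- g$p[[i]]
      pred <- iri_to_predicate(p)
      if (is.na(pred) || pred %in% c("fromSource", "factSource")) next
      o <- g$o[[i]]; ok <- g$o_kind[[i]]
      prov <- if (!is.null(facts_prov))
        facts_prov[facts_prov$s == s & facts_prov$p == p & facts_prov$o == o, , drop = FALSE]
      else NULL
      if (!is.null(prov) && nrow(prov)) {
        for (src in prov$source)
          fact_rows[[length(fact_rows) + 1L]] <- data.frame(
            subject = id, predicate = pred,
            object = if (ok == "iri") substring(o, nchar(.ns$ent) + 1L) else o,
            object_kind = if (ok == "iri") "entity" else "literal",
            source = src, stringsAsFactors = FALSE)
      } else if (ok == "iri" && startsWith(o, .ns$ent)) {
        fact_rows[[length(fact_rows) + 1L]] <- data.frame(
          subject = id, predicate = pred,
          object = substring(o, nchar(.ns$ent) + 1L),
          object_kind = "entity", source = NA_character_,
          stringsAsFactors = FALSE)
      } else if (ok == "literal") {
        attrs[[pred]] <- c(attrs[[pred]], o)
      }
    }
    ent <- new_entity(name = name[[1L]], types = types,
                      sources = sources, attributes = attrs, id = id)
    kb <- kb_add_entity(kb, ent)
  }
  if (length(fact_rows)) {
    df <- unique(do.call(rbind, fact_rows))
    kb <- kb_add_facts(kb, df$subject, df$predicate, df$object,
                       df$object_kind, df$source)
  }
  kb
}

#' Parse an RDF serialization back into a knowledge base
#'
#' @inheritParams parse_rdf_triples
#' @param schema property vocabulary.
#' @return a `symkb_kb`.
#' @export
parse_rdf <- function(text, dialect = c("turtle", "ntriples"),
                      schema = kb_schema()) {
  triples_to_kb(parse_rdf_triples(text, dialect), schema)
}

#' Canonical N-Triples form of a knowledge base
#'
#' Two knowledge bases are equal up to ordering iff their canonical forms
#' are byte-identical; used by the round-trip tests.
#'
#' @param kb a `symkb_kb`.
#' @return a string.
#' @export
rdf_canonical <- function(kb) serialize_rdf(kb, "ntriples")
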