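#' Longest common subsequence length of two strings
#'
#' Computed at character level over Unicode code points (Chinese medical
#' names are short and unsegmented, so word-level LCS would demand a
#' segmenter inside a similarity primitive).
#'
#' @param a,b strings.
#' @return non-negative integer.
#' @export
lcs_length <- function(a, b) {
  lcs_length_cpp(utf8ToInt(enc2utf8(a)), utf8ToInt(enc2utf8(b)))
}

#' Name-string similarity (commonness)
#'
#' `|LCS(a, b)| / max(|a|, |b|)`: the longest-common-subsequence length
#' normalized by the longer name.  Symmetric, in `[0, 1]`, and 1 iff the
#' strings are identical.  Two empty strings are an error (0/0 is
#' undefined, and empty names violate the entity invariants anyway).
#'
#' @param a,b strings, not both empty.
#' @return numeric in `[0, 1]`.
#' @export
string_similarity <- function(a, b) {
  na <- nchar(a, type = "chars"); nb <- nchar(b, type = "chars")
  if (na == 0L && nb == 0L) stop("string similarity of two empty strings is undefined")
  lcs_length(a, b) / max(na, nb)
}

#' Align an entity's type by priority-broken voting
#'
#' The type receiving the most votes wins; among tied top types the one
#' supported by the highest-priority source wins (priorities mirror the
#' sources' traffic rankings).
#'
#' @param votes data.frame with columns `type` and `source`.
#' @param priority character vector of source ids, highest priority first;
#'   must cover every voting source.
#' @return a single type label.
#' @export
align_type <- function(votes, priority) {
  if (!nrow(votes)) stop("empty vote list")
  missing <- setdiff(unique(votes$source), priority)
  if (length(missing))
    stop("voting source(s) not in priority list: ", paste(missing, collapse = ", "))
  tab <- table(votes$type)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  best_rank <- vapply(top, function(tp)
    min(match(votes$source[votes$type == tp], priority)), numeric(1))
  top[[which.min(best_rank)]]
}

#' Fact-overlap relatedness of two same-type entities
#'
#' Over the attributes present in both entities, an attribute counts as
#' similar when some pair of its values reaches the name-similarity
#' threshold; relatedness is the similar share of shared attributes.
#' Entities sharing no attribute get relatedness 0 and are flagged: name
#' evidence alone never merges them.
#'
#' @param a,b `symkb_entity` objects of the same coarse type.
#' @param value_sim_threshold similarity needed for two attribute values to
#'   count as the same fact (default 0.85).
#' @return list with `relatedness`, `n_shared`, `n_similar`, `flagged`.
#' @export
relatedness <- function(a, b, value_sim_threshold = 0.85) {
  if (!length(intersect(coarse_of(a$types), coarse_of(b$types))))
    stop("relatedness requires entities of the same coarse type")
  shared <- intersect(names(a$attributes), names(b$attributes))
  if (!length(shared))
    return(list(relatedness = 0, n_shared = 0L, n_similar = 0L, flagged = TRUE))
  similar <- vapply(shared, function(an) {
    va <- a$attributes[[an]]; vb <- b$attributes[[an]]
    for (x in va) for (y in vb) {
      if (!nzchar(x) && !nzchar(y)) next
      if (string_similarity(x, y) >= value_sim_threshold) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(relatedness = sum(similar) / length(shared),
       n_shared = length(shared), n_similar = sum(similar), flagged = FALSE)
}

# union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[[i]] != i) i <- parent[[i]]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[[max(ri, rj)]] <- min(ri, rj)
  parent
}

#' Map and merge duplicate entities across sources
#'
#' For every pair of entities sharing a coarse type, commonness (name
#' similarity) times relatedness (shared-fact overlap) above the product
#' threshold links the pair; clusters are the transitive closure of links
#' and merge into one entity keeping the name of the highest-priority
#' source, the union of types, sources and attributes.  Pairs whose
#' commonness already rules the product out are skipped, which is what
#' keeps the comparison quadratic only within small candidate sets.
#'
#' @param entities list of `symkb_entity`.
#' @param product_threshold merge when commonness x relatedness exceeds
#'   this (default 0.5).
#' @param value_sim_threshold see [relatedness()].
#' @param priority ordered source ids (highest first); defaults to the
#'   sources in order of first appearance.
#' @return list with `entities` (merged list), `clusters` (list of id
#'   vectors, non-singletons), `audit` (pair decisions) and `flagged`
#'   (same-name pairs blocked for lack of shared attributes, for manual
#'   review).
#' @export
map_entities <- function(entities, product_threshold = 0.5,
                         value_sim_threshold = 0.85, priority = NULL) {
  n <- length(entities)
  ids <- vapply(entities, `[[`, character(1), "id")
  stopifnot(!anyDuplicated(ids))
  if (is.null(priority))
    priority <- unique(unlist(lapply(entities, `[[`, "sources")))
  group_key <- vapply(entities, function(e)
    paste(sort(coarse_of(e$types)), collapse = "|"), character(1))
  parent <- uf_new(n)
  audit <- list()
  flagged <- list()
  for (g in unique(group_key)) {
    idx <- which(group_key == g)
    if (length(idx) < 2L) next
    names_g <- vapply(entities[idx], `[[`, character(1), "name")
    for (ii in seq_len(length(idx) - 1L)) {
      for (jj in seq.int(ii + 1L, length(idx))) {
        i <- idx[[ii]]; j <- idx[[jj]]
        cmn <- string_similarity(names_g[[ii]], names_g[[jj]])
        if (cmn <= product_threshold) next  # product can no longer exceed it
        rel <- relatedness(entities[[i]], entities[[j]], value_sim_threshold)
        product <- cmn * rel$relatedness
        merged <- product > product_threshold
        audit[[length(audit) + 1L]] <- data.frame(
          a = ids[[i]], b = ids[[j]],
          a_name = names_g[[ii]], b_name = names_g[[jj]],
          commonness = cmn, relatedness = rel$relatedness,
          product = product, merged = merged, stringsAsFactors = FALSE)
        if (rel$flagged && cmn == 1)
          flagged[[length(flagged) + 1L]] <- data.frame(
            a = ids[[i]], b = ids[[j]], name = names_g[[ii]],
            stringsAsFactors = FALSE)
        if (merged) parent <- uf_union(parent, i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  merged_entities <- list()
  clusters <- list()
  for (r in sort(unique(roots))) {
    members <- which(roots == r)
    if (length(members) == 1L) {
      e <- entities[[members]]
      merged_entities[[e$id]] <- e
      next
    }
    mem_ents <- entities[members]
    ranks <- vapply(mem_ents, function(e) {
      rk <- match(e$sources, priority)
      if (all(is.na(rk))) Inf else min(rk, na.rm = TRUE)
    }, numeric(1))
    rep_i <- order(ranks, vapply(mem_ents, `[[`, character(1), "id"))[[1]]
    rep <- mem_ents[[rep_i]]
    attrs <- list()
    for (e in mem_ents) for (an in names(e$attributes))
      attrs[[an]] <- unique(c(attrs[[an]], e$attributes[[an]]))
    merged <- new_entity(
      name = rep$name,
      types = unique(unlist(lapply(mem_ents, `[[`, "types"))),
      sources = unique(unlist(lapply(mem_ents, `[[`, "sources"))),
      attributes = attrs, id = rep$id)
    merged_entities[[merged$id]] <- merged
    clusters[[length(clusters) + 1L]] <- sort(ids[members])
  }
  bind <- function(rows, proto) if (length(rows)) do.call(rbind, rows) else proto
  list(entities = unname(merged_entities),
       clusters = clusters,
       audit = bind(audit, data.frame(
         a = character(), b = character(), a_name = character(),
         b_name = character(), commonness = numeric(),
         relatedness = numeric(), product = numeric(), merged = logical(),
         stringsAsFactors = FALSE)),
       flagged = bind(flagged, data.frame(
         a = character(), b = character(), name = character(),
         stringsAsFactors = FALSE)))
}

#' Merged pairs implied by clusters
#'
#' Expands each cluster into its unordered id pairs, the unit at which
#' mapping precision and recall are scored against planted duplicates.
#'
#' @param clusters list of id vectors.
#' @return data.frame with columns `a`, `b` (`a < b`).
#' @export
cluster_pairs <- function(clusters) {
  rows <- list()
  for (cl in clusters) {
    cl <- sort(cl)
    if (length(cl) < 2L) next
    for (i in seq_len(length(cl) - 1L))
      for (j in seq.int(i + 1L, length(cl)))
        rows[[length(rows) + 1L]] <- data.frame(a = cl[[i]], b = cl[[j]],
                                                stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

#' Pairwise precision/recall of a mapping against gold duplicate pairs
#'
#' @param pred,gold data.frames of unordered id pairs (`a`, `b`).
#' @return list with `precision`, `recall`, counts.
#' @export
pair_metrics <- function(pred, gold) {
  norm <- function(df) if (nrow(df))
    unique(paste(pmin(df$a, df$b), pmax(df$a, df$b), sep = "")) else character(0)
  p <- norm(pred); g <- norm(gold)
  hit <- length(intersect(p, g))
  list(precision = if (length(p)) hit / length(p) else NA_real_,
       recall = if (length(g)) hit / length(g) else NA_real_,
       n_pred = length(p), n_gold = length(g), n_match = hit)
}

#' Map a source attribute onto a schema property
#'
#' Rules are matched most-specific first (rules constraining subject and/or
#' value type precede unconstrained ones); the first match wins, and an
#' attribute no rule covers is reported as unmapped so it can be
#' quarantined rather than silently dropped.
#'
#' @param attr_name source attribute name.
#' @param subject_type,value_type coarse concept types of the subject
#'   entity and the value (may be `NA` when unknown).
#' @param rules data.frame with columns `attr`, `subject_type`,
#'   `value_type` (`NA` = unconstrained) and `target`.
#' @return the target property name, or `NA_character_` when unmapped.
#' @export
map_attribute <- function(attr_name, subject_type = NA, value_type = NA,
                          rules) {
  stopifnot(all(c("attr", "subject_type", "value_type", "target") %in%
                  names(rules)))
  specificity <- (!is.na(rules$subject_type)) + (!is.na(rules$value_type))
  rules <- rules[order(-specificity), , drop = FALSE]
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (r$attr != attr_name) next
    if (!is.na(r$subject_type) &&
        (is.na(subject_type) || r$subject_type != subject_type)) next
    if (!is.na(r$value_type) &&
        (is.na(value_type) || r$value_type != value_type)) next
    return(r$target)
  }
  NA_character_
}

#' Default attribute-mapping rules
#'
#' The manual map from healthcare-site attribute names to schema
#' properties, plus the type-sensitive rules used for encyclopedia
#' infoboxes (e.g. a `symptom` attribute between two symptoms maps to the
#' symptom-to-symptom relation).
#'
#' @return a rules data.frame for [map_attribute()].
#' @export
default_attribute_rules <- function() {
  data.frame(
    attr = c("symptom", "symptom",
             "相关科室", "相关疾病",
             "相关症状", "常见部位",
             "药品描述", "描述"),
    subject_type = c("Symptom", NA, NA, NA, NA, NA, NA, NA),
    value_type = c("Symptom", NA, NA, NA, NA, NA, NA, NA),
    target = c("symptom_related_symptom", "symptom_related_symptom",
               "relevant_department", "relevant_disease",
               "symptom_related_symptom", "location",
               "description", "description"),
    stringsAsFactors = FALSE
  )
}

#' Write a merge-audit table as TSV
#'
#' @param audit audit data.frame from [map_entities()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_merge_audit <- function(audit, path) {
  write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Fuse duplicate entities inside a knowledge base
#'
#' Runs [map_entities()] over the KB's entities and rebuilds the store:
#' merged entities replace their cluster members and every fact is rewritten
#' onto the cluster representatives (duplicate facts collapse).
#'
#' @param kb a `symkb_kb`.
#' @inheritParams map_entities
#' @return list with `kb` (fused), `clusters`, `audit`, `flagged`.
#' @export
kb_fuse <- function(kb, product_threshold = 0.5, value_sim_threshold = 0.85,
                    priority = NULL) {
  res <- map_entities(unname(kb$entities), product_threshold,
                      value_sim_threshold, priority)
  remap <- stats::setNames(names(kb$entities), names(kb$entities))
  for (cl in res$clusters) {
    rep_id <- vapply(res$entities, `[[`, character(1), "id")
    rep_id <- rep_id[rep_id %in% cl][[1L]]
    remap[cl] <- rep_id
  }
  out <- kb_new(kb$schema)
  for (e in res$entities) out <- kb_add_entity(out, e)
  if (nrow(kb$facts)) {
    f <- kb$facts
    f$subject <- unname(remap[f$subject])
    is_ent <- f$object_kind == "entity"
    f$object[is_ent] <- unname(remap[f$object[is_ent]])
    f <- unique(f[f$subject != f$object | !is_ent, , drop = FALSE])
    out <- kb_add_facts(out, f$subject, f$predicate, f$object,
                        f$object_kind, f$source)
  }
  list(kb = out, clusters = res$clusters, audit = res$audit,
       flagged = res$flagged)
}
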