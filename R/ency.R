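#' Construct an encyclopedia page record
#'
#' Encyclopedia entity pages decompose into five fields: entity name,
#' abstract, content, full text and the page's category tags.  When
#' `full_text` is not supplied it defaults to abstract + content.
#'
#' @param name entity name (non-empty).
#' @param abstract,content,full_text text fields.
#' @param categories character vector of category tags.
#' @return an object of class `symkb_ency_page`.
#' @export
ency_page <- function(name, abstract = "", content = "", full_text = NULL,
                      categories = character(0)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("page name must be a non-empty string")
  structure(list(name = name, abstract = abstract, content = content,
                 full_text = full_text %||% paste(abstract, content),
                 categories = unique(as.character(categories))),
            class = "symkb_ency_page")
}

#' Read / write encyclopedia pages as JSONL
#'
#' One JSON object per line with the five page fields.
#'
#' @param pages list of `symkb_ency_page`.
#' @param path file path.
#' @return `read_ency_jsonl` returns a list of pages.
#' @export
write_ency_jsonl <- function(pages, path) {
  lines <- vapply(pages, function(p)
    jsonlite::toJSON(unclass(p), auto_unbox = TRUE), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ency_jsonl
#' @export
read_ency_jsonl <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(ln) {
    x <- jsonlite::fromJSON(ln)
    ency_page(x$name, x$abstract %||% "", x$content %||% "",
              x$full_text, as.character(x$categories))
  })
}

#' Collect the categories of seed entities
#'
#' First step of the bootstrap: entities already extracted from healthcare
#' websites act as seeds; the categories of their encyclopedia pages form
#' the candidate category set.  Seeds without a page are skipped with a log.
#'
#' @param seeds character vector of seed entity names.
#' @param pages list of `symkb_ency_page` (indexed by page name).
#' @return character vector (set union of seed-page categories).
#' @export
collect_seed_categories <- function(seeds, pages) {
  idx <- stats::setNames(pages, vapply(pages, `[[`, character(1), "name"))
  out <- character(0)
  for (s in seeds) {
    p <- idx[[s]]
    if (is.null(p)) { symkb_log("seed without encyclopedia page: ", s); next }
    out <- union(out, p$categories)
  }
  out
}

# invert pages into category -> member entity names
category_members <- function(pages) {
  out <- list()
  for (p in pages) for (cat in p$categories)
    out[[cat]] <- c(out[[cat]], p$name)
  lapply(out, unique)
}

#' Score candidate categories by their seed ratio
#'
#' A category's confidence is the ratio of seeds among its member entities;
#' categories at or above the threshold are high-confidence, the rest
#' low-confidence (and their members are treated as noise downstream).
#'
#' @param seeds character vector of seed names.
#' @param members named list: category -> member entity names (each category
#'   must have at least one member).
#' @param threshold ratio cut-off in `[0, 1]` (default 0.1).
#' @return data.frame with columns `category`, `seed_count`, `entity_count`,
#'   `ratio`, `label` (`"high"`/`"low"`).
#' @export
score_categories <- function(seeds, members, threshold = 0.1) {
  if (any(lengths(members) == 0L)) stop("category with zero members")
  seed_count <- vapply(members, function(m) length(intersect(m, seeds)),
                       integer(1))
  entity_count <- lengths(members)
  ratio <- seed_count / entity_count
  data.frame(category = names(members),
             seed_count = unname(seed_count),
             entity_count = unname(entity_count),
             ratio = unname(ratio),
             label = ifelse(ratio >= threshold, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Remove noise pages convicted by low-confidence categories
#'
#' A page is noise iff at least one of its categories is low-confidence.
#' Pages with no categories at all are retained: the rule removes only on
#' positive evidence.
#'
#' @param pages list of `symkb_ency_page`.
#' @param low_confidence character vector of low-confidence categories.
#' @return the retained subset of `pages`.
#' @export
filter_noise_entities <- function(pages, low_confidence) {
  keep <- vapply(pages, function(p)
    !length(intersect(p$categories, low_confidence)), logical(1))
  pages[keep]
}

#' Seed-category bootstrap over an encyclopedia corpus
#'
#' Single pass: collect the categories of the seed pages, score every
#' category observed in the corpus by its seed ratio (a category no seed
#' page reaches simply scores 0), and drop pages convicted by
#' low-confidence categories.
#'
#' @param pages list of `symkb_ency_page`.
#' @param seeds character vector of seed entity names.
#' @param threshold seed-ratio cut-off.
#' @return list with `seed_categories`, `scores` (data.frame), `high`,
#'   `low` (category sets) and `retained` (page list).
#' @export
bootstrap_encyclopedia <- function(pages, seeds, threshold = 0.1) {
  seed_cats <- collect_seed_categories(seeds, pages)
  members <- category_members(pages)
  scores <- if (length(members)) score_categories(seeds, members, threshold)
            else data.frame(category = character(), seed_count = integer(),
                            entity_count = integer(), ratio = numeric(),
                            label = character(), stringsAsFactors = FALSE)
  low <- scores$category[scores$label == "low"]
  list(seed_categories = seed_cats,
       scores = scores, high = scores$category[scores$label == "high"],
       low = low, retained = filter_noise_entities(pages, low))
}

#' Default keyword lists for the 26 page features
#'
#' Word lists per page field driving the entity-type features: name
#' suffixes (department/disease/inflammation/tumour/syndrome/examination),
#' abstract symptom vocabulary, medicine-leaflet and disease-article content
#' vocabularies, TCM full-text markers and category keywords.
#'
#' @return a named list of character vectors.
#' @export
default_feature_config <- function() {
  list(
    name_suffix = c("科", "病", "炎", "瘤",
                    "综合征", "检查"),
    abstract_words = c("症状", "综合征",
                       "病症", "中医病名"),
    content_medicine = c("功能", "规格",
                         "不良反应", "副作用",
                         "成分", "用法", "用量"),
    content_disease = c("病因", "检查", "鉴别",
                        "诊断", "缓解",
                        "发病机制",
                        "临床表现"),
    fulltext_words = c("中成药", "中草药"),
    category_words = c("药品", "疾病", "中医",
                       "药物", "中成药",
                       "症状")
  )
}

#' Turn an encyclopedia page into the 26-dimensional feature vector
#'
#' Features are grouped by page field: per-word name-suffix tests (6) plus
#' an any-suffix aggregate, per-word containment tests on abstract (4),
#' full text (2) and categories (6) each with an aggregate, and for the
#' content field the distinct-hit counts of the medicine and disease word
#' lists plus their "more than 3 distinct words" booleans.  Deterministic
#' and invariant to category ordering.
#'
#' @param page a `symkb_ency_page`.
#' @param config keyword lists, see [default_feature_config()].
#' @return named numeric vector of length 26 (booleans as 0/1).
#' @export
featurize_page <- function(page, config = default_feature_config()) {
  stopifnot(inherits(page, "symkb_ency_page"))
  ends_with <- function(s, suf) {
    ns <- nchar(s); nf <- nchar(suf)
    ns >= nf && substring(s, ns - nf + 1L, ns) == suf
  }
  name_ends <- vapply(config$name_suffix, function(w)
    as.numeric(ends_with(page$name, w)), numeric(1))
  abs_has <- vapply(config$abstract_words, function(w)
    as.numeric(grepl(w, page$abstract, fixed = TRUE)), numeric(1))
  ft_has <- vapply(config$fulltext_words, function(w)
    as.numeric(grepl(w, page$full_text, fixed = TRUE)), numeric(1))
  cat_text <- paste(sort(page$categories), collapse = " ")
  cat_has <- vapply(config$category_words, function(w)
    as.numeric(grepl(w, cat_text, fixed = TRUE)), numeric(1))
  med_hits <- sum(vapply(config$content_medicine, function(w)
    grepl(w, page$content, fixed = TRUE), logical(1)))
  dis_hits <- sum(vapply(config$content_disease, function(w)
    grepl(w, page$content, fixed = TRUE), logical(1)))
  out <- c(
    stats::setNames(name_ends, paste0("name_ends_", seq_along(name_ends))),
    name_ends_any = as.numeric(any(name_ends > 0)),
    stats::setNames(abs_has, paste0("abstract_has_", seq_along(abs_has))),
    abstract_any = as.numeric(any(abs_has > 0)),
    content_med_hits = med_hits,
    content_med_gt3 = as.numeric(med_hits > 3),
    content_dis_hits = dis_hits,
    content_dis_gt3 = as.numeric(dis_hits > 3),
    stats::setNames(ft_has, paste0("fulltext_has_", seq_along(ft_has))),
    fulltext_any = as.numeric(any(ft_has > 0)),
    stats::setNames(cat_has, paste0("category_has_", seq_along(cat_has))),
    category_any = as.numeric(any(cat_has > 0))
  )
  out
}

#' Featurize a list of pages into a data.frame
#'
#' @param pages list of `symkb_ency_page`.
#' @param config keyword lists.
#' @return data.frame, one row per page, 26 feature columns.
#' @export
featurize_pages <- function(pages, config = default_feature_config()) {
  m <- t(vapply(pages, featurize_page, numeric(26), config = config))
  as.data.frame(m)
}

#' Seven entity-type labels of the classifier
#' @return character vector of the seven labels.
#' @export
entity_labels <- function() {
  c("department", "tcm_medicine", "western_medicine", "symptom",
    "disease", "examination", "other")
}

#' Train the seven-label decision-tree entity classifier
#'
#' Positives come from healthcare-site entities; negatives (label
#' `"other"`) from out-of-scope list pages.  The model is a CART decision
#' tree over the 26 page features.
#'
#' @param features data.frame of feature vectors (see [featurize_pages()]).
#' @param labels character/factor of gold labels, one per row.
#' @param minsplit,cp tree-growing controls passed to [rpart::rpart()].
#' @return an object of class `symkb_ency_model`.
#' @export
train_entity_classifier <- function(features, labels, minsplit = 4, cp = 1e-3) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2L)
    stop("training data must contain at least two distinct labels")
  dat <- cbind(features, .label = labels)
  fit <- rpart::rpart(.label ~ ., data = dat, method = "class",
                      control = rpart::rpart.control(
                        minsplit = minsplit, cp = cp, xval = 0))
  structure(list(fit = fit, feature_names = colnames(features),
                 levels = levels(labels)),
            class = "symkb_ency_model")
}

#' Classify a page (or feature row) with a trained entity model
#'
#' @param model a `symkb_ency_model`.
#' @param page a `symkb_ency_page`, or a 1-row feature data.frame.
#' @param config keyword lists used at featurization.
#' @return a single label string.
#' @export
classify_entity <- function(model, page, config = default_feature_config()) {
  feats <- if (inherits(page, "symkb_ency_page"))
    as.data.frame(as.list(featurize_page(page, config)))
  else as.data.frame(page)
  as.character(predict(model$fit, feats, type = "class"))
}

#' Macro-averaged F1 over gold classes
#'
#' @param gold,pred character vectors of labels.
#' @return list with `per_class` (data.frame) and `macro_f1`.
#' @export
macro_f1 <- function(gold, pred) {
  classes <- sort(unique(as.character(gold)))
  rows <- lapply(classes, function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(gold != cl & pred == cl)
    fn <- sum(gold == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = cl, precision = p, recall = r, f1 = f,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_class = per, macro_f1 = mean(per$f1))
}

#' K-fold cross-validation of the entity classifier
#'
#' Stratification-free random fold assignment under a fixed seed, following
#' the standard ten-fold protocol.
#'
#' @param features feature data.frame.
#' @param labels gold labels.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return list with `macro_f1`, `accuracy`, `per_class`, `predictions`.
#' @export
cv_entity_classifier <- function(features, labels, k = 10, seed = 1) {
  labels <- as.character(labels)
  n <- nrow(features)
  stopifnot(n == length(labels), n >= k)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- character(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train_entity_classifier(features[tr, , drop = FALSE], labels[tr])
    pred[!tr] <- classify_entity(model, features[!tr, , drop = FALSE])
  }
  mf <- macro_f1(labels, pred)
  list(macro_f1 = mf$macro_f1, accuracy = mean(pred == labels),
       per_class = mf$per_class, predictions = pred)
}

#' Refine a symptom page into TCM / Western subtypes
#'
#' Harvests department mentions from the page text (runs of Han characters
#' ending in the department suffix) and reuses the department-marker
#' heuristic; a symptom page with no department evidence defaults to
#' `WesternSymptom`, since TCM labels only ever arise from positive marker
#' evidence.
#'
#' @param page a `symkb_ency_page` already classified as a symptom.
#' @param markers TCM marker strings.
#' @return character subset of `c("TCMSymptom", "WesternSymptom")`.
#' @export
refine_symptom_subtype <- function(page,
                                   markers = default_heuristics()$tcm_markers) {
  m <- gregexpr("[\\p{Han}A-Za-z]{1,10}科", page$full_text, perl = TRUE)
  deps <- unique(unlist(regmatches(page$full_text, m)))
  deps <- deps[!is.na(deps)]
  out <- classify_symptom_subtype(deps, markers)
  if (!length(out)) "WesternSymptom" else out
}
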