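#' Configuration for the synthetic cross-lingual linking fixture
#'
#' @param seed integer seed.
#' @param n_exact symptoms whose translated bag of words exactly matches a
#'   concept term (planted links).
#' @param n_near symptoms whose bag differs from the nearest concept by one
#'   word (Jaccard < 1, must not link).
#' @param n_untranslatable symptoms absent from the lexicon.
#' @param semantic_types pool of concept semantic types.
#' @param p_semantic sampling weights for the semantic types.
#' @return a config list.
#' @export
link_config <- function(seed = 19, n_exact = 50, n_near = 50,
                        n_untranslatable = 5,
                        semantic_types = c("Sign or Symptom", "Finding",
                                           "Pathologic Function",
                                           "Disease or Syndrome"),
                        p_semantic = c(0.35, 0.25, 0.2, 0.2)) {
  as.list(environment())
}

# random unique word bags of 1..3 English words
.draw_bags <- function(n, min_words = 1, max_words = 3) {
  used <- character(0)
  bags <- vector("list", n)
  k <- 0L
  while (k < n) {
    bag <- sort(sample(.en_words, sample(min_words:max_words, 1L)))
    key <- paste(bag, collapse = " ")
    if (key %in% used) next
    used <- c(used, key)
    k <- k + 1L
    bags[[k]] <- bag
  }
  bags
}

# render a bag as a concept-table style term ("Fever, High") or as a plain
# translation phrase
.render_term <- function(bag) {
  words <- sample(bag)
  words <- vapply(words, function(w)
    paste0(toupper(substring(w, 1, 1)), substring(w, 2)), character(1))
  paste(words, collapse = ", ")
}

#' Generate the bilingual lexicon, concept table and gold links
#'
#' Plants `n_exact` symptoms whose translation is bag-equal to exactly one
#' concept term (under the frozen normalization) and `n_near` near-misses
#' whose closest concept differs by one word; every bag in the fixture is
#' unique, so the gold link set is exact by construction.
#'
#' @param config a [link_config()].
#' @return list with `symptoms` (data.frame `id`, `name`), `lexicon`
#'   (`chinese`, `english`), `concepts` (`cui`, `term`, `semantic_type`)
#'   and `truth` (`gold_links` data.frame, `untranslatable` names).
#' @export
generate_linking_fixture <- function(config = link_config()) {
  with_seed(config$seed, {
    n_sym <- config$n_exact + config$n_near + config$n_untranslatable
    zh_names <- c(synth_symptom_name(min(n_sym, 150)),
                  synth_tcm_symptom_name(max(0, n_sym - 150)))[seq_len(n_sym)]
    n_bags <- config$n_exact + 2L * config$n_near
    bags <- .draw_bags(n_bags, min_words = 1, max_words = 3)

    lexicon <- list(); concepts <- list(); gold <- list()
    cui_i <- 0L
    next_cui <- function() { cui_i <<- cui_i + 1L; sprintf("C%07d", cui_i) }
    st <- function() sample(config$semantic_types, 1L, prob = config$p_semantic)

    idx <- 0L
    for (k in seq_len(config$n_exact)) {
      idx <- idx + 1L
      bag <- bags[[k]]
      zh <- zh_names[[idx]]
      lexicon[[idx]] <- data.frame(chinese = zh,
                                   english = paste(sample(bag), collapse = " "),
                                   stringsAsFactors = FALSE)
      cui <- next_cui()
      concepts[[length(concepts) + 1L]] <- data.frame(
        cui = cui, term = .render_term(bag), semantic_type = st(),
        stringsAsFactors = FALSE)
      gold[[k]] <- data.frame(name = zh, cui = cui, stringsAsFactors = FALSE)
    }
    for (k in seq_len(config$n_near)) {
      idx <- idx + 1L
      sym_bag <- bags[[config$n_exact + 2L * k - 1L]]
      # concept bag: the symptom bag with one word added or removed
      con_bag <- if (length(sym_bag) > 1L && runif(1) < 0.5)
        sym_bag[-sample(length(sym_bag), 1L)]
      else sort(c(sym_bag, sample(setdiff(.en_words, sym_bag), 1L)))
      # keep the perturbed bag unique in the fixture too
      if (any(vapply(bags, function(b) identical(b, con_bag), logical(1))))
        con_bag <- bags[[config$n_exact + 2L * k]]
      zh <- zh_names[[idx]]
      lexicon[[idx]] <- data.frame(chinese = zh,
                                   english = paste(sample(sym_bag), collapse = " "),
                                   stringsAsFactors = FALSE)
      concepts[[length(concepts) + 1L]] <- data.frame(
        cui = next_cui(), term = .render_term(con_bag), semantic_type = st(),
        stringsAsFactors = FALSE)
    }
    untranslatable <- character(0)
    for (k in seq_len(config$n_untranslatable)) {
      idx <- idx + 1L
      untranslatable <- c(untranslatable, zh_names[[idx]])
    }
    symptoms <- data.frame(
      id = vapply(zh_names, function(n) entity_id("linkfix", n), character(1)),
      name = zh_names, stringsAsFactors = FALSE)
    gold_df <- do.call(rbind, gold)
    gold_df$symptom_id <- symptoms$id[match(gold_df$name, symptoms$name)]
    list(symptoms = symptoms,
         lexicon = do.call(rbind, lexicon),
         concepts = do.call(rbind, concepts),
         truth = list(gold_links = gold_df,
                      untranslatable = untranslatable))
  })
}
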