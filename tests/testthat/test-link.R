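test_that("bag-of-words normalization lowercases, strips punctuation, dedups", {
  expect_setequal(bag_of_words("High Fever"), c("high", "fever"))
  expect_setequal(bag_of_words("fever, high"), c("fever", "high"))
  expect_length(bag_of_words(""), 0L)
  expect_setequal(bag_of_words("Fever fever FEVER!"), "fever")
})

test_that("Jaccard similarity follows set semantics", {
  expect_identical(jaccard("fever", "fever"), 1)
  expect_identical(jaccard(c("high", "fever"), "fever"), 0.5)
  expect_identical(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_error(jaccard(character(0), character(0)), "undefined")
  expect_identical(jaccard(c("a", "b"), c("b", "a")), 1)
})

test_that("linking requires an exactly equal bag, tolerant of order and case", {
  symptoms <- data.frame(id = c("s1", "s2"), name = c("发热", "高热"))
  translator <- make_lexicon_translator(
    data.frame(chinese = c("发热", "高热"),
               english = c("fever", "high fever")))
  concepts <- data.frame(cui = c("C1", "C2"),
                         term = c("Fever", "Fever, Persistent"),
                         semantic_type = c("Sign or Symptom", "Finding"))
  links <- link_symptoms(symptoms, translator, concepts)
  expect_identical(links$symptom_id, "s1")
  expect_identical(links$cui, "C1")
  expect_true(all(audit_links(links)))
})

test_that("untranslatable symptoms are skipped, multi-concept bags all link", {
  symptoms <- data.frame(id = c("s1", "s2"), name = c("发热", "无词条"))
  translator <- make_lexicon_translator(
    data.frame(chinese = "发热", english = "fever"))
  concepts <- data.frame(cui = c("C1", "C3"), term = c("Fever", "fever"),
                         semantic_type = c("Sign or Symptom",
                                           "Pathologic Function"))
  links <- link_symptoms(symptoms, translator, concepts)
  expect_identical(nrow(links), 2L)
  expect_setequal(links$cui, c("C1", "C3"))
})

test_that("semantic-type distribution partitions links, fractions sum to 1", {
  concepts <- data.frame(cui = c("C1", "C2", "C3", "C4"),
                         term = letters[1:4],
                         semantic_type = c("Finding", "Finding",
                                           "Pathologic Function",
                                           "Pathologic Function"))
  links <- data.frame(symptom_id = paste0("s", 1:4), cui = concepts$cui)
  d <- semantic_type_distribution(links, concepts)
  expect_identical(d$fraction[d$semantic_type == "Finding"], 0.5)
  expect_identical(sum(d$fraction), 1)
  expect_identical(nrow(semantic_type_distribution(links[0, ], concepts)), 0L)
  bad <- data.frame(symptom_id = "s9", cui = "C9")
  expect_error(semantic_type_distribution(bad, concepts), "unknown concept")
})

test_that("lexicon and concept tables round-trip through TSV", {
  fx <- generate_linking_fixture(link_config(seed = 19, n_exact = 10,
                                             n_near = 10))
  lp <- file.path(tempdir(), "lex.tsv")
  cp <- file.path(tempdir(), "con.tsv")
  write_lexicon(fx$lexicon, lp)
  write_concept_table(fx$concepts, cp)
  expect_identical(read_lexicon(lp), fx$lexicon)
  expect_identical(read_concept_table(cp), fx$concepts)
})

test_that("links can enter the KB as exact-match facts and export as RDF", {
  fx <- generate_linking_fixture(link_config(seed = 19, n_exact = 5,
                                             n_near = 5))
  kb <- kb_new()
  for (i in seq_len(nrow(fx$symptoms)))
    kb <- kb_add_entity(kb, new_entity(fx$symptoms$name[[i]], "Symptom",
                                       "linkfix", id = fx$symptoms$id[[i]]))
  links <- link_symptoms(fx$symptoms, make_lexicon_translator(fx$lexicon),
                         fx$concepts)
  kb <- kb_add_links(kb, links)
  expect_identical(sum(kb$facts$predicate == "exactMatch"), nrow(links))
  back <- parse_rdf(serialize_rdf(kb, "turtle"), "turtle")
  expect_identical(rdf_canonical(back), rdf_canonical(kb))
})
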