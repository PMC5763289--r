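test_that("the healthcare-site generator is byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "sgen1"); d2 <- file.path(tempdir(), "sgen2")
  g1 <- generate_healthcare_site(d1, site_config(seed = 7))
  g2 <- generate_healthcare_site(d2, site_config(seed = 7))
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(h1, h2)
  expect_identical(g1$truth, g2$truth)
})

test_that("duplication rate 0 plants only singleton clusters", {
  d <- file.path(tempdir(), "sgen0")
  g <- generate_healthcare_site(d, site_config(seed = 7, duplication_rate = 0))
  expect_identical(nrow(g$truth$clusters), 0L)
  expect_false(any(g$truth$entities$site == "site_b"))
})

test_that("planted duplicate pairs respect the name-similarity bound", {
  cfg <- fusion_config(seed = 11)
  fx <- generate_fusion_fixture(cfg)
  by_id <- stats::setNames(fx$entities,
                           vapply(fx$entities, `[[`, character(1), "id"))
  for (i in seq_len(nrow(fx$gold_pairs))) {
    a <- by_id[[fx$gold_pairs$a[[i]]]]
    b <- by_id[[fx$gold_pairs$b[[i]]]]
    L <- nchar(a$name)
    # <= budget edits: LCS >= L - budget and lengths grow by at most budget
    bound <- (L - cfg$name_edit_budget) / (L + cfg$name_edit_budget)
    expect_gte(string_similarity(a$name, b$name), bound)
    expect_setequal(coarse_of(a$types), coarse_of(b$types))
  }
})

test_that("encyclopedia noise counts use floor rounding and reruns are identical", {
  enc1 <- generate_encyclopedia(ency_config(seed = 13, n_pages = 95))
  expect_length(enc1$truth$noise_names, 19L)  # floor(0.2 * 95)
  enc2 <- generate_encyclopedia(ency_config(seed = 13, n_pages = 95))
  expect_identical(enc1, enc2)
  # planted keyword signal: a clean symptom page fires the abstract feature
  sym_names <- enc1$truth$labels$name[enc1$truth$labels$label == "symptom"]
  pages_by_name <- stats::setNames(enc1$pages, vapply(enc1$pages, `[[`,
                                                      character(1), "name"))
  fired <- vapply(sym_names, function(nm)
    featurize_page(pages_by_name[[nm]])[["abstract_any"]] == 1, logical(1))
  expect_gte(mean(fired), 0.9)  # all but the feature-noised pages
})

test_that("EMR and linking generators are deterministic and internally consistent", {
  c1 <- generate_emr_corpus(emr_config(seed = 17, n_records = 20))
  c2 <- generate_emr_corpus(emr_config(seed = 17, n_records = 20))
  expect_identical(c1, c2)
  # every gold span indexes a real token range
  for (s in c(c1$sequences$western[1:20], c1$sequences$tcm[1:20])) {
    sp <- bio_to_spans(s$labels)
    expect_true(all(sp$end <= length(s$tokens)))
    expect_identical(length(s$tokens), length(s$pos))
    expect_identical(length(s$tokens), length(s$labels))
  }
  l1 <- generate_linking_fixture(link_config(seed = 19))
  l2 <- generate_linking_fixture(link_config(seed = 19))
  expect_identical(l1, l2)
  # gold links are bag-equal under the frozen normalization
  lex <- make_lexicon_translator(l1$lexicon)
  for (i in seq_len(nrow(l1$truth$gold_links))) {
    g <- l1$truth$gold_links[i, ]
    term <- l1$concepts$term[l1$concepts$cui == g$cui]
    expect_identical(jaccard(bag_of_words(lex(g$name)), bag_of_words(term)), 1)
  }
})

test_that("EMR records with empty fields and boxless pages exercise edge branches", {
  r <- emr_record("edge1")
  expect_length(select_fields(r, "western"), 0L)
  expect_length(select_fields(r, "tcm"), 0L)
  expect_length(dedup_sentences(character(0)), 0L)
})
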