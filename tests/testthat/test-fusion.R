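test_that("LCS length matches the brute-force subsequence oracle", {
  expect_identical(lcs_length("ABCDE", "ACE"), 3L)
  expect_identical(lcs_length("ABCDE", "ACE"), oracle_lcs("ABCDE", "ACE"))
  expect_identical(lcs_length("相同", "相同"), 2L)
  expect_identical(lcs_length("AAA", "BBB"), 0L)
  set.seed(47)
  for (k in 1:300) {
    a <- random_string(); b <- random_string()
    expect_identical(lcs_length(a, b), oracle_lcs(a, b))
  }
})

test_that("name similarity implements |LCS| / max length with its invariants", {
  expect_identical(string_similarity("ABCDE", "ACE"), 0.6)
  expect_identical(string_similarity("头痛", "头痛"), 1.0)
  expect_identical(string_similarity("A", ""), 0.0)
  expect_error(string_similarity("", ""), "undefined")
  set.seed(48)
  for (k in 1:100) {
    a <- random_string(); b <- random_string()
    if (!nchar(a) && !nchar(b)) next
    s <- string_similarity(a, b)
    expect_identical(s, string_similarity(b, a))
    expect_true(s >= 0 && s <= 1)
    expect_identical(s == 1, identical(a, b))
    if (nchar(a) && nchar(b))
      expect_lte(s, min(nchar(a), nchar(b)) / max(nchar(a), nchar(b)))
  }
})

test_that("type voting takes pluralities, breaking ties by source priority", {
  v <- data.frame(type = c("Symptom", "Symptom", "Disease"),
                  source = c("s1", "s2", "s3"))
  expect_identical(align_type(v, c("s1", "s2", "s3")), "Symptom")
  tie <- data.frame(type = c("Symptom", "Disease"), source = c("s2", "s1"))
  expect_identical(align_type(tie, c("s1", "s2")), "Disease")
  one <- data.frame(type = "Examination", source = "s1")
  expect_identical(align_type(one, "s1"), "Examination")
  expect_error(align_type(one[0, ], "s1"), "empty")
  expect_error(align_type(one, "s9"), "not in priority")
})

test_that("relatedness is the similar share of shared attributes", {
  a <- new_entity("头痛", "Symptom", "s1",
                  list(relevant_department = "内科", location = "头"))
  b <- new_entity("头疼", "Symptom", "s2",
                  list(relevant_department = "内科", location = "头"))
  expect_identical(relatedness(a, b)$relatedness, 1.0)
  c2 <- new_entity("头疼", "Symptom", "s2",
                   list(relevant_department = "内科", location = "脚"))
  expect_identical(relatedness(a, c2)$relatedness, 0.5)
  d <- new_entity("头疼", "Symptom", "s2", list(cause = "不明"))
  rd <- relatedness(a, d)
  expect_identical(rd$relatedness, 0)
  expect_true(rd$flagged)
  e <- new_entity("感冒", "Disease", "s2", list(location = "头"))
  expect_error(relatedness(a, e), "same coarse type")
})

test_that("entity mapping merges perfect duplicates and blocks name-only matches", {
  attrs <- list(relevant_department = "内科", location = "头")
  a <- new_entity("持续性头部胀痛", "Symptom", "src1", attrs, id = "a")
  b <- new_entity("持续性头部胀痛", "Symptom", "src2", attrs, id = "b")
  res <- map_entities(list(a, b), priority = c("src1", "src2"))
  expect_length(res$clusters, 1L)
  expect_length(res$entities, 1L)
  merged <- res$entities[[1]]
  expect_identical(merged$id, "a")  # highest-priority representative
  expect_setequal(merged$sources, c("src1", "src2"))

  c1 <- new_entity("持续性头部胀痛", "Symptom", "src1",
                   list(location = "头"), id = "c1")
  c2 <- new_entity("持续性头部胀痛", "Symptom", "src2",
                   list(cause = "不明"), id = "c2")
  res2 <- map_entities(list(c1, c2))
  expect_length(res2$clusters, 0L)
  expect_identical(nrow(res2$flagged), 1L)  # exported for manual review
})

test_that("mapping never crosses coarse types and is order-independent", {
  fx <- generate_fusion_fixture(fusion_config(seed = 11, n_pairs = 25,
                                              n_singletons = 25))
  res <- map_entities(fx$entities, priority = c("src1", "src2"))
  types_of <- stats::setNames(
    lapply(fx$entities, function(e) coarse_of(e$types)),
    vapply(fx$entities, `[[`, character(1), "id"))
  for (cl in res$clusters) {
    shared <- Reduce(intersect, types_of[cl])
    expect_gt(length(shared), 0L)
  }
  perm <- with_seed(5, sample(length(fx$entities)))
  res_perm <- map_entities(fx$entities[perm], priority = c("src1", "src2"))
  norm <- function(cls) sort(vapply(cls, paste, character(1), collapse = "+"))
  expect_identical(norm(res_perm$clusters), norm(res$clusters))
})

test_that("fusing a KB conserves facts onto representatives and shrinks entities", {
  fx <- generate_fusion_fixture(fusion_config(seed = 11, n_pairs = 20,
                                              n_singletons = 10))
  kb <- kb_new()
  for (e in fx$entities) kb <- kb_add_entity(kb, e)
  kb <- kb_add_facts(kb, fx$gold_pairs$a, "location", "头部", "literal", "src1")
  fz <- kb_fuse(kb, priority = c("src1", "src2"))
  expect_lte(length(fz$kb$entities), length(kb$entities))
  expect_identical(length(fz$kb$entities),
                   length(kb$entities) - sum(lengths(fz$clusters) - 1L))
  expect_true(all(fz$kb$facts$subject %in% names(fz$kb$entities)))
})

test_that("attribute mapping is specificity-first with quarantine for unknowns", {
  rules <- default_attribute_rules()
  expect_identical(map_attribute("symptom", "Symptom", "Symptom", rules),
                   "symptom_related_symptom")
  expect_identical(map_attribute("相关科室", NA, NA, rules),
                   "relevant_department")
  expect_true(is.na(map_attribute("未知属性", NA, NA, rules)))
})
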