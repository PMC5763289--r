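test_that("type expansion adds implied parents and rejects unknown labels", {
  expect_setequal(expand_types("TCMSymptom"), c("Symptom", "TCMSymptom"))
  expect_setequal(expand_types(c("TCMMedicine", "WesternMedicine")),
                  c("Medicine", "TCMMedicine", "WesternMedicine"))
  expect_setequal(expand_types(c("TCMSymptom", "WesternSymptom")),
                  c("Symptom", "TCMSymptom", "WesternSymptom"))
  expect_error(expand_types("Sickness"), "unknown concept type")
})

test_that("entity insertion enforces id uniqueness and non-empty names", {
  kb <- kb_new()
  kb <- kb_add_entity(kb, new_entity("头痛", "Symptom", "s1"))
  expect_length(kb$entities, 1L)
  expect_error(kb_add_entity(kb, new_entity("头痛", "Symptom", "s1")),
               "duplicate entity id")
  expect_error(new_entity("", "Symptom", "s1"), "non-empty")
})

test_that("facts enforce referential integrity and the declared vocabulary", {
  kb <- kb_new()
  e1 <- new_entity("头痛", "Symptom", "s1")
  kb <- kb_add_entity(kb, e1)
  expect_error(kb_add_facts(kb, "missing", "location", "头"), "not in KB")
  expect_error(kb_add_facts(kb, e1$id, "has_color", "red"),
               "not in declared schema")
  expect_error(kb_add_facts(kb, e1$id, "sameAs", "missing", "entity"),
               "not in KB")
  # literal-ranged predicate rejects entity objects
  expect_error(kb_add_facts(kb, e1$id, "location", e1$id, "entity"),
               "incompatible")
  kb <- kb_add_facts(kb, e1$id, "location", "头部", "literal", "s1")
  expect_identical(nrow(kb$facts), 1L)
})

test_that("statistics count multi-type entities once per type and once overall", {
  st <- kb_statistics(kb_new())
  expect_identical(st$n_entities, 0L)
  expect_true(all(st$entities_by_type == 0L))

  st <- kb_statistics(tiny_kb())
  expect_identical(st$n_entities, 5L)
  expect_identical(unname(st$entities_by_type["Symptom"]), 3L)
  expect_identical(unname(st$entities_by_type["TCMSymptom"]), 1L)
  expect_identical(unname(st$entities_by_type["WesternSymptom"]), 1L)
  expect_identical(unname(st$entities_by_type["Disease"]), 2L)
  expect_identical(st$n_facts, 4L)
  # per-source counts sum to >= distinct total when sources overlap
  expect_gte(sum(st$entities_by_source), st$n_entities)
})

test_that("fact sampling is uniform, seed-reproducible and bounds-checked", {
  kb <- tiny_kb()
  expect_error(kb_sample_facts(kb, 5, seed = 1), "exceeds")
  full <- kb_sample_facts(kb, 4, seed = 1)
  expect_identical(nrow(full), 4L)
  expect_setequal(paste(full$subject, full$predicate, full$object),
                  paste(kb$facts$subject, kb$facts$predicate, kb$facts$object))
  expect_identical(kb_sample_facts(kb, 2, seed = 99),
                   kb_sample_facts(kb, 2, seed = 99))
  # law of large numbers: 10,000 singleton draws hit each of 4 facts ~ 1/4
  keys <- vapply(seq_len(10000), function(i) {
    f <- kb_sample_facts(kb, 1, seed = i)
    paste(f$subject, f$predicate, f$object)
  }, character(1))
  freq <- table(keys) / 10000
  expect_true(all(abs(freq - 0.25) <= 0.02))
})

test_that("majority vote takes strict majorities and resolves ties conservatively", {
  expect_identical(majority_vote(rep(c("correct", "incorrect"), c(5, 2))),
                   "correct")
  expect_identical(majority_vote(rep("correct", 7)), "correct")
  expect_identical(majority_vote(rep(c("correct", "incorrect"), c(2, 2))),
                   "incorrect")
  expect_error(majority_vote(character(0)), "empty")
  expect_identical(correctness_ratio(c("correct", "correct", "incorrect")),
                   2 / 3)
})
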