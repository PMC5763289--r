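test_that("field selection picks the two target fields and drops empties", {
  r <- emr_record("r1", physical_examination = "查体见头痛。",
                  antidiastole_western = "鉴别诊断。",
                  disease_analysis = "病情分析。",
                  antidiastole_tcm = "中医鉴别。")
  expect_identical(select_fields(r, "tcm"), c("病情分析。", "中医鉴别。"))
  expect_identical(select_fields(r, "western"), c("查体见头痛。", "鉴别诊断。"))
  only_pe <- emr_record("r2", physical_examination = "查体。")
  expect_identical(select_fields(only_pe, "western"), "查体。")
  expect_length(select_fields(only_pe, "tcm"), 0L)
  expect_error(select_fields(r, "nurse"))
})

test_that("sentence dedup keeps first occurrences and is idempotent", {
  expect_identical(dedup_sentences("甲。乙。甲。"), c("甲", "乙"))
  expect_identical(dedup_sentences(c("甲。乙。", "丙。")), c("甲", "乙", "丙"))
  once <- dedup_sentences("甲。乙。甲。丙！乙？")
  expect_identical(dedup_sentences(paste0(once, "。", collapse = "")), once)
  expect_lte(length(once), 5L)
})

test_that("planted duplicate sentences are removed exactly", {
  corpus <- generate_emr_corpus(emr_config(seed = 17, n_records = 40))
  for (target in c("western", "tcm")) {
    seqs <- corpus$sequences[[target]]
    by_rec <- split(seqs, vapply(seqs, `[[`, character(1), "record_id"))
    for (rid in names(by_rec)[1:10]) {
      rec <- Filter(function(r) r$record_id == rid, corpus$records)[[1]]
      got <- dedup_sentences(select_fields(rec, target))
      expected <- unique(vapply(by_rec[[rid]], function(s)
        sub("。$", "", s$text), character(1)))
      expect_identical(got, expected)
    }
  }
})

test_that("feature extraction emits exactly 37 templates with boundary padding", {
  f1 <- extract_crf_features("头痛", "n", 1)
  expect_length(f1, 37L)
  expect_true(all(grepl("<PAD>", f1[grepl("^U\\[-", f1)])))

  toks <- c("患者", "自述", "头部", "疼痛", "三天", "加重", "。")
  pos <- c("n", "v", "n", "n", "t", "v", "w")
  f4 <- extract_crf_features(toks, pos, 4)
  expect_length(f4, 37L)
  expect_true("B[-1]=头部_疼痛" %in% f4)
  expect_true("IDX=4" %in% f4)
  expect_true("PT[-1]=n_n_t" %in% f4)
  # start boundary: left window slots are padding
  fs <- extract_crf_features(toks, pos, 1)
  expect_true("U[-1]=<PAD>" %in% fs)
  # constant count at every position
  expect_true(all(vapply(seq_along(toks), function(i)
    length(extract_crf_features(toks, pos, i)), integer(1)) == 37L))
})

test_that("BIO spans decode with orphan-inside repair and stay well-formed", {
  sp <- bio_to_spans(c("O", "B-SYM", "I-SYM", "O"), c("查", "头", "痛", "。"))
  expect_identical(sp$start, 2L)
  expect_identical(sp$end, 3L)
  expect_identical(sp$text, "头痛")
  expect_identical(nrow(bio_to_spans(rep("O", 5))), 0L)
  # orphan I promoted to B
  sp2 <- bio_to_spans(c("O", "I-SYM", "I-SYM", "O"))
  expect_identical(sp2$start, 2L)
  expect_identical(sp2$end, 3L)
  # property: random label sequences always give sorted, disjoint, in-bound spans
  set.seed(41)
  for (k in 1:200) {
    n <- sample(1:12, 1)
    labs <- sample(c("B-SYM", "I-SYM", "O"), n, replace = TRUE)
    sp <- bio_to_spans(labs)
    expect_true(all(sp$start <= sp$end))
    expect_true(all(sp$start >= 1 & sp$end <= n))
    if (nrow(sp) > 1) {
      expect_true(all(diff(sp$start) > 0))
      expect_true(all(sp$start[-1] > sp$end[-nrow(sp)]))
    }
  }
})

test_that("entity-level evaluation is exact-match with undefined zero denominators", {
  gold <- data.frame(sentence = 1, start = c(1, 6), end = c(3, 7))
  pred <- data.frame(sentence = 1, start = c(1, 5), end = c(3, 7))
  ev <- evaluate_ner(gold, pred)
  expect_identical(ev$precision, 0.5)
  expect_identical(ev$recall, 0.5)
  same <- evaluate_ner(gold, gold)
  expect_identical(c(same$precision, same$recall, same$f1), c(1, 1, 1))
  none <- evaluate_ner(gold, gold[0, ])
  expect_identical(none$recall, 0)
  expect_true(is.na(none$precision))
  expect_true(is.na(none$f1))
})

test_that("CoNLL files round-trip labeled sequences", {
  corpus <- generate_emr_corpus(emr_config(seed = 17, n_records = 5))
  seqs <- lapply(corpus$sequences$western[1:8], function(s)
    s[c("tokens", "pos", "labels")])
  path <- file.path(tempdir(), "train.conll")
  write_conll(seqs, path)
  expect_identical(read_conll(path), seqs)
})

test_that("record splits reproduce the 660/340 protocol deterministically", {
  ids <- sprintf("r%04d", 1:1000)
  sp <- split_records(ids, n_train = 660, seed = 2)
  expect_length(sp$train, 660L)
  expect_length(sp$test, 340L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, split_records(ids, n_train = 660, seed = 2))
})

test_that("the segmenter does forward maximum matching with POS lookup", {
  seg <- make_segmenter(data.frame(word = c("头痛", "患者", "自述"),
                                   pos = c("n", "n", "v")))
  out <- seg("患者自述头痛。")
  expect_identical(out$tokens, c("患者", "自述", "头痛", "。"))
  expect_identical(out$pos, c("n", "v", "n", "w"))
  chars <- make_segmenter(mode = "char")("头痛")
  expect_identical(chars$tokens, c("头", "痛"))
})
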