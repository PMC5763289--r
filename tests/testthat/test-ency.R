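page <- function(name, cats, abstract = "", content = "") {
  ency_page(name, abstract, content, categories = cats)
}

test_that("seed categories are the union over seed pages, absentees skipped", {
  pages <- list(page("头痛", c("A", "B")), page("发热", c("B", "C")),
                page("其他", "D"))
  expect_setequal(collect_seed_categories(c("头痛", "发热"), pages),
                  c("A", "B", "C"))
  expect_length(collect_seed_categories(c("不存在"), pages), 0L)
})

test_that("category scoring computes seed ratios against the threshold", {
  members <- list(half = paste0("e", 1:10), all = c("s1", "s2"),
                  none = paste0("x", 1:50))
  seeds <- c(paste0("e", 1:5), "s1", "s2")
  sc <- score_categories(seeds, members, threshold = 0.1)
  expect_identical(sc$ratio[sc$category == "half"], 0.5)
  expect_identical(sc$label[sc$category == "half"], "high")
  expect_identical(sc$ratio[sc$category == "all"], 1.0)
  expect_identical(sc$ratio[sc$category == "none"], 0.0)
  expect_identical(sc$label[sc$category == "none"], "low")
  expect_error(score_categories(seeds, list(empty = character(0))),
               "zero members")
  # raising the threshold never grows the high-confidence set
  highs <- vapply(c(0, 0.05, 0.2, 0.6, 1), function(th)
    sum(score_categories(seeds, members, th)$label == "high"), numeric(1))
  expect_true(all(diff(highs) <= 0))
})

test_that("noise filtering removes on low-category evidence only and is idempotent", {
  pages <- list(page("a", c("high1", "low1")), page("b", c("high1", "high2")),
                page("c", character(0)))
  kept <- filter_noise_entities(pages, "low1")
  expect_setequal(vapply(kept, `[[`, character(1), "name"), c("b", "c"))
  expect_identical(filter_noise_entities(kept, "low1"), kept)
})

test_that("bootstrap recovers exactly the planted clean set", {
  enc <- generate_encyclopedia(ency_config(seed = 13, n_pages = 100))
  expect_length(enc$truth$noise_names, 20L)  # floor(0.2 * 100)
  bs <- bootstrap_encyclopedia(enc$pages, enc$seeds, threshold = 0.1)
  retained <- vapply(bs$retained, `[[`, character(1), "name")
  expect_setequal(retained, enc$truth$clean_names)
  expect_true(all(bs$scores$ratio >= 0 & bs$scores$ratio <= 1))
})

test_that("page features fire per the keyword rules, invariant to category order", {
  cfg <- default_feature_config()
  p <- ency_page("咽喉炎", "", "", categories = c("人体疾病", "药品"))
  f <- featurize_page(p, cfg)
  expect_length(f, 26L)
  expect_identical(unname(f["name_ends_any"]), 1)  # ends with 炎
  p_rev <- ency_page("咽喉炎", "", "", categories = c("药品", "人体疾病"))
  expect_identical(f, featurize_page(p_rev, cfg))

  # content rule: strictly more than 3 distinct list words
  four <- ency_page("x", "", "【功能】【规格】【成分】【用法】")
  three <- ency_page("x", "", "【功能】【规格】【成分】")
  expect_identical(unname(featurize_page(four, cfg)["content_med_gt3"]), 1)
  expect_identical(unname(featurize_page(three, cfg)["content_med_gt3"]), 0)

  empty <- featurize_page(ency_page("x"), cfg)
  expect_true(all(empty == 0))
})

test_that("the decision tree separates keyword-keyed labels and needs 2+ classes", {
  # linearly separable toy set: each label keyed to one feature
  feats <- as.data.frame(diag(3)[rep(1:3, each = 10), ])
  labels <- rep(c("symptom", "disease", "other"), each = 10)
  cv <- cv_entity_classifier(feats, labels, k = 5, seed = 1)
  expect_identical(cv$accuracy, 1)
  expect_identical(cv$macro_f1, 1)
  expect_error(train_entity_classifier(feats, rep("symptom", 30)),
               "two distinct labels")
})

test_that("a page with only symptom keywords classifies as symptom", {
  enc <- generate_encyclopedia(ency_config(seed = 13))
  feats <- featurize_pages(enc$pages)
  model <- train_entity_classifier(feats, enc$truth$labels$label)
  probe <- ency_page("怕冷", abstract = "这是一种症状。")
  expect_identical(classify_entity(model, probe), "symptom")
})

test_that("symptom subtype refinement uses department mentions, Western default", {
  tcm <- ency_page("怕冷", content = "可就诊中医内科。")
  expect_setequal(refine_symptom_subtype(tcm), "TCMSymptom")
  west <- ency_page("头晕", content = "可就诊神经内科。")
  expect_setequal(refine_symptom_subtype(west), "WesternSymptom")
  none <- ency_page("头晕", content = "无科室信息。")
  expect_setequal(refine_symptom_subtype(none), "WesternSymptom")
})

test_that("encyclopedia JSONL round-trips the five fields", {
  enc <- generate_encyclopedia(ency_config(seed = 13, n_pages = 30))
  path <- file.path(tempdir(), "pages.jsonl")
  write_ency_jsonl(enc$pages, path)
  back <- read_ency_jsonl(path)
  expect_identical(length(back), length(enc$pages))
  expect_identical(back[[1]]$name, enc$pages[[1]]$name)
  expect_identical(back[[1]]$categories, enc$pages[[1]]$categories)
})
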