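wrapper_a <- function() {
  list(site_id = "site_a", entity_name = "//h1",
       abstract = "//div[@class='abstract']",
       property_box = "//table[@class='property-box']",
       row = ".//tr", name_cell = "./th", value_cell = "./td",
       attribute_map = list("相关科室" = "relevant_department",
                            "相关疾病" = "relevant_disease"))
}

box_page <- function(rows) {
  trs <- paste0("<tr><th>", names(rows), "</th><td>", unlist(rows),
                "</td></tr>", collapse = "")
  paste0("<html><body><h1>头痛</h1><table class='property-box'>",
         trs, "</table></body></html>")
}

test_that("property-box parsing maps known rows in order and skips the rest", {
  html <- box_page(list("相关科室" = " 内科 ",
                        "相关疾病" = "感\n冒",
                        "发病部位" = "头部"))
  out <- parse_property_box(html, wrapper_a())
  expect_identical(out$property, c("relevant_department", "relevant_disease"))
  expect_identical(out$value, c("内科", "感 冒"))  # whitespace normalized
  # no hallucinated pairs: output is a subset of the page's rows
  expect_true(all(out$raw_name %in% c("相关科室", "相关疾病")))
})

test_that("a page without a property box yields an empty result, not an error", {
  html <- "<html><body><h1>头痛</h1><p>no box here</p></body></html>"
  out <- parse_property_box(html, wrapper_a())
  expect_identical(nrow(out), 0L)
})

test_that("symptom subtype follows the TCM department marker", {
  expect_setequal(classify_symptom_subtype("Traditional Chinese Orthopedics"),
                  "TCMSymptom")
  expect_setequal(classify_symptom_subtype("Internal medicine"),
                  "WesternSymptom")
  expect_setequal(classify_symptom_subtype(c("中医内科", "神经内科")),
                  c("TCMSymptom", "WesternSymptom"))
  expect_length(classify_symptom_subtype(character(0)), 0L)
  # pure function: permuting departments does not change the label set
  deps <- c("中医骨伤科", "内科", "儿科")
  expect_setequal(classify_symptom_subtype(deps),
                  classify_symptom_subtype(rev(deps)))
  # comma-separated single string splits
  expect_setequal(classify_symptom_subtype("中医内科、内科"),
                  c("TCMSymptom", "WesternSymptom"))
})

test_that("medicine subtype follows description keywords", {
  expect_setequal(classify_medicine_subtype("a Chinese patent medicine"),
                  "TCMMedicine")
  expect_setequal(classify_medicine_subtype("made of pharmaceuticals"),
                  "WesternMedicine")
  expect_length(classify_medicine_subtype("no keywords at all"), 0L)
  expect_setequal(classify_medicine_subtype("本品为中成药"), "TCMMedicine")
})

test_that("two-slot synonym patterns extract trimmed, non-self pairs", {
  out <- extract_synonyms("hyperpyrexia is known as fever.")
  expect_identical(out$entity1, "hyperpyrexia")
  expect_identical(out$entity2, "fever")
  expect_identical(nrow(extract_synonyms("nothing to see here.")), 0L)
  expect_identical(nrow(extract_synonyms("fever is known as fever.")), 0L)
  zh <- extract_synonyms("高热又称发热。别的句子。")
  expect_identical(zh$entity1, "高热")
  expect_identical(zh$entity2, "发热")
  expect_error(extract_synonyms("x", patterns = character(0)), "non-empty")
  expect_error(extract_synonyms("x", patterns = "{1}只有一个槽"),
               "exactly one")
})

test_that("extracted synonym pairs enter the KB as a symmetric sameAs relation", {
  dir <- file.path(tempdir(), "site-symmetry")
  g <- generate_healthcare_site(dir, site_config(seed = 31, synonym_rate = 0.5))
  w <- load_wrappers(g$wrapper_path)
  kb <- extract_website(file.path(dir, "site_a"), w$site_a)
  same <- kb$facts[kb$facts$predicate == "sameAs", ]
  expect_gt(nrow(same), 0L)
  key <- paste(same$subject, same$object)
  rkey <- paste(same$object, same$subject)
  expect_true(all(rkey %in% key))
})

test_that("whole-site extraction recovers the planted entities and attributes", {
  dir <- file.path(tempdir(), "site-extract")
  g <- generate_healthcare_site(dir, site_config(seed = 7))
  w <- load_wrappers(g$wrapper_path)
  kb <- kb_new()
  for (s in names(w)) kb <- extract_website(file.path(dir, s), w[[s]], kb)
  names_a <- vapply(kb$entities, `[[`, character(1), "name")
  truth_a <- g$truth$entities[g$truth$entities$site == "site_a", ]
  expect_true(all(truth_a$name %in% names_a))
  # attribute values match the planted ground truth for a sampled entity
  ex <- g$truth$attributes[g$truth$attributes$site == "site_a", ][1, ]
  id <- entity_id("site_a", ex$name)
  expect_true(ex$value %in% kb$entities[[id]]$attributes[[ex$property]])
  # the boxless page came through with no attributes
  bx <- entity_id("site_a", g$truth$boxless)
  expect_length(kb$entities[[bx]]$attributes, 0L)
})
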