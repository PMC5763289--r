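#' Configuration for the synthetic encyclopedia corpus
#'
#' @param seed integer seed.
#' @param n_pages total pages; `floor(noise_rate * n_pages)` of them are
#'   noise pages (floor is the documented rounding rule, so "exactly 20
#'   noise pages at rate 0.2 over 100" is well defined).
#' @param noise_rate fraction of noise pages tagged with low-confidence
#'   categories.
#' @param feature_noise per-page probability of corrupting one planted
#'   keyword signal.
#' @param seeds_per_label how many pages per label are named after seed
#'   entities.
#' @param n_uncategorized clean pages emitted with an empty category set
#'   (they exercise the retain-on-no-evidence branch).
#' @return a config list.
#' @export
ency_config <- function(seed = 13, n_pages = 210, noise_rate = 0.2,
                        feature_noise = 0.05, seeds_per_label = 4,
                        n_uncategorized = 2) {
  stopifnot(noise_rate >= 0, noise_rate < 1)
  as.list(environment())
}

.ency_label_category <- c(
  symptom = "常见症状",
  disease = "人体疾病",
  western_medicine = "药品",
  tcm_medicine = "中成药",
  department = "医院科室",
  examination = "医学检查")

ency_names_for_label <- function(label, n) {
  switch(label,
         symptom = synth_symptom_name(n),
         disease = synth_disease_name(n),
         western_medicine = synth_medicine_name(n, tcm = FALSE),
         tcm_medicine = synth_medicine_name(n, tcm = TRUE),
         department = synth_department_name(n),
         examination = synth_examination_name(n),
         stop("no name pool for label ", label))
}

ency_clean_page <- function(name, label) {
  kw <- default_feature_config()
  mk <- function(abstract, content, full_extra = "") {
    ency_page(name, abstract, content,
              full_text = paste(abstract, content, full_extra),
              categories = .ency_label_category[[label]])
  }
  switch(label,
    symptom = mk(paste0(name, "是一种常见症状，患者多有不适感。"),
                 paste0("多见于内科相关疾患，可就诊",
                        sample(c(.zh$departments, .zh$tcm_departments), 1L),
                        "。")),
    disease = mk(paste0(name, "是一种累及人体的疾患。"),
                 "【病因】尚不完全明确。【诊断】结合检查可确诊。【临床表现】起病缓慢。【缓解】对症处理。"),
    western_medicine = mk(paste0(name, "为处方药。"),
                          "【功能】对症治疗。【规格】每盒十粒。【成分】见说明书。【用法】口服。【用量】遵医嘱。【不良反应】偶见不适。"),
    tcm_medicine = mk(paste0(name, "为中成药。"),
                      "【功能】调理气血。【规格】每盒十粒。【成分】中草药提取。【用法】口服。【用量】遵医嘱。",
                      "中成药"),
    department = mk(paste0(name, "是医院的临床科室。"),
                    "负责相关疾患的门诊与住院诊疗。"),
    examination = mk(paste0(name, "是一项临床检查项目。"),
                     "用于辅助判断病情变化。"),
    stop("no page template for label ", label))
}

ency_noise_page <- function(i) {
  base <- .zh$noise_name[[((i - 1L) %% length(.zh$noise_name)) + 1L]]
  ency_page(paste0(base, "专题", i),
            abstract = "生活常识与日常话题。",
            content = "内容整理自生活经验。",
            categories = sample(.zh$noise_categories, sample(1:2, 1L)))
}

# drop one planted keyword signal from a clean page (feature noise)
ency_corrupt_page <- function(page, label) {
  if (label %in% c("disease", "western_medicine", "tcm_medicine")) {
    page$content <- "暂无详细介绍。"
    page$full_text <- paste(page$abstract, page$content)
  } else if (label == "symptom") {
    page$abstract <- gsub("症状", "表现", page$abstract, fixed = TRUE)
    page$full_text <- paste(page$abstract, page$content)
  }
  page
}

#' Generate a synthetic encyclopedia corpus with planted ground truth
#'
#' Clean pages carry the keyword signals of their entity type and a
#' high-confidence type category; noise pages carry only low-confidence
#' lifestyle categories and the gold label `"other"`.  A configurable
#' number of pages per label is named after supplied seed entities, which
#' puts every type category's seed ratio above the default bootstrap
#' threshold while the noise categories stay at zero.
#'
#' @param config an [ency_config()].
#' @param seeds optional data.frame with columns `name`, `label` supplying
#'   seed entity names per label; when `NULL` the generator synthesizes
#'   its own seed names and reports them in the truth.
#' @return list with `pages`, `seeds` (character vector of seed names) and
#'   `truth` (`labels` data.frame, `noise_names`, `clean_names`).
#' @export
generate_encyclopedia <- function(config = ency_config(), seeds = NULL) {
  with_seed(config$seed, {
    labels6 <- names(.ency_label_category)
    n_noise <- floor(config$noise_rate * config$n_pages)
    n_clean <- config$n_pages - n_noise
    per <- rep(n_clean %/% 6L, 6L)
    if (n_clean %% 6L) per[seq_len(n_clean %% 6L)] <- per[seq_len(n_clean %% 6L)] + 1L
    names(per) <- labels6

    pages <- list(); rows <- list(); seed_names <- character(0)
    for (lb in labels6) {
      n_lb <- per[[lb]]
      n_seed <- min(config$seeds_per_label, n_lb)
      from_seeds <- if (!is.null(seeds)) {
        cand <- seeds$name[seeds$label == lb]
        if (length(cand) < n_seed)
          stop("need at least ", n_seed, " seed names for label ", lb)
        cand[seq_len(n_seed)]
      } else character(0)
      synth <- ency_names_for_label(lb, n_lb)
      nm <- c(from_seeds, setdiff(synth, from_seeds))[seq_len(n_lb)]
      if (is.null(seeds)) from_seeds <- nm[seq_len(n_seed)]
      seed_names <- c(seed_names, from_seeds)
      for (name in nm) {
        pg <- ency_clean_page(name, lb)
        if (runif(1) < config$feature_noise) pg <- ency_corrupt_page(pg, lb)
        pages[[length(pages) + 1L]] <- pg
        rows[[length(rows) + 1L]] <- data.frame(name = pg$name, label = lb,
                                                noise = FALSE,
                                                stringsAsFactors = FALSE)
      }
    }
    # a few clean pages with no categories at all
    for (k in seq_len(config$n_uncategorized)) {
      pg <- pages[[k]]
      pg$name <- paste0(pg$name, "别录")
      pg$categories <- character(0)
      pages[[length(pages) + 1L]] <- pg
      rows[[length(rows) + 1L]] <- data.frame(name = pg$name,
                                              label = rows[[k]]$label,
                                              noise = FALSE,
                                              stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_noise)) {
      pg <- ency_noise_page(i)
      pages[[length(pages) + 1L]] <- pg
      rows[[length(rows) + 1L]] <- data.frame(name = pg$name, label = "other",
                                              noise = TRUE,
                                              stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    list(pages = pages, seeds = unique(seed_names),
         truth = list(labels = truth,
                      noise_names = truth$name[truth$noise],
                      clean_names = truth$name[!truth$noise]))
  })
}
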