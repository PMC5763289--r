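#' Configuration for the synthetic healthcare-site generator
#'
#' Two pseudo-sites with list pages and detail pages per entity type.  A
#' configured fraction of entities is duplicated onto the second site with
#' a small name perturbation, planting gold duplicate clusters; a fraction
#' of symptom abstracts carries a synonym sentence matching the default
#' two-slot patterns; one department page is emitted without its property
#' box to exercise the absent-structure branch.
#'
#' @param seed integer seed.
#' @param sites character vector of pseudo-site ids (first = highest
#'   priority).
#' @param n_symptom,n_disease,n_medicine,n_department,n_examination entity
#'   counts per type.
#' @param duplication_rate fraction of entities also appearing on the
#'   second site.
#' @param name_edit_budget maximum character edits applied to a duplicated
#'   name.
#' @param synonym_rate fraction of symptoms given a synonym alias.
#' @param plant_boxless emit one detail page without a property box.
#' @return a config list.
#' @export
site_config <- function(seed = 7, sites = c("site_a", "site_b"),
                        n_symptom = 10, n_disease = 8, n_medicine = 8,
                        n_department = 6, n_examination = 6,
                        duplication_rate = 0.5, name_edit_budget = 1,
                        synonym_rate = 0.3, plant_boxless = TRUE) {
  stopifnot(duplication_rate >= 0, duplication_rate <= 1, length(sites) == 2L)
  as.list(environment())
}

html_detail_page <- function(site, name, abstract, attrs) {
  box <- if (is.null(attrs)) "" else if (site == "site_a") {
    rows <- paste0("<tr><th>", names(attrs), "</th><td>",
                   unlist(attrs), "</td></tr>", collapse = "\n")
    paste0("<table class=\"property-box\">\n", rows, "\n</table>")
  } else {
    rows <- paste0("<tr><td class=\"n\">", names(attrs),
                   "</td><td class=\"v\">", unlist(attrs), "</td></tr>",
                   collapse = "\n")
    paste0("<table class=\"attr-table\">\n", rows, "\n</table>")
  }
  paste0("<html><head><meta charset=\"utf-8\"/><title>", name,
         "</title></head><body>\n<h1>", name, "</h1>\n",
         "<div class=\"abstract\">", abstract, "</div>\n", box,
         "\n</body></html>\n")
}

html_list_page <- function(entries) {
  items <- paste0("<li><a href=\"", entries$file, "\">", entries$name,
                  "</a></li>", collapse = "\n")
  paste0("<html><head><meta charset=\"utf-8\"/></head><body>\n",
         "<ul class=\"entity-list\">\n", items, "\n</ul>\n</body></html>\n")
}

site_wrapper <- function(site) {
  amap <- list("相关科室" = "relevant_department",
               "相关疾病" = "relevant_disease",
               "相关症状" = "symptom_related_symptom",
               "常见部位" = "location",
               "药品描述" = "description",
               "描述" = "description")
  lp <- as.list(stats::setNames(
    paste0("list_", c("symptom", "disease", "medicine", "department",
                      "examination"), ".html"),
    c("symptom", "disease", "medicine", "department", "examination")))
  if (site == "site_a")
    list(site_id = site, entity_name = "//h1",
         abstract = "//div[@class='abstract']",
         property_box = "//table[@class='property-box']",
         row = ".//tr", name_cell = "./th", value_cell = "./td",
         list_link = "//ul[@class='entity-list']//a",
         list_pages = lp, attribute_map = amap)
  else
    list(site_id = site, entity_name = "//h1",
         abstract = "//div[@class='abstract']",
         property_box = "//table[@class='attr-table']",
         row = ".//tr", name_cell = "./td[@class='n']",
         value_cell = "./td[@class='v']",
         list_link = "//ul[@class='entity-list']//a",
         list_pages = lp, attribute_map = amap)
}

#' Generate a synthetic two-site healthcare corpus with ground truth
#'
#' Writes detail and list pages for both pseudo-sites under
#' `out_dir/<site>/`, a wrapper YAML covering them, and returns the
#' planted ground truth (entities, attribute pairs, synonym pairs,
#' duplicate clusters).  Pure function of the config seed: re-runs are
#' byte-identical.
#'
#' @param out_dir output directory.
#' @param config a [site_config()].
#' @return invisibly, a list with `truth`, `wrapper_path`, `sites`.
#' @export
generate_healthcare_site <- function(out_dir, config = site_config()) {
  with_seed(config$seed, {
    s1 <- config$sites[[1]]; s2 <- config$sites[[2]]
    diseases <- synth_disease_name(config$n_disease)
    symptoms <- synth_symptom_name(config$n_symptom)
    medicines <- c(synth_medicine_name(ceiling(config$n_medicine / 2), tcm = TRUE),
                   synth_medicine_name(floor(config$n_medicine / 2), tcm = FALSE))
    med_is_tcm <- rep(c(TRUE, FALSE),
                      c(ceiling(config$n_medicine / 2),
                        floor(config$n_medicine / 2)))
    departments <- synth_department_name(config$n_department)
    examinations <- synth_examination_name(config$n_examination)

    ents <- list(); attr_truth <- list(); syn_truth <- list()
    add_ent <- function(name, type, subtype, attrs, abstract) {
      ents[[length(ents) + 1L]] <<- list(name = name, type = type,
                                         subtype = subtype, attrs = attrs,
                                         abstract = abstract)
    }
    for (i in seq_along(symptoms)) {
      dep <- sample(c(.zh$departments, .zh$tcm_departments),
                    sample(1:2, 1L))
      attrs <- list("相关科室" = paste(dep, collapse = "、"),
                    "相关疾病" = sample(diseases, 1L),
                    "常见部位" = sample(.zh$body, 1L))
      subtype <- classify_symptom_subtype(dep)
      abstract <- paste0(symptoms[[i]], "是一种常见症状。")
      add_ent(symptoms[[i]], "symptom", subtype, attrs, abstract)
    }
    for (d in diseases)
      add_ent(d, "disease", character(0),
              list("相关科室" = sample(.zh$departments, 1L),
                   "相关症状" = sample(symptoms, 1L)),
              paste0(d, "是一种疾病。"))
    for (i in seq_along(medicines)) {
      desc <- if (med_is_tcm[[i]]) "本品为中成药，由中草药制成。"
              else "本品为化学药品制剂。"
      add_ent(medicines[[i]], "medicine",
              if (med_is_tcm[[i]]) "TCMMedicine" else "WesternMedicine",
              list("相关疾病" = sample(diseases, 1L), "药品描述" = desc),
              paste0(medicines[[i]], "说明。"))
    }
    for (d in departments)
      add_ent(d, "department", character(0),
              list("描述" = paste0(d, "是医院临床科室。")),
              paste0(d, "简介。"))
    for (x in examinations)
      add_ent(x, "examination", character(0),
              list("描述" = paste0(x, "是临床检查项目。")),
              paste0(x, "简介。"))

    # synonym aliases: alias symptom pages + pattern sentence in the
    # original's abstract
    n_syn <- floor(config$synonym_rate * config$n_symptom)
    syn_idx <- if (n_syn) sample(seq_len(config$n_symptom), n_syn) else integer(0)
    for (i in syn_idx) {
      alias <- paste0(ents[[i]]$name, "症")
      ents[[i]]$abstract <- paste0(ents[[i]]$abstract,
                                   ents[[i]]$name, "又称", alias, "。")
      add_ent(alias, "symptom", ents[[i]]$subtype,
              ents[[i]]$attrs, paste0(alias, "是一种常见症状。"))
      syn_truth[[length(syn_truth) + 1L]] <-
        data.frame(entity1 = ents[[i]]$name, entity2 = alias,
                   stringsAsFactors = FALSE)
    }

    # duplication onto the second site
    n_ent <- length(ents)
    n_dup <- floor(config$duplication_rate * n_ent)
    dup_idx <- if (n_dup) sort(sample(seq_len(n_ent), n_dup)) else integer(0)
    boxless_name <- if (isTRUE(config$plant_boxless)) departments[[1]] else NA

    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ent_truth <- list(); cluster_truth <- list()
    emit_site <- function(site, members) {
      sd <- file.path(out_dir, site)
      dir.create(sd, showWarnings = FALSE)
      pages <- data.frame(name = character(), type = character(),
                          file = character(), stringsAsFactors = FALSE)
      for (k in seq_along(members)) {
        e <- members[[k]]
        file <- sprintf("d_%s_%03d.html", e$type, k)
        attrs <- e$attrs
        if (site == s1 && identical(e$name, boxless_name)) attrs <- NULL
        writeLines(html_detail_page(site, e$name, e$abstract, attrs),
                   file.path(sd, file), useBytes = TRUE)
        pages <- rbind(pages, data.frame(name = e$name, type = e$type,
                                         file = file, stringsAsFactors = FALSE))
        ent_truth[[length(ent_truth) + 1L]] <<- data.frame(
          site = site, name = e$name, type = e$type,
          subtype = paste(e$subtype, collapse = ","),
          boxless = is.null(attrs), stringsAsFactors = FALSE)
        if (!is.null(attrs)) {
          amap <- site_wrapper(site)$attribute_map
          for (an in names(attrs))
            attr_truth[[length(attr_truth) + 1L]] <<- data.frame(
              site = site, name = e$name, property = amap[[an]],
              value = attrs[[an]], stringsAsFactors = FALSE)
        }
      }
      for (tp in unique(pages$type))
        writeLines(html_list_page(pages[pages$type == tp, ]),
                   file.path(sd, paste0("list_", tp, ".html")),
                   useBytes = TRUE)
    }
    emit_site(s1, ents)
    dup_members <- lapply(ents[dup_idx], function(e) {
      edits <- sample(0:config$name_edit_budget, 1L)
      e2 <- e
      e2$name <- if (edits) perturb_name(e$name, edits) else e$name
      cluster_truth[[length(cluster_truth) + 1L]] <<- data.frame(
        canonical = e$name, site = s2, name = e2$name,
        stringsAsFactors = FALSE)
      e2
    })
    emit_site(s2, dup_members)

    wrappers <- list()
    wrappers[[s1]] <- site_wrapper(s1)
    wrappers[[s2]] <- site_wrapper(s2)
    wrapper_path <- file.path(out_dir, "wrappers.yaml")
    yaml::write_yaml(wrappers, wrapper_path)

    bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
    invisible(list(
      truth = list(
        entities = bind(ent_truth, data.frame()),
        attributes = bind(attr_truth, data.frame()),
        synonyms = bind(syn_truth,
                        data.frame(entity1 = character(),
                                   entity2 = character(),
                                   stringsAsFactors = FALSE)),
        clusters = bind(cluster_truth,
                        data.frame(canonical = character(), site = character(),
                                   name = character(), stringsAsFactors = FALSE)),
        boxless = boxless_name),
      wrapper_path = wrapper_path,
      sites = config$sites))
  })
}

#' Configuration for the synthetic duplicate-entity (fusion) fixture
#'
#' @param seed integer seed.
#' @param n_pairs planted duplicate pairs across the two pseudo-sources.
#' @param n_singletons distractor entities without a duplicate.
#' @param name_edit_budget maximum character edits on a duplicate's name.
#' @param n_perturb_facts how many of the three attribute values of a
#'   duplicate are replaced (the rest stay identical).
#' @return a config list.
#' @export
fusion_config <- function(seed = 11, n_pairs = 100, n_singletons = 100,
                          name_edit_budget = 2, n_perturb_facts = 1) {
  as.list(environment())
}

# compound attribute-value pools large enough that chance value collisions
# between unrelated entities are rare
.fusion_value_pool <- function() {
  list(
    relevant_department = as.vector(outer(
      c(.zh$departments, .zh$tcm_departments),
      c("门诊", "病房", "急诊", "专科", "分部"), paste0)),
    relevant_disease = as.vector(outer(
      paste0(rep(.zh$body, each = 4), .zh$disease_suffix),
      c("初期", "中期", "急性期", "恢复期"), paste0)),
    location = as.vector(outer(
      .zh$body, c("部外侧", "部内侧", "部上方", "部下方", "部深处"), paste0))
  )
}

#' Generate the planted-duplicate fusion fixture
#'
#' Each planted pair is one entity observed in both pseudo-sources: the
#' second observation's name gets up to `name_edit_budget` character edits
#' and exactly `n_perturb_facts` of its three attribute values are replaced.
#' Single-source singletons act as distractors.  Names are long compounds
#' so a two-character edit keeps name similarity high, as for real
#' complaint-style symptom names.
#'
#' @param config a [fusion_config()].
#' @return list with `entities` (list of `symkb_entity`), `gold_pairs`
#'   (data.frame `a`, `b`) and `config`.
#' @export
generate_fusion_fixture <- function(config = fusion_config()) {
  with_seed(config$seed, {
    pools <- .fusion_value_pool()
    n <- config$n_pairs + config$n_singletons
    names_all <- synth_long_name(n)
    types <- sample(c("Symptom", "Disease", "Medicine"), n, replace = TRUE)
    entities <- list(); gold <- list()
    rnd_attrs <- function() lapply(pools, function(p) sample(p, 1L))
    for (k in seq_len(config$n_pairs)) {
      attrs <- rnd_attrs()
      a <- new_entity(names_all[[k]], types[[k]], "src1", attrs,
                      id = sprintf("p%03da", k))
      edits <- sample(0:config$name_edit_budget, 1L)
      name_b <- if (edits) perturb_name(names_all[[k]], edits) else names_all[[k]]
      attrs_b <- attrs
      perturb <- sample(names(pools), config$n_perturb_facts)
      for (an in perturb) {
        repl <- sample(setdiff(pools[[an]], attrs[[an]]), 1L)
        attrs_b[[an]] <- repl
      }
      b <- new_entity(name_b, types[[k]], "src2", attrs_b,
                      id = sprintf("p%03db", k))
      entities <- c(entities, list(a, b))
      gold[[k]] <- data.frame(a = a$id, b = b$id, stringsAsFactors = FALSE)
    }
    for (k in seq_len(config$n_singletons)) {
      entities <- c(entities, list(new_entity(
        names_all[[config$n_pairs + k]],
        types[[config$n_pairs + k]],
        sample(c("src1", "src2"), 1L), rnd_attrs(),
        id = sprintf("s%03d", k))))
    }
    list(entities = entities,
         gold_pairs = do.call(rbind, gold),
         config = config)
  })
}
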