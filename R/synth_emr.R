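#' Configuration for the synthetic EMR corpus
#'
#' @param seed integer seed.
#' @param n_records number of records (the annotation protocol splits
#'   these 660/340 into train and test).
#' @param dup_rate per-field probability of re-planting an earlier
#'   sentence of the same record (clinical copy-forward duplication).
#' @param label_noise per-sentence probability that the training
#'   annotation misses one gold symptom span (gold labels stay clean).
#' @param min_sent,max_sent sentences per populated field.
#' @return a config list.
#' @export
emr_config <- function(seed = 17, n_records = 1000, dup_rate = 0.3,
                       label_noise = 0.05, min_sent = 2, max_sent = 3) {
  as.list(environment())
}

# symptom lexicons: mixes of one-token and two-token surface forms.  The
# vocabularies are deliberately much larger than a few hundred annotated
# records can cover — as in real clinical text — so recognition of rare
# surface forms keeps improving with training-set size.
emr_symptom_lexicon <- function(target) {
  if (target == "western") {
    one <- as.vector(outer(.zh$body, .zh$sens1, paste0))
    two <- expand.grid(b = paste0(.zh$body, "部"), s = .zh$sens2,
                       stringsAsFactors = FALSE)
    three <- expand.grid(b = as.vector(outer(.zh$adj, paste0(.zh$body, "部"),
                                             paste0)),
                         s = .zh$sens2, stringsAsFactors = FALSE)
    c(lapply(one, function(w) c(w)),
      lapply(seq_len(nrow(two)), function(i) c(two$b[[i]], two$s[[i]])),
      lapply(seq_len(nrow(three)), function(i) c(three$b[[i]], three$s[[i]])))
  } else {
    one <- .zh$tcm_sym
    two <- expand.grid(o = .zh$tcm_organ, s = .zh$tcm_sym,
                       stringsAsFactors = FALSE)
    two2 <- expand.grid(o = paste0(.zh$tcm_organ, "经"), s = .zh$tcm_sym,
                        stringsAsFactors = FALSE)
    c(lapply(one, function(w) c(w)),
      lapply(seq_len(nrow(two)), function(i) c(two$o[[i]], two$s[[i]])),
      lapply(seq_len(nrow(two2)), function(i) c(two2$o[[i]], two2$s[[i]])))
  }
}

# non-symptom noun fillers for the ambiguous contexts (gold label O)
emr_distractor_nouns <- function(target) {
  if (target == "western")
    c("作息紊乱", "工作压力", "环境变化", "药物调整", "情绪波动",
      "饮食改变", "家庭矛盾", "睡眠不足", "运动过量", "天气变化",
      "出差劳顿", "值班熬夜", "康复训练", "复查安排", "随访计划",
      "转科流程")
  else
    c("情志不畅", "饮食失节", "起居失常", "劳倦过度", "外感风寒",
      "调护不当", "思虑过度", "久坐少动", "作息颠倒", "节气变化",
      "药后反应", "随访事宜")
}

# sentence templates: context token/POS lists around one or two slots.
# "amb" templates take either a symptom (labeled) or a distractor noun
# (label O), so recognition there depends on token identity, not context.
.emr_templates <- list(
  list(pre = list(c("患者", "n"), c("自述", "v")), post = list(c("三天", "t")), kind = "sym"),
  list(pre = list(c("查体", "v"), c("见", "v")), post = list(c("明显", "a")), kind = "sym"),
  list(pre = list(c("伴有", "v")), post = list(), kind = "sym"),
  list(pre = list(c("诉", "v")), post = list(c("一周", "t")), kind = "sym"),
  list(pre = list(c("近日", "t"), c("反复", "d"), c("出现", "v")), post = list(), kind = "sym"),
  list(pre = list(c("入院", "v"), c("后", "f"), c("仍", "d"), c("有", "v")),
       post = list(c("较前", "d"), c("加重", "v")), kind = "sym"),
  list(pre = list(c("晨起", "t"), c("自觉", "v")), post = list(), kind = "sym2"),
  list(pre = list(c("家属", "n"), c("代诉", "v")), post = list(), kind = "sym"),
  list(pre = list(c("出现", "v")), post = list(), kind = "amb"),
  list(pre = list(c("考虑", "v"), c("与", "p")), post = list(c("有关", "v")), kind = "amb"),
  list(pre = list(c("随访", "v"), c("记录", "v"), c("示", "v")), post = list(), kind = "amb"),
  list(pre = list(c("病程", "n"), c("中", "f"), c("曾", "d"), c("有", "v")),
       post = list(), kind = "amb"),
  list(pre = list(c("既往", "t"), c("体健", "a")), post = list(), kind = "dis"),
  list(pre = list(c("精神", "n"), c("可", "v")), post = list(), kind = "dis"),
  list(pre = list(c("饮食", "n"), c("睡眠", "n"), c("正常", "a")), post = list(), kind = "dis"),
  list(pre = list(c("查", "v"), c("血常规", "n"), c("正常", "a")), post = list(), kind = "dis"),
  list(pre = list(c("心肺", "n"), c("听诊", "v"), c("无", "v"), c("异常", "a")),
       post = list(), kind = "dis")
)

emr_make_sentence <- function(target, lexicon, distractors) {
  tpl <- .emr_templates[[sample(length(.emr_templates), 1L)]]
  toks <- character(0); pos <- character(0); lab <- character(0)
  push <- function(t, p, l) {
    toks <<- c(toks, t); pos <<- c(pos, p); lab <<- c(lab, l)
  }
  for (x in tpl$pre) push(x[[1]], x[[2]], "O")
  emit_slot <- function() {
    if (tpl$kind == "amb" && runif(1) < 0.5) {
      push(sample(distractors, 1L), "n", "O")
    } else {
      sym <- lexicon[[sample(length(lexicon), 1L)]]
      push(sym[[1]], "n", "B-SYM")
      if (length(sym) > 1L) for (t in sym[-1]) push(t, "n", "I-SYM")
    }
  }
  if (tpl$kind %in% c("sym", "amb")) emit_slot()
  if (tpl$kind == "sym2") {
    emit_slot(); push("及", "c", "O"); emit_slot()
  }
  for (x in tpl$post) push(x[[1]], x[[2]], "O")
  push("。", "w", "O")
  list(tokens = toks, pos = pos, labels = lab,
       text = paste(toks, collapse = ""))
}

#' Generate a synthetic EMR corpus with gold symptom annotations
#'
#' Records carry the four narrative fields; Western-symptom sentences are
#' planted in the physical-examination / Western-differential fields and
#' TCM sentences in the disease-analysis / TCM-differential fields.
#' Sentences are built from templated clinical contexts around lexicon
#' symptoms (one- and two-token), distractor sentences, and ambiguous
#' contexts where a slot holds either a symptom or a non-symptom noun.
#' Within-record duplicate sentences are planted at the configured rate;
#' annotation noise drops a span from the training labels only.
#'
#' @param config an [emr_config()].
#' @return list with `records` (list of [emr_record()]), `sequences`
#'   (per target: deduplicated labeled sequences with `tokens`, `pos`,
#'   `labels` (gold) and `labels_train` (noisy)), and `truth` (per-record
#'   planted duplicates and expected deduplicated sentences).
#' @export
generate_emr_corpus <- function(config = emr_config()) {
  with_seed(config$seed, {
    lex <- list(western = emr_symptom_lexicon("western"),
                tcm = emr_symptom_lexicon("tcm"))
    dis <- list(western = emr_distractor_nouns("western"),
                tcm = emr_distractor_nouns("tcm"))
    field_of <- list(
      western = c("physical_examination", "antidiastole_western"),
      tcm = c("disease_analysis", "antidiastole_tcm"))

    records <- vector("list", config$n_records)
    sequences <- list(western = list(), tcm = list())
    dup_truth <- list()
    for (r in seq_len(config$n_records)) {
      rid <- sprintf("emr%05d", r)
      fields <- list()
      for (target in c("western", "tcm")) {
        for (fd in field_of[[target]]) {
          n_sent <- sample(config$min_sent:config$max_sent, 1L)
          sents <- lapply(seq_len(n_sent), function(i)
            emr_make_sentence(target, lex[[target]], dis[[target]]))
          texts <- vapply(sents, `[[`, character(1), "text")
          # keep only the first instance of accidental repeats, then plant
          # an explicit duplicate at the configured rate
          keep <- !duplicated(texts)
          sents <- sents[keep]; texts <- texts[keep]
          planted <- FALSE
          if (runif(1) < config$dup_rate && length(texts) >= 1L) {
            i <- sample.int(length(texts), 1L)
            # copy goes somewhere at or after its source, so first
            # occurrences keep their order
            slots <- seq.int(i, length(texts))
            after <- slots[[sample.int(length(slots), 1L)]]
            texts <- append(texts, texts[[i]], after = after)
            planted <- TRUE
          }
          fields[[fd]] <- paste0(texts, collapse = "")
          dup_truth[[length(dup_truth) + 1L]] <- data.frame(
            record_id = rid, field = fd, planted_dup = planted,
            n_raw = length(texts),
            n_unique = length(unique(texts)),
            stringsAsFactors = FALSE)
          for (s in sents) {
            labels_train <- s$labels
            if (runif(1) < config$label_noise && any(s$labels == "B-SYM")) {
              sp <- bio_to_spans(s$labels)
              drop <- sp[sample(nrow(sp), 1L), ]
              labels_train[drop$start:drop$end] <- "O"
            }
            sequences[[target]][[length(sequences[[target]]) + 1L]] <-
              list(record_id = rid, field = fd,
                   tokens = s$tokens, pos = s$pos,
                   labels = s$labels, labels_train = labels_train,
                   text = s$text)
          }
        }
      }
      records[[r]] <- do.call(emr_record, c(list(record_id = rid), fields))
    }
    # the generated field text ends sentences with the terminator, so the
    # expected deduplicated sentences are recoverable per record and field
    list(records = records, sequences = sequences,
         truth = list(duplication = do.call(rbind, dup_truth),
                      record_ids = vapply(records, `[[`, character(1),
                                          "record_id")))
  })
}

#' Sequences of given records, per target
#'
#' Utility for train/test splits: filters a corpus's labeled sequences to
#' a record-id set.
#'
#' @param corpus result of [generate_emr_corpus()].
#' @param target `"western"` or `"tcm"`.
#' @param ids record ids to keep.
#' @param use_train_labels replace gold labels by the noisy training
#'   annotation.
#' @return list of sequences.
#' @export
corpus_sequences <- function(corpus, target, ids, use_train_labels = FALSE) {
  out <- Filter(function(s) s$record_id %in% ids, corpus$sequences[[target]])
  if (use_train_labels)
    out <- lapply(out, function(s) { s$labels <- s$labels_train; s })
  out
}

#' Write / read EMR records as JSONL
#'
#' @param records list of `symkb_emr`.
#' @param path file path.
#' @return `read_emr_jsonl` returns the list of records.
#' @export
write_emr_jsonl <- function(records, path) {
  lines <- vapply(records, function(r)
    jsonlite::toJSON(unclass(r), auto_unbox = TRUE), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_emr_jsonl
#' @export
read_emr_jsonl <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(ln) {
    x <- jsonlite::fromJSON(ln)
    emr_record(x$record_id, x$physical_examination %||% "",
               x$antidiastole_western %||% "", x$disease_analysis %||% "",
               x$antidiastole_tcm %||% "")
  })
}
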