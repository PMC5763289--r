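#' Construct an EMR record
#'
#' Four narrative fields matter for symptom recognition: physical
#' examination and the Western-medicine differential for Western symptoms,
#' disease analysis and the TCM differential for TCM symptoms.  Fields may
#' be empty.
#'
#' @param record_id unique record identifier.
#' @param physical_examination,antidiastole_western,disease_analysis,antidiastole_tcm
#'   free-text field contents.
#' @return an object of class `symkb_emr`.
#' @export
emr_record <- function(record_id, physical_examination = "",
                       antidiastole_western = "", disease_analysis = "",
                       antidiastole_tcm = "") {
  structure(list(record_id = as.character(record_id),
                 physical_examination = physical_examination,
                 antidiastole_western = antidiastole_western,
                 disease_analysis = disease_analysis,
                 antidiastole_tcm = antidiastole_tcm),
            class = "symkb_emr")
}

#' Select the EMR fields feeding a target symptom model
#'
#' Western-medicine symptoms are learned from the physical-examination and
#' Western-differential fields; TCM symptoms from the disease-analysis and
#' TCM-differential fields.  Empty fields are dropped.
#'
#' @param record a `symkb_emr`.
#' @param target `"western"` or `"tcm"`.
#' @return character vector of field texts (possibly empty).
#' @export
select_fields <- function(record, target = c("western", "tcm")) {
  target <- match.arg(target)
  fields <- if (target == "western")
    c(record$physical_examination, record$antidiastole_western)
  else c(record$disease_analysis, record$antidiastole_tcm)
  fields[nzchar(fields)]
}

#' Split clinical text into sentences
#'
#' Splits on the Chinese terminators (and their ASCII counterparts),
#' dropping the terminator and surrounding whitespace.
#'
#' @param text a string.
#' @return character vector of sentences.
#' @export
split_sentences <- function(text) split_zh_sentences(text)

#' Remove within-record duplicate sentences
#'
#' Clinical text duplicates sentences freely (copy-forward); within one
#' record each distinct sentence is kept once, first occurrence, order
#' otherwise preserved.  Idempotent.
#'
#' @param texts character vector of field texts from one record.
#' @return character vector of deduplicated sentences.
#' @export
dedup_sentences <- function(texts) {
  unique(unlist(lapply(texts, split_sentences)))
}

#' Per-position CRF feature templates
#'
#' Emits exactly 37 feature strings for position `i`: literal unigrams,
#' bigrams and trigrams over the +/-3 token window, the position index, and
#' the same n-gram templates over the POS tags.  Positions off either end
#' are filled with the padding token, so the count is constant everywhere.
#'
#' @param tokens,pos parallel character vectors.
#' @param i position (1-based).
#' @param pad padding token for window slots outside the sequence.
#' @return character vector of length 37.
#' @export
extract_crf_features <- function(tokens, pos, i, pad = "<PAD>") {
  n <- length(tokens)
  stopifnot(length(pos) == n, i >= 1L, i <= n)
  at <- function(v, k) {
    j <- i + k
    if (j >= 1L && j <= n) v[[j]] else pad
  }
  feats <- character(37)
  f <- 0L
  for (k in -3:3) { f <- f + 1L; feats[[f]] <- sprintf("U[%d]=%s", k, at(tokens, k)) }
  for (k in -3:2) { f <- f + 1L
    feats[[f]] <- sprintf("B[%d]=%s_%s", k, at(tokens, k), at(tokens, k + 1L)) }
  for (k in -3:1) { f <- f + 1L
    feats[[f]] <- sprintf("T[%d]=%s_%s_%s", k, at(tokens, k), at(tokens, k + 1L),
                          at(tokens, k + 2L)) }
  f <- f + 1L; feats[[f]] <- sprintf("IDX=%d", i)
  for (k in -3:3) { f <- f + 1L; feats[[f]] <- sprintf("PU[%d]=%s", k, at(pos, k)) }
  for (k in -3:2) { f <- f + 1L
    feats[[f]] <- sprintf("PB[%d]=%s_%s", k, at(pos, k), at(pos, k + 1L)) }
  for (k in -3:1) { f <- f + 1L
    feats[[f]] <- sprintf("PT[%d]=%s_%s_%s", k, at(pos, k), at(pos, k + 1L),
                          at(pos, k + 2L)) }
  feats
}

# feature strings for a whole sequence: n x 37 character matrix
featurize_sequence <- function(tokens, pos, pad = "<PAD>") {
  n <- length(tokens)
  m <- matrix("", nrow = n, ncol = 37)
  for (i in seq_len(n)) m[i, ] <- extract_crf_features(tokens, pos, i, pad)
  m
}

#' Convert BIO labels to entity spans
#'
#' An orphan inside-label (I after O or at sequence start) is promoted to a
#' begin-label before span assembly — the least destructive repair of an
#' invalid transition.  Spans are sorted, non-overlapping and in bounds by
#' construction.
#'
#' @param labels character vector over `{"B-SYM", "I-SYM", "O"}`.
#' @param tokens optional tokens; when given, surface strings are attached.
#' @return data.frame with columns `start`, `end` (inclusive, 1-based) and
#'   `text`.
#' @export
bio_to_spans <- function(labels, tokens = NULL) {
  n <- length(labels)
  starts <- integer(0); ends <- integer(0)
  open <- NA_integer_
  for (i in seq_len(n)) {
    lb <- labels[[i]]
    if (lb == "B-SYM" || (lb == "I-SYM" && is.na(open))) {
      if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, i - 1L) }
      open <- i
    } else if (lb == "O") {
      if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, i - 1L) }
      open <- NA_integer_
    }
  }
  if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, n) }
  text <- if (!is.null(tokens) && length(starts))
    vapply(seq_along(starts), function(k)
      paste(tokens[starts[[k]]:ends[[k]]], collapse = ""), character(1))
  else character(length(starts))
  data.frame(start = starts, end = ends, text = text, stringsAsFactors = FALSE)
}

#' Exact-match entity-level precision, recall and F1
#'
#' Spans match only when sentence, start and end all agree.  A zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param gold,pred data.frames with columns `sentence`, `start`, `end`.
#' @return list with `precision`, `recall`, `f1`, `n_gold`, `n_pred`,
#'   `n_match`.
#' @export
evaluate_ner <- function(gold, pred) {
  key <- function(df) if (nrow(df))
    paste(df$sentence, df$start, df$end, sep = "") else character(0)
  g <- unique(key(gold)); p <- unique(key(pred))
  n_match <- length(intersect(g, p))
  precision <- if (length(p)) n_match / length(p) else NA_real_
  recall <- if (length(g)) n_match / length(g) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
  else if (precision + recall > 0) 2 * precision * recall / (precision + recall)
  else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_gold = length(g), n_pred = length(p), n_match = n_match)
}

#' Write / read labeled sequences in CoNLL-style columns
#'
#' One token per line (`token TAB pos TAB label`), blank line between
#' sentences.
#'
#' @param sequences list of lists with `tokens`, `pos`, `labels`.
#' @param path file path.
#' @return `read_conll` returns the list of sequences.
#' @export
write_conll <- function(sequences, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in sequences) {
    lines <- paste(s$tokens, s$pos, s$labels, sep = "\t")
    writeLines(lines, con, useBytes = TRUE)
    writeLines("", con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  seqs <- list()
  cur <- list(tokens = character(0), pos = character(0), labels = character(0))
  flush <- function() {
    if (length(cur$tokens)) seqs[[length(seqs) + 1L]] <<- cur
    cur <<- list(tokens = character(0), pos = character(0), labels = character(0))
  }
  for (ln in lines) {
    if (!nzchar(ln)) { flush(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    cur$tokens <- c(cur$tokens, parts[[1]])
    cur$pos <- c(cur$pos, if (length(parts) > 2L) parts[[2]] else "n")
    cur$labels <- c(cur$labels, parts[[length(parts)]])
  }
  flush()
  seqs
}

#' Reproducible train/test split of record ids
#'
#' Seeded shuffle assigning the first `n_train` records to the training set
#' (the annotation protocol used 660 of 1000 records for training).
#'
#' @param ids vector of record ids.
#' @param n_train number of training records.
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_records <- function(ids, n_train = 660, seed = 1) {
  stopifnot(n_train <= length(ids))
  shuffled <- with_seed(seed, sample(ids))
  list(train = shuffled[seq_len(n_train)],
       test = shuffled[seq.int(n_train + 1L, length.out = length(ids) - n_train)])
}
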