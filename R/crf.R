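.crf_labels <- c("O", "B-SYM", "I-SYM")

#' Train a linear-chain CRF symptom recognizer
#'
#' A conditional random field over the 37 per-position feature templates
#' (literal/position/POS n-grams in a +/-3 window).  The negative
#' log-likelihood and its gradient are computed exactly by
#' forward-backward and minimized with L-BFGS under an L2 penalty; with a
#' zero initialisation the fit is deterministic given the data order.
#' Separate models are trained for the TCM and Western targets, mirroring
#' their separate source fields.
#'
#' @param sequences list of labeled sequences, each a list with parallel
#'   `tokens`, `pos` and `labels` (BIO over `{"B-SYM","I-SYM","O"}`); at
#'   least one begin-label must be present.
#' @param target `"western"` or `"tcm"`, recorded in the model metadata.
#' @param l2 L2 penalty weight.
#' @param maxit maximum L-BFGS iterations.
#' @param token_mode segmentation mode the sequences came from, recorded in
#'   the metadata (`"word"` or `"char"`).
#' @return an object of class `symkb_crf`.
#' @export
train_crf <- function(sequences, target = c("western", "tcm"), l2 = 1.0,
                      maxit = 150, token_mode = "word") {
  target <- match.arg(target)
  if (!length(sequences)) stop("no training sequences")
  labs <- unlist(lapply(sequences, `[[`, "labels"))
  if (!any(labs == "B-SYM"))
    stop("training data contains no positive (B-SYM) labels")
  if (!all(labs %in% .crf_labels))
    stop("labels must be BIO over {B-SYM, I-SYM, O}")

  fmats <- lapply(sequences, function(s) featurize_sequence(s$tokens, s$pos))
  feat_names <- unique(unlist(fmats))
  feat_idx <- stats::setNames(seq_along(feat_names), feat_names)
  feats <- lapply(fmats, function(m)
    matrix(unname(feat_idx[m]), nrow = nrow(m)))
  ylab <- lapply(sequences, function(s) match(s$labels, .crf_labels))

  n_feat <- length(feat_names)
  n_lab <- length(.crf_labels)
  n_par <- n_feat * n_lab + n_lab * n_lab + 2L * n_lab

  # optim calls fn and gr separately; cache the last evaluation
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$val)
    val <- crf_nll_grad_cpp(par, feats, ylab, n_feat, n_lab, l2)
    cache$par <- par
    cache$val <- val
    val
  }
  fit <- optim(numeric(n_par),
               fn = function(p) evaluate(p)$nll,
               gr = function(p) evaluate(p)$grad,
               method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  structure(list(par = fit$par, feature_index = feat_idx,
                 labels = .crf_labels, n_feat = n_feat,
                 target = target, token_mode = token_mode,
                 l2 = l2, converged = fit$convergence == 0,
                 final_nll = fit$value),
            class = "symkb_crf")
}

#' @export
print.symkb_crf <- function(x, ...) {
  cat(sprintf("<symkb CRF: %s symptoms> %d features, %s tokens, nll %.2f\n",
              x$target, x$n_feat, x$token_mode, x$final_nll))
  invisible(x)
}

# map a feature-string matrix to model indices (0 = unseen at training)
crf_index_features <- function(model, fmat) {
  idx <- model$feature_index[fmat]
  idx[is.na(idx)] <- 0L
  matrix(as.integer(idx), nrow = nrow(fmat))
}

#' Decode symptom spans in a token sequence
#'
#' Viterbi decoding under the trained CRF, followed by BIO-to-span assembly
#' (with orphan-inside repair).
#'
#' @param model a `symkb_crf`.
#' @param tokens,pos parallel character vectors.
#' @return data.frame of spans (`start`, `end`, `text`).
#' @export
decode_crf <- function(model, tokens, pos) {
  stopifnot(inherits(model, "symkb_crf"))
  if (!length(tokens))
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  fmat <- featurize_sequence(tokens, pos)
  path <- crf_viterbi_cpp(model$par, crf_index_features(model, fmat),
                          model$n_feat, length(model$labels))
  bio_to_spans(model$labels[path], tokens)
}

#' Evaluate a CRF on gold-labeled sequences
#'
#' Decodes every sequence and scores exact-match entity-level precision,
#' recall and F1 against the gold BIO labels.
#'
#' @param model a `symkb_crf`.
#' @param sequences list of labeled sequences (`tokens`, `pos`, `labels`).
#' @return list as from [evaluate_ner()], plus `spans` (predicted spans with
#'   a `sentence` column).
#' @export
evaluate_crf <- function(model, sequences) {
  gold_rows <- list(); pred_rows <- list()
  for (k in seq_along(sequences)) {
    s <- sequences[[k]]
    g <- bio_to_spans(s$labels, s$tokens)
    if (nrow(g)) gold_rows[[length(gold_rows) + 1L]] <- cbind(sentence = k, g)
    p <- decode_crf(model, s$tokens, s$pos)
    if (nrow(p)) pred_rows[[length(pred_rows) + 1L]] <- cbind(sentence = k, p)
  }
  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else
    data.frame(sentence = integer(), start = integer(), end = integer(),
               text = character(), stringsAsFactors = FALSE)
  gold <- bind(gold_rows); pred <- bind(pred_rows)
  out <- evaluate_ner(gold, pred)
  out$spans <- pred
  out
}

#' Harvest newly recognized symptom surface forms
#'
#' Runs the decoder over unlabeled sequences and returns the distinct
#' surface strings, ready to enter the knowledge base as new symptom
#' entities.
#'
#' @param model a `symkb_crf`.
#' @param sequences list of sequences (`tokens`, `pos`).
#' @return character vector of distinct symptom strings.
#' @export
harvest_symptoms <- function(model, sequences) {
  out <- character(0)
  for (s in sequences) {
    sp <- decode_crf(model, s$tokens, s$pos)
    out <- c(out, sp$text)
  }
  unique(out[nzchar(out)])
}
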