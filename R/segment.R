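#' Build a pluggable Chinese segmenter with POS lookup
#'
#' Word mode uses forward maximum matching against a lexicon (longest
#' dictionary word starting at the cursor wins; unmatched characters pass
#' through as single-character tokens).  Character mode emits one token per
#' code point; clinical segmenters vary, so the mode is recorded alongside
#' any model trained on the output.  POS tags come from the lexicon, with
#' punctuation tagged `w`, digits `m` and everything else `n`.
#'
#' @param lexicon data.frame with columns `word` and `pos`, or a character
#'   vector of words (POS defaults to `"n"`).
#' @param mode `"word"` or `"char"`.
#' @return a function `text -> list(tokens, pos)`.
#' @export
make_segmenter <- function(lexicon = NULL, mode = c("word", "char")) {
  mode <- match.arg(mode)
  if (is.character(lexicon))
    lexicon <- data.frame(word = lexicon, pos = "n", stringsAsFactors = FALSE)
  pos_of <- if (!is.null(lexicon))
    stats::setNames(as.character(lexicon$pos), lexicon$word) else character(0)
  words <- names(pos_of)
  max_len <- if (length(words)) max(nchar(words)) else 1L
  guess_pos <- function(tok) {
    if (grepl("^[[:punct:]。，！？；、：]+$", tok)) "w"
    else if (grepl("^[0-9０-９]+$", tok)) "m"
    else "n"
  }
  function(text) {
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    n <- length(chars)
    tokens <- character(0); pos <- character(0)
    if (mode == "char" || !length(words)) {
      tokens <- chars
    } else {
      i <- 1L
      while (i <= n) {
        hit <- NULL
        for (len in seq(min(max_len, n - i + 1L), 1L)) {
          cand <- paste(chars[i:(i + len - 1L)], collapse = "")
          if (cand %in% words) { hit <- cand; break }
        }
        if (is.null(hit)) hit <- chars[[i]]
        tokens <- c(tokens, hit)
        i <- i + nchar(hit)
      }
    }
    pos <- vapply(tokens, function(tok) {
      p <- pos_of[tok]
      if (!is.na(p)) unname(p) else guess_pos(tok)
    }, character(1))
    list(tokens = tokens, pos = unname(pos))
  }
}
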