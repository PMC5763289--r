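`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded package operations never disturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 64-bit-ish hex hash of a UTF-8 string: two independent
# 31-bit polynomial hashes, concatenated.  Used for stable IRI local parts;
# collision handling remains the store's responsibility.
str_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h1 <- 5381; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 33 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Mint a deterministic entity identifier
#'
#' Identifiers hash the primary source together with the surface name, so the
#' same extraction re-run yields the same id and Chinese names never need to
#' appear inside an IRI local part.
#'
#' @param source source identifier of the extraction.
#' @param name entity surface name.
#' @return a stable id string such as `"e01ab23..."`.
#' @export
entity_id <- function(source, name) {
  paste0("e", str_hash(paste0(source, "", name)))
}

# collapse runs of whitespace (incl. full-width spaces) and trim
squish <- function(x) {
  x <- gsub("[\\s　]+", " ", x, perl = TRUE)
  trimws(x)
}

symkb_log <- function(...) {
  if (isTRUE(getOption("symkb.verbose", FALSE))) message("[symkb] ", ...)
}
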