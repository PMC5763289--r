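# shared fixture builders and independent oracles

# tiny KB: 3 symptoms (one carrying both TCM and Western subtypes),
# 2 diseases, 4 facts
tiny_kb <- function() {
  kb <- kb_new()
  s1 <- new_entity("头痛", c("TCMSymptom", "WesternSymptom"), "site_a")
  s2 <- new_entity("发热", "Symptom", "site_a")
  s3 <- new_entity("咳嗽", "Symptom", "site_b")
  d1 <- new_entity("感冒", "Disease", "site_a")
  d2 <- new_entity("肺炎", "Disease", "site_b")
  for (e in list(s1, s2, s3, d1, d2)) kb <- kb_add_entity(kb, e)
  kb <- kb_add_facts(kb,
    subject = c(s1$id, s2$id, s3$id, s3$id),
    predicate = c("relevant_disease", "relevant_disease",
                  "relevant_disease", "location"),
    object = c(d1$id, d1$id, d2$id, "咽喉"),
    object_kind = c("entity", "entity", "entity", "literal"),
    source = c("site_a", "site_a", "site_b", "site_b"))
  kb
}

# brute-force LCS oracle: enumerate every subsequence of the shorter string
# and keep the longest that is a subsequence of the other (strings <= 8 chars)
oracle_lcs <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) > length(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
  n <- length(ca)
  if (n == 0L) return(0L)
  is_subseq <- function(x, y) {
    j <- 1L
    for (ch in y) {
      if (j <= length(x) && identical(x[[j]], ch)) j <- j + 1L
    }
    j > length(x)
  }
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    sel <- ca[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (length(sel) > best && is_subseq(sel, cb)) best <- length(sel)
  }
  best
}

# random strings over a mixed Han/ASCII alphabet
random_string <- function(max_len = 8, alphabet = c("A", "B", "C",
                                                    "头", "痛", "热")) {
  n <- sample(0:max_len, 1L)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
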