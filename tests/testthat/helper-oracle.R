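# Independent brute-force mention counter used as the oracle for the
# production matcher. Enumerates every character position where any
# variant matches via anchored regular expressions, then selects
# non-overlapping matches greedily left to right with the longest
# (most-token) match winning at equal starts. Shares no code with the
# token-scanning implementation.

oracle_count_group <- function(text, group) {
  if (is.na(text) || !nzchar(text)) return(0L)
  spans <- NULL
  for (i in seq_len(nrow(group))) {
    variant <- group$variant[i]
    acronym <- group$acronym[i]
    toks <- regmatches(variant, gregexpr("[[:alnum:]]+", variant))[[1]]
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", toks)
    pat <- paste0("(?<![[:alnum:]])",
                  paste(esc, collapse = "[-[:space:]]+"),
                  "(?![[:alnum:]])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = !acronym)[[1]]
    if (m[1] != -1L) {
      spans <- rbind(spans, data.frame(
        start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L,
        ntok = length(toks)))
    }
  }
  if (is.null(spans)) return(0L)
  spans <- spans[order(spans$start, -spans$ntok), , drop = FALSE]
  count <- 0L
  consumed_to <- 0L
  for (r in seq_len(nrow(spans))) {
    if (spans$start[r] > consumed_to) {
      count <- count + 1L
      consumed_to <- spans$end[r]
    }
  }
  count
}

# random "token soup" mixing filler, isolated lexicon tokens, whole
# variants, excluded ambiguous terms, and varied separators; adversarial
# for partial phrases, case, and boundary handling
random_soup_text <- function(lexicon, n_words = 60) {
  variant_tokens <- unique(unlist(
    regmatches(lexicon$variant, gregexpr("[[:alnum:]]+", lexicon$variant))))
  pool <- c(sample(c("alpha", "bravo", "cedar", "delta", "ember", "fjord",
                     "grove", "harbor"), 20, replace = TRUE),
            sample(variant_tokens, 20, replace = TRUE),
            sample(lexicon$variant, 12, replace = TRUE),
            sample(c("environment", "toxic", "chemical", "chemotherapy",
                     "hormone therapy", "Hrthe", "DESk"), 8, replace = TRUE))
  words <- sample(pool, n_words, replace = TRUE)
  seps <- sample(c(" ", " ", ", ", ". ", " - ", "-", "; "), n_words - 1,
                 replace = TRUE)
  paste0(paste0(words[-n_words], seps, collapse = ""), words[n_words])
}
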