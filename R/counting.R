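# Matching semantics, shared by every counting entry point:
#   * a token is a maximal run of letters/digits; punctuation and
#     underscores are boundaries ("BPA," and "pesticides." match);
#   * matches are anchored at token boundaries, so "HRT" never fires
#     inside "Hrthe" and "breast density" never fires on "breast" alone;
#   * multi-word variants tolerate any single run of whitespace and/or
#     hyphens between consecutive tokens ("endocrine-disrupting
#     chemicals" matches), but any other intervening character breaks the
#     phrase;
#   * acronym-flagged variants compare case-sensitively ("des moines"
#     does not trigger DES); all other variants are case-insensitive;
#   * within a group, matching scans left to right and the longest
#     matching variant at a position wins; a matched span is consumed, so
#     a character span contributes to at most one match per group.

# compile every group of a lexicon once; named list factor -> compiled
compile_lexicon <- function(lexicon) {
  factors <- lexicon_factors(lexicon)
  stats::setNames(lapply(factors, function(f) {
    compile_group(lexicon[lexicon$factor_name == f, , drop = FALSE])
  }), factors)
}

# compile a group's variants to token vectors, longest first
compile_group <- function(group) {
  vars <- lapply(seq_len(nrow(group)), function(i) {
    toks <- tokenize(group$variant[i])$token
    list(tokens = toks, acronym = group$acronym[i])
  })
  vars[order(-vapply(vars, function(v) length(v$tokens), integer(1)))]
}

# gap between consecutive matched tokens must be whitespace/hyphens only
gap_ok <- function(text, end_prev, start_next) {
  gap <- substr(text, end_prev + 1L, start_next - 1L)
  grepl("^[-[:space:]]+$", gap)
}

match_variant_at <- function(text, toks, toks_lower, i, variant) {
  k <- length(variant$tokens)
  n <- length(toks$token)
  if (i + k - 1L > n) return(FALSE)
  for (j in seq_len(k)) {
    tok <- toks$token[i + j - 1L]
    want <- variant$tokens[j]
    ok <- if (variant$acronym) identical(tok, want)
          else identical(toks_lower[i + j - 1L], tolower(want))
    if (!ok) return(FALSE)
    if (j > 1L && !gap_ok(text, toks$end[i + j - 2L], toks$start[i + j - 1L])) {
      return(FALSE)
    }
  }
  TRUE
}

count_group_tokens <- function(text, toks, toks_lower, compiled) {
  n <- length(toks$token)
  count <- 0L
  i <- 1L
  while (i <= n) {
    advanced <- FALSE
    for (v in compiled) {
      if (match_variant_at(text, toks, toks_lower, i, v)) {
        count <- count + 1L
        i <- i + length(v$tokens)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) i <- i + 1L
  }
  count
}

#' Count mentions of one term group in a text
#'
#' Number of non-overlapping occurrences of any of the group's surface
#' variants, under the package's word-boundary, longest-match-wins,
#' hyphen-tolerant semantics (see [count_page()] for the full pipeline
#' entry point).
#'
#' @param text Natural-language text.
#' @param group One term group: the rows of a [default_lexicon()] for a
#'   single `factor_name`.
#' @return Non-negative integer count.
#' @examples
#' lex <- default_lexicon()
#' exercise <- lex[lex$factor_name == "Exercise", ]
#' count_group_mentions("Exercise daily; physical activity helps.", exercise)
#' @export
count_group_mentions <- function(text, group) {
  if (is.na(text) || !nzchar(text)) return(0L)
  toks <- tokenize(text)
  count_group_tokens(text, toks, tolower(toks$token), compile_group(group))
}

#' Count all lexicon term groups on one kept page
#'
#' Produces the page-level mention counts that every downstream statistic
#' (site tables, corpus table, per-page averages) is built from. The
#' result always covers the full lexicon: factors that do not occur count
#' zero.
#'
#' @param page A one-row kept page record (from [decode_page()] /
#'   [apply_filters()]).
#' @param lexicon A `lexicon`.
#' @param compiled Optional pre-compiled lexicon (internal; lets callers
#'   counting many pages compile variants once).
#' @return A `page_term_counts` data frame with columns `org_id`, `url`,
#'   `factor_name`, `count` (one row per lexicon factor).
#' @export
count_page <- function(page, lexicon, compiled = compile_lexicon(lexicon)) {
  stopifnot(nrow(page) == 1, inherits(lexicon, "lexicon"))
  if (page$status != "kept") {
    stopf("count_page called on a dropped page (%s, reason %s)",
          page$url, page$drop_reason, class = "riskterms_contract_error")
  }
  text <- if (is.na(page$text)) "" else page$text
  toks <- tokenize(text)
  toks_lower <- tolower(toks$token)
  factors <- names(compiled)
  counts <- vapply(factors, function(f) {
    count_group_tokens(text, toks, toks_lower, compiled[[f]])
  }, integer(1))
  structure(data.frame(org_id = page$org_id, url = page$url,
                       factor_name = factors,
                       count = as.integer(counts), row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("page_term_counts", "data.frame"))
}

#' Count all kept pages in a page set
#'
#' @param pages Page-record data frame; dropped pages are skipped.
#' @param lexicon A `lexicon`.
#' @return Long-format counts data frame (`org_id`, `url`, `factor_name`,
#'   `count`), one row per kept page and lexicon factor.
#' @export
count_pages <- function(pages, lexicon) {
  kept <- pages[pages$status == "kept", , drop = FALSE]
  if (!nrow(kept)) {
    return(structure(data.frame(org_id = character(0), url = character(0),
                                factor_name = character(0),
                                count = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("page_term_counts", "data.frame")))
  }
  compiled <- compile_lexicon(lexicon)
  out <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i) {
    count_page(kept[i, , drop = FALSE], lexicon, compiled)
  }))
  rownames(out) <- NULL
  out
}
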