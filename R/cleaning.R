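# Fixed stopword lists for the language heuristic. High-frequency function
# words; the two lists are compared as fractions so the handful of shared
# forms ("a", "no") cannot flip a call on their own.
SPANISH_STOPWORDS <- c(
  "de", "la", "que", "el", "en", "y", "a", "los", "del", "se", "las", "por",
  "un", "para", "con", "no", "una", "su", "al", "lo", "como", "mas", "pero",
  "sus", "le", "ya", "o", "este", "si", "porque", "esta", "entre", "cuando",
  "muy", "sin", "sobre", "tambien", "me", "hasta", "hay", "donde", "quien",
  "desde", "todo", "nos", "durante", "todos", "uno", "les", "ni", "contra",
  "otros", "ese", "eso", "ante", "ellos", "esto", "antes", "algunos", "unos",
  "yo", "otro", "otras", "otra", "tanto", "esa", "estos", "mucho", "nada",
  "muchos", "cual", "poco", "ella", "estar", "estas", "algunas", "algo",
  "nosotros"
)

ENGLISH_STOPWORDS <- c(
  "the", "of", "and", "to", "in", "a", "is", "that", "it", "for", "on",
  "was", "with", "as", "be", "by", "at", "this", "have", "from", "or",
  "had", "not", "are", "but", "they", "you", "which", "were", "her", "his",
  "she", "will", "all", "we", "can", "an", "there", "their", "has", "more",
  "about", "when", "would", "been", "if", "our", "your", "who", "its"
)

DROP_REASONS <- c("broken", "undecodable", "sponsor_shop_forum", "language",
                  "subset_pattern", "manual")

#' Default page-filter ruleset
#'
#' Encodes the audit's page-exclusion categories as URL-pattern rules plus
#' a stopword-ratio language heuristic. URL patterns cover sponsor, shop /
#' product, and message-board / forum pages; the language rule drops
#' Spanish pages (the lexicon is English, so Spanish-language material
#' would be systematically under-counted rather than measured).
#'
#' @param url_pattern_drops URL substrings that drop a page as
#'   sponsor/shop/forum content.
#' @param min_tokens_for_language_call Below this many tokens the language
#'   is `unknown` and the page is kept (default 25).
#' @param spanish_stopword_threshold Minimum Spanish-stopword fraction for
#'   an `es` call (default 0.12).
#' @return A `filter_ruleset` list.
#' @export
default_ruleset <- function(url_pattern_drops = c("shop", "store", "product",
                                                  "cart", "donate-shop",
                                                  "forum", "board",
                                                  "sponsor"),
                            min_tokens_for_language_call = 25L,
                            spanish_stopword_threshold = 0.12) {
  if (spanish_stopword_threshold < 0 || spanish_stopword_threshold > 1) {
    stopf("spanish_stopword_threshold must be in [0, 1]",
          class = "riskterms_validation_error")
  }
  structure(list(url_pattern_drops = url_pattern_drops,
                 min_tokens_for_language_call =
                   as.integer(min_tokens_for_language_call),
                 spanish_stopword_threshold = spanish_stopword_threshold),
            class = "filter_ruleset")
}

page_record <- function(org_id, url, provenance, html = NA_character_,
                        text = NA_character_, status = "kept",
                        drop_reason = NA_character_) {
  if (status == "dropped" && is.na(drop_reason)) {
    stopf("dropped page requires a drop_reason",
          class = "riskterms_validation_error")
  }
  data.frame(org_id = org_id, url = url, provenance = provenance,
             html = html, text = text, status = status,
             drop_reason = drop_reason, stringsAsFactors = FALSE)
}

# decode the body of a fetch result to a UTF-8 string, or NA.
# candidates: declared charset, charset sniffed from a meta tag in the
# (ASCII-interpreted) head bytes, UTF-8. No blanket latin1 fallback: a
# stream that none of the candidates can decode is reported undecodable.
decode_body <- function(fetch) {
  body <- fetch$body
  if (!length(body)) return("")
  body <- body[body != as.raw(0L)]
  if (!length(body)) return("")
  sniff <- sniff_meta_charset(body)
  candidates <- unique(stats::na.omit(c(fetch$charset, sniff, "UTF-8")))
  for (cs in candidates) {
    txt <- tryCatch(
      suppressWarnings(iconv(list(body), from = cs, to = "UTF-8")),
      error = function(e) NA_character_
    )
    if (length(txt) == 1 && !is.na(txt) && all(validUTF8(txt))) return(txt)
  }
  NA_character_
}

sniff_meta_charset <- function(body) {
  head <- rawToChar(body[seq_len(min(2048L, length(body)))])
  if (!validUTF8(head)) {
    head <- suppressWarnings(iconv(head, from = "latin1", to = "UTF-8"))
    if (is.na(head)) return(NA_character_)
  }
  m <- regmatches(head, regexpr("charset\\s*=\\s*[\"']?[A-Za-z0-9_-]+", head,
                                ignore.case = TRUE))
  if (!length(m)) return(NA_character_)
  sub("^charset\\s*=\\s*[\"']?", "", m, ignore.case = TRUE)
}

#' Decode a fetched page into a page record
#'
#' Non-2xx fetches become dropped records with reason `broken`; bodies
#' that cannot be decoded under the declared charset, a charset sniffed
#' from a `meta` tag, or UTF-8 become dropped records with reason
#' `undecodable`. Successfully decoded pages are provisionally kept with
#' both the HTML and the extracted visible text populated; the page-level
#' filters run afterwards via [apply_filters()].
#'
#' @param fetch A fetch result (see [fixture_fetcher()]).
#' @param org_id Organization the page belongs to.
#' @return A one-row page-record data frame.
#' @export
decode_page <- function(fetch, org_id) {
  if (!fetch_ok(fetch)) {
    return(page_record(org_id, fetch$url, fetch$provenance,
                       status = "dropped", drop_reason = "broken"))
  }
  html <- decode_body(fetch)
  if (is.na(html)) {
    return(page_record(org_id, fetch$url, fetch$provenance,
                       status = "dropped", drop_reason = "undecodable"))
  }
  page_record(org_id, fetch$url, fetch$provenance, html = html,
              text = extract_visible_text(html))
}

#' Classify the language of a text as English, Spanish or unknown
#'
#' Stopword-ratio heuristic: texts shorter than the ruleset's minimum
#' token count are `unknown`; otherwise the text is `es` when the fraction
#' of tokens in a fixed Spanish stopword list exceeds the ruleset threshold
#' and exceeds the English stopword fraction, and `en` otherwise. A
#' page-level `lang` attribute, when supplied, overrides the heuristic.
#'
#' @param text Natural-language text.
#' @param ruleset A [default_ruleset()].
#' @param lang_attr Optional value of the page's `<html lang=...>`
#'   attribute.
#' @return `"en"`, `"es"` or `"unknown"`.
#' @export
detect_language <- function(text, ruleset = default_ruleset(),
                            lang_attr = NULL) {
  if (!is.null(lang_attr) && !is.na(lang_attr) && nzchar(lang_attr)) {
    code <- tolower(substr(trimws(lang_attr), 1, 2))
    if (code == "es") return("es")
    if (code == "en") return("en")
    return("unknown")
  }
  toks <- tolower(tokenize(text)$token)
  if (length(toks) < ruleset$min_tokens_for_language_call) return("unknown")
  es_frac <- mean(toks %in% SPANISH_STOPWORDS)
  en_frac <- mean(toks %in% ENGLISH_STOPWORDS)
  if (es_frac > ruleset$spanish_stopword_threshold && es_frac > en_frac) {
    return("es")
  }
  "en"
}

html_lang_attr <- function(html) {
  if (is.na(html) || !nzchar(html)) return(NULL)
  doc <- tryCatch(xml2::read_html(html), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  root <- xml2::xml_find_first(doc, "//html")
  if (inherits(root, "xml_missing")) return(NULL)
  lang <- xml2::xml_attr(root, "lang")
  if (is.na(lang)) NULL else lang
}

#' Apply the page-exclusion rules to a decoded page
#'
#' Rules run in a fixed precedence order so that drop-reason tallies are
#' stable: broken, undecodable (both already set by [decode_page()]), then
#' manual excludes / organization exclude patterns, organization include
#' (subset) patterns, sponsor/shop/forum URL patterns, and finally the
#' language rule. The first failing rule wins. Pages with empty extracted
#' text are kept (they simply count zero for every factor).
#'
#' @param page A one-row page-record data frame from [decode_page()].
#' @param org The page's [org_record()].
#' @param ruleset A [default_ruleset()].
#' @return The page record, possibly flipped to dropped with a reason.
#' @export
apply_filters <- function(page, org, ruleset = default_ruleset()) {
  stopifnot(nrow(page) == 1)
  if (page$status == "dropped") return(page)
  url_l <- tolower(page$url)
  drop <- function(reason) {
    page$status <- "dropped"
    page$drop_reason <- reason
    page
  }
  if (page$url %in% org$manual_url_excludes) return(drop("manual"))
  if (length(org$exclude_patterns) &&
      any(vapply(tolower(org$exclude_patterns),
                 function(p) grepl(p, url_l, fixed = TRUE), logical(1)))) {
    return(drop("manual"))
  }
  if (length(org$include_patterns) &&
      !any(vapply(tolower(org$include_patterns),
                  function(p) grepl(p, url_l, fixed = TRUE), logical(1)))) {
    return(drop("subset_pattern"))
  }
  if (any(vapply(tolower(ruleset$url_pattern_drops),
                 function(p) grepl(p, url_l, fixed = TRUE), logical(1)))) {
    return(drop("sponsor_shop_forum"))
  }
  lang <- detect_language(page$text, ruleset,
                          lang_attr = html_lang_attr(page$html))
  if (lang == "es") return(drop("language"))
  page
}

#' Clean a set of decoded pages
#'
#' Applies [apply_filters()] to every page, dispatching each to its
#' organization's record.
#'
#' @param pages Page-record data frame (multiple rows).
#' @param registry An `org_registry` (see [read_org_registry()]).
#' @param ruleset A [default_ruleset()].
#' @return The page-record data frame with final keep/drop status, plus a
#'   `drop_tally` attribute (counts by reason).
#' @export
clean_pages <- function(pages, registry, ruleset = default_ruleset()) {
  out <- do.call(rbind, lapply(seq_len(nrow(pages)), function(i) {
    org <- registry[[pages$org_id[i]]]
    if (is.null(org)) {
      stopf("page %s belongs to unknown org '%s'", pages$url[i],
            pages$org_id[i], class = "riskterms_validation_error")
    }
    apply_filters(pages[i, , drop = FALSE], org, ruleset)
  }))
  rownames(out) <- NULL
  attr(out, "drop_tally") <- table(factor(out$drop_reason,
                                          levels = DROP_REASONS))
  out
}
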