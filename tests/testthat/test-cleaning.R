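make_page <- function(text, url = "http://www.x.org/p", org_id = "x",
                      html = NA_character_) {
  data.frame(org_id = org_id, url = url, provenance = "fixture",
             html = if (is.na(html)) paste0("<html><body><p>", text,
                                            "</p></body></html>") else html,
             text = text, status = "kept", drop_reason = NA_character_,
             stringsAsFactors = FALSE)
}

spanish_prose <- paste(
  "la informacion de la pagina se encuentra en los recursos que el grupo",
  "ofrece para las mujeres de la comunidad y por eso no hay un costo para",
  "el apoyo que se brinda a las familias en el estado")

english_prose <- paste(
  "Stopword-ratio heuristic: texts shorter than the minimum token count",
  "are unknown; otherwise the text is Spanish when the fraction of tokens",
  "in a fixed Spanish stopword list exceeds the threshold and exceeds the",
  "English stopword fraction, and English otherwise.")

test_that("decode_page handles broken, undecodable and clean fetches", {
  ok <- fetch_result("http://www.x.org/p", 200L,
                     body = charToRaw("<html><body><p>BPA here</p></body></html>"),
                     charset = "UTF-8", provenance = "fixture")
  page <- decode_page(ok, "x")
  expect_equal(page$status, "kept")
  expect_equal(page$text, "BPA here")

  notfound <- fetch_result("http://www.x.org/gone", 404L,
                           provenance = "fixture")
  page <- decode_page(notfound, "x")
  expect_equal(page$status, "dropped")
  expect_equal(page$drop_reason, "broken")

  # bytes invalid under every candidate charset
  bad <- fetch_result("http://www.x.org/bin", 200L,
                      body = as.raw(c(0xff, 0xfe, 0xff, 0x80, 0x81)),
                      charset = "UTF-8", provenance = "fixture")
  page <- decode_page(bad, "x")
  expect_equal(page$status, "dropped")
  expect_equal(page$drop_reason, "undecodable")

  # declared latin1 content decodes to UTF-8
  latin <- fetch_result("http://www.x.org/l", 200L,
                        body = c(charToRaw("caf"), as.raw(0xe9)),
                        charset = "latin1", provenance = "fixture")
  page <- decode_page(latin, "x")
  expect_equal(page$status, "kept")
  expect_equal(page$text, "café")

  # meta-tag charset sniffing when no charset is declared
  html <- paste0('<html><head><meta charset="ISO-8859-1"></head>',
                 "<body><p>caf", rawToChar(as.raw(0xe9)),
                 "</p></body></html>")
  sniffed <- fetch_result("http://www.x.org/m", 200L,
                          body = charToRaw(html), provenance = "fixture")
  page <- decode_page(sniffed, "x")
  expect_equal(page$status, "kept")
  expect_match(page$text, "café")
})

test_that("language detection follows the stopword-ratio rule", {
  rs <- default_ruleset()
  expect_equal(detect_language(spanish_prose, rs), "es")
  expect_equal(detect_language(english_prose, rs), "en")
  expect_equal(detect_language("tres palabras nada", rs), "unknown")
  # ratio oracle agreement on the fixed lists
  toks <- tolower(regmatches(spanish_prose,
                             gregexpr("[[:alnum:]]+", spanish_prose))[[1]])
  es_frac <- mean(toks %in% riskterms:::SPANISH_STOPWORDS)
  en_frac <- mean(toks %in% riskterms:::ENGLISH_STOPWORDS)
  expect_true(es_frac > rs$spanish_stopword_threshold && es_frac > en_frac)
  # lang attribute overrides the heuristic
  expect_equal(detect_language(english_prose, rs, lang_attr = "es-MX"),
               "es")
  expect_equal(detect_language(spanish_prose, rs, lang_attr = "en"), "en")
})

test_that("filters fire in fixed precedence order with first-wins", {
  rs <- default_ruleset()
  org <- org_record("x", homepages = "http://www.x.org/",
                    manual_url_excludes = "http://www.x.org/old-page")

  p <- make_page("fine text", url = "http://www.x.org/forum/thread-12")
  expect_equal(apply_filters(p, org, rs)$drop_reason, "sponsor_shop_forum")

  p <- make_page("fine text", url = "http://www.x.org/old-page")
  expect_equal(apply_filters(p, org, rs)$drop_reason, "manual")

  org_subset <- org_record("x", homepages = "http://www.x.org/",
                           include_patterns = "breast")
  p <- make_page("fine", url = "http://www.x.org/lung-cancer")
  expect_equal(apply_filters(p, org_subset, rs)$drop_reason,
               "subset_pattern")
  p <- make_page("fine", url = "http://www.x.org/breast-density")
  expect_equal(apply_filters(p, org_subset, rs)$status, "kept")

  # manual/exclude outranks subset, subset outranks sponsor patterns
  org_both <- org_record("x", homepages = "http://www.x.org/",
                         include_patterns = "breast",
                         exclude_patterns = "archive")
  p <- make_page("fine", url = "http://www.x.org/archive/forum/breast")
  expect_equal(apply_filters(p, org_both, rs)$drop_reason, "manual")
  p <- make_page("fine", url = "http://www.x.org/forum/lung")
  expect_equal(apply_filters(p, org_both, rs)$drop_reason,
               "subset_pattern")

  p <- make_page(spanish_prose, url = "http://www.x.org/informacion")
  expect_equal(apply_filters(p, org, rs)$drop_reason, "language")

  p <- make_page("clean English page", url = "http://www.x.org/info")
  expect_equal(apply_filters(p, org, rs)$status, "kept")

  # empty extracted text is kept, not dropped
  p <- make_page("", url = "http://www.x.org/empty")
  expect_equal(apply_filters(p, org, rs)$status, "kept")
})

test_that("clean_pages partitions pages and tallies drop reasons", {
  org <- org_record("x", homepages = "http://www.x.org/")
  registry <- structure(list(x = org), class = "org_registry")
  pages <- rbind(
    make_page("good English text", url = "http://www.x.org/a"),
    make_page("more text", url = "http://www.x.org/shop/item"),
    make_page(spanish_prose, url = "http://www.x.org/es1")
  )
  out <- clean_pages(pages, registry)
  expect_equal(nrow(out), 3)
  expect_true(all(out$status %in% c("kept", "dropped")))
  expect_true(all(!is.na(out$drop_reason[out$status == "dropped"])))
  tally <- attr(out, "drop_tally")
  expect_equal(sum(tally), sum(out$status == "dropped"))
  expect_equal(unname(tally[["sponsor_shop_forum"]]), 1)
  expect_equal(unname(tally[["language"]]), 1)
  # determinism
  expect_identical(as.data.frame(clean_pages(pages, registry)),
                   as.data.frame(out))
})
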