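#' Extract visible text from HTML
#'
#' Returns the concatenated text content of a page with script, style and
#' comment regions removed. Text nodes are joined with spaces so block
#' boundaries (`<div>`, `<br>`, `<p>`, ...) become token boundaries:
#' `"<div>dense<br>breasts</div>"` yields text in which "dense breasts"
#' matches as a two-token phrase. Entity references are resolved by the
#' parser. Plain text without markup passes through unchanged (idempotent),
#' and malformed markup is handled leniently.
#'
#' @param html A single string of (possibly malformed) HTML, or plain text.
#' @return A single string of visible text with runs of whitespace
#'   collapsed to single spaces.
#' @examples
#' extract_visible_text("<p>BPA is common</p><script>var x=1</script>")
#' @export
extract_visible_text <- function(html) {
  if (length(html) != 1 || is.na(html)) return("")
  if (!nzchar(trimws(html))) return("")
  if (!grepl("<", html, fixed = TRUE)) {
    if (!grepl("&[A-Za-z#][A-Za-z0-9]*;", html)) {
      return(squeeze_ws(html))
    }
    # bare text with entity references: read_html() would mistake the
    # string for a file path, so give it an element to parse
    html <- paste0("<p>", html, "</p>")
  }
  doc <- tryCatch(xml2::read_html(html), error = function(e) NULL)
  if (is.null(doc)) return(squeeze_ws(strip_tags(html)))
  drop <- xml2::xml_find_all(doc, "//script | //style | //comment()")
  if (length(drop)) xml2::xml_remove(drop)
  nodes <- xml2::xml_find_all(doc, "//text()")
  if (!length(nodes)) return("")
  pieces <- xml2::xml_text(nodes)
  pieces <- pieces[nzchar(trimws(pieces))]
  squeeze_ws(paste(pieces, collapse = " "))
}

squeeze_ws <- function(x) {
  trimws(gsub("[[:space:]]+", " ", x))
}

# last-resort fallback when even the lenient parser gives up
strip_tags <- function(html) {
  gsub("<[^>]*>", " ", html)
}
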