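#' Crawl an organization's website
#'
#' Breadth-first same-site traversal starting from each homepage. Only
#' links whose registered domain matches a homepage's registered domain are
#' followed (so `www.` and other subdomain variants of one site are crawled
#' together, while external links are ignored). Each canonical URL is
#' fetched at most once, so cyclic link graphs terminate. Frontier order is
#' the document order of links, making discovery order deterministic for a
#' deterministic fetcher.
#'
#' @param org An [org_record()].
#' @param fetcher A fetcher function (see [fixture_fetcher()]).
#' @param max_pages Stop after this many URLs have been fetched
#'   (default 1000); `frontier_truncated` records whether the limit bit.
#' @param max_depth Maximum link depth from a homepage (default 10).
#' @return A `crawl_report`: list with `org_id`, `discovered_urls` (in
#'   discovery order), `fetches` (named list of fetch results),
#'   `frontier_truncated`, and `fetch_failures` (data frame url/status).
#'   If every homepage is unreachable the report has zero discovered URLs
#'   and `all_homepages_unreachable = TRUE`; the pipeline carries such
#'   organizations forward with zero pages rather than aborting.
#' @examples
#' \dontrun{
#' report <- crawl_site(org, fixture_fetcher("fixtures/org1"))
#' }
#' @export
crawl_site <- function(org, fetcher, max_pages = 1000L, max_depth = 10L) {
  stopifnot(inherits(org, "org_record"), max_pages >= 1, max_depth >= 1)
  allowed <- unique(vapply(org$homepages, registered_domain, character(1)))

  queue_urls <- vapply(org$homepages, canonicalize_url, character(1),
                       USE.NAMES = FALSE)
  queue_depth <- rep(0L, length(queue_urls))
  visited <- character(0)
  fetches <- list()
  failures_url <- character(0)
  failures_status <- integer(0)
  truncated <- FALSE

  while (length(queue_urls)) {
    u <- queue_urls[1]
    d <- queue_depth[1]
    queue_urls <- queue_urls[-1]
    queue_depth <- queue_depth[-1]
    if (u %in% visited) next
    if (length(visited) >= max_pages) {
      truncated <- TRUE
      break
    }
    visited <- c(visited, u)
    res <- fetcher(u)
    fetches[[u]] <- res
    if (!fetch_ok(res)) {
      failures_url <- c(failures_url, u)
      failures_status <- c(failures_status, res$status)
      next
    }
    if (d >= max_depth) next
    html <- decode_body(res)
    if (is.na(html)) next
    links <- extract_links(html, base_url = u)
    links <- links[vapply(links, function(l) {
      registered_domain(l) %in% allowed
    }, logical(1))]
    links <- setdiff(links, c(visited, queue_urls))
    if (length(links)) {
      queue_urls <- c(queue_urls, links)
      queue_depth <- c(queue_depth, rep(d + 1L, length(links)))
    }
  }

  structure(list(
    org_id = org$org_id,
    discovered_urls = visited,
    fetches = fetches,
    frontier_truncated = truncated,
    fetch_failures = data.frame(url = failures_url, status = failures_status,
                                stringsAsFactors = FALSE),
    all_homepages_unreachable =
      length(visited) > 0 &&
      all(org$homepages %in% failures_url) &&
      length(visited) == length(failures_url)
  ), class = "crawl_report")
}

#' @export
print.crawl_report <- function(x, ...) {
  cat(sprintf("<crawl_report '%s'>: %d URLs discovered, %d fetch failures%s\n",
              x$org_id, length(x$discovered_urls), nrow(x$fetch_failures),
              if (x$frontier_truncated) " (frontier truncated)" else ""))
  invisible(x)
}
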