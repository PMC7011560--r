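#' Run the full audit pipeline over an organization registry
#'
#' For every organization: crawl the site from its homepages with the
#' supplied fetcher, decode each fetched page, apply the page-exclusion
#' rules, count lexicon term-group mentions on the kept pages, and
#' summarize. Organizations whose homepages are all unreachable are
#' carried through with zero pages (their per-page averages are flagged
#' undefined) rather than aborting the run.
#'
#' @param registry An `org_registry` (see [read_org_registry()]).
#' @param fetcher A fetcher function (see [fixture_fetcher()],
#'   [live_fetcher()]).
#' @param lexicon A `lexicon` (default [default_lexicon()]).
#' @param ruleset A [default_ruleset()].
#' @param max_pages,max_depth Crawl limits per organization.
#' @return A `riskterms_run` list: `crawls` (per-org crawl reports),
#'   `pages` (page-record data frame for all orgs), `counts` (long-format
#'   counts for kept pages), `summaries` (per-org summaries), `report`
#'   (the [corpus_table()] result).
#' @examples
#' \dontrun{
#' run <- run_pipeline(read_org_registry("orgs.csv"),
#'                     fixture_fetcher("fixtures/"))
#' run$report
#' }
#' @export
run_pipeline <- function(registry, fetcher, lexicon = default_lexicon(),
                         ruleset = default_ruleset(),
                         max_pages = 1000L, max_depth = 10L) {
  crawls <- list()
  pages_list <- list()
  counts_list <- list()
  summaries <- list()
  for (org in registry) {
    crawl <- crawl_site(org, fetcher, max_pages = max_pages,
                        max_depth = max_depth)
    crawls[[org$org_id]] <- crawl
    pages <- if (length(crawl$fetches)) {
      do.call(rbind, lapply(crawl$discovered_urls, function(u) {
        decode_page(crawl$fetches[[u]], org$org_id)
      }))
    } else {
      page_record(character(0), character(0), character(0))[0, ]
    }
    if (nrow(pages)) {
      pages <- do.call(rbind, lapply(seq_len(nrow(pages)), function(i) {
        apply_filters(pages[i, , drop = FALSE], org, ruleset)
      }))
    }
    counts <- count_pages(pages, lexicon)
    pages_list[[org$org_id]] <- pages
    counts_list[[org$org_id]] <- counts
    summaries[[org$org_id]] <- summarize_org(counts, org, lexicon)
  }
  all_pages <- do.call(rbind, pages_list)
  rownames(all_pages) <- NULL
  all_counts <- do.call(rbind, counts_list)
  rownames(all_counts) <- NULL
  structure(list(crawls = crawls, pages = all_pages, counts = all_counts,
                 summaries = summaries,
                 report = corpus_table(summaries, lexicon)),
            class = "riskterms_run")
}

#' @export
print.riskterms_run <- function(x, ...) {
  kept <- sum(x$pages$status == "kept")
  cat(sprintf("<riskterms_run>: %d organizations, %d pages (%d kept)\n",
              length(x$summaries), nrow(x$pages), kept))
  print(x$report)
  invisible(x)
}
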