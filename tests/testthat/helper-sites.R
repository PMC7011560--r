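# In-memory fetcher over a named list url -> html string; unknown URLs 404.
mem_fetcher <- function(pages) {
  canon <- stats::setNames(pages,
                           vapply(names(pages), canonicalize_url,
                                  character(1)))
  function(url) {
    cu <- canonicalize_url(url)
    html <- canon[[cu]]
    if (is.null(html)) {
      fetch_result(cu, 404L, provenance = "fixture")
    } else {
      fetch_result(cu, 200L, body = charToRaw(html), charset = "UTF-8",
                   provenance = "fixture")
    }
  }
}

link_list_html <- function(title, urls, body = "filler words here") {
  links <- paste(sprintf('<li><a href="%s">x</a></li>', urls),
                 collapse = "")
  sprintf("<html><head><title>%s</title></head><body><p>%s</p><ul>%s</ul></body></html>",
          title, body, links)
}

# random same-domain link graph with planted external links; returns the
# page list (for mem_fetcher), the org record, and the page URLs
random_graph_site <- function(seed, n_pages = NULL, p_edge = 0.25) {
  set.seed(seed)
  if (is.null(n_pages)) n_pages <- sample(3:12, 1)
  base <- sprintf("http://www.graph%d.org", seed)
  urls <- c(paste0(base, "/"), sprintf("%s/p%d", base, seq_len(n_pages - 1)))
  externals <- c("http://other-domain.org/x", "https://example.net/y",
                 "http://www.unrelated.com/z")
  pages <- list()
  for (i in seq_len(n_pages)) {
    targets <- urls[stats::runif(n_pages) < p_edge]
    # spanning chain keeps every page reachable from the homepage
    if (i < n_pages) targets <- c(targets, urls[i + 1])
    ext <- externals[stats::runif(3) < 0.5]
    pages[[urls[i]]] <- link_list_html(paste("page", i), c(targets, ext))
  }
  list(pages = pages,
       org = org_record(sprintf("graph%d", seed), homepages = urls[1]),
       urls = vapply(urls, canonicalize_url, character(1),
                     USE.NAMES = FALSE))
}

# corpus spec sampler used by the end-to-end soundness checks: mixed
# topologies, planted counts 0-25, Spanish/forum/broken nuisance pages,
# decoy densities up to 0.5
random_corpus_specs <- function(seed, n_orgs = NULL, max_pages_per_site = 50) {
  set.seed(seed)
  lex <- default_lexicon()
  factors <- lexicon_factors(lex)
  if (is.null(n_orgs)) n_orgs <- sample(5:10, 1)
  lapply(seq_len(n_orgs), function(i) {
    n_pages <- sample(3:max_pages_per_site, 1)
    n_plant <- sample(0:6, 1)
    planted <- if (n_plant > 0) {
      data.frame(page = sample(n_pages, n_plant, replace = TRUE),
                 factor_name = sample(factors, n_plant, replace = TRUE),
                 count = sample(0:25, n_plant, replace = TRUE),
                 stringsAsFactors = FALSE)
    } else NULL
    if (!is.null(planted)) {
      planted <- planted[!duplicated(planted[, c("page", "factor_name")]), ]
    }
    synthetic_site_spec(
      org_id = sprintf("corp%d-org%d", seed, i),
      n_pages = n_pages,
      planted = planted,
      n_spanish_pages = sample(0:2, 1),
      n_forum_pages = sample(0:2, 1),
      n_broken_links = sample(0:2, 1),
      decoy_density = stats::runif(1, 0, 0.5),
      link_topology = sample(c("chain", "star", "complete", "random"), 1),
      scope = sample(c("national", "local_regional"), 1),
      seed = seed * 1000L + i
    )
  })
}

# run the fixture pipeline on a generated corpus and compare every level
# against ground truth; returns a character vector of mismatch messages
check_corpus_soundness <- function(corpus, dir, lexicon,
                                   max_depth = 100L) {
  problems <- character(0)
  run <- run_pipeline(corpus$registry, fixture_fetcher(dir),
                      lexicon = lexicon, max_depth = max_depth)
  for (site in corpus$sites) {
    oid <- site$org$org_id
    gt_counts <- site$ground_truth$page_counts
    got <- run$counts[run$counts$org_id == oid, , drop = FALSE]
    m <- merge(gt_counts, got, by = c("org_id", "url", "factor_name"),
               all = TRUE)
    if (nrow(m) != nrow(gt_counts) || any(is.na(m$count.x)) ||
        any(is.na(m$count.y)) || any(m$count.x != m$count.y)) {
      problems <- c(problems, sprintf("%s: page counts differ", oid))
    }
    gt_status <- site$ground_truth$page_status
    pg <- run$pages[run$pages$org_id == oid, , drop = FALSE]
    mm <- merge(gt_status, pg[, c("url", "status", "drop_reason")],
                by = "url", all = TRUE)
    status_ok <- nrow(mm) == nrow(gt_status) &&
      !any(is.na(mm$status.x)) && !any(is.na(mm$status.y)) &&
      all(mm$status.x == mm$status.y) &&
      all(is.na(mm$drop_reason.x) == is.na(mm$drop_reason.y)) &&
      all(mm$drop_reason.x == mm$drop_reason.y, na.rm = TRUE)
    if (!status_ok) {
      problems <- c(problems, sprintf("%s: keep/drop status differs", oid))
    }
    gt_sum <- site$ground_truth$org_summary
    got_sum <- run$summaries[[oid]]
    if (!identical(gt_sum$totals, got_sum$totals) ||
        gt_sum$n_pages_kept != got_sum$n_pages_kept ||
        !identical(gt_sum$env_avg_per_page, got_sum$env_avg_per_page) ||
        !identical(gt_sum$other_avg_per_page, got_sum$other_avg_per_page)) {
      problems <- c(problems, sprintf("%s: org summary differs", oid))
    }
  }
  if (!identical(run$report$rows, corpus$expected_report$rows)) {
    problems <- c(problems, "corpus rows differ")
  }
  if (!identical(run$report$headline, corpus$expected_report$headline)) {
    problems <- c(problems, "headline differs")
  }
  problems
}
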