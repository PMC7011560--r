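# Filler vocabulary for generated pages: classic typesetting filler, which
# shares no token with any lexicon variant (asserted at generation time)
# and none with the Spanish stopword list, so filler can never create a
# term match or flip a language call.
FILLER_VOCAB <- c(
  "lorem", "ipsum", "dolor", "sit", "amet", "consectetur", "adipiscing",
  "elit", "eiusmod", "tempor", "incididunt", "labore", "dolore", "magna",
  "aliqua", "enim", "minim", "veniam", "quis", "nostrud", "ullamco",
  "laboris", "nisi", "aliquip", "commodo", "consequat", "duis", "aute",
  "irure", "reprehenderit", "voluptate", "velit", "esse", "cillum",
  "fugiat", "pariatur", "excepteur", "sint", "occaecat", "cupidatat",
  "proident", "sunt", "culpa", "qui", "officia", "deserunt", "mollit",
  "anim", "laborum", "tempus", "vitae", "sapien", "fermentum", "vestibulum"
)

# ambiguous terms the lexicon deliberately excludes; planted as decoys to
# prove they never contribute to any count
DECOY_TERMS <- c("chemical", "toxic", "environment", "chemotherapy",
                 "toxicity")

SPANISH_FILLER <- c(
  "de", "la", "que", "el", "en", "los", "se", "las", "por", "un", "para",
  "con", "una", "su", "al", "lo", "como", "pero", "sus", "este", "esta",
  "entre", "cuando", "muy", "sin", "sobre", "hasta", "hay", "donde",
  "desde", "todo", "nos", "durante", "salud", "mujeres", "informacion",
  "pagina", "grupo", "apoyo", "recursos", "comunidad"
)

#' Specification of one synthetic organization website
#'
#' Declares a linked multi-page HTML site with exactly known planted term
#' occurrences plus nuisance content: Spanish-language pages (stopword
#' dense filler), forum pages (under a `/forum/` path), broken links
#' (targets absent from the fixture index), and decoy insertions of the
#' excluded ambiguous terms, which by construction never change a count.
#' Nuisance pages are additional to the `n_pages` content pages.
#'
#' @param org_id Organization identifier (also used as the site's domain
#'   label, so it must be free of the filter rules' URL patterns).
#' @param n_pages Number of content pages (>= 1; page 1 is the homepage).
#' @param planted Data frame with columns `page` (1-based content page
#'   index), `factor_name`, `count`: exact occurrences to embed.
#' @param n_spanish_pages,n_forum_pages,n_broken_links Nuisance content.
#' @param decoy_density Decoy insertions per filler token, in [0, 1].
#' @param link_topology `"chain"`, `"star"`, `"complete"` or `"random"`.
#' @param scope Registry scope label for the organization.
#' @param seed Integer seed; part of the spec so fixtures are exactly
#'   reproducible.
#' @return A `synthetic_site_spec` list.
#' @seealso [generate_site()], [generate_corpus()]
#' @export
synthetic_site_spec <- function(org_id, n_pages,
                                planted = NULL,
                                n_spanish_pages = 0L, n_forum_pages = 0L,
                                n_broken_links = 0L, decoy_density = 0,
                                link_topology = c("chain", "star",
                                                  "complete", "random"),
                                scope = c("national", "local_regional"),
                                seed = 1L) {
  link_topology <- match.arg(link_topology)
  scope <- match.arg(scope)
  if (n_pages < 1) {
    stopf("n_pages must be >= 1", class = "riskterms_validation_error")
  }
  if (decoy_density < 0 || decoy_density > 1) {
    stopf("decoy_density must be in [0, 1]",
          class = "riskterms_validation_error")
  }
  if (is.null(planted)) {
    planted <- data.frame(page = integer(0), factor_name = character(0),
                          count = integer(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("page", "factor_name", "count") %in% names(planted)))
  if (nrow(planted) &&
      (any(planted$page < 1) || any(planted$page > n_pages))) {
    stopf("planted counts refer to a page outside 1..n_pages",
          class = "riskterms_validation_error")
  }
  if (any(planted$count < 0)) {
    stopf("planted counts must be non-negative",
          class = "riskterms_validation_error")
  }
  structure(list(org_id = org_id, n_pages = as.integer(n_pages),
                 planted = planted,
                 n_spanish_pages = as.integer(n_spanish_pages),
                 n_forum_pages = as.integer(n_forum_pages),
                 n_broken_links = as.integer(n_broken_links),
                 decoy_density = decoy_density,
                 link_topology = link_topology, scope = scope,
                 seed = as.integer(seed)),
            class = "synthetic_site_spec")
}

# designated planting variant: the group's first listed variant
designated_variant <- function(lexicon, factor_name) {
  rows <- lexicon[lexicon$factor_name == factor_name, , drop = FALSE]
  if (!nrow(rows)) {
    stopf("planted factor '%s' is not in the lexicon", factor_name,
          class = "riskterms_validation_error")
  }
  rows$variant[1]
}

# independent token-level scan used only for ground-truth bookkeeping:
# greedy longest-match count of `group`'s variants inside a short token
# vector (the tokens of one designated variant, known to be separated by
# single spaces, so no gap inspection is needed)
scan_tokens_for_group <- function(tokens, group) {
  vars <- lapply(seq_len(nrow(group)), function(i) {
    list(toks = tokenize(group$variant[i])$token, acr = group$acronym[i])
  })
  vars <- vars[order(-vapply(vars, function(v) length(v$toks), integer(1)))]
  lower <- tolower(tokens)
  n <- length(tokens)
  i <- 1L
  count <- 0L
  while (i <= n) {
    hit <- 0L
    for (v in vars) {
      k <- length(v$toks)
      if (i + k - 1L > n) next
      seg <- if (v$acr) tokens[i:(i + k - 1L)] else lower[i:(i + k - 1L)]
      want <- if (v$acr) v$toks else tolower(v$toks)
      if (identical(seg, want)) { hit <- k; break }
    }
    if (hit > 0L) { count <- count + 1L; i <- i + hit } else i <- i + 1L
  }
  count
}

# contribution of one planted occurrence of `factor` to every group's
# expected count (own group contributes 1; overlapping groups, e.g.
# "air pollution" containing "pollution", contribute too)
planting_contributions <- function(lexicon, factor_name) {
  toks <- tokenize(designated_variant(lexicon, factor_name))$token
  factors <- lexicon_factors(lexicon)
  contrib <- vapply(factors, function(g) {
    scan_tokens_for_group(toks, lexicon[lexicon$factor_name == g, ,
                                        drop = FALSE])
  }, integer(1))
  if (contrib[[factor_name]] != 1L) {
    stopf("designated variant of '%s' does not scan as exactly one
 occurrence of its own group", factor_name,
          class = "riskterms_validation_error")
  }
  contrib
}

site_base_url <- function(org_id) sprintf("http://www.%s.org", org_id)

insert_items <- function(filler, items) {
  if (!length(items)) return(filler)
  slots <- sample.int(length(filler) + 1L, length(items), replace = TRUE) - 1L
  ord <- order(slots)
  items <- items[ord]
  slots <- slots[ord]
  out <- character(0)
  prev <- 0L
  for (j in seq_along(items)) {
    if (slots[j] > prev) out <- c(out, filler[(prev + 1L):slots[j]])
    out <- c(out, items[j])
    prev <- slots[j]
  }
  if (prev < length(filler)) out <- c(out, filler[(prev + 1L):length(filler)])
  out
}

render_page_html <- function(title, body_text, link_urls, link_labels) {
  links <- if (length(link_urls)) {
    paste(sprintf('<li><a href="%s">%s</a></li>', link_urls, link_labels),
          collapse = "\n")
  } else ""
  sprintf(paste0(
    "<!DOCTYPE html>\n<html>\n<head><title>%s</title>",
    "<meta charset=\"UTF-8\"/></head>\n",
    "<body>\n<p>%s</p>\n<ul>\n%s\n</ul>\n",
    "<script>var tracker = 0;</script>\n</body>\n</html>\n"),
    title, body_text, links)
}

topology_links <- function(n_pages, topology) {
  # adjacency as a list: content page i -> integer vector of targets
  out <- vector("list", n_pages)
  if (n_pages == 1) return(out)
  if (topology == "chain") {
    for (i in seq_len(n_pages - 1)) out[[i]] <- i + 1L
  } else if (topology == "star") {
    out[[1]] <- 2:n_pages
    for (i in 2:n_pages) out[[i]] <- 1L
  } else if (topology == "complete") {
    for (i in seq_len(n_pages)) out[[i]] <- setdiff(seq_len(n_pages), i)
  } else { # random: a spanning structure plus extra seeded edges
    for (j in 2:n_pages) {
      from <- sample.int(j - 1L, 1L)
      out[[from]] <- c(out[[from]], j)
    }
    n_extra <- max(0L, stats::rpois(1, n_pages / 2))
    for (e in seq_len(n_extra)) {
      from <- sample.int(n_pages, 1L)
      to <- sample.int(n_pages, 1L)
      if (from != to) out[[from]] <- c(out[[from]], to)
    }
    out <- lapply(out, function(v) sort(unique(v)))
  }
  out
}

#' Generate one synthetic website with known ground truth
#'
#' Writes the site's HTML files and fixture index under `dir` and returns
#' the ground truth the pipeline must reproduce: per-page expected term
#' counts (planted occurrences plus the known cross-group contributions of
#' overlapping designated variants), expected keep/drop status per page,
#' and the expected organization summary. Generation is fully determined
#' by the spec (including its seed): the same spec writes byte-identical
#' files on every run.
#'
#' @param spec A [synthetic_site_spec()].
#' @param lexicon A `lexicon`; every planted factor must exist in it.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `org` (an [org_record()]), `index`
#'   (url/path data frame), and `ground_truth` (`page_status`,
#'   `page_counts`, `org_summary`).
#' @export
generate_site <- function(spec, lexicon, dir) {
  stopifnot(inherits(spec, "synthetic_site_spec"),
            inherits(lexicon, "lexicon"))
  lex_tokens <- unique(tolower(unlist(lapply(lexicon$variant, function(v) {
    tokenize(v)$token
  }))))
  if (any(FILLER_VOCAB %in% lex_tokens)) {
    stopf("filler vocabulary shares token(s) with the lexicon: %s",
          paste(intersect(FILLER_VOCAB, lex_tokens), collapse = ", "),
          class = "riskterms_validation_error")
  }
  for (f in unique(spec$planted$factor_name)) designated_variant(lexicon, f)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- site_base_url(spec$org_id)
  content_urls <- c(paste0(base, "/"),
                    if (spec$n_pages > 1) {
                      sprintf("%s/page-%d.html", base, 2:spec$n_pages)
                    })
  spanish_urls <- if (spec$n_spanish_pages > 0) {
    sprintf("%s/es/pagina-%d.html", base, seq_len(spec$n_spanish_pages))
  } else character(0)
  forum_urls <- if (spec$n_forum_pages > 0) {
    sprintf("%s/forum/thread-%d.html", base, seq_len(spec$n_forum_pages))
  } else character(0)
  broken_urls <- if (spec$n_broken_links > 0) {
    sprintf("%s/missing-%d.html", base, seq_len(spec$n_broken_links))
  } else character(0)

  factors <- lexicon_factors(lexicon)
  contrib <- lapply(stats::setNames(nm = unique(spec$planted$factor_name)),
                    function(f) planting_contributions(lexicon, f))

  files <- character(0)
  urls <- character(0)
  page_counts <- list()

  with_seed(spec$seed, {
    adjacency <- topology_links(spec$n_pages, spec$link_topology)
    for (p in seq_len(spec$n_pages)) {
      n_filler <- sample(30:60, 1)
      filler <- sample(FILLER_VOCAB, n_filler, replace = TRUE)
      rows <- spec$planted[spec$planted$page == p, , drop = FALSE]
      items <- character(0)
      expected <- stats::setNames(integer(length(factors)), factors)
      for (r in seq_len(nrow(rows))) {
        f <- rows$factor_name[r]
        k <- rows$count[r]
        if (k > 0) {
          # trailing period stops phrases bridging into a neighbour item
          items <- c(items, rep(paste0(designated_variant(lexicon, f), "."),
                                k))
          expected <- expected + k * contrib[[f]]
        }
      }
      n_decoys <- as.integer(round(spec$decoy_density * n_filler))
      if (n_decoys > 0) {
        items <- c(items, paste0(sample(DECOY_TERMS, n_decoys,
                                        replace = TRUE), "."))
      }
      if (length(items)) items <- sample(items)
      words <- insert_items(filler, items)
      link_targets <- content_urls[adjacency[[p]]]
      if (p == 1L) {
        link_targets <- c(link_targets, spanish_urls, forum_urls,
                          broken_urls)
      }
      fname <- if (p == 1L) "index.html" else sprintf("page-%d.html", p)
      writeLines(render_page_html(sprintf("%s page %d", spec$org_id, p),
                                  paste(words, collapse = " "),
                                  link_targets,
                                  paste("link", seq_along(link_targets))),
                 file.path(dir, fname), useBytes = TRUE)
      files <- c(files, fname)
      urls <- c(urls, content_urls[p])
      page_counts[[content_urls[p]]] <- expected
    }
    for (j in seq_along(spanish_urls)) {
      words <- sample(SPANISH_FILLER, 80, replace = TRUE)
      fname <- sprintf("es-pagina-%d.html", j)
      writeLines(render_page_html("pagina", paste(words, collapse = " "),
                                  content_urls[1], "inicio"),
                 file.path(dir, fname), useBytes = TRUE)
      files <- c(files, fname)
      urls <- c(urls, spanish_urls[j])
    }
    for (j in seq_along(forum_urls)) {
      words <- sample(FILLER_VOCAB, 40, replace = TRUE)
      fname <- sprintf("forum-thread-%d.html", j)
      writeLines(render_page_html("thread", paste(words, collapse = " "),
                                  content_urls[1], "home"),
                 file.path(dir, fname), useBytes = TRUE)
      files <- c(files, fname)
      urls <- c(urls, forum_urls[j])
    }
  })

  index <- data.frame(url = urls, path = files, stringsAsFactors = FALSE)
  utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)

  status <- data.frame(
    url = vapply(c(urls, broken_urls), canonicalize_url, character(1),
                 USE.NAMES = FALSE),
    status = c(rep("kept", spec$n_pages),
               rep("dropped", spec$n_spanish_pages + spec$n_forum_pages +
                     spec$n_broken_links)),
    drop_reason = c(rep(NA_character_, spec$n_pages),
                    rep("language", spec$n_spanish_pages),
                    rep("sponsor_shop_forum", spec$n_forum_pages),
                    rep("broken", spec$n_broken_links)),
    stringsAsFactors = FALSE
  )

  counts_long <- do.call(rbind, lapply(names(page_counts), function(u) {
    data.frame(org_id = spec$org_id, url = canonicalize_url(u),
               factor_name = factors,
               count = as.integer(page_counts[[u]]),
               stringsAsFactors = FALSE)
  }))
  rownames(counts_long) <- NULL

  org <- org_record(spec$org_id, homepages = content_urls[1],
                    scope = spec$scope)
  gt_summary <- summarize_org(counts_long, org, lexicon)

  invisible(list(org = org, index = index,
                 ground_truth = list(page_status = status,
                                     page_counts = counts_long,
                                     org_summary = gt_summary)))
}

#' Generate a synthetic corpus of organization websites
#'
#' Writes each site under `dir/<org_id>/`, plus a combined fixture index
#' (`index.csv`), an organization registry (`registry.csv`) consumable by
#' [read_org_registry()], and returns corpus-level ground truth including
#' the expected corpus report.
#'
#' @param specs List of [synthetic_site_spec()] with unique org ids.
#' @param lexicon A `lexicon`.
#' @param dir Output directory.
#' @return Invisibly, a list with `registry`, `index`, `sites` (per-site
#'   ground truth), and `expected_report` (a `corpus_report`).
#' @export
generate_corpus <- function(specs, lexicon, dir) {
  ids <- vapply(specs, `[[`, character(1), "org_id")
  if (anyDuplicated(ids)) {
    stopf("duplicate org_id in corpus specs: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "),
          class = "riskterms_validation_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sites <- lapply(specs, function(sp) {
    site <- generate_site(sp, lexicon, file.path(dir, sp$org_id))
    site$index$path <- file.path(sp$org_id, site$index$path)
    site
  })
  index <- do.call(rbind, lapply(sites, `[[`, "index"))
  utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  registry <- structure(stats::setNames(lapply(sites, `[[`, "org"), ids),
                        class = "org_registry")
  write_org_registry(registry, file.path(dir, "registry.csv"))
  expected_report <- corpus_table(lapply(sites, function(s) {
    s$ground_truth$org_summary
  }), lexicon)
  invisible(list(registry = registry, index = index, sites = sites,
                 expected_report = expected_report))
}
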