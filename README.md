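# riskterms

Lexicon-based audit of risk-factor mentions on organization websites.

Health-communication researchers studying how advocacy organizations talk
about disease prevention need a reproducible answer to a simple question:
*which risk factors does an organization's website actually mention, and
how often?* `riskterms` implements that measurement for breast cancer
organizations as a four-stage pipeline:

1. **acquire** — enumerate a site's pages by breadth-first same-domain
   crawling (live, from dated archive snapshots, or from local fixture
   directories, with provenance recorded per page);
2. **clean** — drop broken links, undecodable pages, sponsor/shop/forum
   pages, Spanish-language pages (the lexicon is English), and apply
   per-organization URL subsetting, each with a recorded reason;
3. **count** — count occurrences of a categorized vocabulary of 23
   risk-factor term groups (52 core surface variants; categories:
   general environmental, specific environmental, other) in each kept
   page's visible text, with word-boundary, longest-match-wins,
   hyphen-tolerant semantics and case-sensitive acronyms;
4. **aggregate** — per-site mention tables, a corpus table with
   percent-of-organizations columns (`round(100k/N)`, halves away from
   zero), and per-organization average mentions per kept page
   (environmental vs other), the basis of the specialization scatter.

A synthetic-website generator with exactly known planted counts makes
every stage testable offline, including nuisance content (decoy
ambiguous terms, Spanish pages, forum pages, broken links) that must
never change a count.

## Worked example

Generate a two-organization synthetic corpus, run the full pipeline on
it, and look at the corpus report:

```r
library(riskterms)
lex <- default_lexicon()

specs <- list(
  synthetic_site_spec("org1", n_pages = 4,
                      planted = data.frame(
                        page = c(1, 2, 3),
                        factor_name = c("Pesticides", "Exercise", "Parabens"),
                        count = c(3, 2, 5)),
                      n_spanish_pages = 1, n_forum_pages = 1,
                      decoy_density = 0.3, link_topology = "chain",
                      seed = 11),
  synthetic_site_spec("org2", n_pages = 3,
                      planted = data.frame(page = 2,
                                           factor_name = "Family history",
                                           count = 4),
                      link_topology = "star", scope = "local_regional",
                      seed = 12)
)
dir <- tempfile()
corpus <- generate_corpus(specs, lex, dir)
run <- run_pipeline(corpus$registry, fixture_fetcher(dir),
                    lexicon = lex, max_depth = 100)
run
```

```
<riskterms_run>: 2 organizations, 9 pages (7 kept)
<corpus_report>: 2 organizations, 23 factors
  headline: general env 0%, specific env 50%, other 100%
    factor_name               category n_orgs_mentioning pct_orgs_mentioning
       Exercise                  other                 1                  50
 Family history                  other                 1                  50
       Parabens specific_environmental                 1                  50
     Pesticides specific_environmental                 1                  50
  Air pollution specific_environmental                 0                   0
 ...
```

Reading this: of the two organizations, one (org1) mentions a specific
environmental chemical class — so the specific-environmental headline is
50% — while both mention a non-environmental risk factor (100%). org1's
Spanish and forum pages were dropped with reasons `language` and
`sponsor_shop_forum` (see `run$pages`), and its planted counts come back
exactly (`run$counts`). `plot(run$report)` draws the per-organization
scatter of average environmental vs other mentions per kept page;
`site_report(run$counts[run$counts$org_id == "org1", ], lex)` gives the
single-site table, ordered by descending total.

The published 2018 audit reference (23 factors over 81 organization
websites, plus per-factor totals for two flagship national cancer sites)
ships with the package:

```r
head(published_reference(), 3)
#>      factor_name category n_orgs_mentioning pct_orgs_mentioning total_mentions nci_mentions acs_mentions
#> 1       Exercise    other                60                  74           2796           96          340
#> 2 Family history    other                54                  67           1167          249           74
#> 3           Diet    other                48                  59           1514           28          172
```

A thin CLI over the same functions lives at
`inst/scripts/riskterms` (subcommands `simulate`, `crawl`, `count`,
`run`).

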