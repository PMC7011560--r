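---
title: "Auditing risk-factor mentions on organization websites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing risk-factor mentions on organization websites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskterms)
```

## The measurement

`riskterms` measures how often organizations talk about disease risk
factors on their public websites. The unit of observation is the
*mention*: one occurrence of any surface variant of a named risk-factor
term group in the visible text of one web page. Mentions roll up to three
surfaces:

* a **corpus table** — for each factor, how many (and what percent of)
  organizations mention it at all, and the total mentions across all
  their pages;
* a **site table** — total mentions per factor on one site, for deep
  dives into individual flagship sites;
* a **per-organization scatter** — each organization's average
  environmental mentions per kept page against its average mentions of
  other risk factors per kept page, annotated with national vs
  local/regional scope. Organizations that specialize in environmental
  content sit near one axis; organizations focused on lifestyle and
  genetic factors near the other.

This is deliberately a *prevalence* measurement, not an understanding
one: no context analysis, no sentiment, no negation handling. Terms that
proved too ambiguous for that treatment ("environment", "toxic",
"chemical", "hormone therapy") are excluded from the vocabulary outright
rather than disambiguated, because on cancer-organization websites they
frequently occur in treatment contexts (chemotherapy toxicity, hormone
therapy as treatment) that have nothing to do with environmental
exposure.

## The lexicon

The default vocabulary (`default_lexicon()`) contains 23 factor groups in
three categories: *general environmental* (3 groups, e.g. Pollution),
*specific environmental* (10 groups — named chemical classes such as
Bisphenols, Phthalates, PFAS), and *other* (10 groups — lifestyle,
genetic, pharmaceutical and clinical factors such as Exercise, Genetics,
Hormone replacement therapy). Parenthesized plural notation is expanded
to explicit singular and plural variants — `count_group_mentions()` does
no stemming, because stemming would silently widen matching beyond the
curated list. The printed vocabulary expands to exactly 52 variants.

Three supplemental variants are carried with a `supplemental` flag so the
core count stays 52:

* `BRCA1` / `BRCA2` alongside the spellings `BRAC1` / `BRAC2` in the
  Genetics group. The latter spelling appears in the published term list
  but is almost certainly a typographical variant of the standard gene
  symbols; real pages overwhelmingly use BRCA. Both are kept so either
  convention is counted.
* the spelled-out phrase `hormone replacement therapy` alongside `HRT`.
  The excluded ambiguous term is the bare phrase "hormone therapy";
  the fully qualified phrase refers to the risk factor and is counted.

Exclusion applies to *standalone* terms only: "endocrine disrupting
chemicals" is retained even though it contains the token "chemical",
because the ambiguity attaches to the bare word, not to the curated
phrase. `new_lexicon()` enforces this, along with uniqueness of
(factor, variant) pairs and a single category per factor.

## Matching semantics

The counter works on tokens — maximal runs of letters and digits — so
punctuation and underscores are word boundaries and `"BPA,"` or
`"pesticides."` match naturally, while `"HRT"` never fires inside
`"Hrthe"`. Multi-word variants tolerate any single run of whitespace
and/or hyphens between tokens (`"endocrine-disrupting chemicals"`
matches); any other intervening character breaks the phrase. Variants
flagged as acronyms (all-caps surface forms: BPA, HRT, DES, PAH(s),
PFOA, PFOS, PFAS, PFC(s), the gene symbols) match case-sensitively, so
"des moines" does not count as diethylstilbestrol; all other variants
are case-insensitive. Whether the matching should be case-sensitive at
all is genuinely open for this kind of audit; the acronym-only rule is
the choice that avoids the obvious false positives in both directions.

Within a group, matching scans left to right; at any position the
longest matching variant wins and its span is consumed, so a span
contributes at most one match per group (this resolves nesting such as
"endocrine disruptor" inside "endocrine disrupting chemicals"). Distinct
groups count independently, so a planted "air pollution" legitimately
also counts one Pollution mention — the only such overlap among the
default groups' designated planting variants, and one the synthetic
generator's ground truth accounts for explicitly.

The test suite pins these semantics to an independent brute-force oracle
(regex enumeration of every candidate span followed by greedy
non-overlapping selection) on randomized adversarial texts; the two
implementations share no code.

## Acquisition

`crawl_site()` does breadth-first, same-site traversal from each
registered homepage, following only links whose *registered domain*
(public-suffix aware, so `www.` and `blog.` variants are one site)
matches a homepage's. Frontier order is document order, which makes
discovery order — and therefore every downstream report — deterministic
for a deterministic fetcher. Each canonical URL is fetched once, so
cyclic graphs terminate. URL canonicalization lowercases scheme and
host, strips fragments and `utm_*` tracking parameters, and normalizes
trailing slashes; other query parameters are preserved because they can
address distinct content.

Defaults: `max_pages = 1000` (comfortably above the largest site the
published audit encountered, 894 URLs) and `max_depth = 10`; both are
arguments, and the synthetic-corpus tests raise `max_depth` because
chain-topology fixtures are deliberately deep.

Fetching is a contract (`function(url) -> fetch_result`), with three
implementations: `fixture_fetcher()` for offline directories (all
testing), `live_fetcher()` (polite: robots.txt for `User-agent: *`, a
politeness delay), and `snapshot_fetch()` + `wayback_client()` for
freezing page state at an analysis date — preferring the archived
capture nearest the target date within ±45 days (the window that pairs a
mid-November analysis date with "comparable period" fallbacks), then
falling back to a live fetch, then recording a failure *as data*.
Transport failures are never exceptions: they surface as broken-link
drops in the cleaning report, as they did in the published audit.

## Cleaning

The published audit cleaned its crawl manually; manual curation is not
reproducible, so this package encodes the stated exclusion categories as
explicit rules plus a per-organization manual exclude list for the cases
patterns cannot express. Rules run in a fixed precedence order so
drop-reason tallies are stable, first failure wins:

1. **broken** — non-2xx fetch;
2. **undecodable** — body decodes under neither the declared charset, a
   charset sniffed from a `meta` tag, nor UTF-8 (no blanket latin1
   fallback: with one, nothing would ever be undecodable and the
   category would be meaningless);
3. **manual** — exact-URL excludes and organization exclude patterns;
4. **subset_pattern** — organization include patterns (e.g. keep only
   URLs containing "breast" for a general women's-health site);
5. **sponsor_shop_forum** — URL substrings (`shop`, `store`, `product`,
   `cart`, `forum`, `board`, `sponsor`, ...);
6. **language** — Spanish pages.

Language identification is a stopword-ratio heuristic over fixed
embedded Spanish and English function-word lists: below 25 tokens the
call is `unknown` (and the page is kept); otherwise a page is Spanish
when its Spanish-stopword fraction exceeds 0.12 *and* exceeds its
English-stopword fraction. A page-level `<html lang=...>` attribute
overrides the heuristic. A model-based identifier would be more general,
but the two-language decision this pipeline needs is well inside the
regime where stopword ratios are essentially error-free, and the
heuristic is fully inspectable and offline. The 0.12 threshold sits far
below the ~0.4–0.6 fraction of genuine Spanish prose and far above the
near-zero fraction of English prose, so the margin is wide in both
directions.

Pages with empty extracted text are kept and simply count zero —
emptiness is a finding, not an exclusion.

## The synthetic generator

Because the corpus the published numbers came from was the live 2018
state of 81 public websites, it cannot be re-crawled; every stage is
therefore validated against synthetic websites whose ground truth is
known by construction. `generate_site()` emits linked HTML pages where
each content page embeds *exactly* the planted number of occurrences of
one designated variant per factor, separated by filler drawn from a
vocabulary that is token-disjoint from the entire lexicon (asserted at
generation time) and from the Spanish stopword list. Nuisance content is
layered on top:

* decoy insertions of the excluded ambiguous terms at a configurable
  density (punctuation-guarded so they can never bridge into a phrase),
  which by construction change no count;
* Spanish pages (stopword-dense filler) expected to drop as `language`;
* `/forum/` pages expected to drop as `sponsor_shop_forum`;
* broken links pointing outside the fixture index, expected to drop as
  `broken`;
* four link topologies (chain, star, complete, seeded random) to
  exercise traversal.

Ground truth accounts for the one cross-group overlap among designated
variants ("air pollution" also scans as one Pollution mention) via a
small independent token-subsequence scan, with a generation-time
assertion that no other overlap exists. All randomness flows through the
spec's seed, and generation restores the caller's RNG state, so the same
spec writes byte-identical fixtures on every run.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: JavaScript-rendered content (the
pipeline never executes scripts), shared boilerplate repeated across
pages (counted on every page where it appears, as the pipeline counts
whatever extraction returns), near-miss Spanish/English code-switching,
charset chaos beyond declared/sniffed/UTF-8, and the judgment calls a
human curator would make about what is "really" a sponsor page.

## Verification at the published scale

The corpus-level published statistics (14,087 pages over 81
organizations) are not reproducible offline, so the acceptance layer
verifies two complementary things instead: (a) the percent column of the
published corpus table is reproduced *exactly* from its printed
per-factor organization counts at N = 81 by `percent_mentioning()` —
integer rounding with halves away from zero, a convention verified
compatible with all 23 printed rows (no half case occurs at N = 81); and
(b) on 20 seeded synthetic corpora (5–10 organizations each, 3–50 pages
per site, planted counts 0–25, nuisance pages and decoy densities up to
0.5 — sizes chosen to exercise every topology and filter while keeping a
full run in minutes), the pipeline reproduces generator ground truth
with integer equality at page, organization and corpus level. The same
script checks counter–oracle agreement on 100 randomized texts,
excluded-term neutrality, crawler invariants (domain closure, cycle
termination, idempotence, `max_pages` prefix monotonicity) on 50 random
graphs, and the degenerate corpora (empty, all-Spanish, all-broken,
single-page).

## Numerical and degenerate-input choices

* Percentages are integers, rounded half away from zero.
* Per-page averages divide by *kept* pages, the only denominator the
  pipeline can defend — dropped pages contribute no counted text. An
  organization with zero kept pages gets `NA` averages and an explicit
  `averages_defined = FALSE` flag rather than a silent 0 or NaN, and is
  omitted from the scatter.
* Site-table rows order by descending total with alphabetical
  tie-breaks, so output is reproducible byte for byte.
* The scatter's axis assignment is emitted as labelled columns
  (`env_avg_per_page`, `other_avg_per_page`) so either orientation can
  be plotted.
* Empty registries and empty page sets raise typed validation errors at
  the aggregation boundary; everything upstream degrades to
  zero-page organizations rather than failing.

## Known limitations

Beyond the generator's stated non-goals: the public-suffix table is a
small embedded subset (sufficient for same-site decisions on `.com` /
`.org` style hosts and common two-label country suffixes, not the full
public-suffix list); URL-pattern rules are substring checks and can
overfire on words like "dashboard" (`board`) if an organization's real
URLs collide with them — the per-organization pattern fields exist
precisely to adjust for that; and mention counts are a proxy for
emphasis, not a reading of stance — a page can mention pesticides to
dismiss their relevance.
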