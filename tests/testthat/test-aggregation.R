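lex <- default_lexicon()

fake_counts <- function(org_id, per_page) {
  # per_page: named list url -> named vector factor -> count
  do.call(rbind, lapply(names(per_page), function(u) {
    cts <- stats::setNames(integer(length(lexicon_factors(lex))),
                           lexicon_factors(lex))
    cts[names(per_page[[u]])] <- per_page[[u]]
    data.frame(org_id = org_id, url = u,
               factor_name = names(cts), count = as.integer(cts),
               stringsAsFactors = FALSE)
  }))
}

test_that("percent_mentioning rounds half away from zero", {
  expect_equal(percent_mentioning(60, 81), 74L)
  expect_equal(percent_mentioning(6, 81), 7L)
  expect_equal(percent_mentioning(0, 81), 0L)
  expect_equal(percent_mentioning(81, 81), 100L)
  expect_equal(percent_mentioning(1, 200), 1L)   # 0.5 -> 1
  expect_equal(percent_mentioning(3, 200), 2L)   # 1.5 -> 2
  expect_error(percent_mentioning(1, 0), class = "riskterms_validation_error")
  expect_error(percent_mentioning(5, 4), class = "riskterms_validation_error")
})

test_that("percent column of the published corpus table is reproduced", {
  ref <- published_reference()
  expect_equal(nrow(ref), 23)
  recomputed <- percent_mentioning(ref$n_orgs_mentioning, attr(ref, "n_orgs"))
  expect_equal(recomputed, ref$pct_orgs_mentioning)
})

test_that("summarize_org computes totals, flags and per-page averages", {
  org <- org_record("x", homepages = "http://www.x.org/")
  counts <- fake_counts("x", list(
    "http://www.x.org/" = c(Pesticides = 2L),
    "http://www.x.org/p2" = c(Pesticides = 1L, Exercise = 4L)
  ))
  s <- summarize_org(counts, org, lex)
  expect_equal(s$n_pages_kept, 2)
  expect_equal(unname(s$totals[["Pesticides"]]), 3)
  expect_true(s$mentions_any_specific_env)
  expect_false(s$mentions_any_general_env)
  expect_true(s$mentions_any_other)
  expect_equal(s$env_avg_per_page, 3 / 2)
  expect_equal(s$other_avg_per_page, 4 / 2)

  # degenerate: no kept pages
  empty <- fake_counts("x", list())
  empty <- data.frame(org_id = character(0), url = character(0),
                      factor_name = character(0), count = integer(0))
  s0 <- summarize_org(empty, org, lex)
  expect_equal(s0$n_pages_kept, 0)
  expect_false(s0$averages_defined)
  expect_true(is.na(s0$env_avg_per_page))
  expect_true(all(s0$totals == 0))

  # contract: counts from another org
  other <- fake_counts("y", list("http://www.y.org/" = c(Diet = 1L)))
  expect_error(summarize_org(other, org, lex),
               class = "riskterms_contract_error")
})

test_that("corpus_table rows, headline and scatter points are consistent", {
  orgs <- list(
    env_only = list("http://www.a.org/" = c(Parabens = 2L)),
    other_only = list("http://www.b.org/" = c(Diet = 3L)),
    both = list("http://www.c.org/" = c(Pesticides = 1L, Diet = 1L,
                                        Pollution = 2L))
  )
  summaries <- lapply(names(orgs), function(id) {
    summarize_org(fake_counts(id, orgs[[id]]),
                  org_record(id, homepages = sprintf("http://www.%s.org/", id),
                             scope = if (id == "both") "local_regional"
                                     else "national"),
                  lex)
  })
  rep <- corpus_table(summaries, lex)
  expect_equal(rep$n_orgs, 3)
  rows <- rep$rows
  expect_equal(rows$n_orgs_mentioning[rows$factor_name == "Parabens"], 1L)
  expect_equal(rows$pct_orgs_mentioning[rows$factor_name == "Parabens"], 33L)
  expect_equal(rows$total_mentions[rows$factor_name == "Diet"], 4L)
  # headline from category flags: specific env mentioned by 2 of 3
  expect_equal(unname(rep$headline[["pct_specific_env"]]),
               percent_mentioning(2, 3))
  expect_equal(unname(rep$headline[["pct_general_env"]]),
               percent_mentioning(1, 3))
  expect_equal(unname(rep$headline[["pct_other"]]),
               percent_mentioning(2, 3))
  # specialization: env-only orgs sit on one axis, other-only on the other
  pts <- rep$fig_points
  expect_equal(pts$other_avg_per_page[pts$org_id == "env_only"], 0)
  expect_equal(pts$env_avg_per_page[pts$org_id == "other_only"], 0)

  # permutation invariance
  rep2 <- corpus_table(rev(summaries), lex)
  expect_identical(rep$rows, rep2$rows)
  expect_identical(rep$headline, rep2$headline)
  expect_identical(rep$fig_points, rep2$fig_points)

  # duplicate org ids rejected
  expect_error(corpus_table(c(summaries, summaries[1]), lex),
               class = "riskterms_validation_error")
})

test_that("single-org corpus yields only 0 or 100 percents", {
  s <- summarize_org(fake_counts("solo",
                                 list("http://www.solo.org/" = c(Diet = 2L))),
                     org_record("solo", homepages = "http://www.solo.org/"),
                     lex)
  rep <- corpus_table(list(s), lex)
  expect_true(all(rep$rows$pct_orgs_mentioning %in% c(0L, 100L)))
})

test_that("site_report orders by descending total with alphabetical ties", {
  counts <- fake_counts("site", list(
    "http://www.s.org/a" = c(`Family history` = 5L, Diet = 3L,
                             Exercise = 7L, Alcohol = 7L)
  ))
  rep <- site_report(counts, lex)
  expect_equal(nrow(rep), 23)
  top4 <- rep$factor_name[1:4]
  expect_equal(top4, c("Alcohol", "Exercise", "Family history", "Diet"))
  expect_equal(rep$total_mentions[1:4], c(7L, 7L, 5L, 3L))
  # remaining factors present with zeros, alphabetical
  zeros <- rep$factor_name[rep$total_mentions == 0]
  expect_equal(zeros, sort(zeros))

  empty <- data.frame(org_id = character(0), url = character(0),
                      factor_name = character(0), count = integer(0))
  rep0 <- site_report(empty, lex)
  expect_true(all(rep0$total_mentions == 0L))
})
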