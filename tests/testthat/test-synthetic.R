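lex <- default_lexicon()

test_that("generated fixtures are byte-identical for the same spec and seed", {
  spec <- synthetic_site_spec("det", n_pages = 3,
                              planted = data.frame(page = 1,
                                                   factor_name = "Parabens",
                                                   count = 3),
                              n_spanish_pages = 1, decoy_density = 0.3,
                              link_topology = "random", seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_site(spec, lex, d1)
  generate_site(spec, lex, d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("planted counts survive the full pipeline exactly", {
  spec <- synthetic_site_spec("plant", n_pages = 2,
                              planted = data.frame(
                                page = c(1, 2),
                                factor_name = c("Parabens", "Exercise"),
                                count = c(3, 4)),
                              decoy_density = 0.4, link_topology = "chain",
                              seed = 5)
  dir <- withr::local_tempdir()
  site <- generate_site(spec, lex, dir)
  registry <- structure(list(plant = site$org), class = "org_registry")
  run <- run_pipeline(registry, fixture_fetcher(dir), lexicon = lex,
                      max_depth = 100)
  counts <- run$counts
  home <- counts[grepl("/$", counts$url), ]
  expect_equal(home$count[home$factor_name == "Parabens"], 3L)
  expect_true(all(home$count[home$factor_name != "Parabens"] == 0L))
  p2 <- counts[grepl("page-2", counts$url), ]
  expect_equal(p2$count[p2$factor_name == "Exercise"], 4L)
})

test_that("decoy insertions never change any expected or observed count", {
  mk <- function(density) {
    synthetic_site_spec("decoy", n_pages = 2,
                        planted = data.frame(page = 1,
                                             factor_name = "Phthalates",
                                             count = 2),
                        decoy_density = density, seed = 21)
  }
  d0 <- withr::local_tempdir()
  d5 <- withr::local_tempdir()
  s0 <- generate_site(mk(0), lex, d0)
  s5 <- generate_site(mk(0.5), lex, d5)
  expect_identical(s0$ground_truth$page_counts, s5$ground_truth$page_counts)
  for (site in list(list(d = d0, s = s0), list(d = d5, s = s5))) {
    registry <- structure(list(decoy = site$s$org), class = "org_registry")
    run <- run_pipeline(registry, fixture_fetcher(site$d), lexicon = lex,
                        max_depth = 100)
    m <- merge(site$s$ground_truth$page_counts, run$counts,
               by = c("org_id", "url", "factor_name"))
    expect_true(all(m$count.x == m$count.y))
  }
})

test_that("overlapping designated variants contribute to both groups", {
  # "air pollution" contains the Pollution variant "pollution"
  spec <- synthetic_site_spec("overlap", n_pages = 1,
                              planted = data.frame(page = 1,
                                                   factor_name = "Air pollution",
                                                   count = 2),
                              seed = 8)
  dir <- withr::local_tempdir()
  site <- generate_site(spec, lex, dir)
  gt <- site$ground_truth$page_counts
  expect_equal(gt$count[gt$factor_name == "Air pollution"], 2L)
  expect_equal(gt$count[gt$factor_name == "Pollution"], 2L)
  registry <- structure(list(overlap = site$org), class = "org_registry")
  run <- run_pipeline(registry, fixture_fetcher(dir), lexicon = lex)
  m <- merge(gt, run$counts, by = c("org_id", "url", "factor_name"))
  expect_true(all(m$count.x == m$count.y))
})

test_that("nuisance pages get the expected drop reasons end to end", {
  spec <- synthetic_site_spec("nuis", n_pages = 2,
                              n_spanish_pages = 2, n_forum_pages = 1,
                              n_broken_links = 2, link_topology = "star",
                              seed = 33)
  dir <- withr::local_tempdir()
  site <- generate_site(spec, lex, dir)
  registry <- structure(list(nuis = site$org), class = "org_registry")
  run <- run_pipeline(registry, fixture_fetcher(dir), lexicon = lex)
  pg <- run$pages
  expect_equal(sum(pg$status == "kept"), 2)
  expect_equal(sum(pg$drop_reason == "language", na.rm = TRUE), 2)
  expect_equal(sum(pg$drop_reason == "sponsor_shop_forum", na.rm = TRUE), 1)
  expect_equal(sum(pg$drop_reason == "broken", na.rm = TRUE), 2)
})

test_that("zero-planted corpus produces an all-zero report", {
  specs <- list(synthetic_site_spec("z1", n_pages = 3, seed = 1),
                synthetic_site_spec("z2", n_pages = 2, seed = 2))
  dir <- withr::local_tempdir()
  corpus <- generate_corpus(specs, lex, dir)
  run <- run_pipeline(corpus$registry, fixture_fetcher(dir), lexicon = lex)
  expect_true(all(run$report$rows$total_mentions == 0L))
  expect_true(all(run$report$rows$pct_orgs_mentioning == 0L))
  expect_true(all(run$report$headline == 0L))
})

test_that("corpus generator emits a registry the fixture pipeline consumes", {
  specs <- list(
    synthetic_site_spec("ga", n_pages = 4,
                        planted = data.frame(page = 2,
                                             factor_name = "Pesticides",
                                             count = 1),
                        link_topology = "chain", seed = 3),
    synthetic_site_spec("gb", n_pages = 3,
                        planted = data.frame(page = 1,
                                             factor_name = "Diet",
                                             count = 2),
                        link_topology = "complete",
                        scope = "local_regional", seed = 4)
  )
  dir <- withr::local_tempdir()
  corpus <- generate_corpus(specs, lex, dir)
  # round-trip the registry through its CSV form
  registry <- read_org_registry(file.path(dir, "registry.csv"))
  run <- run_pipeline(registry, fixture_fetcher(dir), lexicon = lex,
                      max_depth = 100)
  # chain reachability: all 4 pages of ga discovered and kept
  expect_equal(run$summaries[["ga"]]$n_pages_kept, 4)
  expect_equal(unname(run$summaries[["ga"]]$totals[["Pesticides"]]), 1)
  expect_equal(unname(run$report$headline[["pct_specific_env"]]),
               percent_mentioning(1, 2))
  expect_identical(run$report$rows, corpus$expected_report$rows)
})

test_that("planting validation rejects unknown factors", {
  expect_error(
    generate_site(synthetic_site_spec("bad", n_pages = 1,
                                      planted = data.frame(
                                        page = 1,
                                        factor_name = "Nonexistent",
                                        count = 1),
                                      seed = 1),
                  lex, withr::local_tempdir()),
    class = "riskterms_validation_error")
  expect_error(generate_corpus(list(synthetic_site_spec("dup", 1, seed = 1),
                                    synthetic_site_spec("dup", 1, seed = 2)),
                               lex, withr::local_tempdir()),
               class = "riskterms_validation_error")
})

test_that("filler vocabulary shares no token with any lexicon variant", {
  lex_tokens <- unique(tolower(unlist(
    regmatches(lex$variant, gregexpr("[[:alnum:]]+", lex$variant)))))
  expect_length(intersect(riskterms:::FILLER_VOCAB, lex_tokens), 0)
  expect_length(intersect(riskterms:::SPANISH_FILLER, lex_tokens), 0)
})
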