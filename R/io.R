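#' Write page records as JSON lines
#'
#' One JSON object per page with fields `org_id`, `url`, `provenance`,
#' `status`, `drop_reason` and `text` (raw HTML is not serialized).
#'
#' @param pages Page-record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pages_jsonl <- function(pages, path) {
  keep <- c("org_id", "url", "provenance", "status", "drop_reason", "text")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(pages))) {
    rec <- as.list(pages[i, intersect(keep, names(pages)), drop = FALSE])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' Read page records from JSON lines
#' @param path Input path.
#' @return Page-record data frame.
#' @export
read_pages_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- do.call(rbind, lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    data.frame(org_id = rec$org_id, url = rec$url,
               provenance = rec$provenance %||% "fixture",
               html = NA_character_,
               text = rec$text %||% NA_character_,
               status = rec$status,
               drop_reason = rec$drop_reason %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write page term counts as JSON lines (one object per page)
#' @param counts Long-format counts data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_jsonl <- function(counts, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (u in unique(counts$url)) {
    rows <- counts[counts$url == u, , drop = FALSE]
    rec <- list(org_id = rows$org_id[1], url = u,
                counts = as.list(stats::setNames(rows$count,
                                                 rows$factor_name)))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read page term counts from JSON lines
#' @param path Input path.
#' @return Long-format counts data frame.
#' @export
read_counts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- do.call(rbind, lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    data.frame(org_id = rec$org_id, url = rec$url,
               factor_name = names(rec$counts),
               count = as.integer(unlist(rec$counts)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write the corpus report's output tables as CSV files
#'
#' Emits `corpus_table.csv` (per-factor rows), `headline.csv` (the three
#' category percentages) and `fig_points.csv` (per-organization average
#' mentions per page, labelled by scope) under `dir`.
#'
#' @param report A `corpus_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_csvs <- function(report, dir) {
  stopifnot(inherits(report, "corpus_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$rows, file.path(dir, "corpus_table.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(measure = names(report$headline),
                              percent = unname(report$headline)),
                   file.path(dir, "headline.csv"), row.names = FALSE)
  utils::write.csv(report$fig_points, file.path(dir, "fig_points.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Published corpus and flagship-site reference results
#'
#' Loads the published 2018 audit results shipped with the package: for
#' each of the 23 lexicon factors, the number and percent of the 81
#' surveyed organizations mentioning it, the total mentions across all
#' organization websites, and the mention totals on the two flagship
#' national cancer sites (463 and 348 breast-cancer pages respectively).
#'
#' @return A data frame with columns `factor_name`, `category`,
#'   `n_orgs_mentioning`, `pct_orgs_mentioning`, `total_mentions`,
#'   `nci_mentions`, `acs_mentions`, plus attribute `n_orgs` (81).
#' @export
published_reference <- function() {
  path <- system.file("extdata", "published_results_2018.csv",
                      package = "riskterms")
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(out, "n_orgs") <- 81L
  out
}
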