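#' Integer percent of organizations mentioning a factor
#'
#' `round(100 * k / N)` with halves rounded away from zero — the rounding
#' convention that reproduces every percent in the published corpus table
#' from its bracketed organization count at N = 81 (no half cases occur at
#' that N, so the convention is compatible with the table).
#'
#' @param k Number of organizations mentioning the factor (0 <= k <= N).
#' @param N Total number of organizations (> 0).
#' @return Integer percent.
#' @examples
#' percent_mentioning(60, 81)  # 74
#' percent_mentioning(6, 81)   # 7
#' @export
percent_mentioning <- function(k, N) {
  if (length(N) != 1 || is.na(N) || N <= 0) {
    stopf("N must be a positive organization count",
          class = "riskterms_validation_error")
  }
  if (any(k < 0) || any(k > N)) {
    stopf("k must satisfy 0 <= k <= N", class = "riskterms_validation_error")
  }
  as.integer(floor(100 * k / N + 0.5))
}

#' Summarize one organization's page counts
#'
#' Rolls page-level term counts up to the organization: per-factor totals,
#' per-category totals, category presence flags, and the two per-page
#' averages behind the corpus scatter (environmental mentions per kept
#' page vs other-risk-factor mentions per kept page). Averages are flagged
#' undefined when the organization has no kept pages.
#'
#' @param counts Long-format counts for this organization's kept pages
#'   (from [count_pages()]); zero rows for an organization with no kept
#'   pages.
#' @param org The [org_record()].
#' @param lexicon A `lexicon`.
#' @return An `org_summary` list.
#' @export
summarize_org <- function(counts, org, lexicon) {
  stopifnot(inherits(org, "org_record"), inherits(lexicon, "lexicon"))
  if (nrow(counts) && !all(counts$org_id == org$org_id)) {
    stopf("counts contain pages from an organization other than '%s'",
          org$org_id, class = "riskterms_contract_error")
  }
  factors <- lexicon_factors(lexicon)
  cat_map <- lexicon_category_map(lexicon)
  totals <- stats::setNames(integer(length(factors)), factors)
  if (nrow(counts)) {
    agg <- tapply(counts$count, counts$factor_name, sum)
    totals[names(agg)] <- as.integer(agg)
  }
  n_pages_kept <- length(unique(counts$url))
  category_totals <- vapply(LEXICON_CATEGORIES, function(cc) {
    sum(totals[names(cat_map)[cat_map == cc]])
  }, numeric(1))
  env_total <- category_totals[["general_environmental"]] +
    category_totals[["specific_environmental"]]
  other_total <- category_totals[["other"]]
  defined <- n_pages_kept > 0
  structure(list(
    org_id = org$org_id,
    scope = org$scope,
    n_pages_kept = n_pages_kept,
    totals = totals,
    category_totals = category_totals,
    mentions_any_general_env =
      category_totals[["general_environmental"]] > 0,
    mentions_any_specific_env =
      category_totals[["specific_environmental"]] > 0,
    mentions_any_other = category_totals[["other"]] > 0,
    averages_defined = defined,
    env_avg_per_page = if (defined) env_total / n_pages_kept else NA_real_,
    other_avg_per_page = if (defined) other_total / n_pages_kept
                         else NA_real_
  ), class = "org_summary")
}

#' @export
print.org_summary <- function(x, ...) {
  cat(sprintf("<org_summary '%s'> (%s): %d kept pages, %d total mentions\n",
              x$org_id, x$scope, x$n_pages_kept, sum(x$totals)))
  if (x$averages_defined) {
    cat(sprintf("  env mentions/page = %.3f, other mentions/page = %.3f\n",
                x$env_avg_per_page, x$other_avg_per_page))
  } else {
    cat("  per-page averages undefined (no kept pages)\n")
  }
  invisible(x)
}

#' Build the corpus-level report
#'
#' One row per lexicon factor with the number and integer percent of
#' organizations mentioning it (total mentions > 0 across kept pages) and
#' its corpus-wide mention total; headline percentages for the three
#' factor categories; and the per-organization scatter points (average
#' environmental vs other mentions per kept page, labelled by geographic
#' scope). Output is independent of the order the summaries arrive in.
#'
#' @param summaries List of [summarize_org()] results with unique org ids.
#' @param lexicon A `lexicon`.
#' @return A `corpus_report` list: `n_orgs`, `rows` (data frame),
#'   `headline` (named percents), `fig_points` (data frame).
#' @export
corpus_table <- function(summaries, lexicon) {
  if (!length(summaries)) {
    stopf("no organization summaries supplied",
          class = "riskterms_validation_error")
  }
  ids <- vapply(summaries, `[[`, character(1), "org_id")
  if (anyDuplicated(ids)) {
    stopf("duplicate org_id in summaries: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "),
          class = "riskterms_validation_error")
  }
  summaries <- summaries[order(ids)]
  n <- length(summaries)
  factors <- lexicon_factors(lexicon)
  cat_map <- lexicon_category_map(lexicon)
  total_mat <- vapply(summaries, function(s) s$totals[factors],
                      numeric(length(factors)))
  total_mat <- matrix(total_mat, nrow = length(factors),
                      dimnames = list(factors, NULL))
  rows <- data.frame(
    factor_name = factors,
    category = unname(cat_map[factors]),
    n_orgs_mentioning = as.integer(rowSums(total_mat > 0)),
    pct_orgs_mentioning = percent_mentioning(rowSums(total_mat > 0), n),
    total_mentions = as.integer(rowSums(total_mat)),
    stringsAsFactors = FALSE
  )
  headline <- c(
    pct_general_env = percent_mentioning(
      sum(vapply(summaries, `[[`, logical(1), "mentions_any_general_env")), n),
    pct_specific_env = percent_mentioning(
      sum(vapply(summaries, `[[`, logical(1), "mentions_any_specific_env")), n),
    pct_other = percent_mentioning(
      sum(vapply(summaries, `[[`, logical(1), "mentions_any_other")), n)
  )
  defined <- vapply(summaries, `[[`, logical(1), "averages_defined")
  fig_points <- data.frame(
    org_id = vapply(summaries[defined], `[[`, character(1), "org_id"),
    scope = vapply(summaries[defined], `[[`, character(1), "scope"),
    env_avg_per_page = vapply(summaries[defined], `[[`, numeric(1),
                              "env_avg_per_page"),
    other_avg_per_page = vapply(summaries[defined], `[[`, numeric(1),
                                "other_avg_per_page"),
    stringsAsFactors = FALSE
  )
  structure(list(n_orgs = n, rows = rows, headline = headline,
                 fig_points = fig_points),
            class = "corpus_report")
}

#' @export
print.corpus_report <- function(x, ...) {
  cat(sprintf("<corpus_report>: %d organizations, %d factors\n",
              x$n_orgs, nrow(x$rows)))
  cat(sprintf("  headline: general env %d%%, specific env %d%%, other %d%%\n",
              x$headline[["pct_general_env"]],
              x$headline[["pct_specific_env"]],
              x$headline[["pct_other"]]))
  top <- x$rows[order(-x$rows$pct_orgs_mentioning,
                      x$rows$factor_name), , drop = FALSE]
  print(utils::head(top, 10), row.names = FALSE)
  if (nrow(top) > 10) cat(sprintf("  ... %d more rows\n", nrow(top) - 10))
  invisible(x)
}

#' Scatter of per-organization average mentions per page
#'
#' Plots each organization's average environmental mentions per kept page
#' against its average other-risk-factor mentions per page, with national
#' organizations as blue circles and local/regional organizations as
#' purple squares, and a dashed line of equal average usage. Organizations
#' specializing in environmental content fall on one side of the dashed
#' line; organizations focused on lifestyle/genetic content on the other.
#'
#' @param x A `corpus_report`.
#' @param ... Passed to [plot()].
#' @return Invisibly, the plotted points data frame.
#' @export
plot.corpus_report <- function(x, ...) {
  pts <- x$fig_points
  if (!nrow(pts)) {
    warning("no organizations with defined averages to plot")
    return(invisible(pts))
  }
  national <- pts$scope == "national"
  lim <- range(0, pts$env_avg_per_page, pts$other_avg_per_page)
  plot(pts$other_avg_per_page, pts$env_avg_per_page,
       pch = ifelse(national, 21, 22),
       bg = ifelse(national, "blue", "purple"),
       xlab = "Average mentions per page, other risk factors",
       ylab = "Average mentions per page, environmental factors",
       xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topright", pch = c(21, 22), pt.bg = c("blue", "purple"),
                   legend = c("national", "local/regional"), bty = "n")
  invisible(pts)
}

#' Per-factor mention totals for a single site
#'
#' The single-site view used for the deep dives into individual flagship
#' sites: total mentions per factor over the site's kept pages, ordered by
#' descending total with ties broken alphabetically by factor name.
#'
#' @param counts Long-format counts for the site's kept pages.
#' @param lexicon A `lexicon`.
#' @return A `site_report` data frame (`factor_name`, `category`,
#'   `total_mentions`).
#' @export
site_report <- function(counts, lexicon) {
  factors <- lexicon_factors(lexicon)
  cat_map <- lexicon_category_map(lexicon)
  totals <- stats::setNames(integer(length(factors)), factors)
  if (nrow(counts)) {
    agg <- tapply(counts$count, counts$factor_name, sum)
    totals[names(agg)] <- as.integer(agg)
  }
  out <- data.frame(factor_name = factors,
                    category = unname(cat_map[factors]),
                    total_mentions = unname(totals),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_mentions, out$factor_name), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("site_report", "data.frame"))
}
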