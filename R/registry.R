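#' Construct an organization record
#'
#' One row of the audit's organization registry: a stable identifier, one
#' or more homepage URLs (more than one models an organization whose main
#' site and campaign site are analyzed together), a geographic scope label,
#' and optional URL subsetting patterns (e.g. keep only URLs containing
#' "breast" for a general women's-health site).
#'
#' @param org_id Stable identifier.
#' @param name Display name (defaults to `org_id`).
#' @param homepages Character vector of homepage URLs (at least one).
#' @param scope `"national"` or `"local_regional"`.
#' @param include_patterns URL substrings; when non-empty, only URLs
#'   containing at least one are kept.
#' @param exclude_patterns URL substrings; matching URLs are dropped.
#' @param manual_url_excludes Exact URLs to drop (manual curation list).
#' @return An `org_record` object (a list).
#' @export
org_record <- function(org_id, name = org_id, homepages,
                       scope = c("national", "local_regional"),
                       include_patterns = character(0),
                       exclude_patterns = character(0),
                       manual_url_excludes = character(0)) {
  scope <- match.arg(scope)
  if (length(homepages) < 1) {
    stopf("org '%s' has no homepages", org_id,
          class = "riskterms_validation_error")
  }
  homepages <- vapply(homepages, canonicalize_url, character(1),
                      USE.NAMES = FALSE)
  manual_url_excludes <- vapply(manual_url_excludes, function(u) {
    tryCatch(canonicalize_url(u), error = function(e) u)
  }, character(1), USE.NAMES = FALSE)
  structure(list(org_id = org_id, name = name, homepages = homepages,
                 scope = scope, include_patterns = include_patterns,
                 exclude_patterns = exclude_patterns,
                 manual_url_excludes = manual_url_excludes),
            class = "org_record")
}

#' Read an organization registry from CSV
#'
#' Columns: `org_id`, `name`, `homepages` (pipe-separated), `scope`
#' (`national` or `local_regional`), and optional pipe-separated
#' `include_patterns`, `exclude_patterns`, `manual_url_excludes`.
#'
#' @param path Path to the registry CSV.
#' @return An `org_registry`: a named list of [org_record()] objects.
#' @export
read_org_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("org_id", "homepages", "scope")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("registry is missing column(s): %s",
          paste(missing, collapse = ", "),
          class = "riskterms_config_error")
  }
  if (anyDuplicated(df$org_id)) {
    stopf("duplicate org_id in registry: %s",
          paste(unique(df$org_id[duplicated(df$org_id)]), collapse = ", "),
          class = "riskterms_validation_error")
  }
  recs <- lapply(seq_len(nrow(df)), function(i) {
    org_record(
      org_id = df$org_id[i],
      name = if ("name" %in% names(df) && nzchar(df$name[i])) df$name[i]
             else df$org_id[i],
      homepages = split_pipes(df$homepages[i]),
      scope = df$scope[i],
      include_patterns = split_pipes(df$include_patterns[i] %||% ""),
      exclude_patterns = split_pipes(df$exclude_patterns[i] %||% ""),
      manual_url_excludes = split_pipes(df$manual_url_excludes[i] %||% "")
    )
  })
  structure(stats::setNames(recs, df$org_id), class = "org_registry")
}

#' Write an organization registry to CSV
#' @param registry An `org_registry` or list of `org_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_org_registry <- function(registry, path) {
  df <- do.call(rbind, lapply(registry, function(o) {
    data.frame(org_id = o$org_id, name = o$name,
               homepages = paste(o$homepages, collapse = "|"),
               scope = o$scope,
               include_patterns = paste(o$include_patterns, collapse = "|"),
               exclude_patterns = paste(o$exclude_patterns, collapse = "|"),
               manual_url_excludes = paste(o$manual_url_excludes,
                                           collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
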