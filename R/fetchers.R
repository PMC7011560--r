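# A fetcher is a function(url) returning a fetch result: a list with
# fields url, status (integer; 599 is the transport-failure sentinel),
# body (raw), charset (declared charset or NA), provenance, and
# snapshot_timestamp (Date or NULL). Fetchers are injected into the
# crawler so the pipeline runs identically against live sites, archive
# snapshots, or local fixture directories.

STATUS_TRANSPORT_FAILURE <- 599L

#' Construct a fetch result
#'
#' The value every fetcher returns for a URL. Custom fetchers (in-memory
#' page sets, test doubles, alternative archives) build their results with
#' this constructor.
#'
#' @param url Canonical URL fetched.
#' @param status Integer HTTP status; 599 is the transport-failure
#'   sentinel.
#' @param body Raw vector of body bytes.
#' @param charset Declared charset, or `NA`.
#' @param provenance `"live"`, `"archived"` or `"fixture"`.
#' @param snapshot_timestamp `Date` of the archived capture; required when
#'   `provenance = "archived"`.
#' @return A `fetch_result` list.
#' @export
fetch_result <- function(url, status, body = raw(0), charset = NA_character_,
                         provenance = c("live", "archived", "fixture"),
                         snapshot_timestamp = NULL) {
  provenance <- match.arg(provenance)
  if (provenance == "archived" && is.null(snapshot_timestamp)) {
    stopf("archived fetch result requires a snapshot_timestamp",
          class = "riskterms_validation_error")
  }
  structure(list(url = url, status = as.integer(status), body = body,
                 charset = charset, provenance = provenance,
                 snapshot_timestamp = snapshot_timestamp),
            class = "fetch_result")
}

fetch_ok <- function(fetch) !is.na(fetch$status) &&
  fetch$status >= 200L && fetch$status < 300L

#' Fixture fetcher over a local directory of HTML files
#'
#' Builds a fetcher that resolves URLs against an index file mapping
#' canonical URLs to files on disk (CSV with columns `url`, `path`; paths
#' relative to the fixture directory). URLs absent from the index get a 404
#' result, which the cleaning stage records as a broken link. Used for all
#' offline work, including the synthetic corpora.
#'
#' @param dir Fixture directory containing `index.csv` (or pass `index`).
#' @param index Optional data frame with columns `url`, `path`, overriding
#'   the on-disk index.
#' @return A fetcher function `function(url) -> fetch result`.
#' @seealso [generate_corpus()], [crawl_site()]
#' @export
fixture_fetcher <- function(dir, index = NULL) {
  if (is.null(index)) {
    index_path <- file.path(dir, "index.csv")
    if (!file.exists(index_path)) {
      stopf("fixture index not found: %s", index_path,
            class = "riskterms_config_error")
    }
    index <- utils::read.csv(index_path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("url", "path") %in% names(index)))
  lookup <- stats::setNames(as.character(index$path),
                            vapply(index$url, canonicalize_url, character(1)))
  force(dir)
  function(url) {
    cu <- canonicalize_url(url)
    path <- unname(lookup[cu])
    if (length(path) != 1 || is.na(path)) {
      return(fetch_result(cu, 404L, provenance = "fixture"))
    }
    full <- file.path(dir, path)
    if (!file.exists(full)) {
      return(fetch_result(cu, 404L, provenance = "fixture"))
    }
    body <- readBin(full, "raw", n = file.size(full))
    fetch_result(cu, 200L, body = body, charset = "UTF-8",
                 provenance = "fixture")
  }
}

#' Live HTTP fetcher (base R connections)
#'
#' A minimal polite live fetcher: honours `Disallow` rules for
#' `User-agent: *` in each host's robots.txt and sleeps `delay` seconds
#' between requests. Intended for interactive use against real sites; all
#' package tests run against fixture fetchers.
#'
#' @param delay Politeness delay in seconds between requests (default 1).
#' @param respect_robots Fetch and honour robots.txt (default TRUE).
#' @return A fetcher function.
#' @export
live_fetcher <- function(delay = 1, respect_robots = TRUE) {
  robots_cache <- new.env(parent = emptyenv())
  disallowed <- function(url) {
    if (!respect_robots) return(FALSE)
    p <- parse_url(url)
    key <- paste0(tolower(p$scheme), "://", tolower(p$server))
    rules <- robots_cache[[key]]
    if (is.null(rules)) {
      rules <- tryCatch({
        lines <- suppressWarnings(readLines(paste0(key, "/robots.txt"),
                                            warn = FALSE))
        parse_robots(lines)
      }, error = function(e) character(0))
      robots_cache[[key]] <- rules
    }
    path <- if (nzchar(p$path)) p$path else "/"
    any(vapply(rules, function(r) startsWith(path, r), logical(1)))
  }
  function(url) {
    cu <- canonicalize_url(url)
    if (disallowed(cu)) {
      return(fetch_result(cu, 403L, provenance = "live"))
    }
    Sys.sleep(delay)
    res <- tryCatch({
      con <- url(cu, open = "rb")
      on.exit(close(con), add = TRUE)
      chunks <- list()
      repeat {
        chunk <- readBin(con, "raw", n = 65536L)
        if (!length(chunk)) break
        chunks[[length(chunks) + 1L]] <- chunk
      }
      fetch_result(cu, 200L, body = do.call(c, c(chunks, list(raw(0)))),
                   provenance = "live")
    }, error = function(e) fetch_result(cu, STATUS_TRANSPORT_FAILURE,
                                        provenance = "live"))
    res
  }
}

# Disallow prefixes applying to User-agent: * (first matching group wins)
parse_robots <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  out <- character(0)
  in_star <- FALSE
  for (ln in lines) {
    if (grepl("^user-agent\\s*:", ln, ignore.case = TRUE)) {
      agent <- trimws(sub("^user-agent\\s*:", "", ln, ignore.case = TRUE))
      in_star <- agent == "*"
    } else if (in_star && grepl("^disallow\\s*:", ln, ignore.case = TRUE)) {
      path <- trimws(sub("^disallow\\s*:", "", ln, ignore.case = TRUE))
      if (nzchar(path)) out <- c(out, path)
    }
  }
  out
}

#' Fetch a page from a dated archive snapshot, falling back to live
#'
#' Retrieval policy for freezing website state at an analysis date: prefer
#' the archived capture nearest `target_date` within `window_days` days
#' either side; if the archive has none, fetch the URL live; if both fail,
#' return a failure-status result (never an exception) so that failures
#' stay visible as data in the cleaning report.
#'
#' @param url URL to retrieve.
#' @param target_date `Date`; the analysis date to freeze content at.
#' @param archive_client Function `(url, target_date, window_days)`
#'   returning `NULL` or a list with `timestamp` (Date), `body` (raw) and
#'   optionally `charset`. See [wayback_client()].
#' @param live_fetcher A fetcher used as fallback.
#' @param window_days Half-width of the acceptable capture window
#'   (default 45 days).
#' @return A fetch result with `provenance` set to `"archived"` or
#'   `"live"`; on total failure a result whose status is the transport
#'   failure sentinel.
#' @export
snapshot_fetch <- function(url, target_date, archive_client, live_fetcher,
                           window_days = 45L) {
  cu <- canonicalize_url(url)
  snap <- tryCatch(archive_client(cu, target_date, window_days),
                   error = function(e) NULL)
  if (!is.null(snap) &&
      abs(as.numeric(snap$timestamp - target_date)) <= window_days) {
    return(fetch_result(cu, 200L, body = snap$body,
                        charset = snap$charset %||% NA_character_,
                        provenance = "archived",
                        snapshot_timestamp = snap$timestamp))
  }
  live <- tryCatch(live_fetcher(cu),
                   error = function(e) fetch_result(cu,
                                                    STATUS_TRANSPORT_FAILURE,
                                                    provenance = "live"))
  live
}

#' Internet Archive availability client
#'
#' Thin client for the Wayback Machine availability API, usable as the
#' `archive_client` argument of [snapshot_fetch()]. Requires network
#' access; offline workflows (and the whole test suite) use mock clients
#' or fixture fetchers instead.
#'
#' @return A function `(url, target_date, window_days)` returning `NULL` or
#'   a snapshot list (`timestamp`, `body`, `charset`).
#' @export
wayback_client <- function() {
  function(url, target_date, window_days) {
    stamp <- format(target_date, "%Y%m%d")
    api <- paste0("https://archive.org/wayback/available?url=",
                  utils::URLencode(url, reserved = TRUE),
                  "&timestamp=", stamp)
    info <- tryCatch(jsonlite::fromJSON(api), error = function(e) NULL)
    snap <- info$archived_snapshots$closest
    if (is.null(snap) || !isTRUE(snap$available)) return(NULL)
    ts <- as.Date(substr(snap$timestamp, 1, 8), format = "%Y%m%d")
    if (is.na(ts) || abs(as.numeric(ts - target_date)) > window_days) {
      return(NULL)
    }
    body <- tryCatch({
      con <- url(snap$url, open = "rb")
      on.exit(close(con), add = TRUE)
      readBin(con, "raw", n = 50e6)
    }, error = function(e) NULL)
    if (is.null(body)) return(NULL)
    list(timestamp = ts, body = body, charset = NA_character_)
  }
}
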