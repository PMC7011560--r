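#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "riskterms_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All seeded randomness in the package (notably the synthetic-site
#' generator) runs through this helper so that generating fixtures never
#' perturbs the RNG stream of the calling session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

# split a pipe-separated registry field into a character vector; "" -> none
split_pipes <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

# tokens = maximal runs of letters/digits; returns token strings with
# character start/end offsets (the matcher needs the inter-token gaps)
tokenize <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(token = substring(text, start, start + len - 1L),
             start = start, end = start + len - 1L, stringsAsFactors = FALSE)
}
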