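# Terms that the audit deliberately does not count when they stand alone:
# they occur on cancer websites in contexts unrelated to environmental
# exposure (e.g. "chemical" in a discussion of chemotherapy, "toxic" for
# treatment side effects, "hormone therapy" as a treatment).
EXCLUDED_STANDALONE_TERMS <- c("environment", "toxic", "chemical",
                               "hormone therapy")

LEXICON_CATEGORIES <- c("general_environmental", "specific_environmental",
                        "other")

#' Build the default risk-factor lexicon
#'
#' Returns the categorized vocabulary of 23 breast cancer risk-factor term
#' groups used by the website audit: three-way categories (general
#' environmental, specific environmental, other), with "(s)" notation
#' expanded to explicit singular and plural variants and all-caps acronyms
#' (BPA, HRT, DES, PAH/PAHs, PFOA, PFOS, PFAS, PFC/PFCs, gene symbols)
#' flagged for case-sensitive matching.
#'
#' The printed vocabulary expands to 52 variants. Three supplemental
#' variants are carried in addition, marked `supplemental = TRUE`: the
#' standard gene symbols BRCA1/BRCA2 alongside the printed spellings
#' BRAC1/BRAC2, and the spelled-out phrase "hormone replacement therapy"
#' alongside its acronym HRT. Ambiguous standalone terms ("environment",
#' "toxic", "chemical", "hormone therapy") are deliberately absent; the
#' multi-word phrases that contain those tokens (e.g. "endocrine disrupting
#' chemicals") are retained, because the exclusion applies to the bare
#' terms, not to tokens inside longer phrases.
#'
#' @return A `lexicon` object: a data frame with one row per variant and
#'   columns `factor_name`, `category`, `variant`, `acronym`,
#'   `supplemental`.
#' @seealso [read_lexicon()], [lexicon_summary()], [count_page()]
#' @examples
#' lex <- default_lexicon()
#' lexicon_summary(lex)
#' @export
default_lexicon <- function() {
  g <- function(factor_name, category, variants, acronyms = character(0),
                supplemental = character(0)) {
    data.frame(factor_name = factor_name, category = category,
               variant = variants,
               acronym = variants %in% acronyms,
               supplemental = variants %in% supplemental,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    g("Exercise", "other",
      c("exercise", "physical activity", "physically active")),
    g("Family history", "other", "family history"),
    g("Diet", "other", "diet"),
    g("Genetics", "other",
      c("genetics", "BRAC1", "BRAC2", "BRCA1", "BRCA2"),
      acronyms = c("BRAC1", "BRAC2", "BRCA1", "BRCA2"),
      supplemental = c("BRCA1", "BRCA2")),
    g("Alcohol", "other", "alcohol"),
    g("Breast density", "other", c("breast density", "dense breasts")),
    g("Body weight", "other", c("overweight", "obese")),
    g("Hormone replacement therapy", "other",
      c("HRT", "hormone replacement therapy"),
      acronyms = "HRT",
      supplemental = "hormone replacement therapy"),
    g("Pesticides", "specific_environmental", c("pesticide", "pesticides")),
    g("Bisphenols", "specific_environmental",
      c("BPA", "bisphenol", "bisphenols"), acronyms = "BPA"),
    g("Contamination", "general_environmental",
      c("contaminant", "contaminants", "contamination")),
    g("Pollution", "general_environmental",
      c("pollution", "pollutant", "pollutants")),
    g("Birth control", "other", c("birth control", "oral contraceptives")),
    g("Parabens", "specific_environmental", c("paraben", "parabens")),
    g("Endocrine disrupting chemicals", "specific_environmental",
      c("endocrine disruptor", "endocrine disruptors",
        "endocrine disrupting chemical", "endocrine disrupting chemicals",
        "hormone disrupting chemical", "hormone disrupting chemicals")),
    g("Phthalates", "specific_environmental", c("phthalate", "phthalates")),
    g("Diethylstilbestrol", "other", c("diethylstilbestrol", "DES"),
      acronyms = "DES"),
    g("The precautionary principle", "general_environmental",
      "precautionary principle"),
    g("Flame retardants", "specific_environmental",
      c("flame retardant", "flame retardants")),
    g("Air pollution", "specific_environmental", "air pollution"),
    g("Polycyclic aromatic hydrocarbons", "specific_environmental",
      c("PAH", "PAHs"), acronyms = c("PAH", "PAHs")),
    g("PFAS", "specific_environmental",
      c("PFOA", "PFOS", "PFAS", "PFC", "PFCs", "perfluorinated chemicals"),
      acronyms = c("PFOA", "PFOS", "PFAS", "PFC", "PFCs")),
    g("Oxybenzone", "specific_environmental", "oxybenzone")
  )
  new_lexicon(rows, version_tag = "default-2018-audit")
}

#' Construct and validate a lexicon
#'
#' @param rows Data frame with columns `factor_name`, `category`, `variant`,
#'   and optionally `acronym` (logical) and `supplemental` (logical).
#' @param version_tag Free-text tag recorded on the object.
#' @return A validated `lexicon` object.
#' @export
new_lexicon <- function(rows, version_tag = "custom") {
  required <- c("factor_name", "category", "variant")
  missing <- setdiff(required, names(rows))
  if (length(missing)) {
    stopf("lexicon is missing column(s): %s", paste(missing, collapse = ", "),
          class = "riskterms_config_error")
  }
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (is.null(rows$acronym)) rows$acronym <- FALSE
  if (is.null(rows$supplemental)) rows$supplemental <- FALSE
  rows$acronym <- as.logical(rows$acronym)
  rows$supplemental <- as.logical(rows$supplemental)
  rows <- rows[, c("factor_name", "category", "variant", "acronym",
                   "supplemental")]
  validate_lexicon_rows(rows)
  structure(rows, class = c("lexicon", "data.frame"),
            version_tag = version_tag)
}

validate_lexicon_rows <- function(rows) {
  if (nrow(rows) == 0) {
    stopf("lexicon has no term groups", class = "riskterms_config_error")
  }
  if (any(is.na(rows$variant)) || any(!nzchar(trimws(rows$variant)))) {
    stopf("lexicon contains an empty variant",
          class = "riskterms_validation_error")
  }
  bad_cat <- setdiff(unique(rows$category), LEXICON_CATEGORIES)
  if (length(bad_cat)) {
    stopf("unknown lexicon category: %s (must be one of %s)",
          paste(bad_cat, collapse = ", "),
          paste(LEXICON_CATEGORIES, collapse = ", "),
          class = "riskterms_config_error")
  }
  # one category per factor
  cats <- tapply(rows$category, rows$factor_name,
                 function(x) length(unique(x)))
  if (any(cats > 1)) {
    stopf("factor(s) assigned more than one category: %s",
          paste(names(cats)[cats > 1], collapse = ", "),
          class = "riskterms_validation_error")
  }
  key <- paste(rows$factor_name, tolower(rows$variant), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- rows$variant[duplicated(key)]
    stopf("duplicate (factor, variant) pair(s): %s",
          paste(unique(dup), collapse = ", "),
          class = "riskterms_validation_error")
  }
  banned <- tolower(trimws(rows$variant)) %in% EXCLUDED_STANDALONE_TERMS
  if (any(banned)) {
    stopf("variant(s) equal an excluded ambiguous standalone term: %s",
          paste(unique(rows$variant[banned]), collapse = ", "),
          class = "riskterms_validation_error")
  }
  invisible(rows)
}

#' @export
print.lexicon <- function(x, ...) {
  s <- lexicon_summary(x)
  cat(sprintf("<lexicon '%s'>: %d term groups, %d variants (%d printed core)\n",
              attr(x, "version_tag") %||% "?", s$n_groups, s$n_variants,
              s$n_core_variants))
  cat("  categories:",
      paste(sprintf("%s=%d", names(s$groups_by_category),
                    s$groups_by_category), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a lexicon
#'
#' Reports group and variant counts, overall and per category. The variant
#' count is reported both in total and restricted to the core (non
#' supplemental) vocabulary, which for the default lexicon is the 52-term
#' printed list.
#'
#' @param lexicon A `lexicon` object.
#' @return A list with `n_groups`, `n_variants`, `n_core_variants`,
#'   `groups_by_category` and `variants_by_category`.
#' @export
lexicon_summary <- function(lexicon) {
  stopifnot(inherits(lexicon, "lexicon"))
  groups <- unique(lexicon[, c("factor_name", "category")])
  list(
    n_groups = nrow(groups),
    n_variants = nrow(lexicon),
    n_core_variants = sum(!lexicon$supplemental),
    groups_by_category = table(factor(groups$category,
                                      levels = LEXICON_CATEGORIES)),
    variants_by_category = table(factor(lexicon$category,
                                        levels = LEXICON_CATEGORIES))
  )
}

#' Names of the factor groups in a lexicon, in lexicon order
#' @param lexicon A `lexicon` object.
#' @return Character vector of factor names.
#' @export
lexicon_factors <- function(lexicon) {
  unique(lexicon$factor_name)
}

# named vector factor_name -> category
lexicon_category_map <- function(lexicon) {
  groups <- unique(lexicon[, c("factor_name", "category")])
  stats::setNames(groups$category, groups$factor_name)
}

#' Read a lexicon from a CSV file
#'
#' The file format is one variant per row with columns `factor_name`,
#' `category`, `variant`, `acronym_flag` (0/1 or TRUE/FALSE) and optionally
#' `supplemental`. All lexicon invariants are enforced: no empty variants,
#' no excluded standalone terms, unique (factor, variant) pairs, a single
#' category per factor.
#'
#' @param path Path to the CSV file.
#' @return A `lexicon` object.
#' @export
read_lexicon <- function(path) {
  rows <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stopf("cannot parse lexicon file '%s': %s", path, conditionMessage(e),
            class = "riskterms_config_error")
    }
  )
  if ("acronym_flag" %in% names(rows) && is.null(rows$acronym)) {
    rows$acronym <- as.logical(rows$acronym_flag)
    rows$acronym_flag <- NULL
  }
  new_lexicon(rows, version_tag = basename(path))
}

#' Write a lexicon to a CSV file
#'
#' @param lexicon A `lexicon` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "lexicon"))
  out <- as.data.frame(lexicon)
  names(out)[names(out) == "acronym"] <- "acronym_flag"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
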