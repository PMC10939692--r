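#' @title GWAS summary-statistic input
#' @description Readers and validators for per-SNP association records: one
#'   row per variant with its identifier, alleles, effect-allele frequency,
#'   additive effect estimate, standard error, P-value and sample size.
#' @name summary-data
NULL

# canonical column set; only the first four are mandatory on input
MR_COLUMNS <- c(
  "rsid", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)
MR_REQUIRED <- c("rsid", "beta", "se", "pvalue")
MR_NUMERIC <- c("pos", "eaf", "beta", "se", "pvalue", "n")

# Tolerant numeric parser for published tables: accepts unicode minus
# (U+2212), thousands separators ("293,723") and bare leading decimal
# points (".0034"). Returns NA for anything else non-numeric.
parse_mr_number <- function(x) {
  if (is.numeric(x)) {
    return(as.double(x))
  }
  x <- trimws(as.character(x))
  x <- gsub("−", "-", x)
  x <- gsub(",", "", x, fixed = TRUE)
  x[!nzchar(x)] <- NA_character_
  suppressWarnings(as.double(x))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file (delimiter auto-detected from the
#' header line) into a tibble with the canonical columns `rsid`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`,
#' `n`. Files whose headers use other names are mapped through `column_map`.
#' Numeric fields are parsed tolerantly (unicode minus, thousands
#' separators); rows with unparseable mandatory numerics are dropped with a
#' warning that reports their row indices.
#'
#' `rsid`, `beta`, `se` and `pvalue` are mandatory; the remaining columns
#' are optional and filled with `NA` when absent (alleles are only needed
#' for [harmonize()], `eaf`/`n` only for [instrument_strength()]).
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(rsid = "SNP", beta = "Effect")`. Unmapped
#'   canonical names are looked up verbatim.
#' @return A tibble of validated summary records.
#' @examples
#' edu <- read_summary_stats(mr_extdata("education_gwas.tsv"))
#' nrow(edu)
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("summary-statistics file not found: '%s'", path))
  }
  header <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )

  name_for <- function(canon) {
    mapped <- if (!is.null(column_map) && canon %in% names(column_map)) {
      column_map[[canon]]
    } else {
      canon
    }
    if (mapped %in% names(raw)) mapped else NA_character_
  }
  found <- vapply(MR_COLUMNS, name_for, character(1))
  missing_req <- MR_REQUIRED[is.na(found[MR_REQUIRED])]
  if (length(missing_req) > 0) {
    abort(sprintf(
      "mandatory column(s) missing from '%s': %s",
      path, paste(missing_req, collapse = ", ")
    ), class = "tidymr_config_error")
  }

  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in MR_COLUMNS) {
    col <- if (is.na(found[[canon]])) rep(NA_character_, nrow(raw)) else raw[[found[[canon]]]]
    out[[canon]] <- if (canon %in% MR_NUMERIC) parse_mr_number(col) else as.character(col)
  }
  out$effect_allele <- toupper(out$effect_allele)
  out$other_allele <- toupper(out$other_allele)

  # reject rows whose mandatory numerics failed to parse
  present_req <- intersect(MR_REQUIRED, MR_NUMERIC)
  bad <- rowSums(is.na(out[present_req])) > 0
  if (any(bad)) {
    warn(sprintf(
      "dropped %d row(s) with unparseable numeric fields (row index: %s)",
      sum(bad), paste(which(bad), collapse = ", ")
    ))
    out <- out[!bad, ]
  }
  validate_summary_stats(out)
}

#' Validate a summary-statistics tibble
#'
#' Checks the per-record invariants: positive standard errors, P-values in
#' (0, 1], allele frequencies in (0, 1), single-nucleotide alleles drawn
#' from A/C/G/T with effect and other allele distinct. Violations are
#' errors naming the offending rsid; optional fields may be `NA`.
#'
#' @param records A tibble with the canonical summary-statistic columns.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_summary_stats <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(MR_REQUIRED, names(records))
  if (length(missing) > 0) {
    abort(sprintf("mandatory column(s) missing: %s", paste(missing, collapse = ", ")),
      class = "tidymr_config_error"
    )
  }
  for (canon in setdiff(MR_COLUMNS, names(records))) {
    records[[canon]] <- if (canon %in% MR_NUMERIC) NA_real_ else NA_character_
  }
  records <- records[MR_COLUMNS]

  fail <- function(cond, what) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      abort(sprintf(
        "%s for rsid(s): %s", what,
        paste(records$rsid[cond], collapse = ", ")
      ), class = "tidymr_validation_error")
    }
  }
  fail(records$se <= 0, "standard error must be > 0")
  fail(records$pvalue <= 0 | records$pvalue > 1, "P-value must be in (0, 1]")
  fail(records$eaf <= 0 | records$eaf >= 1, "effect-allele frequency must be in (0, 1)")
  fail(records$n <= 0, "sample size must be positive")
  ok_allele <- function(a) is.na(a) | a %in% c("A", "C", "G", "T")
  fail(!ok_allele(records$effect_allele), "effect allele must be one of A/C/G/T")
  fail(!ok_allele(records$other_allele), "other allele must be one of A/C/G/T")
  fail(
    !is.na(records$effect_allele) & !is.na(records$other_allele) &
      records$effect_allele == records$other_allele,
    "effect and other allele must differ"
  )
  records
}

#' Select genome-wide-significant instruments
#'
#' Retains the records whose association P-value falls strictly below the
#' significance threshold, preserving input order. The default threshold is
#' the conventional genome-wide significance level 5e-8.
#'
#' @param records A summary-statistics tibble (see [read_summary_stats()]).
#' @param p_threshold Significance level in (0, 1); records with
#'   `pvalue < p_threshold` are kept.
#' @return The filtered tibble (possibly empty).
#' @examples
#' edu <- read_summary_stats(mr_extdata("education_gwas.tsv"))
#' nrow(filter_instruments(edu, 5e-8))
#' @export
filter_instruments <- function(records, p_threshold = 5e-8) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
    is.na(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    abort("p_threshold must be a single number in (0, 1]")
  }
  dplyr::filter(tibble::as_tibble(records), .data$pvalue < p_threshold)
}
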