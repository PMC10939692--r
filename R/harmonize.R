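#' @title Allele harmonization
#' @description Aligning exposure and outcome effect estimates to the same
#'   effect allele before any causal estimation. Strand flips are resolved
#'   by nucleotide complement; palindromic (A/T, C/G) variants whose
#'   frequency is too close to 0.5 are ambiguous and dropped.
#' @name harmonize
NULL

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) !is.na(ea) & !is.na(oa) & COMPLEMENT[ea] == oa

new_instrument_set <- function(df, exposure_name, outcome_name, drops = NULL) {
  df <- tibble::as_tibble(df)[, c("rsid", "beta_exp", "se_exp", "beta_out", "se_out")]
  if (nrow(df) < 1) {
    abort("no usable instruments", class = "tidymr_validation_error")
  }
  if (anyDuplicated(df$rsid)) {
    abort("rsIDs must be unique within an instrument set",
      class = "tidymr_validation_error"
    )
  }
  if (any(df$se_exp <= 0) || any(df$se_out <= 0)) {
    abort("instrument standard errors must be > 0", class = "tidymr_validation_error")
  }
  structure(df,
    class = c("instrument_set", class(df)),
    exposure_name = exposure_name, outcome_name = outcome_name,
    drops = drops %||% tibble::tibble(rsid = character(), reason = character())
  )
}

#' Coerce a data frame to an instrument set
#'
#' An instrument set is a tibble of harmonized per-SNP effects with columns
#' `rsid`, `beta_exp`, `se_exp`, `beta_out`, `se_out` — both betas refer to
#' the same effect allele — plus exposure/outcome labels carried as
#' attributes. All estimators in the package consume this shape.
#'
#' @param df Data frame with the five instrument columns.
#' @param exposure_name,outcome_name Trait labels.
#' @return An `instrument_set` tibble.
#' @export
as_instrument_set <- function(df, exposure_name = "exposure", outcome_name = "outcome") {
  need <- c("rsid", "beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("instrument set lacks column(s): %s", paste(missing, collapse = ", ")),
      class = "tidymr_config_error"
    )
  }
  new_instrument_set(df, exposure_name, outcome_name)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "# Instrument set: %s -> %s (%d SNPs, %d dropped)\n",
    attr(x, "exposure_name"), attr(x, "outcome_name"),
    nrow(x), nrow(attr(x, "drops"))
  ))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' SNPs dropped during harmonization
#'
#' @param set An `instrument_set` built by [harmonize()].
#' @return A tibble with columns `rsid` and `reason` (`missing`,
#'   `palindromic` or `irreconcilable`).
#' @export
instrument_drops <- function(set) {
  attr(set, "drops") %||% tibble::tibble(rsid = character(), reason = character())
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects two summary-statistics tables by rsid and aligns the outcome
#' effect to the exposure's effect allele:
#'
#' * identical allele coding passes through unchanged;
#' * swapped effect/other alleles flip the sign of the outcome beta and
#'   complement its frequency;
#' * strand-flipped alleles are complemented and then matched as above;
#' * palindromic variants (A/T or C/G) within `palindromic_eaf_window` of
#'   frequency 0.5 cannot be oriented and are dropped; outside the window
#'   they are oriented by allele match, corrected by frequency concordance
#'   when frequencies are available on both sides;
#' * variants missing from the outcome, or with irreconcilable alleles, are
#'   dropped with a warning.
#'
#' Every drop is recorded with its reason (retrievable via
#' [instrument_drops()]) and reported as a message.
#'
#' @param exposure,outcome Summary-statistics tibbles (see
#'   [read_summary_stats()]); both must carry `effect_allele` and
#'   `other_allele`.
#' @param palindromic_eaf_window Half-width of the ambiguity window around
#'   frequency 0.5 for palindromic SNPs (default 0.08, i.e. drop when
#'   `min(eaf, 1 - eaf) > 0.42`).
#' @param exposure_name,outcome_name Trait labels for the resulting set.
#' @return An `instrument_set` tibble satisfying the shared-effect-allele
#'   sign convention.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08,
                      exposure_name = "exposure", outcome_name = "outcome") {
  exposure <- validate_summary_stats(exposure)
  outcome <- validate_summary_stats(outcome)
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    abort("both exposure and outcome must be nonempty")
  }
  if (any(is.na(exposure$effect_allele)) || any(is.na(exposure$other_allele)) ||
    any(is.na(outcome$effect_allele)) || any(is.na(outcome$other_allele))) {
    abort("harmonization requires effect_allele and other_allele on both sides",
      class = "tidymr_config_error"
    )
  }

  out_idx <- match(exposure$rsid, outcome$rsid)
  drops <- tibble::tibble(rsid = character(), reason = character())
  note_drop <- function(rsid, reason) {
    drops <<- dplyr::bind_rows(drops, tibble::tibble(rsid = rsid, reason = reason))
  }
  rows <- vector("list", nrow(exposure))

  for (i in seq_len(nrow(exposure))) {
    e <- exposure[i, ]
    if (is.na(out_idx[i])) {
      note_drop(e$rsid, "missing")
      next
    }
    o <- outcome[out_idx[i], ]
    ea <- e$effect_allele
    oa <- e$other_allele
    o_ea <- o$effect_allele
    o_oa <- o$other_allele

    if (is_palindromic(ea, oa)) {
      eaf_ref <- if (!is.na(o$eaf)) o$eaf else e$eaf
      if (is.na(eaf_ref) || abs(eaf_ref - 0.5) < palindromic_eaf_window) {
        note_drop(e$rsid, "palindromic")
        next
      }
      # same two letters in either order; orient by letters, then check
      # frequency concordance (strand flip reverses the frequency side)
      if (identical(c(o_ea, o_oa), c(ea, oa))) {
        flip <- FALSE
      } else if (identical(c(o_ea, o_oa), c(oa, ea))) {
        flip <- TRUE
      } else {
        note_drop(e$rsid, "irreconcilable")
        next
      }
      if (!is.na(e$eaf) && !is.na(o$eaf)) {
        eaf_aligned <- if (flip) 1 - o$eaf else o$eaf
        if ((e$eaf - 0.5) * (eaf_aligned - 0.5) < 0) flip <- !flip
      }
    } else {
      if (identical(c(o_ea, o_oa), c(ea, oa))) {
        flip <- FALSE
      } else if (identical(c(o_ea, o_oa), c(oa, ea))) {
        flip <- TRUE
      } else {
        c_ea <- unname(COMPLEMENT[o_ea])
        c_oa <- unname(COMPLEMENT[o_oa])
        if (identical(c(c_ea, c_oa), c(ea, oa))) {
          flip <- FALSE
        } else if (identical(c(c_ea, c_oa), c(oa, ea))) {
          flip <- TRUE
        } else {
          note_drop(e$rsid, "irreconcilable")
          next
        }
      }
    }
    rows[[i]] <- tibble::tibble(
      rsid = e$rsid,
      beta_exp = e$beta, se_exp = e$se,
      beta_out = if (flip) -o$beta else o$beta, se_out = o$se
    )
  }

  if (nrow(drops) > 0) {
    tab <- table(drops$reason)
    warn(sprintf(
      "harmonization dropped %d SNP(s): %s", nrow(drops),
      paste(sprintf("%s (%s)", names(tab), tab), collapse = ", ")
    ))
    for (j in seq_len(nrow(drops))) {
      inform(sprintf("  dropped %s: %s", drops$rsid[j], drops$reason[j]))
    }
  }
  kept <- dplyr::bind_rows(rows)
  if (nrow(kept) == 0) {
    abort("no usable instruments", class = "tidymr_validation_error")
  }
  new_instrument_set(kept, exposure_name, outcome_name, drops)
}

#' Write an instrument set to tab-delimited text
#'
#' Writes the five instrument columns with numeric fields at 10 significant
#' digits so that [read_instrument_set()] round-trips the set exactly.
#'
#' @param set An `instrument_set` (or coercible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instrument_set <- function(set, path) {
  set <- as_instrument_set(set,
    exposure_name = attr(set, "exposure_name") %||% "exposure",
    outcome_name = attr(set, "outcome_name") %||% "outcome"
  )
  num <- function(x) sprintf("%.10g", x)
  lines <- c(
    "rsid\tbeta_exp\tse_exp\tbeta_out\tse_out",
    sprintf(
      "%s\t%s\t%s\t%s\t%s", set$rsid,
      num(set$beta_exp), num(set$se_exp), num(set$beta_out), num(set$se_out)
    )
  )
  tryCatch(
    writeLines(lines, path, useBytes = TRUE),
    error = function(e) abort(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Read an instrument set written in the 5-column harmonized format
#'
#' @param path Path to a tab- or comma-delimited file with columns `rsid`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @param exposure_name,outcome_name Trait labels for the resulting set.
#' @return An `instrument_set` tibble.
#' @export
read_instrument_set <- function(path, exposure_name = "exposure",
                                outcome_name = "outcome") {
  if (!file.exists(path)) {
    abort(sprintf("instrument-set file not found: '%s'", path))
  }
  header <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  need <- c("rsid", "beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(sprintf(
      "instrument-set file lacks column(s): %s",
      paste(missing, collapse = ", ")
    ), class = "tidymr_config_error")
  }
  df <- tibble::tibble(rsid = as.character(raw$rsid))
  for (col in need[-1]) df[[col]] <- parse_mr_number(raw[[col]])
  as_instrument_set(df, exposure_name, outcome_name)
}

# TRUE when a file's header already matches the harmonized 5-column format
is_harmonized_file <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "[\t,]")[[1]]
  all(c("rsid", "beta_exp", "se_exp", "beta_out", "se_out") %in% trimws(header))
}
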