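#' @title Heterogeneity and instrument-strength diagnostics
#' @description Cochran's Q and I-squared across per-SNP Wald ratios, and
#'   per-instrument strength: variance in the exposure explained by the
#'   variant and the corresponding F-statistic (F < 10 conventionally
#'   flags a weak instrument).
#' @name diagnostics
NULL

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (r_j - center)^2)` over per-SNP Wald ratios, with an
#' upper-tail chi-square P-value at `df` degrees of freedom and
#' `I^2 = max(0, (Q - df) / Q) * 100` (0 when Q = 0). Centred at the IVW
#' estimate with `df = n - 1`, Q is the usual meta-analytic heterogeneity
#' test; Q is minimized over all centers at exactly the IVW estimate.
#'
#' @param ratios A tibble of Wald ratios as produced by [wald_ratios()]
#'   (columns `ratio` and `weight`).
#' @param center The causal estimate the ratios are measured about.
#' @param df Degrees of freedom (>= 1); `n - 1` for IVW, `n - 2` for the
#'   Egger residual Q.
#' @return A one-row tibble with columns `q`, `df`, `p.value`,
#'   `i.squared`.
#' @examples
#' fn <- read_instrument_set(mr_extdata("fn_bmd.tsv"))
#' fit <- mr_ivw(fn)
#' cochran_q(wald_ratios(fn), center = tidy(fit)$estimate, df = 6)
#' @export
cochran_q <- function(ratios, center, df) {
  if (nrow(ratios) == 0) abort("ratios must be nonempty")
  if (df < 1) abort("degrees of freedom must be >= 1")
  q <- sum(ratios$weight * (ratios$ratio - center)^2)
  tibble::tibble(
    q = q, df = df,
    p.value = pchisq(q, df, lower.tail = FALSE),
    i.squared = if (q > 0) max(0, (q - df) / q) * 100 else 0
  )
}

#' Variance in the exposure explained per variant
#'
#' For a standardized trait, a variant with effect-allele frequency `p`
#' and per-allele effect `beta` explains `r2 = 2 p (1 - p) beta^2` of the
#' trait variance.
#'
#' @param records A summary-statistics tibble with `eaf` and `beta`.
#' @return The tibble with an added `r2` column.
#' @export
variance_explained <- function(records) {
  records <- tibble::as_tibble(records)
  if (any(is.na(records$eaf) | records$eaf <= 0 | records$eaf >= 1)) {
    abort("variance_explained requires eaf in (0, 1) for every record")
  }
  dplyr::mutate(records, r2 = 2 * .data$eaf * (1 - .data$eaf) * .data$beta^2)
}

#' Instrument-strength F-statistic
#'
#' `F = r2 * (n - 2) / (1 - r2)` where `r2` is the variance in the
#' exposure explained by the variant and `n` the exposure GWAS sample
#' size. Values below 10 conventionally indicate a weak instrument.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n Sample size (> 2).
#' @return F value(s), at full precision.
#' @examples
#' f_statistic(1.08e-4, 293723)
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) abort("r2 must be in [0, 1)")
  if (any(n <= 2)) abort("sample size must exceed 2")
  r2 * (n - 2) / (1 - r2)
}

#' Per-instrument strength table
#'
#' Combines [variance_explained()] and [f_statistic()] into one
#' diagnostic table and warns when any instrument is weak (F < 10).
#'
#' @param records A summary-statistics tibble with `eaf`, `beta` and `n`.
#' @return A tibble with columns `rsid`, `r2`, `f_stat`, `weak`.
#' @examples
#' edu <- read_summary_stats(mr_extdata("education_gwas.tsv"))
#' instrument_strength(edu)
#' @export
instrument_strength <- function(records) {
  records <- variance_explained(records)
  if (any(is.na(records$n))) {
    abort("instrument_strength requires a sample size (n) for every record")
  }
  out <- tibble::tibble(
    rsid = records$rsid, r2 = records$r2,
    f_stat = f_statistic(records$r2, records$n)
  )
  out$weak <- out$f_stat < 10
  if (any(out$weak)) {
    warn(sprintf(
      "weak instrument(s) (F < 10): %s",
      paste(out$rsid[out$weak], collapse = ", ")
    ))
  }
  out
}
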