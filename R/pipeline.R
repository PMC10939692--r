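#' @title Analysis pipeline
#' @description One exposure, many outcomes: filter instruments, harmonize
#'   (or accept pre-harmonized instrument files), run IVW, weighted median
#'   and MR-Egger with heterogeneity diagnostics, and emit a
#'   machine-readable results table plus per-outcome forest-plot data.
#' @name pipeline
NULL

result_columns <- c(
  "outcome", "n_snps",
  "ivw_estimate", "ivw_se", "ivw_ci_low", "ivw_ci_high", "ivw_p",
  "q", "q_df", "q_p", "i_squared",
  "wm_estimate", "wm_se", "wm_ci_low", "wm_ci_high", "wm_p",
  "egger_estimate", "egger_se", "egger_ci_low", "egger_ci_high", "egger_p",
  "egger_intercept", "egger_intercept_se", "egger_intercept_ci_low",
  "egger_intercept_ci_high", "egger_intercept_p"
)

flat <- function(prefix, row) {
  out <- list(row$estimate, row$std.error, row$conf.low, row$conf.high, row$p.value)
  suffixes <- if (prefix == "egger_intercept") {
    c("", "_se", "_ci_low", "_ci_high", "_p")
  } else {
    c("_estimate", "_se", "_ci_low", "_ci_high", "_p")
  }
  names(out) <- paste0(prefix, suffixes)
  out
}

resolve_input <- function(x, what) {
  if (is.character(x) && length(x) == 1) {
    if (is_harmonized_file(x)) read_instrument_set(x) else read_summary_stats(x)
  } else if (is.data.frame(x)) {
    x
  } else {
    abort(sprintf("%s must be a data frame or a file path", what))
  }
}

#' Run the full Mendelian randomization analysis
#'
#' For each outcome: build the harmonized instrument set (from full
#' summary statistics via [harmonize()], or directly when the outcome is
#' already in the 5-column harmonized format), then compute the IVW
#' estimate with Cochran's Q, the weighted median and MR-Egger. Outcomes
#' with fewer than 3 surviving instruments get an IVW-only row with a
#' warning. The run is deterministic given the seed: outcome `i` uses
#' bootstrap seed `seed + i - 1`.
#'
#' @param exposure Exposure summary statistics: a tibble or a file path.
#' @param outcomes Named list of outcomes, each a tibble or file path —
#'   either full summary statistics or the 5-column harmonized format.
#' @param p_threshold Instrument significance threshold (default 5e-8).
#' @param model IVW effects model: `"auto"`, `"fixed"` or `"random"`.
#' @param n_boot Weighted-median bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap; required when `n_boot > 0`.
#' @param palindromic_eaf_window Passed to [harmonize()].
#' @param exposure_name Exposure label for logs and plots.
#' @return An `mr_results` tibble, one row per outcome with flattened
#'   estimate columns plus heterogeneity; the fitted objects and
#'   instrument sets ride along in the `"fits"` attribute and feed
#'   [render_results()], [tidy()] and [autoplot()].
#' @examples
#' res <- run_mr(
#'   read_summary_stats(mr_extdata("education_gwas.tsv")),
#'   outcomes = list("FN-BMD" = mr_extdata("fn_bmd.tsv")),
#'   seed = 1
#' )
#' res$ivw_estimate
#' @export
run_mr <- function(exposure, outcomes, p_threshold = 5e-8,
                   model = c("auto", "fixed", "random"),
                   n_boot = 1000, seed = NULL,
                   palindromic_eaf_window = 0.08,
                   exposure_name = "exposure") {
  model <- match.arg(model)
  if (n_boot > 0 && is.null(seed)) {
    abort("a seed is required when n_boot > 0", class = "tidymr_config_error")
  }
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes)))) {
    abort("outcomes must be a named list", class = "tidymr_config_error")
  }
  exposure <- resolve_input(exposure, "exposure")
  exposure <- validate_summary_stats(exposure)
  instruments <- filter_instruments(exposure, p_threshold)
  inform(sprintf(
    "%d of %d exposure SNP(s) pass P < %g",
    nrow(instruments), nrow(exposure), p_threshold
  ))
  if (nrow(instruments) == 0) {
    abort("no instruments pass the significance threshold",
      class = "tidymr_validation_error"
    )
  }

  fits <- list()
  rows <- purrr::imap(outcomes, function(outc, nm) {
    i <- match(nm, names(outcomes))
    raw <- resolve_input(outc, sprintf("outcome '%s'", nm))
    set <- if (inherits(raw, "instrument_set") ||
      all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(raw))) {
      keep <- raw$rsid %in% instruments$rsid
      if (any(!keep)) {
        warn(sprintf(
          "outcome '%s': %d pre-harmonized SNP(s) not among the selected instruments were dropped",
          nm, sum(!keep)
        ))
      }
      as_instrument_set(raw[keep, ],
        exposure_name = exposure_name, outcome_name = nm
      )
    } else {
      harmonize(instruments, raw,
        palindromic_eaf_window = palindromic_eaf_window,
        exposure_name = exposure_name, outcome_name = nm
      )
    }
    n <- nrow(set)
    inform(sprintf("outcome '%s': %d instrument(s) after harmonization", nm, n))

    ivw <- mr_ivw(set, model = model)
    inform(sprintf(
      "outcome '%s': IVW fixed-effects SE %.4g, reported SE %.4g (scale %.3f, %s effects)",
      nm, ivw$estimates$se_fixed, ivw$estimates$std.error,
      ivw$scale_factor, ivw$model
    ))
    wm <- NULL
    egger <- NULL
    if (n >= 3) {
      wm <- mr_weighted_median(set, n_boot = n_boot, seed = seed + i - 1)
      egger <- mr_egger(set)
    } else {
      warn(sprintf(
        "outcome '%s' has only %d instrument(s); reporting IVW only", nm, n
      ))
    }
    fits[[nm]] <<- list(set = set, ivw = ivw, weighted_median = wm, egger = egger)

    het <- ivw$heterogeneity
    iv <- tidy(ivw)
    wm_row <- if (is.null(wm)) NULL else tidy(wm)
    eg <- if (is.null(egger)) NULL else tidy(egger)
    na5 <- function(prefix) {
      suffixes <- if (prefix == "egger_intercept") {
        c("", "_se", "_ci_low", "_ci_high", "_p")
      } else {
        c("_estimate", "_se", "_ci_low", "_ci_high", "_p")
      }
      setNames(as.list(rep(NA_real_, 5)), paste0(prefix, suffixes))
    }
    tibble::as_tibble(c(
      list(outcome = nm, n_snps = n),
      flat("ivw", iv),
      list(
        q = if (is.null(het)) NA_real_ else het$q,
        q_df = if (is.null(het)) NA_real_ else het$df,
        q_p = if (is.null(het)) NA_real_ else het$p.value,
        i_squared = if (is.null(het)) NA_real_ else het$i.squared
      ),
      if (is.null(wm_row)) na5("wm") else flat("wm", wm_row),
      if (is.null(eg)) na5("egger") else flat("egger", eg[eg$term == "egger_slope", ]),
      if (is.null(eg)) {
        na5("egger_intercept")
      } else {
        flat("egger_intercept", eg[eg$term == "egger_intercept", ])
      }
    ))
  })

  out <- dplyr::bind_rows(rows)[, result_columns]
  structure(out,
    class = c("mr_results", class(tibble::tibble())),
    fits = fits, exposure_name = exposure_name
  )
}

#' Run the pipeline from a YAML configuration file
#'
#' The configuration mirrors [run_mr()]'s arguments: `exposure` (path),
#' `outcomes` (mapping of label to path), and optionally `p_threshold`,
#' `model`, `n_boot`, `seed`, `palindromic_eaf_window`, `exposure_name`.
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param config_path Path to the YAML file.
#' @param out_dir Optional directory; when given, [render_results()] is
#'   called on the result.
#' @return The `mr_results` tibble, invisibly when `out_dir` is given.
#' @export
run_mr_config <- function(config_path, out_dir = NULL) {
  if (!file.exists(config_path)) {
    abort(sprintf("config file not found: '%s'", config_path))
  }
  cfg <- yaml::read_yaml(config_path)
  for (field in c("exposure", "outcomes")) {
    if (is.null(cfg[[field]])) {
      abort(sprintf("config lacks required field '%s'", field),
        class = "tidymr_config_error"
      )
    }
  }
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base, p)
  }
  res <- run_mr(
    exposure = resolve(cfg$exposure),
    outcomes = lapply(cfg$outcomes, resolve),
    p_threshold = cfg$p_threshold %||% 5e-8,
    model = cfg$model %||% "auto",
    n_boot = cfg$n_boot %||% 1000,
    seed = cfg$seed,
    palindromic_eaf_window = cfg$palindromic_eaf_window %||% 0.08,
    exposure_name = cfg$exposure_name %||% "exposure"
  )
  if (!is.null(out_dir)) {
    render_results(res, out_dir)
    return(invisible(res))
  }
  res
}

fmt_est <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
fmt_p <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 1e-4, "<.0001", sprintf("%.3f", p)))
}

#' Write the results table and per-outcome forest data
#'
#' Writes `results.tsv` (one row per outcome; estimates, SEs, CIs and Q
#' rounded to 3 decimals, P-values to 3 decimals with `<.0001` below
#' 1e-4 — internal values stay at full precision, rounding happens only
#' here) and, for each outcome, `forest_<outcome>.tsv` with one line per
#' SNP (Wald ratio and 95% CI) followed by the three combined estimates,
#' ready for external forest plotting.
#'
#' @param results An `mr_results` tibble from [run_mr()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_results <- function(results, dir) {
  if (!inherits(results, "mr_results") || nrow(results) == 0) {
    abort("results must be a nonempty mr_results table")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory '%s'", dir))

  rounded <- tibble::as_tibble(results)
  for (col in setdiff(result_columns, c("outcome", "n_snps", "q_df"))) {
    rounded[[col]] <- if (grepl("_p$|^q_p$", col)) {
      fmt_p(results[[col]])
    } else {
      fmt_est(results[[col]])
    }
  }
  results_path <- file.path(dir, "results.tsv")
  readr::write_tsv(rounded, results_path, progress = FALSE)
  paths <- results_path

  fits <- attr(results, "fits")
  for (nm in names(fits)) {
    f <- fits[[nm]]
    wr <- f$ivw$data
    snp_rows <- tibble::tibble(
      label = wr$rsid, kind = "snp", estimate = wr$ratio, se = wr$se_ratio,
      ci_low = wr$ratio - Z95 * wr$se_ratio,
      ci_high = wr$ratio + Z95 * wr$se_ratio,
      weight = wr$weight
    )
    comb <- purrr::map_dfr(
      purrr::compact(f[c("ivw", "weighted_median", "egger")]),
      function(e) {
        td <- tidy(e)
        td <- td[td$term != "egger_intercept", ]
        tibble::tibble(
          label = td$term, kind = "combined", estimate = td$estimate,
          se = td$std.error, ci_low = td$conf.low, ci_high = td$conf.high,
          weight = NA_real_
        )
      }
    )
    slug <- gsub("[^A-Za-z0-9]+", "_", tolower(nm))
    forest_path <- file.path(dir, sprintf("forest_%s.tsv", slug))
    readr::write_tsv(dplyr::bind_rows(snp_rows, comb), forest_path, progress = FALSE)
    paths <- c(paths, forest_path)
  }
  invisible(paths)
}

#' Check the pipeline against the bundled reference results
#'
#' Runs the full analysis on the bundled education-on-BMD instrument
#' tables and compares every cell against the published results table
#' shipped as `expected_results.tsv`. Deterministic quantities (IVW,
#' Egger, Q, weighted-median point estimates) must agree with the printed
#' 3-decimal values to within 0.0015 (half a printed unit, plus the
#' source's own last-digit rounding); the weighted-median bootstrap SE
#' and the columns derived from it are stochastic and are allowed 20%
#' relative deviation.
#'
#' @param seed Bootstrap seed (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @return A tibble with one row per compared cell (`outcome`, `metric`,
#'   `expected`, `computed`, `tolerance`, `pass`); the overall verdict is
#'   in attribute `"pass"` and printed.
#' @export
mr_validate <- function(seed = 1, n_boot = 1000) {
  res <- suppressMessages(run_mr(
    read_summary_stats(mr_extdata("education_gwas.tsv")),
    outcomes = list(
      "FN-BMD" = mr_extdata("fn_bmd.tsv"),
      "FA-BMD" = mr_extdata("fa_bmd.tsv"),
      "LS-BMD" = mr_extdata("ls_bmd.tsv"),
      "HE-BMD" = mr_extdata("he_bmd.tsv")
    ),
    n_boot = n_boot, seed = seed, exposure_name = "education"
  ))
  exp_raw <- readr::read_tsv(mr_extdata("expected_results.tsv"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  # the weighted-median SE comes from a bootstrap: allow it (and the CI and
  # P-value it induces) to move within a +/-20% band around the printed SE
  checks <- purrr::map_dfr(seq_len(nrow(exp_raw)), function(i) {
    outc <- exp_raw$outcome[i]
    j <- match(outc, res$outcome)
    wm_se_exp <- parse_mr_number(exp_raw$wm_se[i])
    wm_est_exp <- parse_mr_number(exp_raw$wm_estimate[i])
    purrr::map_dfr(setdiff(names(exp_raw), "outcome"), function(col) {
      expected_chr <- exp_raw[[col]][i]
      computed <- res[[col]][j]
      if (startsWith(expected_chr, "<")) {
        bound <- parse_mr_number(sub("^<", "", expected_chr))
        pass <- computed < bound
        tol <- bound
        expected <- bound
      } else {
        expected <- parse_mr_number(expected_chr)
        tol <- switch(col,
          wm_se = 0.2 * wm_se_exp,
          wm_ci_low = ,
          wm_ci_high = Z95 * 0.2 * wm_se_exp + 0.0015,
          wm_p = {
            band <- two_sided_p(wm_est_exp / (wm_se_exp * c(0.8, 1.2)))
            max(abs(band - expected)) + 0.0015
          },
          0.0015
        )
        pass <- abs(computed - expected) <= tol
      }
      tibble::tibble(
        outcome = outc, metric = col, expected = expected,
        computed = computed, tolerance = tol, pass = pass
      )
    })
  })
  overall <- all(checks$pass)
  inform(sprintf(
    "validation %s: %d/%d cells within tolerance",
    if (overall) "PASSED" else "FAILED", sum(checks$pass), nrow(checks)
  ))
  structure(checks, pass = overall)
}
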