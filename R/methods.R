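#' Tidy an MR estimate
#'
#' One row per fitted term (`ivw`, `weighted_median`, or the Egger slope
#' and intercept) with the estimate, standard error, 95% confidence
#' bounds, two-sided normal P-value and the number of instruments used.
#'
#' @param x An `mr_estimate` from [mr_ivw()], [mr_weighted_median()] or
#'   [mr_egger()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- x$estimates
  out$n_snps <- x$n_snps
  out
}

#' One-row model summary of an MR estimate
#'
#' Reports the fit-level quantities: number of instruments, effects model,
#' the residual scale applied to the SE, and the heterogeneity statistics
#' (Cochran's Q, its degrees of freedom and P-value, and I-squared) when
#' the method defines them.
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mr_estimate <- function(x, ...) {
  het <- x$heterogeneity
  tibble::tibble(
    method = x$method, n_snps = x$n_snps, model = x$model,
    scale_factor = x$scale_factor,
    q = if (is.null(het)) NA_real_ else het$q,
    q_df = if (is.null(het)) NA_real_ else het$df,
    q_p = if (is.null(het)) NA_real_ else het$p.value,
    i_squared = if (is.null(het)) NA_real_ else het$i.squared
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("# MR estimate: %s (%d SNPs", x$method, x$n_snps))
  if (!is.na(x$model)) cat(sprintf(", %s effects", x$model))
  cat(")\n")
  print(tidy(x), ...)
  if (!is.null(x$heterogeneity)) {
    h <- x$heterogeneity
    cat(sprintf(
      "# Cochran's Q = %.3f (df %d, P = %.3g), I^2 = %.0f%%\n",
      h$q, h$df, h$p.value, h$i.squared
    ))
  }
  invisible(x)
}

#' Forest plot of per-SNP and combined causal estimates
#'
#' Per-SNP Wald ratios with 95% intervals and the method's combined
#' estimate(s) below, the usual forest display for a single
#' exposure-outcome pair.
#'
#' @param object An `mr_estimate` (carrying its per-SNP Wald ratios).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_estimate <- function(object, ...) {
  wr <- object$data
  if (is.null(wr)) abort("this estimate carries no per-SNP data to plot")
  snps <- tibble::tibble(
    label = wr$rsid, estimate = wr$ratio,
    conf.low = wr$ratio - Z95 * wr$se_ratio,
    conf.high = wr$ratio + Z95 * wr$se_ratio,
    kind = "SNP"
  )
  comb <- tidy(object)
  combined <- tibble::tibble(
    label = comb$term, estimate = comb$estimate,
    conf.low = comb$conf.low, conf.high = comb$conf.high,
    kind = "combined"
  )
  dat <- dplyr::bind_rows(snps, combined)
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$kind), size = 2) +
    ggplot2::scale_shape_manual(values = c(SNP = 16, combined = 18), guide = "none") +
    ggplot2::labs(x = "Causal estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an instrument set with fitted causal slopes
#'
#' Exposure effects against outcome effects (instruments oriented to a
#' positive exposure effect) with the IVW line through the origin and the
#' MR-Egger line with its intercept.
#'
#' @param object An `instrument_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.instrument_set <- function(object, ...) {
  s <- sign(object$beta_exp)
  dat <- tibble::tibble(
    bx = object$beta_exp * s, by = object$beta_out * s,
    sx = object$se_exp, sy = object$se_out
  )
  ivw <- tidy(mr_ivw(object))
  egg <- tidy(mr_egger(object))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$by - .data$sy, ymax = .data$by + .data$sy),
      width = 0, colour = "grey70"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$bx - .data$sx, xmax = .data$bx + .data$sx),
      height = 0, colour = "grey70"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = ivw$estimate[1], intercept = 0, colour = "#2166ac") +
    ggplot2::geom_abline(
      slope = egg$estimate[egg$term == "egger_slope"],
      intercept = egg$estimate[egg$term == "egger_intercept"],
      colour = "#b2182b", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = sprintf("SNP effect on %s", attr(object, "exposure_name")),
      y = sprintf("SNP effect on %s", attr(object, "outcome_name"))
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot across outcomes and methods
#'
#' @param object An `mr_results` tibble from [run_mr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_results <- function(object, ...) {
  long <- tidy(object)
  long <- long[long$term != "egger_intercept", ]
  long$outcome <- factor(long$outcome, levels = rev(unique(long$outcome)))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$estimate, y = .data$outcome,
    colour = .data$term
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.25, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Causal estimate (95% CI)", y = NULL, colour = "Method") +
    ggplot2::theme_minimal()
}

#' Tidy a multi-outcome results table into long form
#'
#' @param x An `mr_results` tibble from [run_mr()].
#' @param ... Unused.
#' @return A tibble with one row per outcome and term.
#' @export
tidy.mr_results <- function(x, ...) {
  fits <- attr(x, "fits")
  purrr::map_dfr(names(fits), function(outc) {
    ests <- purrr::compact(fits[[outc]][c("ivw", "weighted_median", "egger")])
    out <- purrr::map_dfr(ests, tidy)
    out$outcome <- outc
    dplyr::relocate(out, "outcome")
  })
}
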