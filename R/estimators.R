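#' @title Causal-effect estimators
#' @description The two-sample Mendelian randomization estimators: per-SNP
#'   Wald ratios, inverse-variance-weighted (IVW) meta-analysis under fixed
#'   or multiplicative random effects, the weighted median with a
#'   parametric-bootstrap standard error, and MR-Egger regression whose
#'   intercept tests for directional pleiotropy. All are computed from
#'   explicit weighted-least-squares / meta-analytic algebra.
#' @name estimators
NULL

new_mr_estimate <- function(method, estimates, n_snps, model = NA_character_,
                            scale_factor = 1, heterogeneity = NULL, data = NULL) {
  structure(
    list(
      method = method, estimates = estimates, n_snps = n_snps,
      model = model, scale_factor = scale_factor,
      heterogeneity = heterogeneity, data = data
    ),
    class = c(paste0("mr_", method), "mr_estimate")
  )
}

estimate_row <- function(term, beta, se) {
  tibble::tibble(
    term = term, estimate = beta, std.error = se,
    conf.low = beta - Z95 * se, conf.high = beta + Z95 * se,
    p.value = two_sided_p(beta / se)
  )
}

#' Two-sided P-value from a standard-normal statistic
#'
#' Computes `2 * (1 - pnorm(|z|))`, the two-tailed tail probability of the
#' standard normal. The normal (rather than Student's t) reference is used
#' uniformly for every estimator in the package.
#'
#' @param z Standardized statistic(s); must be finite.
#' @return P-value(s) in (0, 1].
#' @examples
#' two_sided_p(1.959964)
#' @export
two_sided_p <- function(z) {
  if (any(!is.finite(z))) abort("z must be finite")
  2 * pnorm(-abs(z))
}

#' Per-SNP Wald ratios
#'
#' For each instrument the causal-effect ratio `beta_out / beta_exp` with
#' its first-order (delta-method) standard error `se_out / |beta_exp|` and
#' the inverse-variance weight `beta_exp^2 / se_out^2`. The first-order SE
#' treats the exposure effect as known; the second-order variant adds the
#' exposure-side term `beta_out^2 * se_exp^2 / beta_exp^4` under the
#' square root.
#'
#' @param set An `instrument_set` (see [as_instrument_set()]).
#' @param second_order Use the second-order delta-method SE (default FALSE).
#' @return A tibble with columns `rsid`, `ratio`, `se_ratio`, `weight`
#'   (`weight = 1 / se_ratio^2`).
#' @examples
#' fn <- read_instrument_set(mr_extdata("fn_bmd.tsv"))
#' wald_ratios(fn)
#' @export
wald_ratios <- function(set, second_order = FALSE) {
  set <- as_instrument_set(set)
  zero <- set$beta_exp == 0
  if (any(zero)) {
    abort(sprintf(
      "degenerate instrument(s) with zero exposure effect: %s",
      paste(set$rsid[zero], collapse = ", ")
    ), class = "tidymr_validation_error")
  }
  ratio <- set$beta_out / set$beta_exp
  se_ratio <- if (second_order) {
    sqrt(set$se_out^2 / set$beta_exp^2 +
      set$beta_out^2 * set$se_exp^2 / set$beta_exp^4)
  } else {
    set$se_out / abs(set$beta_exp)
  }
  tibble::tibble(
    rsid = set$rsid, ratio = ratio, se_ratio = se_ratio,
    weight = 1 / se_ratio^2
  )
}

#' Inverse-variance-weighted causal estimate
#'
#' The IVW estimate is the precision-weighted mean of the per-SNP Wald
#' ratios, `sum(w_j r_j) / sum(w_j)` with `w_j = beta_exp^2 / se_out^2` —
#' algebraically the slope of a weighted regression of outcome on exposure
#' effects through the origin. The fixed-effects SE is
#' `(sum w_j)^(-1/2)`; the multiplicative random-effects model inflates it
#' by the residual scale `sqrt(Q / (n - 1))`, floored at 1, where Q is
#' Cochran's Q about the estimate. `model = "auto"` uses fixed effects
#' below 4 instruments and random effects otherwise.
#'
#' @param set An `instrument_set`.
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @return An `mr_estimate` object; its heterogeneity statistics are the
#'   Q test at `n - 1` degrees of freedom (see [cochran_q()]). Access the
#'   estimate with [tidy()] and the heterogeneity with [glance()].
#' @examples
#' fn <- read_instrument_set(mr_extdata("fn_bmd.tsv"))
#' tidy(mr_ivw(fn))
#' @export
mr_ivw <- function(set, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  wr <- wald_ratios(set)
  n <- nrow(wr)
  if (model == "auto") model <- if (n < 4) "fixed" else "random"

  w <- wr$weight
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  het <- if (n >= 2) cochran_q(wr, center = beta, df = n - 1) else NULL
  scale_factor <- if (model == "random" && !is.null(het)) {
    max(1, sqrt(het$q / het$df))
  } else {
    1
  }
  se <- se_fixed * scale_factor
  est <- estimate_row("ivw", beta, se)
  est$se_fixed <- se_fixed
  new_mr_estimate("ivw", est,
    n_snps = n, model = model,
    scale_factor = scale_factor, heterogeneity = het, data = wr
  )
}

# Bowden cumulative-weight interpolation: sort ratios, form
# p_j = cumsum(w') - w'/2 from normalized weights, interpolate at 0.5;
# beyond the first/last p_j the boundary ratio is returned.
weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  p <- cumsum(w) - w / 2
  if (length(r) == 1) {
    return(r)
  }
  approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios: ratios are sorted, each
#' assigned the midpoint of its normalized cumulative weight, and the
#' ratio at cumulative weight 0.5 is linearly interpolated. It is a
#' consistent causal estimate when at least half the total weight comes
#' from valid instruments. The standard error is the standard deviation of
#' the estimate over `n_boot` parametric-bootstrap replicates in which
#' each `beta_exp` and `beta_out` is resampled from a normal distribution
#' centred at its observed value with its reported SE; the inverse-variance
#' weights stay fixed at their observed values while the ratios are
#' recomputed from the resampled effects.
#'
#' @param set An `instrument_set` with at least 3 instruments.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed; required so the bootstrap SE is
#'   reproducible. The global RNG state is left untouched.
#' @return An `mr_estimate` object.
#' @examples
#' fn <- read_instrument_set(mr_extdata("fn_bmd.tsv"))
#' tidy(mr_weighted_median(fn, seed = 1))
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed) {
  set <- as_instrument_set(set)
  n <- nrow(set)
  if (n < 3) {
    abort("weighted median requires >= 3 instruments",
      class = "tidymr_validation_error"
    )
  }
  if (n_boot < 1) abort("n_boot must be >= 1")
  if (missing(seed) || is.null(seed)) {
    abort("a seed is required for the weighted-median bootstrap")
  }
  wr <- wald_ratios(set)
  beta <- weighted_median_point(wr$ratio, wr$weight)

  # orient to positive exposure effects before resampling: ratios and
  # weights are invariant to a joint sign flip, so this changes nothing in
  # the estimator but makes the bootstrap invariant to instrument recoding
  s <- sign(set$beta_exp)
  mx <- set$beta_exp * s
  my <- set$beta_out * s
  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(n, mx, set$se_exp)
      by <- rnorm(n, my, set$se_out)
      weighted_median_point(by / bx, wr$weight)
    }, numeric(1))
  })
  se <- sd(boots)
  new_mr_estimate("weighted_median", estimate_row("weighted_median", beta, se),
    n_snps = n, data = wr
  )
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept and weights `1 / se_out^2`, after orienting every
#' instrument to a positive exposure effect. The slope is a
#' pleiotropy-adjusted causal estimate under the InSIDE assumption; a
#' nonzero intercept indicates directional horizontal pleiotropy, and the
#' intercept's P-value is the pleiotropy test. Both SEs are inflated by
#' the residual scale `sqrt(Q_resid / (n - 2))`, floored at 1.
#'
#' @param set An `instrument_set` with at least 3 instruments.
#' @return An `mr_estimate` object whose [tidy()] output has one row for
#'   the slope (`term = "egger_slope"`) and one for the intercept
#'   (`term = "egger_intercept"`); heterogeneity is the residual Q at
#'   `n - 2` degrees of freedom.
#' @examples
#' fn <- read_instrument_set(mr_extdata("fn_bmd.tsv"))
#' tidy(mr_egger(fn))
#' @export
mr_egger <- function(set) {
  set <- as_instrument_set(set)
  n <- nrow(set)
  if (n < 3) {
    abort("MR-Egger requires >= 3 instruments (2 model parameters)",
      class = "tidymr_validation_error"
    )
  }
  s <- sign(set$beta_exp)
  bx <- set$beta_exp * s
  by <- set$beta_out * s
  w <- 1 / set$se_out^2

  # explicit weighted least squares: solve (X'WX) b = X'Wy
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * by)
  coefs <- drop(solve(XtWX, XtWy))
  resid <- by - drop(X %*% coefs)
  q_resid <- sum(w * resid^2)
  df <- n - 2
  scale_factor <- max(1, sqrt(q_resid / df))
  se_unscaled <- sqrt(diag(solve(XtWX)))
  se <- se_unscaled * scale_factor

  het <- tibble::tibble(
    q = q_resid, df = df,
    p.value = pchisq(q_resid, df, lower.tail = FALSE),
    i.squared = if (q_resid > 0) max(0, (q_resid - df) / q_resid) * 100 else 0
  )
  est <- dplyr::bind_rows(
    estimate_row("egger_slope", coefs[["slope"]], se[["slope"]]),
    estimate_row("egger_intercept", coefs[["intercept"]], se[["intercept"]])
  )
  new_mr_estimate("egger", est,
    n_snps = n, model = "random",
    scale_factor = scale_factor, heterogeneity = het, data = wald_ratios(set)
  )
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
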