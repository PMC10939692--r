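test_that("Wald ratios follow the first-order delta method", {
  fn <- fn_set()
  wr <- wald_ratios(fn)
  # rs301800: 0.014618 / 0.019111853 and 0.009739 / 0.019111853
  expect_equal(wr$ratio[1], 0.76486566, tolerance = 1e-7)
  expect_equal(wr$se_ratio[1], 0.50957906, tolerance = 1e-7)
  expect_equal(wr$weight, 1 / wr$se_ratio^2)

  one <- as_instrument_set(tibble::tibble(
    rsid = "s", beta_exp = 1, se_exp = 0.1, beta_out = 0.5, se_out = 0.1
  ))
  expect_equal(wald_ratios(one)$ratio, 0.5)
  expect_equal(wald_ratios(one)$se_ratio, 0.1)

  neg <- as_instrument_set(tibble::tibble(
    rsid = "s", beta_exp = -0.02, se_exp = 0.003, beta_out = 0.01, se_out = 0.01
  ))
  expect_equal(wald_ratios(neg)$ratio, -0.5)
  expect_equal(wald_ratios(neg)$se_ratio, 0.5)

  zero <- as_instrument_set(tibble::tibble(
    rsid = "rs_zero", beta_exp = 0, se_exp = 0.1, beta_out = 0.1, se_out = 0.1
  ))
  expect_error(wald_ratios(zero), "rs_zero")

  # second-order SE adds the exposure-side variance term
  expect_gt(wald_ratios(fn, second_order = TRUE)$se_ratio[1], wr$se_ratio[1])
})

test_that("IVW on the femoral-neck set reproduces the published estimate", {
  fit <- mr_ivw(fn_set())
  td <- tidy(fit)
  expect_printed(td$estimate, 0.406)
  expect_printed(td$std.error, 0.176)
  expect_equal(round(td$conf.low, 3), 0.061)
  expect_equal(round(td$conf.high, 3), 0.751)
  expect_printed(td$p.value, 0.021)
  expect_equal(fit$model, "random") # auto with 7 SNPs
  expect_equal(fit$scale_factor, 1) # floor active: Q/6 < 1
})

test_that("a single instrument reduces IVW to its Wald ratio", {
  one <- as_instrument_set(tibble::tibble(
    rsid = "s", beta_exp = 0.02, se_exp = 0.003, beta_out = 0.01, se_out = 0.008
  ))
  td <- tidy(mr_ivw(one))
  expect_equal(td$estimate, 0.5)
  expect_equal(td$std.error, 0.008 / 0.02)
  expect_equal(tidy(mr_ivw(one, model = "auto"))$estimate, 0.5)
})

test_that("IVW equals the slope of origin-constrained weighted least squares", {
  for (seed in 1:6) {
    set <- random_set(5 + seed, seed)
    oracle <- lm(beta_out ~ beta_exp - 1, data = set, weights = 1 / set$se_out^2)
    ours <- tidy(mr_ivw(set))$estimate
    expect_equal(ours, unname(coef(oracle)), tolerance = 1e-12)
  }
})

test_that("estimates are scale-equivariant and invariant to instrument recoding", {
  set <- random_set(9, 11)
  c_out <- 2.5
  scaled <- as_instrument_set(dplyr::mutate(
    tibble::as_tibble(set),
    beta_out = beta_out * c_out, se_out = se_out * c_out
  ))
  for (fitfun in list(mr_ivw, mr_egger, function(s) mr_weighted_median(s, 200, seed = 5))) {
    a <- tidy(fitfun(set))
    b <- tidy(fitfun(scaled))
    expect_equal(b$estimate, a$estimate * c_out, tolerance = 1e-10)
    expect_equal(b$std.error, a$std.error * c_out, tolerance = 1e-10)
  }

  flip <- rep(1, 9)
  flip[c(2, 5)] <- -1
  recoded <- as_instrument_set(dplyr::mutate(
    tibble::as_tibble(set),
    beta_exp = beta_exp * flip, beta_out = beta_out * flip
  ))
  expect_equal(tidy(mr_ivw(recoded)), tidy(mr_ivw(set)), tolerance = 1e-12)
  expect_equal(tidy(mr_egger(recoded)), tidy(mr_egger(set)), tolerance = 1e-12)
  expect_equal(
    tidy(mr_weighted_median(recoded, 200, seed = 7)),
    tidy(mr_weighted_median(set, 200, seed = 7)),
    tolerance = 1e-12
  )
})

test_that("the random-effects IVW SE is never below the fixed-effects SE", {
  for (seed in 1:8) {
    set <- random_set(7, seed * 13)
    expect_gte(
      tidy(mr_ivw(set, model = "random"))$std.error,
      tidy(mr_ivw(set, model = "fixed"))$std.error
    )
  }
  # heel set: heavy heterogeneity, inflation ~4.2 over the fixed SE
  he_fixed <- tidy(mr_ivw(he_set(), model = "fixed"))$std.error
  he_random <- mr_ivw(he_set(), model = "random")
  expect_equal(he_fixed, 0.041908, tolerance = 1e-5)
  expect_equal(he_random$scale_factor, sqrt(105.853472 / 6), tolerance = 1e-6)
  expect_equal(tidy(he_random)$std.error, 0.176, tolerance = 1e-3)
})

test_that("the weighted median interpolates the cumulative weights and matches the published estimates", {
  eq <- as_instrument_set(tibble::tibble(
    rsid = c("a", "b", "c"),
    beta_exp = 1, se_exp = 0.1,
    beta_out = c(0.1, 0.2, 0.9), se_out = 1
  ))
  expect_equal(tidy(mr_weighted_median(eq, 10, seed = 1))$estimate, 0.2)

  expect_printed(tidy(mr_weighted_median(fn_set(), 1000, seed = 1))$estimate, 0.519)
  expect_printed(tidy(mr_weighted_median(ls_set(), 1000, seed = 1))$estimate, 0.150)
})

test_that("with equal weights and odd n the weighted median is the sample median of the ratios", {
  for (n in c(3, 5, 9)) {
    withr::local_seed(100 + n)
    ratios <- rnorm(n)
    set <- as_instrument_set(tibble::tibble(
      rsid = sprintf("s%d", 1:n),
      beta_exp = 1, se_exp = 0.1, beta_out = ratios, se_out = 1
    ))
    expect_equal(
      tidy(mr_weighted_median(set, 5, seed = 1))$estimate,
      median(ratios)
    )
  }
})

test_that("the weighted-median bootstrap is reproducible under a fixed seed and needs >= 3 instruments", {
  fn <- fn_set()
  a <- mr_weighted_median(fn, 300, seed = 99)
  b <- mr_weighted_median(fn, 300, seed = 99)
  expect_identical(tidy(a)$std.error, tidy(b)$std.error)
  c <- mr_weighted_median(fn, 300, seed = 100)
  expect_false(identical(tidy(a)$std.error, tidy(c)$std.error))

  # and it leaves the caller's RNG stream untouched
  withr::local_seed(1)
  before <- .Random.seed
  invisible(mr_weighted_median(fn, 50, seed = 3))
  expect_identical(.Random.seed, before)

  two <- as_instrument_set(tibble::tibble(
    rsid = c("a", "b"), beta_exp = 1, se_exp = 0.1,
    beta_out = c(0.1, 0.2), se_out = 1
  ))
  expect_error(mr_weighted_median(two, 10, seed = 1), ">= 3")
  expect_error(mr_weighted_median(fn, 100), "seed")
})

test_that("MR-Egger recovers an exact linear relationship and matches weighted lm", {
  exact <- as_instrument_set(tibble::tibble(
    rsid = sprintf("s%d", 1:4),
    beta_exp = c(0.01, 0.02, 0.03, 0.04), se_exp = 0.003,
    beta_out = 0.01 + 0.5 * c(0.01, 0.02, 0.03, 0.04),
    se_out = c(0.01, 0.02, 0.015, 0.012)
  ))
  td <- tidy(mr_egger(exact))
  expect_equal(td$estimate[td$term == "egger_slope"], 0.5, tolerance = 1e-10)
  expect_equal(td$estimate[td$term == "egger_intercept"], 0.01, tolerance = 1e-10)
  expect_equal(mr_egger(exact)$heterogeneity$q, 0, tolerance = 1e-16)

  for (seed in 1:5) {
    set <- random_set(8, seed * 7)
    s <- sign(set$beta_exp)
    oracle <- lm(I(set$beta_out * s) ~ I(set$beta_exp * s),
      weights = 1 / set$se_out^2
    )
    sm <- summary(oracle)
    td <- tidy(mr_egger(set))
    expect_equal(td$estimate[td$term == "egger_slope"],
      unname(coef(oracle)[2]),
      tolerance = 1e-12
    )
    # lm scales by the residual sigma with no floor; undo and re-floor
    se_oracle <- sm$coefficients[, 2] / sm$sigma * max(1, sm$sigma)
    expect_equal(td$std.error[td$term == "egger_intercept"],
      unname(se_oracle[1]),
      tolerance = 1e-12
    )
    expect_equal(td$std.error[td$term == "egger_slope"],
      unname(se_oracle[2]),
      tolerance = 1e-12
    )
  }

  expect_error(mr_egger(as_instrument_set(tibble::tibble(
    rsid = c("a", "b"), beta_exp = 1, se_exp = 0.1,
    beta_out = 0.1, se_out = 1
  ))), ">= 3")
})

test_that("MR-Egger on the femoral-neck and forearm sets reproduces the published slope and intercept", {
  td <- tidy(mr_egger(fn_set()))
  expect_printed(td$estimate[td$term == "egger_slope"], 1.140)
  expect_printed(td$std.error[td$term == "egger_slope"], 0.700)
  expect_printed(td$estimate[td$term == "egger_intercept"], -0.014)
  expect_printed(td$std.error[td$term == "egger_intercept"], 0.013)
  expect_printed(td$p.value[td$term == "egger_intercept"], 0.278)

  fa <- tidy(mr_egger(fa_set()))
  expect_printed(fa$estimate[fa$term == "egger_slope"], -0.431)
  expect_printed(fa$estimate[fa$term == "egger_intercept"], 0.013)
})

test_that("two-sided P-values use the standard normal tail", {
  expect_equal(two_sided_p(0), 1.0)
  expect_equal(two_sided_p(0.406 / 0.176), 0.02106496, tolerance = 1e-6)
  expect_equal(two_sided_p(1.140 / 0.700), 0.10340378, tolerance = 1e-6)
  expect_equal(two_sided_p(-2), two_sided_p(2))
  expect_error(two_sided_p(Inf), "finite")
})

test_that("confidence intervals bracket the estimate with the fixed 95% multiplier", {
  for (fit in list(
    mr_ivw(fn_set()), mr_egger(fn_set()),
    mr_weighted_median(fn_set(), 100, seed = 1)
  )) {
    td <- tidy(fit)
    expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
    expect_equal(td$conf.high - td$estimate, 1.959964 * td$std.error)
  }
})
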