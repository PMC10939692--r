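test_that("swapped outcome alleles flip the outcome beta and identical coding passes through", {
  exp <- allele_pair("rs1", "A", "G", beta = 0.02)
  out_swapped <- allele_pair("rs1", "G", "A", eaf = 0.7, beta = -0.01, se = 0.005)
  set <- harmonize(exp, out_swapped)
  expect_equal(set$beta_out, 0.01)

  out_same <- allele_pair("rs1", "A", "G", beta = -0.01, se = 0.005)
  set2 <- harmonize(exp, out_same)
  expect_equal(set2$beta_out, -0.01)
  expect_equal(set2$beta_exp, 0.02)
})

test_that("strand-complemented alleles are resolved, with and without a swap", {
  exp <- allele_pair("rs1", "A", "G", beta = 0.02)
  out_comp <- allele_pair("rs1", "T", "C", beta = 0.015, se = 0.005)
  expect_equal(harmonize(exp, out_comp)$beta_out, 0.015)

  out_comp_swap <- allele_pair("rs1", "C", "T", beta = 0.015, se = 0.005)
  expect_equal(harmonize(exp, out_comp_swap)$beta_out, -0.015)
})

test_that("ambiguous palindromic SNPs are dropped; well-resolved ones are kept and oriented by frequency", {
  exp2 <- dplyr::bind_rows(
    allele_pair("rs_pal", "A", "T", eaf = 0.50),
    allele_pair("rs_keep", "A", "G")
  )
  out2 <- dplyr::bind_rows(
    allele_pair("rs_pal", "A", "T", eaf = 0.50, beta = 0.01, se = 0.005),
    allele_pair("rs_keep", "A", "G", beta = 0.01, se = 0.005)
  )
  expect_warning(set <- harmonize(exp2, out2, palindromic_eaf_window = 0.08), "palindromic")
  expect_equal(set$rsid, "rs_keep")
  expect_equal(instrument_drops(set)$reason, "palindromic")

  # palindrome far from 0.5: kept; discordant frequencies force a flip
  exp3 <- allele_pair("rs_pal2", "A", "T", eaf = 0.2)
  out3 <- allele_pair("rs_pal2", "A", "T", eaf = 0.8, beta = 0.01, se = 0.005)
  set3 <- harmonize(exp3, out3)
  expect_equal(set3$beta_out, -0.01)
})

test_that("missing and irreconcilable SNPs drop with a warning; zero survivors is an error", {
  exp <- dplyr::bind_rows(
    allele_pair("rs1", "A", "G"),
    allele_pair("rs2", "A", "G"),
    allele_pair("rs3", "A", "G")
  )
  out <- dplyr::bind_rows(
    allele_pair("rs1", "A", "G", beta = 0.01, se = 0.005),
    allele_pair("rs2", "A", "C", beta = 0.01, se = 0.005) # unmatchable pair
  )
  expect_warning(set <- harmonize(exp, out), "dropped 2")
  expect_equal(set$rsid, "rs1")
  expect_setequal(instrument_drops(set)$reason, c("missing", "irreconcilable"))

  out_none <- allele_pair("rs9", "A", "G", beta = 0.01, se = 0.005)
  expect_error(
    suppressWarnings(harmonize(exp, out_none)),
    "no usable instruments"
  )
})

test_that("harmonization is invariant to recoding an input SNP (swap alleles, negate beta, complement eaf)", {
  exp <- dplyr::bind_rows(
    allele_pair("rs1", "A", "G", beta = 0.02),
    allele_pair("rs2", "T", "C", beta = -0.015, eaf = 0.6)
  )
  out <- dplyr::bind_rows(
    allele_pair("rs1", "A", "G", beta = 0.01, se = 0.005),
    allele_pair("rs2", "C", "T", beta = 0.004, se = 0.004, eaf = 0.35)
  )
  base <- harmonize(exp, out)

  recoded <- out
  recoded$effect_allele[1] <- "G"
  recoded$other_allele[1] <- "A"
  recoded$beta[1] <- -recoded$beta[1]
  recoded$eaf[1] <- 1 - recoded$eaf[1]
  expect_equal(
    tibble::as_tibble(harmonize(exp, recoded)),
    tibble::as_tibble(base)
  )

  # recoding the exposure side flips beta_exp and beta_out together,
  # leaving every Wald ratio unchanged
  exp_rec <- exp
  exp_rec$effect_allele[2] <- "C"
  exp_rec$other_allele[2] <- "T"
  exp_rec$beta[2] <- -exp_rec$beta[2]
  exp_rec$eaf[2] <- 1 - exp_rec$eaf[2]
  flipped <- harmonize(exp_rec, out)
  expect_equal(
    wald_ratios(flipped)$ratio,
    wald_ratios(base)$ratio
  )
})

test_that("harmonization is idempotent on an already-aligned pair", {
  exp <- dplyr::bind_rows(
    allele_pair("rs1", "A", "G", beta = 0.02),
    allele_pair("rs2", "T", "C", beta = -0.015)
  )
  out <- dplyr::bind_rows(
    allele_pair("rs1", "A", "G", beta = 0.01, se = 0.005),
    allele_pair("rs2", "T", "C", beta = 0.004, se = 0.004)
  )
  once <- harmonize(exp, out)
  out_aligned <- out
  out_aligned$beta <- once$beta_out
  twice <- harmonize(exp, out_aligned)
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(once))
})

test_that("instrument sets round-trip through write/read exactly at 10 significant digits", {
  for (seed in c(1, 2, 3)) {
    set <- random_set(8, seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_instrument_set(set, path)
    back <- read_instrument_set(path)
    for (col in c("beta_exp", "se_exp", "beta_out", "se_out")) {
      expect_identical(
        sprintf("%.10g", back[[col]]),
        sprintf("%.10g", set[[col]])
      )
    }
    expect_identical(back$rsid, set$rsid)
  }

  # the bundled FN-BMD set (7 rows) round-trips identically
  fn <- fn_set()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_instrument_set(fn, path)
  expect_equal(nrow(fn), 7)
  expect_equal(
    tibble::as_tibble(read_instrument_set(path, "education", "FN-BMD")),
    tibble::as_tibble(fn)
  )
})

test_that("empty or malformed instrument sets are rejected", {
  expect_error(
    as_instrument_set(tibble::tibble(
      rsid = character(), beta_exp = numeric(), se_exp = numeric(),
      beta_out = numeric(), se_out = numeric()
    )),
    "no usable instruments"
  )
  expect_error(
    as_instrument_set(tibble::tibble(rsid = "rs1", beta_exp = 0.1)),
    "lacks column"
  )
  dup <- tibble::tibble(
    rsid = c("rs1", "rs1"), beta_exp = 0.1, se_exp = 0.1,
    beta_out = 0.1, se_out = 0.1
  )
  expect_error(as_instrument_set(dup), "unique")
})
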