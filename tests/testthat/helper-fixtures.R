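# Shared fixtures built in code.

expect_printed <- function(computed, printed, digits = 3) {
  # agreement with a value printed at `digits` decimals, allowing the
  # source's own half-unit last-digit rounding
  expect_lt(abs(computed - printed), 1.5 * 10^(-digits))
}

# random but valid harmonized instrument set, for property-style tests
random_set <- function(n, seed) {
  withr::local_seed(seed)
  as_instrument_set(tibble::tibble(
    rsid = sprintf("snp_%03d", seq_len(n)),
    beta_exp = rnorm(n, 0.02, 0.01) * sample(c(-1, 1), n, replace = TRUE),
    se_exp = runif(n, 0.001, 0.005),
    beta_out = rnorm(n, 0, 0.02),
    se_out = runif(n, 0.005, 0.02)
  ))
}

# small exposure/outcome summary-stat pair with full allele information
allele_pair <- function(rsid = "rs1", ea = "A", oa = "G", eaf = 0.3,
                        beta = 0.02, se = 0.003, pvalue = 1e-9, n = 1e5) {
  tibble::tibble(
    rsid = rsid, chrom = "1", pos = 100, effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = beta, se = se,
    pvalue = pvalue, n = n
  )
}

edu_path <- function() mr_extdata("education_gwas.tsv")
fn_set <- function() read_instrument_set(mr_extdata("fn_bmd.tsv"), "education", "FN-BMD")
ls_set <- function() read_instrument_set(mr_extdata("ls_bmd.tsv"), "education", "LS-BMD")
he_set <- function() read_instrument_set(mr_extdata("he_bmd.tsv"), "education", "HE-BMD")
fa_set <- function() read_instrument_set(mr_extdata("fa_bmd.tsv"), "education", "FA-BMD")

bmd_outcomes <- function() {
  list(
    "FN-BMD" = mr_extdata("fn_bmd.tsv"),
    "FA-BMD" = mr_extdata("fa_bmd.tsv"),
    "LS-BMD" = mr_extdata("ls_bmd.tsv"),
    "HE-BMD" = mr_extdata("he_bmd.tsv")
  )
}

# R^2 and F columns as printed alongside the 12 education instruments
EDU_PRINTED_R2 <- c(
  rs301800 = 1.08e-4, rs11210860 = 1.37e-4, rs34305371 = 2.14e-4,
  rs1008078 = 1.31e-4, rs11588857 = 1.31e-4, rs1777827 = 1.09e-4,
  rs2992632 = 1.14e-4, rs76076331 = 1.05e-4, rs11689269 = 1.11e-4,
  rs11690172 = 1.07e-4, rs2457660 = 1.31e-4, rs10496091 = 1.31e-4
)
EDU_PRINTED_F <- c(
  rs301800 = 32, rs11210860 = 40, rs34305371 = 63, rs1008078 = 39,
  rs11588857 = 39, rs1777827 = 32, rs2992632 = 33, rs76076331 = 31,
  rs11689269 = 33, rs11690172 = 32, rs2457660 = 39, rs10496091 = 38
)
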