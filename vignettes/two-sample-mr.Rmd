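---
title: "Two-sample Mendelian randomization with tidymr: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with tidymr: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidymr)
```

## The design and its assumptions

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome using genetic variants as instrumental variables,
with the variant-exposure and variant-outcome associations taken from two
separate GWAS. A SNP $j$ qualifies as an instrument under three
assumptions: it is robustly associated with the exposure (relevance,
enforced here by the genome-wide threshold $P < 5\times10^{-8}$); it is
independent of confounders of the exposure-outcome relationship; and it
affects the outcome only through the exposure (no horizontal pleiotropy).
Only summary statistics are needed: per-SNP effect estimates
$\hat\gamma_j$ (exposure) and $\hat\Gamma_j$ (outcome) with standard
errors.

The bundled example data are the instruments of a published two-sample MR
analysis of educational attainment (GWAS meta-analysis, $n = 293{,}723$)
on bone mineral density (BMD) at the femoral neck, forearm and lumbar
spine ($n = 53{,}236$) and the heel ($n = 426{,}824$): 12 instrument SNPs
and their harmonized per-site outcome effects, plus the reference results
table that `mr_validate()` reproduces cell by cell.

## Estimators

**Wald ratio.** Each SNP's causal estimate is
$r_j = \hat\Gamma_j / \hat\gamma_j$ with first-order (delta-method)
standard error $\sigma_j = \mathrm{se}(\hat\Gamma_j)/|\hat\gamma_j|$,
treating the exposure effect as known. A second-order SE that
propagates $\mathrm{se}(\hat\gamma_j)$ is available
(`wald_ratios(second_order = TRUE)`) but off by default: the first-order
form is what the reference results use, and with instrument F-statistics
of 30-60 the correction is negligible.

**IVW.** The inverse-variance-weighted estimate is
$\hat\theta = \sum_j w_j r_j / \sum_j w_j$ with
$w_j = 1/\sigma_j^2 = \hat\gamma_j^2/\mathrm{se}(\hat\Gamma_j)^2$ —
algebraically the slope of weighted least squares of $\hat\Gamma$ on
$\hat\gamma$ through the origin (a property the test suite checks to
$10^{-12}$ against `lm`). The fixed-effects SE is
$(\sum_j w_j)^{-1/2}$. Under the multiplicative random-effects model the
SE is inflated by the residual scale $\sqrt{Q/(n-1)}$, floored at 1,
where $Q = \sum_j w_j (r_j - \hat\theta)^2$ is Cochran's Q. The floor
matters in practice: the bundled reference results exhibit both regimes
(femoral neck and forearm sit below the floor, lumbar spine and heel
above it, the heel with an inflation factor of 4.2), and one rule
reproduces all four printed SEs. `model = "auto"` uses fixed effects
below 4 instruments — too few SNPs to estimate heterogeneity usefully —
and random effects otherwise.

**Weighted median.** Ratios are sorted; with normalized weights $w'_j$,
each receives the midpoint $p_j$ of its cumulative-weight interval, and
the estimate interpolates the ratio at $p = 0.5$ (no extrapolation: the
boundary ratio is returned when 0.5 falls outside $[p_1, p_n]$). It
remains consistent when up to half the total weight comes from invalid
instruments. The SE is the standard deviation of the estimate over
parametric-bootstrap replicates (default `n_boot = 1000`, seed
mandatory): each $\hat\gamma_j$ and $\hat\Gamma_j$ is resampled from a
normal at its observed value and SE and the ratios recomputed, while the
inverse-variance weights stay fixed at their observed values. We hold
the weights fixed for two reasons: it reproduces the reference SEs at
all four skeletal sites (including the strongly heterogeneous heel
outcome, where recomputing weights from resampled exposure effects
inflates the SE by roughly 20%), and it avoids the ratio-blowup
instability when a resampled exposure effect lands near zero.
Instruments are oriented to positive exposure effects before resampling;
ratios and weights are invariant to that joint sign flip, so the
estimator is unchanged and the bootstrap becomes exactly invariant to
allele recoding.

**MR-Egger.** Weighted least squares of $\hat\Gamma_j$ on
$\hat\gamma_j$ with a free intercept and weights
$1/\mathrm{se}(\hat\Gamma_j)^2$, after orienting every instrument to
$\hat\gamma_j > 0$. Under the InSIDE assumption (instrument strength
independent of direct effects) the slope is a pleiotropy-adjusted causal
estimate and the intercept estimates the average direct (pleiotropic)
effect; the intercept's P-value is the directional-pleiotropy test. Both
SEs carry the same floored multiplicative scale, with residual Q at
$n - 2$ degrees of freedom. The regression is solved from the explicit
normal equations; `lm` serves only as an independent oracle in the
tests.

**Inference.** All P-values are two-sided from the standard normal,
$2(1 - \Phi(|z|))$, and all 95% intervals use the fixed multiplier
$z = 1.959964$. The normal reference (rather than Student's t) is a
deliberate choice: it is what reproduces the reference Egger slope
P-value (.103 for $z = 1.140/0.700$; t with 5 df would give ≈ .16), and
it is applied uniformly to every method.

## Harmonization

Exposure and outcome tables are intersected by rsid and the outcome
effect aligned to the exposure's effect allele: identical coding passes
through; swapped alleles flip the outcome beta and complement its
frequency; strand-flipped alleles are complemented first. Palindromic
SNPs (A/T, C/G) cannot be resolved by allele letters alone: within
`palindromic_eaf_window = 0.08` of frequency 0.5 (i.e.
$\min(p, 1-p) > 0.42$) they are dropped as ambiguous; outside it they
are oriented by allele match and corrected by frequency concordance when
both sides report frequencies. The window value is conventional MR
practice; none of the bundled instruments is palindromic, so the
reference reproduction does not depend on it. SNPs missing from the
outcome are dropped (no proxy search — that requires an external LD
reference panel, out of scope), as are SNPs whose alleles remain
irreconcilable after swap and complement; every drop is logged with its
reason and kept in `instrument_drops()`.

Instrument strength is diagnosed per SNP as the variance explained on a
standardized trait, $R^2 = 2p(1-p)\beta^2$, and
$F = R^2(N-2)/(1-R^2)$, with $F < 10$ flagged as weak. The $R^2$
formula reproduces all 12 published instrument values, a check the test
suite performs.

## The synthetic-data generator

`simulate_pair()` draws true exposure effects
$\gamma_j \sim N(0.02, 0.005)$, direct effects $\alpha_j$ (zero,
balanced $N(0, \sigma_\alpha)$, or directional
$N(\mu_\alpha, \sigma_\alpha)$ — independent of $\gamma_j$, so InSIDE
holds by construction), and observed effects
$\hat\gamma_j \sim N(\gamma_j, 0.003)$,
$\hat\Gamma_j \sim N(\theta\gamma_j + \alpha_j, 0.009)$. The defaults —
12 SNPs, $\theta = 0.4$, exposure $n = 293{,}723$, outcome
$n = 53{,}236$, frequencies uniform on (0.1, 0.9) — mirror the bundled
education-on-BMD setting, putting F-statistics in the 30-60 range of the
real instruments. Alleles are drawn from non-palindromic pairs so
harmonization passes every simulated SNP through.

What the generator does *not* emulate: linkage disequilibrium between
instruments, sample overlap between the two GWAS, winner's-curse
selection of instruments, allele-frequency-dependent effect sizes, and
InSIDE violations (a correlation between $\alpha_j$ and $\gamma_j$ is
deliberately not modelled — the generator implements the estimators' own
assumption set). Passing recovery tests therefore demonstrate
correctness of the estimators under their assumed model, not robustness
on real data.

`recovery_report()` summarizes bias, empirical SD, mean model SE and 95%
coverage over replicates. The test suite runs 200 replicates for the
recovery and coverage properties (Monte-Carlo SE of the mean is then
$\mathrm{SD}/\sqrt{200}$, and coverage has binomial SE ≈ 1.5%) and
asserts the three-estimator consistency property under strong
instruments ($\mathrm{se}(\hat\gamma) = 0.001$ against an effect spread
of 0.02): at realistic strength (F ≈ 40) the Egger slope shows its known
regression-dilution attenuation of order
$1 - \mathrm{var}(\gamma)/(\mathrm{var}(\gamma) + \mathrm{se}^2)$,
which is a property of the estimator, not an implementation defect.
Directional pleiotropy ($\mu_\alpha = 0.01$) is checked to bias IVW
upward while the Egger intercept recovers $\mu_\alpha$.

## Numerical and interface choices

* Rounding happens only at render time: `render_results()` writes
  estimates, SEs, CIs and Q to 3 decimals and P-values to 3 decimals
  with `<.0001` below $10^{-4}$; everything upstream is full precision.
* `write_instrument_set()` prints numerics at 10 significant digits, so
  write-then-read is exact at that precision.
* The numeric parser accepts unicode minus signs, thousands separators
  and bare leading decimal points, as found in published tables.
* Degenerate inputs fail loudly: zero exposure effects name the SNP,
  fewer than 3 instruments disable the median and Egger fits (the
  pipeline then emits an IVW-only row with a warning), zero surviving
  instruments is an error.
* Bootstrap and simulation seeds are mandatory; seeded code restores the
  caller's RNG state. `run_mr()` derives the per-outcome bootstrap seed
  as `seed + i - 1` so results are deterministic for a given
  configuration and outcome order.

## Notes on the bundled tables

Two quirks of the source tables are worth recording. First, the printed
instrument table transposes its SE and P-value column headers (the
values of magnitude $10^{-8}$-$10^{-14}$ are the P-values; the values
around 0.003 are the SEs, consistent with the exposure SEs in the
harmonized table); the bundled `education_gwas.tsv` stores the values
under the corrected headers, and one frequency entry's stray trailing
character is treated as a typo. Second, the source's narrative text for
the lumbar-spine IVW estimate (0.396, P = .340) disagrees with its own
results table (0.369, P = .145); the bundled inputs reproduce the
results table, which is what `expected_results.tsv` and `mr_validate()`
target.

## Known limitations

No LD clumping, proxy-SNP search, or reference-panel handling: inputs
must be pre-clumped, and missing outcome SNPs are simply dropped. No
MR-PRESSO, mode-based, SIMEX-corrected Egger, or multivariable MR. The
weighted-median SE is a bootstrap quantity: it is reproducible under a
fixed seed but carries replicate-count noise of a few percent at
`n_boot = 1000`, and the reference SEs it is compared against were
produced by a procedure whose replicate count is not stated — the
package treats those comparisons as stochastic with a ±20% band.

## A worked run

```{r, eval = FALSE}
edu <- read_summary_stats(mr_extdata("education_gwas.tsv"))
res <- run_mr(
  edu,
  outcomes = list(
    "FN-BMD" = mr_extdata("fn_bmd.tsv"),
    "FA-BMD" = mr_extdata("fa_bmd.tsv"),
    "LS-BMD" = mr_extdata("ls_bmd.tsv"),
    "HE-BMD" = mr_extdata("he_bmd.tsv")
  ),
  seed = 1, exposure_name = "education"
)
res[, c("outcome", "ivw_estimate", "ivw_se", "ivw_p", "q", "i_squared")]
render_results(res, "results/")
autoplot(res)
```
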