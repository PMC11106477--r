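# bloodcellmr

Two-sample Mendelian randomization (MR) of the 15 complete-blood-count
traits (RBC, HGB, HCT, MCV, MCH, MCHC, RDW, WBC, NEU, LYM, MON, BAS, EOS,
PLT, MPV) on Crohn's disease (CD) and ulcerative colitis (UC), for
epidemiologists and statistical geneticists who want the whole causal
workflow — instrument validation, univariable estimation, multivariable
Bayesian model averaging, and an observational dose-response stage — as
tested, reusable R functions that run end to end on synthetic data with
known ground truth.

## What it computes

**Instruments.** Variants reaching genome-wide significance (p < 5×10⁻⁸)
for at least one trait are LD-clumped (greedy, keep the minimum-p variant,
drop neighbours with r² > 0.001), variants absent from the outcome study
are replaced by proxies with r² ≥ 0.8, variants with
genome-wide-significant confounder associations are removed, and effect
alleles are harmonized across studies (palindromic A/T and C/G variants
kept only when allele frequencies identify the orientation). Instrument
strength is summarized by F = (R²/k)/((1−R²)/(n−k−1)) and the per-SNP
approximation (β/se)².

**Univariable MR.** For exposure effects βX and outcome log-odds effects
βY over J instruments, the package reports six estimators per
exposure-outcome pair: fixed-effects IVW
θ̂ = Σ βXⱼβYⱼ/seYⱼ² / Σ βXⱼ²/seYⱼ², its multiplicative random-effects
version (SE scaled by max(1, √(Q/(J−1)))), simple / weighted / penalized
weighted medians of the per-SNP Wald ratios βYⱼ/βXⱼ (bootstrap SEs), and
MR-Egger regression whose intercept tests directional pleiotropy.
Cochran's Q quantifies heterogeneity; significance uses the Bonferroni
threshold 0.05/30 ≈ 0.0017 for 15 traits × 2 outcomes.

**Multivariable MR via Bayesian model averaging.** On the
inverse-variance-standardized scale (response βYⱼ/seYⱼ, design
βXⱼₖ/seYⱼ), every exposure subset S receives a closed-form Gaussian
marginal likelihood (independent N(0, σ²) priors on included
coefficients, unit residual variance) and a posterior probability
PP(S) ∝ p^|S|(1−p)^(K−|S|) · ML(S). Per-exposure marginal inclusion
probabilities (MIP) and model-averaged causal estimates (MACE) summarize
the space. Instruments with per-SNP heterogeneity q > 10 or Cook's
distance above the F(d, J−d) median under any high-PP model are pruned
iteratively, with a full audit trail and the pre-pruning posterior kept
for the consistency check.

**Dose-response.** Restricted-cubic-spline logistic regression of case
status on each trait (4 knots at Harrell's percentiles) yields a log-OR
curve anchored at the healthy-group median with a delta-method 95% band;
trait values where a band boundary crosses zero are reported (to 2
decimals) as candidate clinical risk-assessment thresholds, alongside
rank-based group comparisons.

A synthetic-data module generates all inputs — sparse correlated per-SNP
effects across the trait panel, a causal subset driving a binary outcome,
configurable pleiotropy, block LD, confounder catalogs, and a
100 healthy / 230 CD / 80 UC blood-count cohort — so every stage is
testable without consortium downloads.

## Worked example

```r
library(bloodcellmr)
report <- run_pipeline(list(seed = 7, n_snps = 1000L,
  causal_effects = list(CD = c(LYM = -0.2), UC = c(EOS = 0.3))))
print(report)
```

```
bloodcellmr run (seed 7)
  CD: instrument selection funnel: 465 genome-wide significant; 23 missing in outcome (23 proxied); 190 after LD clumping; 10 removed as confounder-associated; 180 final
  UC: instrument selection funnel: 475 genome-wide significant; 25 missing in outcome (25 proxied); 197 after LD clumping; 8 removed as confounder-associated; 189 final
  uvMR Bonferroni-significant (random-effects IVW): none
  MR-BMA CD: top exposure LYM (MIP 0.906, MACE -0.432), 6 SNPs pruned
  MR-BMA UC: top exposure EOS (MIP 0.900, MACE 0.233), 1 SNPs pruned
```

The planted truth here is a protective lymphocyte effect on CD
(log-OR −0.2 per SD) and a harmful eosinophil effect on UC (+0.3 per SD).
Model averaging ranks exactly those traits first:

```r
head(bma_rank_exposures(report$bma$UC$posterior), 4)
#>   exposure       mip        mace
#> 1      EOS 0.8996473  0.23310115
#> 2      NEU 0.6017348 -0.12256909
#> 3     MCHC 0.4467758 -0.07874974
#> 4      HCT 0.1539807 -0.02855556
```

and the random-effects IVW estimate for EOS on UC is an odds ratio per SD
with its 95% CI and p-value:

```r
report$uvmr[report$uvmr$method == "ivw_random" &
            report$uvmr$exposure == "EOS" &
            report$uvmr$outcome == "UC",
            c("or", "or_ci_low", "or_ci_high", "pvalue", "n_snps")]
#>     or or_ci_low or_ci_high  pvalue n_snps
#>   1.23      1.07       1.42 0.00347     19
```

At this simulation size the EOS-UC IVW p-value (0.0035) sits above the
30-test Bonferroni bar of 0.0017 — a reminder that with ~19 instruments
per trait the median-powered estimators need the full consortium scale to
clear family-wise correction, while model averaging already identifies
the right traits.

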