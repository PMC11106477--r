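---
title: "Methods: Mendelian randomization of blood-cell traits on IBD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization of blood-cell traits on IBD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodcellmr)
```

## The causal question and the instrumental-variable model

Patients with inflammatory bowel disease routinely show abnormal complete
blood counts, but observational associations cannot separate cause from
consequence. Mendelian randomization treats genetic variants as
instruments: a variant associated with a blood-cell trait, independent of
confounders, and affecting disease only through that trait supports a
causal reading of the trait-disease association. Because variants are
fixed at conception, reverse causation is excluded by design.

The two-sample setting uses only summary statistics: per-SNP effects on
each of the 15 blood-count traits (per SD of trait) from one large GWAS,
and per-SNP log-odds effects on Crohn's disease (CD) or ulcerative
colitis (UC) from a separate case-control GWAS. All estimators in this
package operate on a harmonized J x K matrix of exposure effects, the
matching outcome vector, and their standard errors.

## Instrument selection and validation

The selection funnel applies, in order:

1. **Relevance.** Variants with p < 5e-8 for at least one trait.
2. **Proxy substitution.** A variant absent from the outcome study is
   replaced by the variant in highest LD with it (r-squared >= 0.8, the
   conventional proxy bound) that is present; otherwise it is dropped.
3. **Independence of instruments.** Greedy LD clumping: repeatedly keep
   the remaining variant with the smallest exposure p-value and discard
   all others with r-squared > 0.001 to it. The retained set is
   exhaustively pairwise-independent at that threshold. Genomic-window
   restrictions are deliberately not applied: the synthetic LD model is
   block-structured, so windows would be a no-op with extra machinery.
4. **Independence of confounders.** Variants carrying a
   genome-wide-significant association with a screening phenotype
   (autoimmune disease, metabolic disease, cancer, death) in the supplied
   catalog are removed.

Harmonization aligns every outcome row to the exposure panels' effect
allele, flipping the sign of the outcome coefficient when the alleles are
swapped. Palindromic variants (A/T, C/G) cannot be oriented by alleles
alone; they are retained only when both studies' minor-allele frequencies
are below 0.42 and identify the orientation, otherwise dropped. This is
the conservative convention in common harmonization tools; the 0.42 bound
is exposed as an argument. Harmonization is involutive — aligning an
already-aligned panel changes nothing — and the test suite asserts this.

Instrument strength is reported two ways: the overall
F = (R²/k) / ((1−R²)/(n−k−1)) for k instruments explaining R² of trait
variance in a study of size n, and the per-SNP first-order approximation
(β/se)². Statistical power for a binary outcome uses a normal
approximation: power = Φ(|ln OR|·√(n·R²·φ(1−φ)) − z₁₋α/₂) with φ the case
fraction. The tests pin this exact formula against adaptive quadrature of
the same non-centrality model, so the implemented definition — not a
citation — is the contract.

## Univariable estimators

Writing the per-SNP Wald ratio rⱼ = βYⱼ/βXⱼ with weight wⱼ = βXⱼ²/seYⱼ²:

* **Fixed-effects IVW** is the weight-w least-squares slope through the
  origin; its SE is 1/√Σwⱼ.
* **Multiplicative random-effects IVW** scales that SE by
  max(1, √(Q/(J−1))), where Q = Σ wⱼ(rⱼ − θ̂)² is Cochran's Q. The floor
  at 1 means heterogeneity can only widen intervals. Both flavours are
  always reported side by side.
* **Medians**: the simple median of rⱼ; the weighted median (weighted
  50th percentile with inverse-variance ratio weights, linearly
  interpolated on the cumulative weights); and the penalized weighted
  median, which multiplies each weight by min(1, 20·pⱼ) where pⱼ is the
  upper χ²₁ tail of the SNP's Q contribution about the weighted median.
  The constant 20 follows the published median-estimator methodology and
  is a tunable argument. Median SEs come from a seeded parametric
  bootstrap (default 1000 resamples of βX and βY from their SEs) with a
  normal-theory CI from the bootstrap SD.
* **MR-Egger**: weighted regression of βY on βX *with* an intercept after
  orienting all βX ≥ 0; the slope is the pleiotropy-corrected estimate
  and the intercept's p-value tests directional pleiotropy. SEs carry the
  same max(1, σ̂) multiplicative floor.

Ratio weights ignore measurement error in βX (the no-measurement-error
approximation standard to these estimators); with consortium-scale
exposure GWAS the exposure SEs are an order of magnitude below the
outcome SEs, and the simulation tests quantify the residual effect. The
grid runner applies all six methods to every exposure-outcome pair,
marking per-cell failures (e.g. too few instruments) without aborting,
and flags significance at α/(K·outcomes) — 0.05/30 ≈ 0.0017 for the full
panel.

## Multivariable MR with Bayesian model averaging

With correlated traits, univariable MR cannot say *which* trait carries
the signal. The multivariable stage standardizes by the outcome SE
(response yⱼ = βYⱼ/seYⱼ, design xⱼₖ = βXⱼₖ/seYⱼ) so the residual
variance is approximately 1, then scores every non-empty exposure subset
S up to `max_model_size`:

* marginal likelihood: y ~ N(0, I + σ²X_S X_Sᵀ), the closed form of
  independent N(0, σ²) priors on included coefficients with unit residual
  variance, evaluated through the |S| x |S| Gram matrix;
* prior: p^|S|(1−p)^(K−|S|), i.e. independent inclusion with probability
  p per trait;
* posterior model probabilities normalized over the enumerated space;
* per-model estimates θ̂ by least squares on the subset columns;
* MIP (sum of PP over models containing a trait) and MACE (PP-weighted
  average of that trait's subset estimates).

Defaults σ = 0.25 and p = 0.1 are the published defaults of the model-
averaging methodology this stage implements; both sit in `bma_config()`.
Fixing the residual variance at 1 keeps the marginal likelihood closed
form; the inverse-variance standardization is what justifies it. The
default `max_model_size = 12` caps enumeration; with K = 15 the full 2¹⁵
space is still feasible by setting it to K. Exactly duplicated exposure
columns make subset least squares rank-deficient; those models fall back
to the minimal-norm solution so exchangeability (equal MIPs for duplicate
columns) is preserved.

**Outlier pruning.** Under each model with PP above 0.02 (or the single
top model when none qualifies), every SNP gets a heterogeneity
contribution qⱼ (squared standardized residual; these sum to the model's
Q) and a classical Cook's distance. A SNP offending in any such model —
qⱼ > 10, or Cd above the median of F(d, J−d) with d the model size — is
removed, and the posterior is refit, up to `max_prune_rounds` times. Two
interpretation choices were genuinely open and are made explicit here:
diagnostics aggregate over *all* high-PP models (a SNP is dropped if any
flags it), and "the relevant F-distribution" is read as F(d, J−d). The
pre-pruning posterior is retained in every result so the before/after
consistency comparison is always available. A hard threshold on a χ²₁
quantity necessarily removes a sporadic clean SNP now and then
(P(χ²₁ > 10) ≈ 0.0016 per instrument); the audit trail records every
removal with its round, statistic and value so such cases are visible
rather than silent.

## Restricted-cubic-spline dose-response

The observational stage fits, per trait and disease, a logistic
regression of case status (cases vs healthy) on a restricted cubic
spline of the trait. The basis is the truncated-power natural-spline
construction: m knots give m−1 columns (linear term plus m−2 cubics),
linear beyond the boundary knots, scaled by the squared boundary span for
conditioning. Knots default to 4 at Harrell's percentiles (5, 35, 65,
95); the knot count is an argument because no placement is canonical for
blood counts. The reported curve is the log odds ratio relative to a
reference value — the healthy-group median, so the curve reads as risk
relative to a typical healthy level — with a pointwise delta-method 95%
band on a 300-point grid (200 is the enforced minimum). Complete or
quasi-complete separation is detected and flagged on the fit rather than
silently returned. Crossings of either band boundary with zero are
located by linear interpolation (grid points exactly at zero count as
crossings) and rounded to 2 decimals, matching how such clinical
thresholds are conventionally reported; all sign changes are returned,
even when they do not pair into clean intervals, and interpretation is
left to the user. Group comparisons are rank-based (Wilcoxon) with an
explicit direction flag. Age/sex adjustment is available behind a flag
but off by default, mirroring a design where groups are age- and
sex-balanced.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions for every downstream check:

* per-SNP exposure effects are sparse (independent Bernoulli masks per
  trait, default 5% of SNPs per trait, applied to correlated Gaussian
  draws with exchangeable correlation 0.3 and effect SD 0.05 per SD of
  trait) — at the default exposure-study size of 563,085 this yields
  per-SNP F statistics in the tens-to-thousands range typical of
  blood-count GWAS;
* the outcome's true per-SNP log-odds effect is Σₖ θₖ·γⱼₖ plus a direct
  (pleiotropic) effect for a configurable fraction of SNPs;
* observed coefficients add Gaussian noise with the SE implied by study
  sizes: 1/√(2f(1−f)·n) for a standardized trait and the standard log-OR
  approximation 1/√(2f(1−f)·n·φ(1−φ)) for the binary outcome, with
  allele frequencies uniform on (0.05, 0.95) to avoid degenerate
  variances; default case/control sizes are the UC study's 6,968/20,464;
* a fraction of outcome rows is reported on the flipped allele
  orientation, and a fraction of SNPs is withheld from the outcome panel
  (preferring SNPs with an LD-block partner, so the proxy rule is
  exercisable);
* `noise = FALSE` produces the exact noiseless limit in which every
  estimator must recover the true effect to machine precision — the
  strongest correctness check in the suite;
* the cohort generator draws lognormal trait values (410 subjects:
  100 healthy, 230 CD, 80 UC; ages 28-54) with multiplicative group
  shifts reproducing the reported direction of every significant
  CD-vs-healthy and UC-vs-healthy difference, e.g. lower lymphocytes in
  CD and higher eosinophils in UC.

What it does **not** emulate: real human LD structure, ancestry-specific
allele frequencies, genomic coordinates, winner's-curse selection bias,
or sample overlap between studies. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery under the
stated generative model, not robustness to those real-data complications.

## Problem sizes and numerical choices in the test suite

The simulation tests use sizes chosen to exercise each property at
adequate Monte-Carlo resolution: calibration of the random-effects IVW
under the null uses 1000 replicates of a 60-instrument single-trait
study (about the 910/15 instruments-per-trait density of a full
consortium analysis), and rejects at most at the nominal Bonferroni rate
within three binomial standard errors; power at a true log-OR of 0.3 is
measured over 200 such replicates. Model-averaging recovery uses 100
replicates of K = 8 traits and J = 150 instruments with a single causal
effect of 0.4, with sparsity 0.125 so each instrument serves about one
trait, emulating a pooled instrument set; the causal trait must attain
the top MIP in at least 90% of replicates. Pruning recovery plants three
direct effects of eight outcome-SEs among 150 instruments — far above
noise yet small enough not to destabilize the round-one fit — and
requires all three to be removed within two rounds in at least 95% of
replicates. Oracle equivalences (weighted least squares, leave-one-out
Cook's distance, quadrature of the marginal likelihood) are asserted at
1e-10 or 1e-6 as appropriate on small instances.

## Known limitations

* Clumping is purely r-squared-based; no genomic windows or per-trait
  clumping (the pooled convention over all traits is used before
  multivariable MR, and per-trait instrument subsets are taken from the
  pooled clumped set for univariable MR).
* Median-estimator SEs are bootstrap-based and therefore seeded;
  different seeds move SEs by Monte-Carlo error, never the point
  estimates.
* The marginal likelihood assumes unit residual variance after
  standardization; strong violations (e.g. severe overdispersion from
  widespread pleiotropy) shift posterior mass toward larger models, which
  is exactly what the pruning diagnostics are there to catch.
* The dose-response stage models one trait at a time; no multivariable
  spline surface is attempted.
* Trait transformation of the exposure GWAS (rank-inverse-normal vs raw)
  is left unmodeled; exposure effects are treated as per-SD throughout.
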