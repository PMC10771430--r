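---
title: "Methods: proteome-wide MR and colocalization with pqtlmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR and colocalization with pqtlmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlmr)
```

## The problem

Circulating proteins are attractive candidate biomarkers and drug targets
for traits of reproductive timing such as age at menarche (AAM) and age at
natural menopause (ANM), but observational protein–trait associations are
confounded and prone to reverse causation. Two-sample Mendelian
randomization (MR) addresses this by using a genetic variant that robustly
alters a protein's circulating level — a *cis*-pQTL, lying within 1 Mb of
the encoding gene's transcription start site — as an instrumental
variable: the variant's effect on the outcome, divided by its effect on
the protein, estimates the causal effect of the protein in outcome units
per SD of protein. `pqtlmr` implements the full analytic chain of such a
proteome-wide screen: instrument selection, MR estimation, directionality
testing, Bayesian colocalization, mediation through BMI, multivariable
MR, and analytic power — together with a synthetic GWAS generator that
gives every stage a ground-truthed test surface without downloading any
real summary statistics.

## The synthetic generator

Real cis regions enter the pipeline only as summary statistics, so the
generator works directly at that level. For one region with LD matrix $R$
(default AR(1): $R_{ij} = \rho^{|i-j|}$, positive definite for
$\rho \in [0,1)$; a block-diagonal option serves two-signal scenarios),
the marginal z-scores of one trait are drawn as

$$ z \sim N(R\,\lambda,\; R), $$

the standard multivariate model for GWAS z-scores under joint causal
effects. The non-centrality of a causal variant explaining a fraction
$r^2$ of a standardized trait in a GWAS of $n$ samples is
$\lambda = \sqrt{n\,r^2/(1-r^2)}$, so the expected squared z-score at the
causal variant is $1 + n r^2/(1-r^2)$ — a closed form the test-suite
checks against the simulation. z-scores are converted to per-allele
effects on the standardized-phenotype scale with
$\mathrm{se} = 1/\sqrt{2 f (1-f) n}$, consistent with the
variance-explained approximation $R^2 \approx 2\beta^2 f(1-f)$ used
throughout. Exposure, outcome and mediator draws are independent given
the truth: the two-sample, no-overlap design.

Six causal models cover the study's scenario space: `null`;
`shared_causal` (one variant drives the protein, and the protein's effect
$\theta$, in outcome-SD units per protein SD, propagates it to the
outcome — the colocalization H4 case); `two_causal_in_ld` (distinct
causal variants correlated at `ld_causal` — the H3 case);
`mediated` (protein → mediator path $a$, mediator → outcome path $b$,
optional direct $\theta$; the outcome inherits $\theta + ab$ times the
variant's protein effect); `reverse` (the outcome owns the causal
variant and the protein inherits a downstream echo, so the Steiger test
should return FALSE); and `pleiotropic` (a direct variant → outcome
effect violating exclusion restriction).

Default study conditions mirror the proteomic and reproductive-timing
GWAS being emulated: exposure GWAS of ~3,000 samples (the scale of the
major proteomic panels), outcome GWAS of 370,000 (AAM) with 200,000 used
in reverse-MR panels (ANM-scale), instrument $r^2 = 0.1$, minor allele
frequencies in (0.05, 0.5). Two additional generators are part of the
same module: `simulate_mr_instruments()` (mutually independent
instruments for multi-instrument estimators, each explaining
`r2_per_snp` of the exposure) and `simulate_reverse_panel()` (a
block-diagonal genome of genome-wide-significant outcome loci to be
clumped, with an optional outcome → protein effect `kappa`).

What the generator deliberately does not emulate: sample overlap between
exposure and outcome GWAS, allele-frequency mismatch between studies,
imputation noise, population stratification, and real LD panels. Passing
tests therefore demonstrate correctness of the estimators under the
stated sampling model, not robustness to those artefacts of real data.
Phenotypes are assumed standardized throughout (the source proteomic
GWAS use rank-normalized levels; their exact transformations are not
modelled).

## Instrument selection and strength

`select_cis_pqtl()` keeps variants within 1 Mb (inclusive) of the
transcription start site passing $p \le 5\times10^{-8}$ (both
configurable; some proteomic GWAS apply study-specific thresholds),
ranked by p-value. Strength metrics use the printed formulas:
$R^2 \approx 2\beta^2 f(1-f)$ and
$F = (R^2/k) / \left[(1-R^2)/(n-k-1)\right]$ with $k=1$ for
single-instrument cis MR; $F>10$ is the conventional adequacy bound.
Variants missing allele frequency are ineligible for $R^2$, Steiger and
colocalization and are dropped with a message. When the lead pQTL is
absent from the outcome GWAS, `find_proxy()` takes the candidate with
the highest squared LD above 0.8 (strict), breaking ties by candidate
p-value and then position — a stated convention, since tie-breaking has
no canonical rule. `clump()` is the greedy algorithm: take the
smallest-p significant variant, discard everything with $r^2 \ge$
threshold to it, repeat; the output is mutually quasi-independent by
construction and the tests assert that exhaustively. "Conditionally
independent" pQTLs from source publications are treated as given input;
no conditional analysis is re-run.

## Harmonization

`align_alleles()` re-expresses an outcome record on the exposure's
effect allele: swapped alleles flip the effect sign and frequency,
complementary alleles are strand-corrected, and palindromic (A/T, C/G)
variants are oriented by allele frequency. Palindromic variants with
frequency in [0.42, 0.58] in either study are flagged ambiguous and
excluded by `harmonize()` — the common default band of harmonization
tooling; the band is configurable because no universal value exists.
Alignment is idempotent, which the suite checks property-style.

## MR estimators

* **Wald ratio** (the primary single-instrument estimator):
  $\hat\theta = \beta_Y/\beta_X$ with first-order delta-method
  $\mathrm{se} = |\mathrm{se}_Y/\beta_X|$, the convention of standard MR
  tooling (it ignores exposure-side noise; a second-order option is
  available behind a flag). Two-sided normal p-values throughout.
* **IVW**: the inverse-variance-weighted mean of per-variant ratios,
  identical to zero-intercept weighted regression of $\beta_Y$ on
  $\beta_X$ with weights $1/\mathrm{se}_Y^2$. When Cochran's $Q$ exceeds
  its degrees of freedom the standard error is inflated by
  $\sqrt{Q/(n-1)}$ (multiplicative random effects); below that,
  fixed-effect. The forward proteome-wide screen is single-instrument,
  so this choice matters only for the multi-instrument reverse arm.
* **MR-Egger**: weighted regression with intercept after orienting all
  $\beta_X \ge 0$; the intercept tests directional pleiotropy.
* **Weighted median / weighted mode**: median of ratio estimates under
  cumulative inverse-variance weights; mode of a kernel-smoothed
  weighted ratio density with bandwidth 1.5× a Silverman-style rule.
  Both get parametric-bootstrap standard errors (5,000 draws by default,
  fixed seed for reproducibility; `nboot = 0` skips the bootstrap when
  only point estimates are needed in simulations).
* **Steiger directionality**: compares $2\beta^2f(1-f)$ in exposure vs
  outcome; TRUE when the instrument explains more exposure variance.
  The p-value compares the implied correlations by Fisher's z-transform
  with the two sample sizes — a stated decision, as the reference
  implementation's internals are not documented.
* **Power**: Brion-style analytic power for a continuous outcome,
  $\Phi(-z_{1-\alpha/2} + |b|\sqrt{nR^2}) + \Phi(-z_{1-\alpha/2} -
  |b|\sqrt{nR^2})$ with $b$ the effect in outcome-SD units. The
  acceptance suite cross-checks it against the Monte-Carlo rejection
  rate of the simulated Wald pipeline at a mid-power operating point.
* **Bonferroni**: `alpha / m` where `m` is the number of distinct
  proteins actually tested in the run, mirroring the study convention
  (0.05/1271 and 0.05/1349 for the two outcomes).

## Colocalization

Per-variant evidence is the Wakefield approximate Bayes factor
$\log\mathrm{ABF} = \tfrac12\log(1-r) + \tfrac12 z^2 r$ with
$r = w/(w+V)$, prior effect variance $w = 0.15^2$ (suited to
standardized quantitative traits; configurable) and $V$ the squared
standard error. `coloc_abf()` enumerates H0–H4 with per-SNP priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (the standard defaults; no
values are stated in the source analyses), over variants with MAF > 0.01
within 1 Mb of the pQTL. All accumulators run in log space, so $|z|$ of
several hundred cannot overflow; in a single-SNP region the H3
accumulator is exactly zero and the function warns, while in larger
regions a non-positive accumulator is benign cancellation under one
dominant shared signal and is clamped silently.

`susie_rss()` relaxes the single-causal-variant assumption: a
sum-of-single-effects model on summary statistics ($X'X = nR$,
$X'y = \sqrt n\,z$, residual variance fixed at 1, per-effect prior SD
0.15), iterating up to `L = 10` single-effect components until the
posterior-mean effects move less than `tol`. The LD matrix gets a
$10^{-4}$ diagonal ridge for numerical stability. Each component's 95%
credible set is the smallest inclusion-probability set reaching
coverage; sets below 0.5 purity (minimum absolute pairwise LD) are
discarded, which removes the diffuse sets of null components.
`coloc_susie()` then runs the H0–H4 enumeration on every pair of
surviving components' per-variant log Bayes factors — the mechanism that
rescues colocalization when a second, independent signal dilutes the
single-variant H4.

`multi_trait_coloc()` is an explicit simplification of regional
multi-trait colocalization (and is labelled as such in its output): it
sums log ABFs across traits per variant and weighs the all-shared
configuration against the null and every all-but-one configuration.
Below a posterior of 0.25 no candidate variant is reported (the "NA"
convention). It is invariant to trait order. The full branch-and-bound
regional selection of dedicated multi-trait methods is out of scope.

## Mediation and multivariable MR

`two_step_mediation()` multiplies the protein → mediator and
mediator → outcome MR estimates; the Sobel standard error is the
first-order form $\sqrt{a^2\mathrm{se}_b^2 + b^2\mathrm{se}_a^2}$ (the
classical test; the second-order variant adding
$\mathrm{se}_a^2\mathrm{se}_b^2$ sits behind a flag). The proportion
mediated, indirect/total, is reported unclamped with a warning outside
[0, 1]. `mvmr_ivw()` regresses variant–outcome effects on the matrix of
variant–exposure effects (weights $1/\mathrm{se}_Y^2$, no intercept)
over the union of the exposures' instruments; collinear exposures are a
named error, an exposure with all-zero instrument effects is reduced
out with a warning (its presence cannot change the others' estimates),
and a single-exposure call reproduces univariable IVW exactly.

## The screen and its bookkeeping

`run_forward_screen()` ties the stages together per protein —
instrument selection with proxy fallback, Wald MR, Bonferroni flag at
$\alpha/m$ with $m$ the proteins actually tested, Steiger, then both
colocalization variants for the Bonferroni-significant hits — with
per-protein failure isolation (an error marks that protein's row and
the screen continues). `run_reverse_mr()` clumps the outcome GWAS at
$p < 5\times10^{-8}$, $r^2 < 0.001$, runs IVW/Egger/median/mode of
outcome → protein, and tabulates which methods reach nominal
significance, the reporting style used for reverse-causation positives
such as luteinizing-hormone subunit B. Reports are deterministic given
config and seed, and every run can be reproduced from its persisted
YAML config alone. The CLI (`inst/scripts/pqtlmr.R`) is a thin wrapper
exposing `simulate`, `screen`, `reverse`, `mediate`, `mvmr`, `coloc`
and `power` subcommands over these functions.

## Numerical and design choices

* Coordinates are 1-based and the cis window inclusive on both sides.
* Simulated p-values are floored at the smallest positive double so
  that extreme signals ($|z| > 38$) remain representable and valid.
* The degenerate Wald case $\beta_X = 0$ is an error, not NaN.
* Bootstrap seeds default to a fixed value so that repeated calls are
  reproducible; simulation functions save and restore the caller's RNG
  state.
* Problem sizes in the test suite — regions of 20–100 variants,
  100–500 replicates per scenario, 2,000-replicate calibration checks —
  were chosen as the smallest sizes at which the Monte-Carlo error of
  each check is comfortably below the property being asserted.
* In the Egger calibration suite the intercept statistic is compared to
  a normal reference, so the check uses 30 instruments, where the
  statistic's finite-sample t distribution is close enough to normal
  for the nominal level to apply.

## Known limitations

Reported H4-style posteriors from the original full summary statistics
are not reproducible from synthetic data; the package's validation is
scenario-level recovery (H4 dominance under a shared variant, H3 under
two variants in LD, the credible-set rescue under two signals).
Weak-instrument bias of the Wald estimator is documented behaviour, not
corrected. The multi-trait operation is a single-variant scan, not a
regional multi-signal selection. No annotation, pathway, enrichment or
drug-target lookups are included.
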