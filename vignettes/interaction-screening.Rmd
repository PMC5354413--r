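---
title: "Simulating, testing and screening interaction effects in expression data"
author: "interscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating, testing and screening interaction effects in expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`interscreen` does three connected things:

1. simulates quantitative outcomes (gene expression phenotypes) under a
   generative model with a SNP, an interacting exposure, a non-interacting
   covariate and a residual, with *exact* variance-fraction calibration;
2. tests SNP-by-exposure interactions under five analysis strategies and
   summarizes batches of such tests with the standard calibration metrics
   of genetic association studies;
3. runs a two-step cis-eQTL SNP-by-transcription-factor trio screen on
   genotype/expression matrices with genomic coordinates, under four
   strategy variants.

This vignette explains the model and its assumptions, the tunable
parameters and the defaults chosen where a choice was genuinely open, the
numerical conventions, and what the synthetic data do and do not emulate.

# The generative model and its calibration

A cohort is drawn from

$$Y = \gamma_G G + \gamma_E E + \gamma_{GE}\,G E + \gamma_Z Z + \varepsilon,$$

where $G$ is a biallelic dosage (0/1/2) drawn under Hardy–Weinberg
equilibrium at a coded-allele frequency (CAF) in $(0, 0.5]$, and $E$, $Z$
are continuous exposures. In the eQTL reading, $E$ is the mRNA level of a
transcription factor that truly modifies the SNP effect, and $Z$ is
whatever factor the analyst happens to test.

Effect sizes are parameterized as **variance fractions** $\tau$. With all
predictors standardized to mean 0 and variance 1 and mutually independent,
a term with coefficient $\gamma$ contributes $\gamma^2$ to $\mathrm{var}(Y)$
— including the product term, because
$\mathrm{var}(GE) = E[G^2]E[E^2] = 1$ when $E[G] = 0$. So
`coefFromTau(tau)` returns $\sqrt\tau$, and the residual is scaled to
$1 - \sum\tau$, giving $\mathrm{var}(Y) = 1$ exactly in expectation.

Two deliberate conventions:

* **Genotypes are standardized with theoretical moments** ($2\,\mathrm{caf}$
  and $\sqrt{2\,\mathrm{caf}(1-\mathrm{caf})}$), not sample moments, so the
  calibration is unbiased at any sample size.
* **A nonzero exposure mean (`meanE`) only shifts offsets.** The generative
  sum uses the centered exposure; the stored exposure is the centered draw
  plus `meanE`. This keeps variance fractions exact while reproducing
  plots of $Y$ against an exposure centered at, say, 5.

The `"right_skew"` distribution is a skew-normal with slant $\alpha = 5$,
recentred and rescaled analytically to mean 0 and variance 1. The slant is
a free parameter of the design: 5 gives a visually pronounced right skew
(skewness $\approx 0.851$ by the closed-form skew-normal moments) while
keeping all moments finite; `sampleSkewed(n, alpha = 0)` degenerates to the
standard normal, which the tests use as an internal consistency check.

## The randomized-effects (robustness) grid

The robustness study draws, per replicate, the active coefficients from
$\mathrm{Uniform}(0,1)$ and asks whether the *null* G-by-Z interaction test
stays calibrated when the outcome truly carries a G-by-E interaction with
an unmeasured E. The grid spans sample size $\{100, 500, 1000, 5000\}$,
CAF $\{0.05, 0.3, 0.5\}$, all-normal vs all-right-skewed continuous
variables, and four main-effect regimes (E only, Z only, both, neither) —
96 cells; the SNP main effect and the interaction are always drawn.

How strongly the drawn coefficients should explain the outcome is
under-determined by "explained variance varies from 0 to 80%", so both
readings are implemented behind `epsRule`:

* `"uniform_r2"` (default): draw a target $R^2 \sim U(0, 0.8)$ per
  replicate, compute the systematic variance $S = \sum\gamma^2$, and set
  $\mathrm{var}(\varepsilon) = S(1/R^2 - 1)$, which realizes the target
  exactly;
* `"unit"`: fix $\mathrm{var}(\varepsilon) = 1$ and let the coefficient
  draws imply the explained fraction.

The default makes the stated range exact by construction; the alternative
is retained because it is the other natural reading.

`runGridCell()` additionally accepts `dist = "mixture"` and
`regime = "mixture"` (distribution regime drawn per replicate; the
unmeasured exposure always active, the measured covariate in half the
replicates) — the pooled condition used when a single sample-size/CAF panel
summarizes several regimes.

Reproducibility uses one root seed with L'Ecuyer-CMRG substreams
(`useSubstream(seed, index)`): any cell can be recomputed in isolation, in
any order, bit-identically.

# The five testing strategies

All strategies fit by OLS and test one interaction coefficient with a
1-df Wald statistic referred to $\chi^2_1$:

* **std** — naive covariance $\hat\sigma^2 (X'X)^{-1}$;
* **hc0** — White sandwich
  $(X'X)^{-1} X' \mathrm{diag}(\delta_i^2) X (X'X)^{-1}$;
* **hc3** — jackknife flavor, $\delta_i^2/(1-h_{ii})^2$, the recommended
  small-sample choice (undefined, and refused, when a point has leverage 1);
* **bin** — the exposure replaced by a median-split indicator (values
  below the median map to 0, values at or above it to 1 — the "smaller
  than" rule read literally, deterministic under ties);
* **sat** — genotype dummy main effects for $G=1$ and $G=2$ (reference
  $G=0$, intercept kept), main effects of $Z$ and $Z^2$, and the ordinal
  $G \times Z$ term under test. An empty genotype class (no minor-allele
  homozygotes at low CAF) drops its dummy and records the fact; the fit
  errors only if $G$ is constant.

The $\chi^2_1$ reference (rather than a $t$ reference) is intentional:
small-sample anticonservatism of the Wald tests is part of the phenomenon
under study. A `reference = "t"` option exists for sensitivity analyses.

An intercept is always included even though the screening model is usually
written without one; this is standard practice and required for the
dichotomized and saturated variants to be comparable.

The rank-based inverse normal transformation maps value $i$ to
$\Phi^{-1}((r_i - 0.5)/n)$ with tie-averaged ranks $r_i$. A Blom offset
($(r - 3/8)/(n + 1/4)$) is available behind a flag; the half offset is the
default because the difference is negligible at the sample sizes involved
but must be pinned for bit-reproducibility. The output is not rescaled by
the sample SD afterwards — the quantile map is already asymptotically
unit-variance, and rescaling would break the exact symmetry
`out[i] = -out[n+1-i]`.

# Evaluation metrics

* `type1Error(p, alpha)` — the rejection fraction at `alpha`.
* `lambdaGC(p)` — median of the $\chi^2_1$-transformed statistics over the
  $\chi^2_1$ median (0.4549...), the GWAS convention. Inputs must lie in
  $(0, 1]$; the trio screen floors underflowed p-values at 1e-300 so this
  stays defined in signal-rich data.
* `qqPoints(p)` — observed vs expected $-\log_{10} p$ at half-offset
  positions, with optional Beta order-statistic 95% envelopes.
* `varianceByGenotype(delta, gRaw, eps)` — within-genotype variances of the
  fitted residual $\delta$ and the true residual $\varepsilon$, and their
  difference. Subtracting $\varepsilon$ makes models with different
  residual scales comparable; under a G-by-E interaction with unmeasured E,
  the conditional-variance identity gives
  $\mathrm{var}(\delta \mid G=g) - \mathrm{var}(\varepsilon \mid G=g)
  \approx (\gamma_E + \gamma_{GE}\, g_{std})^2$, the quadratic-in-dosage
  signature the test suite checks at $n = 10^6$.

`runTauSweep()` drives the interaction-fraction sweep (default
$\tau = 0$ to $0.3$, $n = 400$, 10,000 replicates per point, the active
main effect matched to $\tau$). Its default CAF is 0.1, the SNP frequency
used throughout the single-SNP generative experiments; rare alleles give
the heteroscedasticity more leverage, and at CAF 0.3 the inflation at
$\tau = 0.3$ is roughly half as large.

`nullSelectedR2()` answers a selection question: if all associations were
null, what effect sizes would survive an FDR cut? The per-test p threshold
is reconstructed as the Benjamini–Hochberg boundary $q\,k/m$; the null
$r^2$ of a single-predictor regression on $n$ samples is
$\mathrm{Beta}(1/2, (n-2)/2)$; the p threshold maps to an $r^2$ threshold
through the $F(1, n-2)$ relation; the reported mean is the truncated-Beta
mean (analytic by default, with a Monte-Carlo route retained as a
cross-check), and the expected maximum over $m$ draws is computed by
integrating $1 - F^m$. A BH-style threshold is used because the original
q-value method is a per-study choice; the threshold itself is an input.

# The trio screen

`generateScreeningDataset()` emulates the matrices of a blood eQTL study:
per-SNP CAF from $U(0.05, 0.5)$, Hardy–Weinberg dosages, standard-normal TF
expression, and target expression assembled on the variance-fraction scale
with unit total variance. Planted layers — cis effects (default
$\tau \in [0.3, 0.6]$, emulating the large marginal effects seen for
cis-eQTLs), TF main effects, measured SNP-by-TF interactions, and
SNP-by-*hidden*-factor interactions — are recorded in a truth ledger.
Each target's co-located SNP sits within 100 kb; remaining SNPs and all
TF probes are placed uniformly over a small synthetic genome (5 chromosomes
of 200 Mb by default), so cis-proximal and distal features both exist. If
a target's planted fractions sum beyond 0.9 they are rescaled
proportionally (the realized values go into the ledger). Hidden-interaction
targets also receive a measured-TF main effect, so the spurious,
heteroscedasticity-driven signal concentrates among strongly associated
TFs — the configuration in which stratifying the inflation factor by TF
marginal p-value is informative.

The pipeline itself:

1. `selectCisEqtls()` tests every same-chromosome SNP–target pair within
   250 kb (inclusive, single representative coordinate per feature, since
   no transcript-interval convention is imposed), BH-adjusts across all
   tested pairs, keeps $q \le 0.01$, and retains the most significant SNP
   per probe (ties broken by SNP id).
2. `buildTrios()` pairs each hit with every TF probe passing the marginal
   filter ($p < 0.05$ against the target, computed on the same expression
   matrix fed to the interaction tests) and the exclusion rule (more than
   10 Mb from the SNP, or another chromosome).
3. `screenTrios()` computes std, h3, rkt and rkt.h3 p-values per trio,
   dense ranks per strategy (ties broken by trio order for determinism)
   and significance flags at $10^{-8}$. Monomorphic SNPs skip the trio
   with a flag.
4. `stratifiedLambda()` reports per-strategy $\lambda_{GC}$ within strata
   of the TF marginal p-value, flagging strata with fewer than 100 tests.

Step 1 uses an OLS Wald test of the additive dosage effect; a score test
is asymptotically equivalent here and the pipeline's conclusions do not
depend on the form. Only probes not flagged as TFs are treated as targets
in step 1, which keeps the synthetic truth unambiguous.

# What the synthetic data do not emulate

No linkage disequilibrium, haplotypes or multi-SNP architecture; no
missing genotypes; no confounding structure between covariates and
predictors; no probe-level technical noise, batch effects or the upstream
normalization pipeline (log/quantile normalization and principal-component
residualization are assumed done); no RNA-Seq count models. Passing tests
therefore demonstrate the statistical behavior of the estimators under the
stated generative model — not robustness to the technical artifacts of any
particular platform.

# Numerical choices and degenerate inputs

* OLS goes through a QR decomposition; rank deficiency is an error naming
  the collinear columns. The replicate-heavy drivers use an equivalent
  Cholesky path (cross-checked against the QR path and against an
  independent sandwich implementation to 12 significant digits).
* `lambdaGC` requires at least 100 p-values before it is reported by the
  grid drivers; medians over fewer tests are too noisy to summarize.
* Constant outcomes, monomorphic SNPs and constant exposures are contract
  errors, not silent NAs; sparse genotype classes (fewer than 2
  observations) are excluded from variance profiles with a warning.
* Matrix I/O is plain TSV (samples in rows); dosages are validated into
  [0, 2] with the offending cell named. Missing expression values are
  tolerated at load time and dropped per-test downstream. VCF input is a
  convenience converter (DS field if present, otherwise GT allele counts),
  not the internal representation.

# Problem sizes used by the shipped checks

The test suite and the acceptance script run at sizes chosen to make
Monte-Carlo noise small relative to the assertions they make: 10,000
replicates for the null-calibration check (binomial SE 0.0022 at the 0.05
level), 20,000 replicates for inflation-factor checks
($\lambda_{GC}$ SE $\approx 0.02$), $10^6$ observations for closed-form
moment comparisons, and a few thousand trios for end-to-end screening
calibration. The full 96-cell grid at these replicate counts is a
several-hour computation and is exposed through `runGrid()` /
`interscreen grid` rather than run routinely; every cell is independently
reproducible from the root seed.

# Known limitations

* The HC3 correction restores calibration at moderate-to-large sample
  sizes and common alleles; nothing here rescues $n \approx 100$ or rare
  variants, where all five strategies are anticonservative.
* The saturated model absorbs quadratic exposure effects only; other
  non-linear main effects can still masquerade as interactions.
* The trio screen's marginal TF filter is a power heuristic; because TFs
  correlated with the target by chance are preferentially selected, trios
  on targets carrying real (hidden) interactions are mildly enriched for
  partially true signals, which inflates all strategies slightly in
  signal-rich synthetic data.
* Interaction effects remain scale-dependent: the rkt variants answer a
  different scientific question than the raw-scale variants, and the
  package treats the choice of scale as the analyst's hypothesis, not a
  nuisance to optimize away.
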