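---
title: "Multilevel plasticity evolution under environmental predictability: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel plasticity evolution under environmental predictability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastevol)
```

# The scientific problem

Theory predicts that phenotypic plasticity should evolve to match the
predictability of environmental fluctuations: when the environment at
induction reliably predicts the environment of selection, high plasticity
pays; when it does not, plasticity produces mismatched phenotypes and is
selected against. `plastevol` implements a complete analysis chain for
testing this prediction across three biological levels — DNA methylation,
gene expression and cell morphology — in populations of a halotolerant
microalga experimentally evolved under randomly fluctuating salinity with
controlled autocorrelation, then assayed at a low (0.8 M NaCl) and a high
(4.0 M NaCl) salinity.

The package has two halves:

1. a **synthetic-data generator** that emulates every input of such an
   experiment (AR(1) salinity histories, per-cytosine bisulfite counts,
   transcript counts, per-cell morphology, annotation and GO maps) with
   *planted*, known effects; and
2. the **analysis chain** itself: DMR calling, negative-binomial
   differential expression, partial redundancy analysis, plasticity
   distances regressed on realized predictability, and GO
   over-representation.

Running the analysis on the generator's output with known ground truth
turns the whole pipeline into a testable object: planted effects must be
recovered, null configurations must produce nominal false-positive rates.

# The environmental driver

Salinity at transfer $t+1$ follows a stationary AR(1) law
$$s_{t+1} = \mu + \rho\,(s_t - \mu) + \varepsilon_t, \qquad
\varepsilon_t \sim \mathcal N\!\big(0,\ \sigma^2 (1-\rho^2)\big),$$
with $s_0 \sim \mathcal N(\mu, \sigma^2)$. The innovation variance is
$\sigma^2(1-\rho^2)$ *by construction*, so that the stationary mean and
SD are $\mu$ and $\sigma$ for every $\rho$: treatments share long-term
moments and differ only in predictability $\rho^2$, the fraction of
temporal variance explained by the previous salinity. Defaults are
$\mu = 2.4$ M, $\sigma = 1$ M and target $\rho \in \{0, -0.5, 0.9\}$,
i.e. predictability $\rho^2 \in \{0, 0.25, 0.81\}$.

Design choices worth making explicit:

* **Clipping.** Simulated salinities are clipped to a feasible interval,
  by default $[0, 4.8]$ M — the range achievable by mixing the hypo-
  (0 M) and hyper-saline (4.8 M) media (`mixing_volumes()` solves the
  salt mass balance, accounting for the inoculate). Whether an
  out-of-range draw should be clipped or redrawn is not dictated by the
  design; clipping is our documented choice and the bounds are
  configurable. Clipping slightly shrinks the realized SD at high
  $|\rho|$, one reason to regress on *realized* rather than target
  predictability.
* **Realized predictability.** For each finite series, realized $\rho$
  is the plain Pearson correlation of consecutive-transfer pairs
  $(s_t, s_{t+1})$, ignoring the alternating 3/4-day spacing (no spacing
  correction is part of the estimator's definition), and excluding any
  acclimation period. Its square is the regressor used by the
  plasticity analysis.
* **Series length.** The default 143 transfers corresponds to roughly
  500 generations at one generation per day with transfers twice a week;
  a series holds `n_transfers + 1` values (initial state included).
* **Seeding.** One master seed; per-population streams are derived
  deterministically (`master + 104729 k mod 2^31-1`), so populations are
  independent but the whole design is reproducible bit-for-bit.

# What the generator plants, and why

The generator's defaults define the study conditions; they were chosen
once, to mirror the *qualitative* structure such an experiment produces,
and are not tuned to any particular analysis outcome:

* **Design**: 3 treatments × 3 populations × 2 assay salinities
  (18 samples), 150 cells per sample.
* **Methylome**: 10,000 CpG-context cytosines scattered over 1,000
  non-overlapping 100-bp windows of one synthetic chromosome; coverage
  negative-binomial with mean 40 (deep whole-genome bisulfite scale);
  window-level baseline proportions Beta(2, 5) across background
  windows. Planted salinity-responsive windows number 4/12/24 in the
  low/intermediate/high-predictability treatments — non-decreasing in
  $\rho^2$ and *disjoint* across treatments — with shifts of
  +30 to +45 percentage points (always beyond the 20-point calling
  cutoff) on uniform(0.15, 0.45) baselines so shifted proportions stay
  in range. A further 15 windows differ among treatments in proportion
  to each treatment's predictability score.
* **Transcriptome**: 2,000 transcripts (a desk-scale stand-in for a
  full transcriptome — scale parameters matter for runtime, not
  correctness), log2 baselines $\mathcal N(7, 1.5^2)$, gene-wise
  dispersions log-normal around 0.05, library size factors log-normal
  (SD 0.15). Planted |log2FC| are drawn uniform(1.5, 3) with random
  sign — always beyond the |log2FC| > 1 cutoff and varied enough that
  effect-recovery regressions have leverage. Salinity-responsive
  transcripts comprise a 60-transcript core shared by all treatments
  plus treatment-private sets of 6/16/36 (growing with $\rho^2$);
  40 transcripts carry a $\rho^2$ main effect and 30 a
  predictability-graded salinity interaction.
* **Morphology**: three flow-cytometry-like channels (forward scatter,
  side scatter, red fluorescence; arbitrary units). Each population's
  between-salinity mean displacement has Euclidean norm
  $1 + 2\rho^2_{\text{realized}} + \mathcal N(0, 0.2)$ in a random
  direction — the planted linear plasticity–predictability relation —
  with cells trivariate-normal around the salinity-specific mean
  (per-channel SD 2, so 150 cells estimate the mean displacement with
  small error).
* **Annotation**: transcripts placed with random strand and TSS on the
  synthetic chromosome; ~30% of transcripts receive at least one GO
  term (a typical assignment rate for a de novo annotation of a
  non-model alga); planted DE sets each receive a dedicated enriched
  term covering ~70% of the set.

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: sequence content and read-level artefacts
(mapping bias, bisulfite conversion error, PCR duplicates), biological
replicate overdispersion of methylation proportions beyond binomial
sampling, correlated gene modules, cytometer channel distributions
beyond trivariate normality, and any demographic or selective dynamics
of the evolving populations (only the environmental driver is
simulated).

# The analysis chain

## Differential methylation

Cytosines are kept if they have the requested context (CpG by default)
and coverage ≥ 10 in *every* sample, then pooled across strands into
non-overlapping 100-bp windows (a cytosine at 1-based position $p$ maps
to window $\lfloor (p-1)/100 \rfloor$; windows are 0-based half-open).
For a two-group contrast, counts are pooled *within group* by summing
across the group's samples, and each window is tested with a two-sided
Fisher exact test (minimum-likelihood rule for two-sidedness) on the
pooled 2×2 table. Significance is conjunctive: BH-adjusted $q < 0.05$
*and* |methylation difference| > 20 percentage points (second group
minus first; high minus low salinity for salinity contrasts). Each
contrast forms its own BH family. Comparisons among more than two
groups are run as all pairwise two-group tests with a union of
significant windows, since the exact-test framework is 2×2.

Pooling is the price of the exact-test framework: replicate-level
biological overdispersion is ignored, which makes the test anticonservative
against between-replicate variability that the generator does not plant.
Under the generator's binomial sampling the test is if anything
conservative, because the hypergeometric null is discrete — the null
false-positive rate sits *below* nominal, and the calibration check is
accordingly a one-sided bound.

The window-inclusion rule (`min_cytosines_per_window`, default 1) is
exposed in the configuration rather than fixed, since different window
universes are defensible.

For *cis* analysis, each cytosine is assigned to the transcript whose
TSS is nearest in absolute genomic distance (ties break toward the
lower TSS coordinate, then the first transcript id), cytosines sharing
a transcript are merged into one gene-associated region, and the same
pooled test is applied at the region level; `cis_concordance()` then
counts regions whose transcript is also differentially expressed for
the same comparison.

## Differential expression

Counts are normalized with median-of-ratios size factors. Each
transcript is fitted with a log-link negative-binomial GLM (offset
log size factor) by Fisher-scoring IRLS, deterministic given the data.
The model is `~ treatment + salinity + treatment:salinity`, both
factors categorical. Gene-wise dispersion is estimated once per
transcript by maximizing the Cox–Reid adjusted profile likelihood over
$\log \alpha$ (method-of-moments initialization, floor $10^{-8}$,
method-of-moments fallback on failure). The Cox–Reid adjustment
$-\tfrac12 \log\det(X^\top W X)$ corrects the downward bias of the
plain profile MLE that estimating the mean coefficients induces; without
it, at $n = 18$, Wald tests are visibly anticonservative.

Tests:

* **salinity within a treatment**: Wald $z$ = coefficient / SE (SE from
  the Fisher information at the optimum), two-sided normal $p$;
* **salinity overall**: likelihood-ratio test dropping salinity and
  interaction;
* **evolution ($\rho^2$)**: LRT dropping treatment and interaction;
* **evolution of plasticity**: LRT dropping only the interaction,
  statistic $2(\ell_{\text{full}} - \ell_{\text{red}})$ clipped at 0
  against $\chi^2_{df}$.

Significance is again conjunctive: $q < 0.05$ and |log2FC| > 1 (for
LRTs, the largest-magnitude log2FC among the dropped coefficients; the
threshold is configurable, and setting it to 0 recovers a pure-FDR
rule). Effects are reported in log2 by dividing natural-log
coefficients by $\ln 2$. Non-converged fits get `NA` p-values and are
excluded from the BH family.

This is a deliberately simplified NB-GLM engine: gene-wise dispersion
without empirical-Bayes shrinkage toward a trend, no log2FC shrinkage,
no independent filtering, no outlier handling. The inferential logic
(NB GLM + Wald + LRT + BH + fold-change cutoff) is the object of
interest; the shrinkage machinery of production DE engines is out of
scope, and the package's tests pin the engine to independent oracles
(exact Poisson-limit equality, chi-square reference, null calibration)
rather than to another implementation.

Because the Wald reference is the normal rather than a $t$ law, a mild
finite-sample inflation of the type-I rate remains at small $n$ (at
$n = 18$, roughly 0.07 at a nominal 0.05, driven by the
dispersion-estimation noise); the null-calibration test therefore runs
in an asymptotic regime ($n = 60$) where the normal reference is
accurate. The variance-stabilized matrix used downstream is the shifted
log of normalized counts, $\log_2(\text{count}/s_j + 1)$ — a simple
transform with the same contract as regularized-log transforms.

## Partial redundancy analysis

`partial_rda()` centres the response matrix, residualizes response and
design columns on the covariates, regresses by least squares, and takes
the principal components of the fitted values as constrained axes. Each
term's $R^2$ is *marginal* — the drop in explained variance when that
term alone is removed from the full conditioned model — as a fraction
of the conditioned total variance; the adjusted value uses the Ezekiel
formula $1-(1-R^2)(n'-1)/(n'-m-1)$ with the covariate degrees of
freedom removed from the sample count first ($n' = n - df_{\text{cov}}$,
the semi-partial convention, stated here because adjustment conventions
differ between implementations). Significance comes from ANOVA-like
permutation tests (999 randomizations by default) under the
Freedman–Lane scheme: residuals from the reduced model (covariates +
other terms) are row-permuted, re-added to the reduced fit, and the
marginal pseudo-$F$ recomputed; $p = (1 + \#\{F^\ast \ge F\})/(1 + n_p)$.

One structural point matters for this design: population identity is
*nested* in treatment, so once population enters as a covariate the
treatment main effect is exactly collinear with the population dummies
and cannot be tested in the conditioned model. `partial_rda()` treats
aliased columns as an error by default (naming them), with an explicit
`drop_aliased` escape hatch. The pipeline therefore tests salinity and
the treatment×salinity interaction — the terms that vary within
populations — in the population-conditioned RDA, and the treatment
($\rho^2$) effect in a separate unconditioned RDA. Zero-variance
features are dropped with a warning before centring. The morphology
matrix is analysed cell-level with the population covariate (the
population-mean alternative is available through the same functions;
neither is asserted as canonical). Restricted within-population
permutation is a conceivable alternative to covariate conditioning; the
covariate route is the default here, matching the standard paired-sample
treatment in constrained ordination.

## Plasticity distance and the predictability regression

The degree of plasticity of a population at a level is the Euclidean
distance between its multivariate means at low and high salinity — one
sample row per salinity for methylation (window percent-methylation) and
expression (stabilized log), 150 cell rows per salinity for morphology.
No feature standardization is applied before the distance (a z-scoring
flag exists for sensitivity analysis); the window-level methylation
table is used (the cytosine-level alternative is exposed through the
same functions). Distances are regressed on realized $\rho^2$ by
ordinary least squares across the 9 populations; the slope is tested
with a two-sided $t$ test ($n - 2$ df) and reported with the 95%
confidence band of the fitted line. No mixed-model treatment of the
population nesting is attempted at $n = 9$.

With the default ground truth all three levels have a planted positive
plasticity–predictability relation: morphology directly through the
distance law, methylation and expression through the planted counts of
salinity-responsive features increasing with $\rho^2$.

## GO over-representation

Per term, a one-sided (over-representation) Fisher exact test of the
2×2 table in/out-of-set × in/out-of-term against the annotated
universe — the "classic" algorithm, every term tested independently.
Sidedness is one-sided by convention of that algorithm. BH families
are per GO category (a single-family option exists), terms with fewer
than 2 annotated transcripts are skipped (configurable), and reported
terms are those with $q \le 0.1$, sorted by increasing $p$ within
category. If DAG parent edges are supplied, annotations are propagated
to ancestors before testing (on by default when edges are provided,
off otherwise, since the propagation convention of any given upstream
annotation is not always known).

# Numerical choices and degenerate inputs

* Fisher two-sidedness uses the minimum-likelihood rule with the
  conventional $1 + 10^{-7}$ relative tolerance; degenerate margins
  (an empty row or column) give $p = 1$.
* The BH family excludes `NA` p-values (non-converged fits, zero
  pooled coverage) rather than counting them in $m$.
* IRLS: working weights $\mu/(1+\alpha\mu)$, linear predictor clipped
  to $\pm 30$, convergence on relative coefficient change $10^{-8}$,
  50-iteration cap; all-zero count rows are flagged non-converged with
  unidentifiable coefficients rather than fitted at a boundary.
* Dispersion profiling searches $\log\alpha$ in a ±6 window around the
  method-of-moments start, within $[10^{-8}, 100]$, and accepts the
  floor when the boundary beats the interior optimum (under-dispersed
  rows).
* RDA rank handling distinguishes columns absorbed by the covariates
  (residual norm ≤ $10^{-8}$ of the original) from linear dependence
  among the remaining columns; both are reported as aliasing.
* Permutation p-values can never be 0 by the $+1$ counting convention;
  with $n_p$ permutations the smallest attainable value is
  $1/(n_p+1)$.
* Nearest-TSS ties (equidistant TSSs, or duplicate TSS coordinates)
  resolve deterministically to the lower coordinate, then the first
  transcript id.

# Problem sizes and what the test suite runs

The package's own test and validation runs use the generator defaults —
2,000 transcripts, 10,000 cytosines in 1,000 windows, 9 populations,
999 permutations — which complete the full pipeline in about a minute
on a single core; unit tests use smaller replicas of the same design.
Null-calibration checks use 500 windows/transcripts/replicates per
test. These sizes were chosen as the smallest at which the asymptotic
approximations under test are expected to hold, not as statements about
real-data scale, which is three to four orders of magnitude larger and
changes runtime, not logic.

# Known limitations

* Pooled Fisher DMR tests ignore replicate-level overdispersion; on
  real data with biological replicate variance they overstate
  significance. A beta-binomial or logistic-regression mode would be
  the natural extension.
* The NB engine's gene-wise dispersions are noisier than
  empirical-Bayes-moderated ones; at 3-vs-3 within-treatment contrasts
  the Wald test leans on small counts of degrees of freedom.
* The normal Wald reference is mildly anticonservative at small $n$
  (see above).
* The treatment effect cannot be separated from population identity in
  the conditioned RDA (nesting); its unconditioned test is a joint
  test of treatment-plus-population differences.
* Realized $\rho^2$ is treated as a fixed regressor; its estimation
  error (non-negligible for short series) is not propagated into the
  plasticity regression.
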