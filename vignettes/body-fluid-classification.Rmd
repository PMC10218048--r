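---
title: "Classifying body fluids from miRNA ΔCq panels: models and design choices"
author: "fluidQDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying body fluids from miRNA ΔCq panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidQDA)
```

## The problem

A forensic stain yields a DNA extract; the question is which body fluid
produced it. Seven microRNAs with fluid-specific expression (miR-200b,
miR-320c, miR-10b, miR-891a, miR-141, miR-412, miR-205) are assayed by
RT-qPCR alongside two endogenous references (let-7g, let-7i) that are
expressed stably across fluids. Because the input quantity of an
evidentiary sample is unknowable, expression is summarized relatively:

$$\Delta C_q = C_q(\text{target}) - \tfrac{1}{2}\left[C_q(\text{let-7g}) + C_q(\text{let-7i})\right]$$

in PCR cycles; one cycle is roughly a two-fold expression difference, and
lower ΔCq means higher expression. A sample is a point in 7-dimensional
ΔCq space, and fluid identification is a classification problem there.

## Preprocessing model

Each marker is amplified in duplicate technical replicates. The aggregate
Cq is their arithmetic mean; a replicate that never crossed the
fluorescence threshold ("Undetermined") makes the whole measurement a
non-detect, and a replicate spread above `concordanceLimit` (default 1.0
cycle) flags the value as discordant without rejecting it — the panel has
no published rejection rule, so discordance is surfaced as QC metadata
rather than silently acted on.

Non-detect *target* markers become missing values to be imputed, not a
ceiling Cq: the downstream model is a Gaussian fit, and a spike of values
pinned at the cycle limit would distort every covariance it touches.
Non-detect *reference* markers are different: without the normalizer, ΔCq
is undefined, so such samples are excluded and reported in an exclusion
table rather than guessed at.

## Imputation

Panels evolve, and not every archived sample was measured for every
marker; in a population of several hundred samples roughly a quarter of
profiles can be expected to have at least one gap. Missing markers are
filled by single conditional-mean imputation under a pooled multivariate
normal $(\mu, \Sigma)$ fitted to the fully observed profiles:

$$\hat{x}_m = \mu_m + \Sigma_{mo}\Sigma_{oo}^{-1}(x_o - \mu_o)$$

so each imputed value depends on all observed values of that sample.
Single (not multiple) imputation keeps a one-to-one mapping from sample to
prediction, which is what a classification workflow validates. The pooled
(not per-class) fit reflects deployment reality: at prediction time the
class is unknown, so the imputation cannot be conditioned on it. The cost
of these choices is a mild underestimate of within-class spread for
heavily imputed samples, and imputed profiles carry no extra uncertainty
into the posterior — a known limitation.

Complete-case estimation of $(\mu, \Sigma)$ was chosen over an EM fit:
with ~70% complete profiles the complete cases identify the moments well,
and the missingness here is assumed unrelated to the values (untested
marker/fluid combinations, not censoring).

## The "Other" class and open-set behavior

A discriminant classifier over seven fluids will force *any* input —
contamination, a fluid outside the panel, a degraded unmeasurable stain —
into its nearest fluid. To give the model a rejection region, the training
set is augmented with a synthetic eighth class drawn outside the
3.5-standard-deviation ellipsoid of the pooled fit, i.e. the set
$\{x : \sqrt{(x-\mu)^\top\Sigma^{-1}(x-\mu)} > 3.5\}$. The ellipsoid
reading of "3.5 standard deviations" (a Mahalanobis ball, not a per-axis
box) follows from the geometry: it is the set whose boundary is
equidistant from the data cloud in its own metric.

Draws are produced by rejection sampling: proposals come from
$N(\mu, \text{inflation}^2\,\Sigma)$ (default inflation 2) and proposals
inside the ellipsoid are discarded. In 7 dimensions this accepts ~88% of
proposals while concentrating the Other mass just beyond the boundary,
which is where the rejection decision is actually contested. The number of
Other rows defaults to the mean fluid-class size, keeping the augmented
design balanced. Both the proposal distribution and the class size are
genuinely open choices — nothing in the underlying method pins them down —
and both are exposed as parameters (`inflation`, `otherN`).

One behavioral consequence deserves emphasis: genuine samples in the far
tail of their own class can fall near the Other shell and be rejected.
This is the designed trade of open-set classification (a fraction of a
percent of genuine samples on well-separated data, a few percent when
classes overlap), not a defect; lowering `inflation` sharpens the
boundary, raising it softens it.

## Classification and the confidence gate

Quadratic discriminant analysis places one Gaussian per class with its own
covariance — fluids differ in their spreads and correlations, so a shared
covariance (LDA) would be wrong on its face. Posteriors are

$$p(k \mid x) = \frac{\pi_k\, N(x;\mu_k,\Sigma_k)}{\sum_j \pi_j\, N(x;\mu_j,\Sigma_j)}$$

computed entirely in log space with max-subtraction before
exponentiation, so points far from every component still yield finite,
normalized posteriors. Priors default to uniform over all classes
including Other: forensic casework has no defensible prevalence for body
fluids, and empirical priors would merely encode the accidental
composition of the training archive (an `empirical` mode exists for
study-design use).

A call is made only when the winning posterior reaches the confidence
threshold (default 0.5); otherwise the sample is reported *inconclusive* —
a distinct outcome, not a silent coercion. Published population tables for
this kind of panel have three outcome columns (correct / another fluid /
Other) with no inconclusive column, so whether their gate relabeled
sub-threshold calls or simply never fired is ambiguous; the package
exposes both readings via `gate = FALSE`, which always reports the argmax.
Exact posterior ties break to the earlier class in canonical order (panel
fluid order, then Other) — an arbitrary but deterministic rule.

## Cross-validation

Model assessment uses stratified 10-fold cross-validation. Stratification
is a deliberate strengthening: with ~50 samples per class, unstratified
folds can lose a class from a training fold entirely, which is an error
condition here, not a silent skip. Within each fold, *everything*
data-dependent — the pooled imputation MVN, the Other draws, the QDA
components — is refitted on the training fold only, and held-out samples
are imputed with training-fold parameters. The alternative ordering
(impute the whole dataset once, then split) leaks held-out information
into the imputation model; it is available as `imputeFirst = TRUE` for
comparison because some published pipelines are ambiguous about the order,
but the leakage-free ordering is the default and the per-fold parameters
are retained in the result object so the purity of each fold can be
audited after the fact.

Per-fold Other draws get their own seeds, derived once from the top-level
seed, so a cross-validation run is reproducible byte-for-byte and each
fold's parameters can be recomputed independently.

## The synthetic-data generator

No machine-readable population dataset accompanies panels of this kind, so
the generator stands in for one. It emulates the *statistical structure*
of a population study: seven fluids with sizes (51, 53, 50, 46, 53, 52,
50; 355 total), per-fluid multivariate-normal ΔCq with exchangeable
correlation 0.3 and marker SDs of 1.25–1.5 cycles, and a per-marker
missing-completely-at-random rate solved from $(1-r)^7 = 252/355$ so that
~71% of profiles are fully observed. The per-fluid mean vectors are
qualitative fixtures — each fluid extreme in its field-reported
discriminating markers (semen in miR-891a, saliva in miR-205, feces in
miR-141, blood in miR-200b/10b), menstrual and vaginal secretions
deliberately overlapping — calibrated once so the default pipeline lands
around 90% cross-validated accuracy with menstrual/vaginal weakest, the
regime in which the method's trade-offs are visible. They are not measured
values from any real cohort, and no conclusion about real fluids should be
read off them.

Two generation levels exist. `level = "profile"` draws ΔCq vectors
directly. `level = "cq"` goes one level deeper — reference Cqs around 22
cycles (SD 1.5), target Cq = reference average + latent ΔCq, duplicate
replicates with 0.25-cycle noise, non-detects beyond cycle 40 — and its
output, run through the preprocessing module, recovers the latent vectors
exactly in the noiseless limit. This closes the loop: the preprocessing
arithmetic is validated against the generative model it inverts.

Degradation scenarios (`heat`, `chemical`, `uv`) are additive per-marker
ΔCq offsets, reflecting that degradation delays amplification of
susceptible markers. What the generator does **not** emulate: within-donor
longitudinal correlation, mixed-fluid stains, marker-specific non-detect
mechanisms tied to expression level (missingness is MCAR), or PCR
efficiency differences. Passing tests on synthetic data therefore
demonstrate the statistical machinery, not casework validity.

## Numerical choices

* All covariance work goes through Cholesky factorizations; log
  determinants come from the factor diagonals. A factorization failure is
  reported with advice to raise the ridge — never silently
  pseudo-inverted.
* `fitMVN` adds `ridge × trace/d` (default ridge $10^{-6}$) to the
  covariance diagonal, a scale-free stabilizer.
* Model JSON serializes doubles as 17-significant-digit decimal strings,
  which round-trip IEEE doubles bit-identically; 15-digit default JSON
  printing does not.
* Degenerate inputs: a fully missing profile is an error (nothing to
  condition on); identical training profiles give a zero covariance that
  only the ridge rescues; an exhausted rejection-sampling budget (10⁶
  proposals) reports the acceptance problem and advises a larger
  inflation.

## Problem sizes in the test suite

The suite exercises the pipeline at the default population size (355
samples), with Monte-Carlo checks at 1,000–20,000 draws and oracle
comparisons (explicit-inverse Mahalanobis, direct-density posteriors, OLS
regression for the conditional mean, a reference QDA implementation) on
problems of dimension 1–7. These sizes were chosen so each statistical
bound has comfortable power while the full suite stays fast enough to run
on every change.

## Known limitations

Mixed-source stains are out of scope — the model assigns one label per
profile. Imputation uncertainty is not propagated. The Other class is a
geometric construct, not a model of any real contaminant population.
Degradation is modeled as deterministic mean shift, ignoring the variance
inflation real treatments induce.
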