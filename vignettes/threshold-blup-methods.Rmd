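---
title: "Methods: the liability-threshold animal model in pedblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the liability-threshold animal model in pedblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedblup)
```

## The problem

Familial cancer registries record multi-generation pedigrees in which the
only "genotype" is the pedigree itself plus a binary disease status per
person. Two questions drive the analysis: how much of the liability to
disease is additive-genetic (heritability), and which unaffected
relatives carry the most genetic risk (so that imaging surveillance can
be prioritized)? pedblup answers both with a Bayesian liability-threshold
animal model — the quantitative-genetics workhorse for binary traits on
pedigrees.

## Model and assumptions

Individual $i$ has a latent liability
$$
l_i = \mathbf{x}_i'\boldsymbol\beta + a_i + f_{(i)} + g_{(i)} + e_i,
\qquad e_i \sim N(0, 1),
$$
and is affected iff $l_i > 0$. The additive-genetic vector
$\mathbf{a} \sim N(0, \sigma^2_a \mathbf{A})$, where $\mathbf{A}$ is the
additive (numerator) relationship matrix implied by the pedigree
(Fisher's infinitesimal model: many loci of small additive effect);
family effects $f \sim N(0, \sigma^2_f)$ and generation effects
$g \sim N(0, \sigma^2_g)$ are iid across their levels. Identification is
the standard probit convention: threshold fixed at 0, residual liability
variance fixed at 1, intercept free (the intercept carries prevalence; a
free threshold and a free intercept would be redundant).

Assumptions worth stating plainly: additivity (no dominance/epistasis
variance is estimated — the non-additive part of the genotypic variance
is not separable from this design), no ascertainment correction (see
Limitations), and exchangeable family/generation effects.

Three effect configurations are shipped as presets, ordered by
biological plausibility: model I (fixed sex + family + generation,
random individual), model II (fixed sex + generation, random
individual + family) and model III (fixed sex, random
individual + family + generation). Model I forces all familial
resemblance into the genetic term and is expected to overestimate
heritability grossly — it is retained as a contrast, not a
recommendation.

## Relationship machinery

$\mathbf{A}$ is built by the tabular method in a parents-first ordering
($A_{kj} = (A_{sj}+A_{dj})/2$, $A_{kk} = 1 + A_{sd}/2$); an individual
with an unknown parent gets founder-level variance on that side.
$\mathbf{A}^{-1}$ — the only form the sampler needs — is assembled
directly and sparsely by Henderson's rules with inbreeding, through the
Mendelian-sampling variance ratio $d_i = 0.5 - 0.25(F_s + F_d)$ (both
parents known), $0.75 - 0.25F_p$ (one), $1$ (none). The tests verify
$\mathbf{A}^{-1}\mathbf{A} = \mathbf{I}$ against the dense tabular
matrix and gene-dropping Monte-Carlo estimates of pairwise relatedness,
so inbred loops (e.g. consanguineous matings present in real kindreds)
are handled exactly, not approximately.

"Off-kindred" cleaning: within each family we keep the connected
component(s) of the parent–offspring graph that contain an affected
member (or the largest component if none does) and drop isolated
individuals. Registry practice excludes off-kindred persons but does not
define the rule operationally; the connected-component reading is this
package's choice and is documented as such, not asserted as the only one.

## Posterior computation

The sampler augments the binary data with liabilities (one-sided
truncated normal full conditionals — exact tail sampling via Robert's
exponential-rejection method, stable to $|\mu|/\sigma = 30$), then
updates all location effects and the variance components:

* Location effects are updated by a **single-site Gauss–Seidel sweep**
  over Henderson's mixed-model equations. The coefficient matrix
  $\mathbf{C}(\boldsymbol\sigma) = \mathbf{W}'\mathbf{W} + \sum_b
  \mathbf{K}_b/\sigma^2_b$ has a fixed sparsity pattern, so each sweep is
  $O(\text{nnz})$ in compiled code. A joint draw via a sparse
  factorization per iteration would mix faster per iteration but costs a
  new numeric factorization every iteration (the variances change); the
  sweep gives far more iterations per second at equal stationary
  distribution, which is the better trade at the chain lengths used
  here. The gaussian-response mode (a testing back-door, fixed
  variances) verifies that the sweep's posterior means reproduce the
  exact mixed-model-equation solution to within Monte-Carlo error.
* Each variance component has a scaled-inverse-chi-square full
  conditional under its inverse-gamma prior (default scale $V = 1$,
  degree of belief $\nu = 1$). **Parameter expansion** is on by default:
  a working scale $\alpha_b \sim N(0, 1000)$ multiplies the block, is
  refreshed from its Gaussian full conditional each iteration, and the
  block and its variance are rescaled. This both accelerates mixing when
  a variance is near zero and changes the effective prior to a
  heavy-tailed (F-like) one that does not exclude zero — important for
  honestly answering "is the heritability zero?".

Divergent variance draws (> 1e8) abort with a diagnostic rather than
silently poisoning the chain. A chain is a deterministic function of the
seed; identical configurations reproduce draws bit for bit.

Two chain protocols are shipped as presets in addition to the
minutes-scale default (`desk`, 50,000 iterations / 5,000 burn-in / thin
10): `paper` (5.25M / 250k / 2,500; 2,000 retained draws) and
`paper_pdac` (6.25M / 250k / 2,500; 2,400 retained). The source
protocols are reported inconsistently in places (a shorter 500k/600k
variant is mentioned for the PDAC refit); both long presets are provided
and neither is treated as canonical.

## Heritability and its scales

Per retained draw,
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_f + \sigma^2_g + \sigma^2_e)$;
the point estimate is the posterior mean and the interval the empirical
shortest-window HPD (deterministic; ties broken toward the smaller lower
bound). Two denominator conventions exist for threshold models: with the
unit residual included (the full liability variance — the default here,
and the only convention under which an individual-only model can yield
$h^2 \approx 0.99$ rather than exactly 1) and without it
(`includeResidual = FALSE`), which reproduces the components-only ratio
as sometimes printed.

The observed ("real") scale uses the Dempster–Lerner transform
$h^2_{obs} = h^2 \, z^2 / (p(1-p))$ with $t = \Phi^{-1}(1-p)$,
$z = \phi(t)$. At the cohort prevalences this reproduces the printed
model-III conversions ($0.27 \to 0.07$ at $p = 213/3780$;
$0.21 \to 0.10$ at $p = 752/3780$):

```{r}
round(liabilityToObserved(0.27, 213 / 3780), 2)
round(liabilityToObserved(0.21, 752 / 3780), 2)
```

The default prevalence is the affected proportion among modeled
individuals; it can be overridden.

For the null hypothesis $h^2 = 0$, three summaries are reported
(posterior mass below a practical-nullity epsilon, a Savage–Dickey-style
density ratio at zero, and whether the HPD excludes zero — the operative
reject/not-reject criterion). A single construction labeled "the Bayes
factor" is deliberately not offered: with the residual variance fixed
and a boundary null, any such number depends strongly on the prior, so
the ingredients are exposed instead.

## Convergence diagnostics

The Heidelberger–Welch procedure: a Cramér–von-Mises test on the
standardized cumulative-sum process of each variance chain, with the
long-run variance estimated by an AR fit; on failure the first 10% is
discarded and the test repeated, up to 50%. The series is linearly
detrended before the AR fit so that a drifting chain inflates the test
statistic rather than the variance it is standardized by — without
this, a strong trend masks itself (a behavior the reference
implementation in coda exhibits: it flags such chains only through the
halfwidth test). The halfwidth criterion (normal-theory halfwidth below
10% of the mean) is reported alongside; a constant chain passes
stationarity with the halfwidth marked not applicable. Diagnostic
failures in the pipeline are warnings in the report, not aborts.

## The synthetic-data generator

The generator is the package's study design: it draws data from exactly
the generative process the model assumes, so estimator correctness can
be tested with known truth. Defaults emulate a familial-cancer registry:
96 families, 4 generations from a founder couple, Poisson(2.5) offspring
per couple (the founding couple always has at least one child; childless
pairings add no married-in spouse, so pedigrees stay connected), 90% of
spouses married-in founders, unit residual liability, additive variance
$3/7$ (implied liability $h^2 = 0.3$, matching the scale of the
registry estimates), no family/generation variance unless requested,
and a target prevalence of 0.15 (between the cohort's any-cancer rates
of ~0.15–0.18). The liability intercept is set to
$-\Phi^{-1}(1-p)\sqrt{\text{total variance}}$; the realized prevalence
is reported, never forced. Breeding values follow the exact
infinitesimal model including parental-inbreeding-adjusted Mendelian
sampling, keeping the simulator consistent with the $\mathbf{A}$-matrix
machinery.

What the generator does **not** emulate — and therefore what passing
recovery tests do not demonstrate about real registries: ascertainment
through affected probands (registry families are enrolled because they
are dense in cases; neither the source analysis nor this simulator
corrects for that), age/censoring structure, misreported or incomplete
branches, and non-additive genetic variance.

Problem sizes for the shipped studies were chosen to make a full
recovery experiment a desk-scale computation: 40 families (~1,500–2,000
individuals) per replicate with the `desk` chain preset, 20 replicates
for coverage (the 95% HPD is required to cover the true $h^2 = 0.3$ in
at least 17), and 3 replicates for the null. The acceptance script runs
a smaller 8-replicate version of the same experiment.

## Interval calibration at registry scale

A 95% HPD is a Bayesian statement; its *frequentist* coverage of a fixed
true $h^2$ is not guaranteed to be 95% and, under the recovery study's
conditions (40 families, ~1,400–1,800 individuals, ~200 cases at 15%
prevalence), runs somewhat below nominal: binary status at moderate
prevalence carries weak information about a liability-scale variance, so
replicate point estimates scatter more widely (RMSE ≈ 0.1–0.13 around an
essentially unbiased mean) than the posterior spread of any single fit.
The recovery experiment in the test suite measures exactly this — it
counts HPD coverage of the true value across replicates — and the
package's own diagnostics (long-chain refits reproducing the desk-preset
posterior; variance draws matching an analytic grid posterior in a
conjugate-structure check) localize the gap to the information content
of the data, not to sampler error. Users comparing HPDs across cohorts
should read them as posterior summaries, not confidence intervals.

## EGV transmission structure: a caution

Two superficially similar correlations behave very differently with
heritability, and conflating them is a common trap when reading EGV
scatter plots:

* **Prediction accuracy** — the correlation between an offspring's
  *true* breeding value and its parental-mean EGV — grows with $h^2$
  (the test suite verifies monotone growth over implied $h^2 \in \{0.1,
  0.3, 0.5\}$): more heritable traits make parental merit better
  estimable.
* The correlation between the offspring's *estimated* EGV and the
  parental-mean EGV moves the **opposite** way. At low $h^2$ both child
  and parent EGVs are shrunken onto the same shared family information
  and are nearly collinear; as $h^2$ grows, each EGV gains
  individual-specific (Mendelian-sampling) information and the
  child–parent correlation falls toward the true-breeding-value limit
  $\sqrt{1/2} \approx 0.707$. The package's BLUP-limit experiments
  (exact mixed-model-equation solves on observed liabilities, no
  Monte-Carlo noise) show exactly this decreasing pattern.

An estimate-level child–parent correlation is therefore a poor proxy
for transmitted genetic signal; use prediction accuracy against known
truth (simulation) or discrimination of future cases (AUC) instead.

## Numerical choices and degenerate inputs

* Reference-level (corner) coding keeps the fixed design full rank;
  single-level fixed factors are dropped with a warning. Random blocks
  need no such care — they are regularized by their variance priors.
* Pedigree validation collects findings (duplicates, self-parentage,
  unresolved parents, cycles, parent-sex conflicts; generation
  non-monotonicity is a warning since real registries contain it)
  instead of throwing; `strict` escalates.
* Unknown phenotypes are coded unaffected by default (the registry
  convention of coding everyone 0/1); `unknownAsMissing = TRUE` instead
  samples their liabilities unconstrained.
* Parental-mean EGV predictions are `NA` for founders and, by default,
  for single-known-parent individuals (`singleParentHalf = TRUE` gives
  known-parent/2, the expectation under an average unknown mate).
  ROC analyses drop `NA` predictions rather than imputing zeros.
* AUC uses mid-rank ties (pair-counting equivalent); the Kruskal–Wallis
  statistic applies the tie correction, with $H = 0, p = 1$ when all
  values tie.
* The Cramér–von-Mises CDF series is clamped to 1 above statistic 2
  (where the asymptotic series degrades and the tail mass is below
  double precision).

## Known limitations

* No ascertainment modeling (above) — heritability from proband-enrolled
  families can be biased, and the direction depends on the enrollment
  rule. This limitation is shared with the analysis the package
  implements.
* One chain per fit; multi-chain potential-scale-reduction diagnostics
  are out of scope.
* The "kinship" input to the model is taken as the additive relationship
  matrix $\mathbf{A} = 2\times$ kinship ($\texttt{kinshipMatrix()}$
  exports the halved form); if a data source supplies kinship
  proper, the factor 2 is absorbed into $\sigma^2_a$ and leaves $h^2$
  unchanged, but the variance components themselves change scale.
* Genomic (marker-based) relationship matrices, dominance matrices and
  X-linked inheritance are not supported.
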