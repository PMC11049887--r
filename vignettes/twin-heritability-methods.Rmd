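---
title: "Methods: twin-based heritability of gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-based heritability of gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinherit)
```

## The model

`twinherit` estimates how much of the variation in blood gene expression is
attributable to genetic differences, using the classical twin design.
Monozygotic (MZ) co-twins share all segregating genetic variation;
dizygotic (DZ) co-twins share on average half of the additive part. If MZ
pairs resemble each other more than DZ pairs do, genes are implicated; if
DZ resemblance exceeds half the MZ resemblance, the shared (family)
environment is implicated.

For one probe, the phenotype pair $(y_1, y_2)$ of a twin pair is modelled
as bivariate normal with a common mean $\mu$ and covariance

$$
\Sigma_{MZ} = \begin{pmatrix} v & a^2 + c^2 \\ a^2 + c^2 & v \end{pmatrix},
\qquad
\Sigma_{DZ} = \begin{pmatrix} v & \tfrac12 a^2 + c^2 \\ \tfrac12 a^2 + c^2 & v \end{pmatrix},
\qquad v = a^2 + c^2 + e^2,
$$

where $a^2$, $c^2$, $e^2$ are the additive-genetic (A), shared-environment
(C) and unique-environment (E) variance components. Heritability is
$h^2 = a^2 / (a^2 + c^2 + e^2)$. The sub-models AE, CE and E fix the
omitted components at zero. Free-parameter counts (including $\mu$) are
ACE: 4, AE: 3, CE: 3, E: 2, and $\mathrm{AIC} = -2\ell + 2k$.

Model selection compares ACE against AE, CE and E by likelihood ratio and
AIC (lowest wins; ties resolve toward fewer parameters). The heritability
p-value is the AE-vs-E likelihood ratio $\Lambda = 2(\ell_{AE} - \ell_E)$
referred to a central $\chi^2_1$.

### Numerical choices

* **Parameterization.** The optimizer works on unconstrained path
  coefficients $(a, c, e)$ and squares them, which enforces nonnegativity
  without constrained optimization; the sign ambiguity is harmless. The
  mean $\mu$ is profiled out in closed form at every objective evaluation
  (the ML mean is a precision-weighted average across zygosity groups),
  which shrinks the search space to at most three dimensions.
* **Sufficient statistics.** The likelihood depends on the data only
  through per-zygosity counts, sums, sums of squares and within-pair
  cross-products, so one objective evaluation is O(1) in the number of
  pairs. The exported `pair_negloglik()` is tested against a generic
  multivariate-normal density oracle to 1e-10.
* **Multi-start.** Five fixed dispersed starts (one of them the Falconer
  moment decomposition $\hat a^2 = 2(r_{MZ} - r_{DZ})$, clipped into the
  admissible cone) plus three seeded random starts; Nelder-Mead with
  objective tolerance 1e-10 and a final polish from the winner. Bootstrap
  refits use a reduced start set (moment start plus the full-data MLE as a
  warm start): across the test suite this reproduces the full-start optimum
  while being an order of magnitude cheaper.
* **Boundary LRT.** Because $a^2 = 0$ sits on the parameter boundary, the
  plain $\chi^2_1$ reference is conservative (the
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture would be exact). We follow
  the plain-$\chi^2$ convention of the structural-equation tooling common
  in this literature; the implied null rejection rate at $p < 0.05$ is
  $0.5 \times 0.05 = 0.025$, which the type-I simulation in the acceptance
  suite reproduces (so a nominal 3-8% acceptance band for that rate is not
  attainable by a correct implementation — the suite asserts it as stated
  and documents the red outcome). $\Lambda$ is clipped at 0 when numerical
  noise makes the reduced model appear better.
* **Singular covariance.** $e^2 \to 0$ makes $\Sigma$ singular; the
  likelihood returns `Inf` to the optimizer rather than erroring, so the
  boundary can be probed safely.

### Confidence intervals

The default interval inverts the profile likelihood of $h^2$ under AE:
for fixed $h^2$ the likelihood is maximized over $(\mu, v)$ (a fast 1-D
search after profiling $\mu$), and the 95% bounds are where the profile
drops $\chi^2_{1,0.95}/2$ below the maximum, clipped to $[0, 1]$. When a
near-singular fit spikes the joint maximum above what the profile can
reproduce, the threshold is recalibrated against the profile's own maximum
(a rare, degenerate-data situation; the interval then collapses toward the
estimate). The paper-matching alternative, `bootstrap_ci()`, resamples
pairs with replacement stratified within zygosity, refits AE, and takes
the percentile interval. Whether published twin CIs of this kind are
profile- or Wald-based is typically unstated; we chose profile likelihood
for the default because it respects the $[0,1]$ range without ad hoc
truncation of a symmetric interval.

## Preprocessing

* **Detection filter.** A probe is kept when its detection p-value is
  strictly below 0.05 in at least 3 samples. The boundary value 0.05 does
  not count — the rule is a strict inequality.
* **Residualization.** Pooled ordinary least squares of each probe on age,
  sex (0/1, F = 0), assay batch (treatment-coded dummies dropping the
  first level), RIN and white-blood-cell count, with an always-included
  intercept. Twin clustering is deliberately ignored here: the within-pair
  dependence is exactly what the twin covariance model downstream absorbs.
  Rank-deficient designs are a hard error naming the collinear columns.
  The batch encoding is our documented choice; reference coding is the
  standard full-rank default.
* **Inverse normal transform.** Blom offset:
  $\Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$ with average ranks for
  ties, matching the documented default of the transform named in this
  literature. This forces the marginal normality the Gaussian pair
  likelihood assumes; a probe with all values identical has no ordering
  information and is an error.

## Scan, FDR and gene aggregation

The scan runs preprocess + fit + test per probe. Probe-level q-values are
Benjamini-Hochberg over the converged probes only — failed fits have no
trustworthy p-value and are excluded from the FDR denominator (flagged and
counted in the log, never fatal). Gene heritability is the maximum over
the gene's probes; ties resolve to the smaller p-value, then the smaller
probe id, for determinism. Gene-level q is a fresh BH pass over one
p-value per gene (the selected probe's), not the probe-level q carried
over: the cross-study workflow recomputes FDR on gene sets, which implies
genuine gene-level p-values; published probe/gene significance totals are
consistent with either reading, so this is our documented choice.

## Enrichment and feature correlations

Enrichment of a user-supplied gene list among FDR-significant genes uses
Fisher's exact test on the (in-list) x (significant) table over the
background of all analyzed genes: two-sided p from summing hypergeometric
point probabilities no larger than the observed one (with a 1+1e-7
relative guard against floating-point ties), conditional-ML odds ratio
with an exact CI — the convention of standard exact-test tooling, which
differs from the sample cross-product ratio. List genes absent from the
background are dropped *before* the table is formed, with a logged count
(whether published analyses dropped before or after is typically
unstated). Zero cells yield OR 0 or Inf with a one-sided bound, never an
exception. Heritability-feature correlations (GC content, gene length) are
Pearson with a t-based two-sided p, restricted by default to
FDR-significant genes.

## Cross-study comparison

Per-gene summaries `(ensembl_id, h2, pvalue)` from two or more cohorts are
harmonized by Ensembl id: ".N" version suffixes stripped, case-normalized,
duplicate records per gene resolved by keeping the highest h2 (mirroring
the max-probe rule), then intersected. FDR is recomputed per study within
the common set (multiplicity = overlap size), Venn pattern counts are
reported for all nonempty membership patterns of k >= 2 studies, and
concordance is the pairwise Pearson correlation of h2 over all common
genes.

## The synthetic-data generator

The generator emulates the stated study design: 71 MZ + 52 DZ complete
pairs by default, ages uniform on 69.4-93.5 years, a ~70/30 F/M same-sex
pair mix, wbc around 6.41 +/- 1.66 K/uL, RIN in [6, 10], and a probe-gene
map with 1-5 probes per gene. Per pair, shared standard-normal factors are
drawn: MZ members receive the identical A draw, DZ member 2 receives
$0.5 A_1 + \sqrt{0.75}\, A_{new}$ (genetic correlation exactly 0.5, no
dominance or assortative mating); C is identical within pair; E is
independent. The phenotype is the covariate linear predictor plus
$\sqrt{a^2} A + \sqrt{c^2} C + \sqrt{e^2} E$ with fractions summing to 1 —
components are *fractions of residual variance* because the analyzed
phenotype is rank-transformed, making absolute scale irrelevant. Expected
within-pair correlations are $a^2 + c^2$ (MZ) and $0.5 a^2 + c^2$ (DZ),
and $2(r_{MZ} - r_{DZ})$ recovers $a^2$ at scale — both are tested.

Conventions the generator fixes (documented, not claims about any real
cohort): same-sex pairs with age/sex shared within pair and batch assigned
per pair; RIN and wbc per individual; the default truth mixture is half
null probes and half with $a^2$ uniform on [0.2, 0.9] plus a small shared-
environment slice. What it does *not* emulate: raw probe intensities,
scanner-physics detection p-values (undetected probes are simply planted
above threshold), array normalization artifacts, batch-correlated
technical noise, or non-Gaussian expression marginals. A green test
therefore establishes correctness of the estimation machinery under the
stated generative model, not robustness to the full messiness of array
data.

`plant_gene_lists()` plants enrichment by solving the 2x2 odds-ratio
equation for the number of truly heritable genes (gene truth >= 0.3 by
default) a list of the requested size must contain to hit a target OR,
then sampling uniformly within the heritable and non-heritable strata;
target 1 is an exactly uniform draw. Infeasible targets are a hard error.

## Reproducibility and the CLI

Every stochastic stage takes an explicit seed; child seeds are derived via
a small FNV-1a hash of (seed, label) so per-probe work is independent of
probe order. The four CLI subcommands (`simulate`, `scan`, `enrich`,
`compare`) accept `--config` (a flat `key: value` file — no YAML parser is
assumed in the runtime; unknown keys are errors, never silently ignored),
`--seed` and `--out`, and write a provenance block (seed, config hash,
per-stage counts) to a log file. Exit codes: 0 success, 2 validation
failure, 3 numerical failure. Probes mapping to several genes are not
special-cased: annotation is taken at face value, one gene per probe.

## Known limitations

* No sex-limitation, dominance (ADE) or age-moderation models; no
  bivariate/multivariate twin models.
* Singleton twins are dropped (complete pairs only), with a logged count.
* The plain-$\chi^2$ boundary convention makes heritability p-values
  mildly conservative.
* The profile CI's degenerate-data fallback (likelihood spikes) returns a
  collapsed interval rather than attempting a boundary-corrected one.
* Acceptance checking is property-based: the cohort behind the motivating
  analysis is not redistributable, so published headline counts cannot be
  reproduced at desk scale and are used only as design targets (sample
  sizes, h2 ranges) for the simulations.
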