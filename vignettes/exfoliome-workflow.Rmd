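---
title: "Methods: from stool counts to tissue concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stool counts to tissue concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(exfoliomics)
```

This vignette is the package's own account of its statistics: the models
behind each stage, the parameters that matter and why their defaults are
what they are, what the synthetic generator does and does not emulate, and
the numerical choices a maintainer would otherwise have to reverse-engineer.
No empirical claim is made here that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific question

Host cells exfoliated from the intestinal mucosa survive transit and can be
recovered from stool; their mRNA (the *exfoliome*) is a candidate
non-invasive window onto the small intestine, whose mucosa is otherwise
accessible only terminally in mice or endoscopically in patients. The
workflow asks two questions of a three-source design (small-intestinal
mucosa, colonic mucosa, stool exfoliated cells; control vs drug-treated
groups): does the exfoliome *mirror* the SI transcriptome, and does it
*discriminate* treated from control subjects when the colon — largely
spared by the injury — does not?

## Count preprocessing

**Filtering.** A gene is removed when it is nonzero in at most
`min_samples = 4` samples *or* has at most `min_total = 50` reads across
all samples. The "or" is literal and the boundaries are inclusive: a gene
seen in exactly 4 samples is removed however abundant; a gene seen in 5
samples with 51 reads survives. Presence is evaluated per sample across
the whole dataset (group structure plays no role). Filtering removes genes,
never samples.

**Normalization.** Between-sample scaling uses the upper-quartile method:
the raw factor is the 75th percentile of the sample's *nonzero* gene counts
divided by its library size, and raw factors are rescaled so their
geometric mean is exactly 1 (asserted to 1e-12 in the tests). Restricting
to nonzero counts is the standard convention for this method — with many
zeros the unrestricted quartile can vanish. Quartile dialects change the
factors, so the definition is pinned to linear interpolation between order
statistics (R's `quantile(type = 7)`) and exposed via `probs`. CPM is
`count / effective_library × 1e6`; log-CPM adds a prior count of 0.5 to the
numerator and twice that to the denominator so zeros stay finite.

**Diagnostics.** The housekeeping fraction (share of reads in a stable
gene set, by default 532 genes in the simulator) separates "small library"
from "broken assay": stool libraries are an order of magnitude smaller
than tissue because microbial rRNA displaces host transcripts, but their
housekeeping *fraction* should be comparable. Cross-source Spearman
correlation of per-gene mean log-CPM within a treatment group quantifies
mirroring; on default synthetic data it exceeds 0.8, the conventional
"strong correlation" cutoff.

## Dispersion and differential expression

Counts are modelled as negative binomial with variance `mu + phi * mu^2`;
`sqrt(phi)` is the biological coefficient of variation (BCV), the relative
standard deviation of expression across biological replicates.

**Common dispersion.** The default estimator equalizes libraries to their
geometric mean and maximizes the *conditional* NB log-likelihood of each
gene's within-group counts given their sum. Because sums of iid NB
variables share the size parameter, the group mean drops out of the
conditional density exactly; with 5 samples per group this matters. The
plug-in profile likelihood (group means estimated, then phi profiled) is
kept as `method = "profile"`, but it loses roughly `(n - groups)/n` of the
variance to mean estimation — at the package's own recovery scale (2000
genes, 5 + 5 samples, phi = 0.5) it lands near 0.41 where the conditional
estimator lands near 0.51 — which is why it is not the default.

**Exact test.** Library sizes are equalized by scaling each sample's counts
to the geometric-mean effective library (a documented approximation; the
quantile-to-quantile adjustment used by some packages is deliberately not
reimplemented). Group sums are rounded to integers, and the conditional
distribution of one group's sum given the gene's total is evaluated by
direct enumeration of the two NB factors. The two-sided p doubles the
smaller tail (observed value included) and caps at 1, so a gene with
identical group totals under a balanced design gets exactly p = 1. The
log2 fold change compares normalized group means with a prior count of
0.125 per group to avoid infinities; the treatment is the second factor
level, so positive log2FC means "up in treatment". FDR control is
Benjamini–Hochberg step-up with monotonicity enforcement.

Tagwise or trended dispersions and GLM designs with covariates are out of
scope: the design is a two-group comparison and acceptance is parameter
recovery, not numerical identity with any named package.

## Ordination and ANOSIM

Bray–Curtis dissimilarity is computed on CPM (configurable) —
`sum|x_i - x_j| / sum(x_i + x_j)`. ANOSIM ranks all pairwise
dissimilarities and compares between- to within-group mean ranks,
`R = (r_between - r_within) / (M/2)`, `M = n(n-1)/2`; being rank-based it
is invariant to monotone transformations of the distances. Significance
uses 999 random label permutations by default with the add-one rule
`p = (1 + #{R_perm >= R_obs}) / (1 + n_perm)`, so p is never zero; an
`exhaustive` mode enumerates all permutations for small n and is checked
against an independent enumeration oracle in the tests. The permutation
count and the CPM input are choices the upstream description leaves open;
both are configurable.

NMDS minimizes Kruskal's stress-1 by alternating isotonic regression of
configuration distances on the dissimilarity order (primary tie treatment:
tied dissimilarities are ordered by current distance, so they impose no
constraint) with a Guttman majorization update. Stress never increases
across iterations — asserted in the tests on the recorded trajectory — and
the best of 20 random starts plus one classical-MDS start is returned.
The treatment-oriented "MDS plot" of count workflows is provided as
`mds_leading_logfc`: pairwise distances are the root-mean-square of the
`top_n = 500` largest absolute log2 fold changes between two samples,
embedded by classical MDS. This leading-logFC convention is one of several
in circulation; it is documented here and configurable rather than treated
as ground truth.

## Sparse canonical correlation analysis

With n = 10 samples and thousands of genes, classical CCA is ill-posed
(sample covariance matrices are singular) and dense loadings are
uninterpretable. The diagonal-covariance simplification replaces the
within-set covariances by the identity after column standardization
(population SD; constant columns are dropped with a warning), leaving

max over u, v of `u' X'Y v` subject to `||u||2 <= 1, ||v||2 <= 1,
||u||1 <= c1, ||v||1 <= c2`.

Each update is an exactly solvable projection: `u` maximizing `a'u` under
the constraint set is the soft-thresholded, L2-normalized `a`, with the
threshold found by binary search (60 bisections, tolerance 1e-8 on the L1
norm) so that the L1 budget binds. Alternating these updates never
decreases the objective; with inactive budgets the fixed point is the
leading singular pair of `X'Y`, which the tests verify to 1e-8 against an
SVD oracle. Initialization is the leading right singular vector computed
by deterministic power iteration; the first nonzero entry of `u` is made
positive so runs are reproducible. Later components come from deflation
`M <- M - d u v'`, after which `u'Mv = 0` exactly. Two components are
fitted by default (ordination plots use components 1 and 2).

**Penalty scale.** User-facing penalties `(c1, c2)` live in (0, 1); the
feasible L1 range for a unit-L2 vector is `[1, sqrt(dim)]`, and the
fractions are mapped affinely, `budget = 1 + c (sqrt(dim) - 1)`. The
mapping is a package choice (the feasible range is dictated by geometry,
the affine form is not) and is configurable via `fractions = FALSE`.

**Tuning.** Leave-one-out cross-validation: for each grid point, fit on
n − 1 samples (standardizing with training statistics and applying them to
the held-out sample), score the held-out sample, and pool the n held-out
score pairs into one absolute correlation — per-fold correlations are
undefined for a single sample. Fold loadings are sign-aligned to a
full-data reference fit, since `(u, v)` and `(-u, -v)` are the same
solution but mixing them across folds would artificially decorrelate the
pooled scores. Ties take the first grid point with `c1` varying slowest.
A degenerate held-out variance scores the grid point 0. Whether CCA should
see all filtered genes or only DE genes is not dictated upstream; the
default is all shared filtered genes, and callers can subset.

## Bolstered single-feature LDA

Among DE genes, each gene is scored by how well it alone separates the
groups. The classifier is equal-prior, equal-variance LDA in one
dimension: the boundary is the midpoint of the class means. Resubstitution
error with n = 10 is almost always an optimistic 0; bolstering replaces
each training point with a Gaussian kernel and integrates the kernel mass
on the wrong side of the boundary, which in one dimension is
`Phi(-d_i / sigma_class)` per point.

The kernel SD derives from the mean within-class nearest-neighbor
distance: that distance estimates the *median* inter-point distance of the
kernel, which for a 1-D Gaussian is `sqrt(2) * sigma * qnorm(0.75)`, so
`sigma = mean_NN / (sqrt(2) * qnorm(0.75))` (~ mean_NN / 0.954). The
original bolstering literature admits several calibration constants; the
one above is documented in code (`BOLSTER_CALIBRATION`), configurable, and
the package's acceptance checks use this constant rather than guessing an
unrecoverable original. Classes whose points coincide get a
machine-epsilon-scale floor with a warning. Errors are invariant to affine
transformations of the feature, agree with 100k-draw Monte-Carlo
bolstering to ±0.005 in the tests, and rank genes ascending with
lexicographic tie-breaks. Features are log2-CPM by default; raw counts can
be passed. Multi-feature search and cross-validated error are out of
scope.

## Marker panels and concordance statistics

A cell type or anatomic site is called present in a sample when at least
2 of its marker genes are detected (count > 0); the flag is monotone in
the data, and panel genes missing from a matrix score zero rather than
failing the run. Pathway-level agreement between datasets is computed on
*user-supplied* occupancy/Z-score tables: proprietary pathway knowledge
bases are deliberately not reimplemented, so occupancy proportions
(rounded integer percent), pooled two-proportion z-tests, McNemar's test
(exact binomial below 25 discordant pairs, continuity-corrected χ² above)
and Pearson/Spearman correlation of Z-scores reproduce the concordance
arithmetic for any such table with the right shape.

## The synthetic world

`simulation_params()` states the world once; its defaults are the design's
conditions, not dials:

* 5 subjects per group, subjects matched across the three sources;
* per-source mean library sizes 27e6 (SI), 39e6 (colon), 3.8e6 (exfoliome)
  reads, divided by `lib_scale = 100` so desk-scale runs keep the real
  relative depths; per-sample sizes are log-normal with 20 % CV (the
  upstream description is silent on library variability; 20 % is typical
  of replicate RNA-seq libraries);
* per-source NB dispersions 0.143, 0.126, 0.592 — the observed common
  dispersions;
* a long-tailed log-normal baseline abundance profile (sdlog = 1.5) shared
  by all sources, n_genes = 2000 at desk scale;
* a treatment effect on 10 % of genes (the real datasets call >1000 of
  ~13–17k genes DE) of ±2 log2 units, expressed in SI and exfoliome but
  not colon — the injury is confined to the small intestine, and stool
  cells carry its signature;
* exfoliome dropout: the lowest-abundance 30 % of genes are zeroed in
  stool (13,944 of ~20,000 genes detected in the real assay);
* `contamination_fraction` shrinks the exfoliome library to model
  microbial displacement of host reads; the default is 0 because the
  3.8e6-read mean already embodies the displacement. No microbial reads
  are emitted — contamination is purely library shrinkage;
* 532 housekeeping genes drawn from stably expressed (non-DE, upper-half
  abundance) genes; a 10-cell-type marker panel with 3 genes each.

All randomness flows from a single integer seed; identical seeds give
bit-identical output.

**What a green test does and does not establish.** The generator emulates
the *statistical* structure the analysis assumes: NB counts with the
stated moments, coupled treatment structure, realistic depth ratios,
dropout. It does not emulate gene–gene correlation, transcript degradation
gradients, compositional effects of a few dominant genes, batch effects,
or microbial reads. Desk scale also interacts with the abundance filter:
at 1/100 depth the filter removes ~10 % of SI genes but ~45–50 % of
exfoliome genes (the real data lose 22 % there), which structurally caps
exfoliome-only recovery of injected effects. The recovery acceptance
check therefore evaluates the sources the effect is injected into — SI
alone and the SI/exfoliome union — while the exfoliome contributes through
the ordination, correlation and CCA patterns it was designed to show.

## Numerical choices, degenerate inputs, limitations

* Dispersion search is bounded to phi in [1e-6, 20] on the log scale;
  hitting the floor is reported (`at_lower_bound`), as with
  constant-within-group counts.
* Exact-test enumeration is O(total count) per gene; at desk scale totals
  are a few thousand. Very deep data would want a saddlepoint or normal
  tail approximation — not implemented, documented.
* The add-one permutation p can never reach below `1/(n_perm + 1)`:
  ANOSIM "p = 0.014" at 999 permutations is one resolution step above the
  minimum.
* NMDS stress trajectories are recorded; convergence is declared when the
  stress change drops below 1e-9, and non-convergence returns the best
  configuration found with a flag rather than an error.
* CCA binary search can face ties at the maximal |a_i|; the degenerate
  fallback places all mass on the first argmax, which is the c = 1 limit.
* Bolstered LDA refuses zero pooled variance (no classifier exists);
  `rank_features` converts that to an NA error ranked last rather than
  aborting a whole ranking.
* JSON is the only config format (no YAML parser among the declared
  dependencies); pipeline provenance sidecars carry parameters, seed,
  input checksums and versions, and omit timestamps so reruns are
  byte-identical.
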