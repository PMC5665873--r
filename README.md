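# exfoliomics

Non-invasive surveillance of the small intestine from stool: tools for
testing whether the transcriptome of host cells exfoliated into feces (the
**exfoliome**) mirrors the small-intestinal (SI) mucosal transcriptome and
discriminates drug-treated from control subjects, the motivating case being
NSAID enteropathy in the mouse.

The package is aimed at computational biologists who have gene-by-sample
count matrices from matched tissue and stool samples (or who want to study
the statistical behaviour of such designs on simulated data). Everything
downstream of a count matrix is covered; alignment and quantification are
out of scope.

## What it computes

Given count matrices for up to three sources (SI mucosa, colonic mucosa,
exfoliated cells) with control and treated groups:

* **Preprocessing** — removal of genes present in low abundance (nonzero in
  ≤ 4 samples or ≤ 50 reads overall), upper-quartile normalization factors
  scaled to geometric mean 1, (log₂) counts per million, housekeeping-gene
  library diagnostics, cross-source Spearman screening of mean log-CPM.
* **Dispersion and differential expression** — a common negative-binomial
  dispersion φ (variance μ + φμ²) by exact conditional maximum likelihood,
  the biological coefficient of variation BCV = √φ, the two-group NB exact
  conditional test on library-equalized counts, Benjamini–Hochberg FDR,
  MA tables and gene-set (Venn) intersections.
* **Ordination** — Bray–Curtis dissimilarity, the ANOSIM permutation test
  R = (r̄_between − r̄_within)/(M/2), non-metric multidimensional scaling by
  majorization of Kruskal's stress-1, and leading-logFC metric MDS.
* **Sparse CCA** — diagonal-covariance sparse canonical correlation:
  maximize uᵀXᵀYv subject to ‖u‖₂ ≤ 1, ‖v‖₂ ≤ 1, ‖u‖₁ ≤ c₁, ‖v‖₁ ≤ c₂,
  solved by alternating soft-thresholded updates with binary search on the
  threshold, deflation for later components, and leave-one-out
  cross-validated tuning of (c₁, c₂) by held-out score correlation.
* **Single-feature LDA with bolstered error** — each candidate gene is
  scored by the bolstered resubstitution error of a one-dimensional linear
  discriminant (each training point replaced by a Gaussian kernel sized
  from within-class nearest-neighbor distances; the misclassified kernel
  mass has a closed form), ranked, and selected at < 5 % error.
* **Signatures and concordance** — marker-panel scoring (a cell type is
  "present" when ≥ 2 of its marker genes are detected), rounded proportion
  arithmetic, pooled two-proportion z-tests, exact/χ² McNemar tests, and
  correlation of externally supplied pathway Z-score tables.
* **Synthetic data** — a coupled three-source NB count generator with the
  design's structure (5 subjects/group, per-source library sizes 27e6 /
  39e6 / 3.8e6 reads ÷ scale, dispersions 0.143 / 0.126 / 0.592, a
  treatment effect shared by SI and exfoliome but absent from colon,
  housekeeping and marker-gene subsets, exfoliome gene dropout), plus
  ground truth for power studies.

## Worked example

```r
library(exfoliomics)

params <- simulation_params(seed = 1)        # the default synthetic world
dat    <- simulate_counts(params)

si  <- dat$counts$SI
md  <- dat$metadata[dat$metadata$source == "SI", ]
grp <- factor(md$group, levels = c("control", "NSAID"))

fl <- filter_low_abundance(si)
fl$report
#> low-abundance filter: 2000 -> 1798 genes (10% reduction),
#>   2,662,315 -> 2,656,844 reads (0.205% reduction)

nm   <- upper_quartile_factors(fl$counts)
disp <- estimate_common_dispersion(fl$counts, grp, nm)
disp
#> common dispersion = 0.146, BCV = 0.382

de <- exact_test(fl$counts, grp, disp, nm)
sum(de$fdr < 0.05)
#> [1] 187
head(de, 3)
#>     gene     logFC   logCPM       pvalue          fdr
#> 1 g00644  3.376848 7.426217 5.421715e-15 9.748244e-12
#> 2 g01616 -2.915539 9.686925 3.937085e-14 3.539439e-11
#> 3 g01527  2.905106 8.532962 2.276160e-13 1.364179e-10

bc <- bray_curtis(cpm(fl$counts, nm))
anosim(bc, grp, n_perm = 999, seed = 1)
#> ANOSIM R = 1.000, p = 0.014 (999 permutations)
```

Reading the output: the filter drops 10 % of genes but only 0.2 % of reads;
the estimated common dispersion 0.146 recovers the simulated SI value
0.143 (BCV 0.382 vs 0.379); 187 genes reach FDR < 0.05, recovering 88 % of
the 200 genes carrying a simulated treatment effect; and
ANOSIM separates the treatment groups perfectly (R = 1) with the smallest
p-value its permutation resolution allows here. Running the same stages on
the simulated colon gives a near-null result (0 DE genes, ANOSIM p > 0.05)
— the package's core contrast: the exfoliome tracks the injured small
intestine, the colon does not.

The whole workflow (all three sources, plus sparse CCA between the
exfoliome and each tissue and the LDA ranking) is one call:

```r
out <- run_pipeline(pipeline_config(seed = 1))   # writes TSV/JSON stages
```

or, from a shell, `Rscript -e 'exfoliomics::exfo_cli()' run --out results`.

## Further reading

`vignettes/exfoliome-workflow.Rmd` documents the statistical model behind
every stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the package's numerical choices.
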