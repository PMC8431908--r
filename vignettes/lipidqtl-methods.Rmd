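---
title: "Methods: lipid QTL mapping, network inference and gene prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid QTL mapping, network inference and gene prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidqtl)
```

# Overview

`lipidqtl` maps genetic determinants of the circulating lipidome and places
them in a metabolic context. The pipeline chains eight stages:

1. **Synthetic cohort generation** — a two-platform study with planted lipid
   QTLs and known ground truth.
2. **Lipid preprocessing** — total-signal normalisation, natural-log
   transform, covariate residualisation, a PCA-based significance
   threshold, and pairwise lipid ratios.
3. **Association** — per-platform variant QC and additive OLS regression,
   combined by fixed-effect inverse-variance-weighted (IVW) meta-analysis
   with cross-platform concordance filters and genomic-inflation
   monitoring.
4. **Conditional dissection** — stepwise forward conditioning within 5-Mb
   chunks, ±500-kb locus clustering, variance explained, and a
   clinical-lipid sensitivity re-analysis.
5. **Gaussian graphical model (GGM)** — shrinkage partial correlations with
   FDR and magnitude edge filters.
6. **Enrichment** — degree-preserving permutation tests for fatty-acyl-chain
   and subclass connectivity.
7. **Gene prioritisation** — hierarchical integration of variant-centric
   ("bottom-up") and knowledge-base ("top-down") evidence.
8. **Networks** — combined gene/subclass and species-level graphs exported
   as SIF or GraphML.

Every stage is exercised end to end by `run_pipeline()` on the synthetic
cohort, so each algorithmic claim is testable against planted truth without
any external data.

# The synthetic cohort generator

The generator (`sim_config()`, `generate_cohort()`) emulates the design of a
two-platform lipidomics GWAS: two disjoint sample sets genotyped on a shared
variant panel, a lipid intensity matrix with subclass structure, covariates,
and missing values.

**Genotypes.** Each variant's minor allele frequency is drawn uniformly from
`maf_range` (default 0.05–0.5) and genotypes are binomial(2, maf) hard
calls. An optional blur `genotype_blur` moves probability mass `eps` from
each call onto neighbouring genotype classes, producing expected dosages and
an info score computed as one minus the ratio of mean posterior dosage
variance to `2p(1-p)` — the conventional imputation-quality measure. Hard
calls give info = 1. Linkage disequilibrium is *not* simulated beyond the
explicit pairwise LD fixture table; variants are independent.

**Lipids.** Log-scale traits are built additively: a subclass latent factor
with loading `sqrt(lipid_block_correlation)`, a neighbour factor with
variance share `lipid_neighbor_correlation` shared by consecutive lipids of
a block, planted per-allele genetic effects (in SD units of the trait, whose
non-genetic variance is fixed at 1), small random covariate effects
(SD `covariate_effect_sd`, default 0.05), and independent noise.
Intensities are the exponential of these traits around heterogeneous
baselines, so raw values are log-normal and the pipeline's log transform
recovers approximately normal traits. The neighbour factor deserves a note:
a pure one-factor block model spreads correlation so thinly that no lipid
pair survives the |partial correlation| > 0.2 edge filter once a block has
~10 members; real lipid panels instead show strong coupling between
adjacent species (one chain or one double bond apart), which is what the
neighbour term emulates and what makes the GGM stage testable on cohort
output.

**Missingness** is missing-completely-at-random: a baseline cell-level rate
(`missing_rate_lipids`) plus a small fraction of elevated-dropout subjects
(`missing_rate_subjects`, cell rate 0.15) that exercises the subject
filter. A missing-not-at-random mechanism (e.g. intensity-dependent
censoring, common in mass spectrometry) is deliberately out of scope, so
passing tests say nothing about robustness to informative missingness.

**Clinical measures** (total cholesterol, HDL-C, triglycerides) are linear
combinations of the lipid traits plus noise, so they act as partial
mediators of planted QTL effects — exactly the structure the sensitivity
analysis is designed to probe.

**What the generator does not emulate:** LD between panel variants,
population stratification (the genetic PCs are pure noise with small planted
effects), imputation error correlated across variants, batch-by-lipid
interactions, and mass-spectral artefacts. Results on synthetic data
validate the statistical machinery, not instrument-level preprocessing.

# Preprocessing choices

- **Normalisation** expresses each intensity as a proportion of the
  subject's total non-missing signal; it is scale-invariant per sample by
  construction.
- **Log base** is natural.
- **Residualisation** regresses each logged lipid on age group, sex, batch,
  fasting status and the first six genetic principal components, per lipid,
  on its observed samples; missing values propagate.
- **Significance threshold.** PCA runs on the residualised matrix after
  per-lipid mean imputation, correlation-scaled; the threshold is
  `5e-8 / k` where `k` is the smallest number of components explaining more
  than 95% of variance. With 56 components this gives 8.929e-10; with 112,
  4.464e-10. The PCA input convention (residualised + mean-imputed +
  correlation-scaled) is a package decision recorded in the run log, since
  several conventions are defensible.
- **Ratios** are formed on normalised (pre-log) intensities, then logged,
  then residualised identically to single lipids; a ratio is therefore the
  difference of two logged lipids and is antisymmetric under swapping.
  Ratio traits are tested at the standard genome-wide 5e-8 because far
  fewer ratio tests are run.

One subtlety worth stating: the log of a proportion subtracts the log total
signal, a weighted sum of log-normals whose right skew leaves a small left
skew (up to roughly −0.25 at a 60-lipid panel) in the logged proportions of
high-share lipids, even though raw intensities are exactly log-normal. This
is a structural property of total-signal normalisation, not a generator
defect; the planted-effect attenuation it causes is of order one over the
number of lipids.

# Association and meta-analysis

Per platform, each trait is regressed on each variant's dosage by OLS over
pairwise-complete samples (the association engine vectorises this across
the whole panel; the scalar `regress_additive()` is the reference
implementation the vectorised path is tested against). Platforms are
combined by fixed-effect IVW: weights `1/se^2`, pooled SE
`(sum w)^(-1/2)`, normal-approximation P.

Variant QC follows the quoted filters with strict inequalities: a variant
fails on HWE P < 1e-7 (exact conditional test, chosen over chi-square for
robustness at low counts), call rate < 0.97, MAF < 0.01 or info < 0.80.
Post-meta QC additionally requires direction concordance and per-platform
P < 0.01 on both platforms; failure reasons are enumerated per record.
Genomic inflation is the median association chi-square over 0.4549364.

A deliberate simplification: the missing-data likelihood score test used by
some GWAS software for imputed genotypes is replaced by expected-dosage OLS
Wald tests, which agree asymptotically when info is near 1. Mixed-model
association is out of scope; both platforms use the same fixed-effect
regression.

# Conditional analysis

Chunks are a fixed 5-Mb tiling anchored at position 1 per chromosome.
Within a chunk, conditioning is forward-only: the current lead (smallest
meta P) joins the conditioning set, regressions re-run with the selected
dosages as covariates (via Frisch–Waugh–Lovell projection, with degrees of
freedom reduced accordingly), and the loop stops when no conditional meta P
is below the same threshold used genome-wide. No backward elimination.
Collinear candidates are dropped with a warning.

Sentinels cluster into loci by single-linkage with a 500-kb gap rule, so a
chain of sentinels 400 kb apart forms one locus regardless of total span —
a documented, deterministic choice. Variance explained is the joint
multiple-regression R² of the residualised trait on all sentinel dosages.
The clinical sensitivity analysis reports the attenuation ratio
`beta_adjusted / beta`; mediated effects attenuate, independent clinical
variation does not.

# Gaussian graphical model

Subjects with more than 10% missing lipids, then lipids missing in more
than 20% of remaining subjects, are removed (strict inequalities; boundary
cases retained). Remaining missing values are mean-imputed per lipid — a
pragmatic choice at the few-percent missingness the filters guarantee.

The correlation matrix is shrunk toward the identity with the analytic
intensity `lambda = sum var_hat(r_ij) / sum r_ij^2` (clipped to [0, 1]),
which guarantees positive definiteness; partial correlations come from the
inverse: `pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`. With `lambda = 0`
and n much larger than p this reduces to the classical inverse-correlation
estimator, which the tests use as an oracle. Edge significance uses the
Fisher z-transform with effective degrees of freedom `n - p - 1` (floored
at 3) and Benjamini–Hochberg adjustment across all pairs — a deterministic
substitute for empirical-null mixture fitting with the same 0.05 FDR
contract. Edges are retained at q ≤ 0.05 **and** |pcor| > 0.2; the
magnitude filter is applied to the absolute value, since negative partial
correlations genuinely occur in lipid data. The `n - p - 1` convention
under shrinkage is conservative for the planted designs tested; calibration
on null data (no retained edges in 200 replicates at n = 1000, p = 30) is
part of the acceptance suite.

# Permutation enrichment

Edges are counted per unordered annotation pair; a lipid with several
fatty-acyl chains contributes one count for each distinct chain-pair
combination of an edge. The null preserves annotation degrees exactly:
checkerboard swaps (two incidence ones at distinct rows and columns swap
corners when the opposite corners are free), attempted `10 x` the number of
incidence ones per permutation — a standard burn-in for such chains,
recorded in the output metadata. For single-label annotations (subclass)
the null is a label permutation preserving subclass sizes. Empirical P
values are add-one smoothed, `(1 + #extreme) / (n_perm + 1)`, so they are
never zero and enrichment/depletion P values overlap at equality. The
default is 1000 permutations; calibration tests use 200 for speed.
Because counts are discrete, the enrichment P values are mildly
conservative — the calibrated fraction below 0.05 sits near 0.03 rather
than 0.05.

# Gene prioritisation

Bottom-up evidence links a variant to genes through exonic consequences,
splice-site proximity (within 2 bp of an intron–exon boundary), high LD
(r² ≥ 0.8, inclusive) with a non-synonymous variant, or cis-eQTL status in
subcutaneous adipose, visceral adipose, liver or whole blood only.
Top-down evidence scores all genes within 500 kb (inclusive, interval-edge
distance) by membership in five lipid-related gene-set tables; two or more
memberships make a gene a recurrent candidate. Compound-specific matches
require the gene's subclass tags to intersect the variant's associated
subclasses.

Integration is strictly hierarchical: (1) genes in both evidence sets;
else (2) compound-specific matches; else (3) the highest-scoring top-down
gene(s) — ties keep all — plus every bottom-up gene; else (4) the nearest
protein-coding gene, with ties broken by smaller start then symbol. The
nearest gene is always reported alongside the assignment, and rule 2 only
fires when rule 1 produced nothing (the narrative left this open; the
strict hierarchy is the implemented reading).

The fixture generator designates one evidence path per planted variant and
cycles through all six paths, so the validation stage
(`validate_against_truth()`) checks that each integration rule actually
fires and recovers the planted gene.

# Networks

The subclass-level network has gene-or-locus and subclass nodes.
An association edge requires at least one QC-passing significant
association between a variant assigned to the gene and a lipid of the
subclass. Loci without a single confident gene (multi-gene assignments)
enter under their locus id instead. Subclass-pair representation edges are
signed (over/under) with the permutation z-score as magnitude; gene–gene
edges come from a user-supplied functional-interaction table. The
species-level subnetwork restricts to chosen subclasses and carries the GGM
partial correlations. GraphML is the lossless interchange format (round-trip
tested); SIF is lossy by design (no attributes). Gene-symbol collisions
across loci raise an error rather than silently merging nodes.

# Problem sizes and determinism

The default demonstration configuration is 2,000 samples per platform,
20,000 variants, 60 lipids in 6 subclasses and 6 planted QTLs with effects
between 0.25 and 0.5 SD per allele — large enough for the planted
architecture to be recovered with near-certainty, small enough to run on a
single CPU in a few minutes. Calibration suites use 200 replicates at
reduced permutation counts (200) and panel sizes (30 lipids, n = 1000),
stated alongside each test. All randomness flows from the configuration
seed; identical configurations produce byte-identical outputs, including
the written TSV/SIF/GraphML files, which is asserted by checksum in the
test suite.

# Known limitations

- No LD between panel variants: stepwise conditioning is tested for
  independent signals and tight-proxy behaviour only through the LD fixture
  table, not through realistic haplotype structure.
- MCAR missingness only; informative missingness is untested.
- The effective-degrees-of-freedom convention for shrunk partial
  correlations is approximate; with heavy shrinkage (n close to p) edge
  P values are conservative.
- Fixture annotation databases are synthetic stand-ins with the schemas of
  the real resources; concordance results on them validate the integration
  logic, not the biological accuracy of any particular database snapshot.
- The enrichment null conditions on the observed network and annotation
  margins; it does not model uncertainty in the GGM edges themselves.
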