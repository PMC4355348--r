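---
title: "Diversity statistics and genomic prediction in selfing diversity panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity statistics and genomic prediction in selfing diversity panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gspanel` implements the complete computational chain of a crop
diversity-panel study — marker diversity, population structure, structure
adjustment, and genomic prediction under a repeated train/test protocol —
for highly selfing species genotyped with SSR, SNP and RBIP markers. This
vignette documents the models, the tunable parameters and their defaults,
the numerical choices, and the places where the design was genuinely open
and a choice had to be made.

## Data model

A `marker_panel` stores categorical calls per accession x marker. Three
call states matter in a selfing crop: a homozygous allele code, a
*heterogeneous* call (more than one allele in the sampled seed lot —
usually a mixture of homozygous lines rather than a true heterozygote),
and missing. Heterogeneous calls are kept as a distinct state for the
diversity statistics (so the per-system "% heterogeneous accessions" can
be reported) but encode to dosage 1 for prediction, which keeps the
dosage expectation unbiased. How heterogeneous calls should enter a
prediction matrix is not standardised; dosage-1 is this package's choice
and is confined to `encode_numeric()`.

Dosage encoding uses the minor allele as the counted allele; the
reference (major) allele is chosen per marker with ties broken
lexicographically, for determinism. Missing input tokens `-`, empty and
`NA` are canonicalised; unparseable cells become missing with a logged
count.

Marker filtering follows the usual pre-prediction hygiene: markers with
MAF <= 2% are dropped, as are markers with more than 10% missing or more
than 10% heterogeneous calls. Only the 2% MAF bound is a community
convention for low-density panels; the other two thresholds are package
defaults, exposed as arguments.

## Diversity statistics

PIC is computed as gene diversity `1 - sum(p_i^2)` over the allele
frequencies at the marker (heterogeneous calls excluded). This is the
simplest standard definition and the one consistent with multi-allelic
SSRs reaching values near 0.8; note that under any standard definition a
biallelic marker cannot exceed PIC 0.5, so reported "max PIC" values near
1 for biallelic systems in the literature are not reproducible and are
not attempted here.

The Rogers distance between two accessions is the proportion of co-scored
markers (both calls non-missing) at which the calls differ. A
heterogeneous call differs from every homozygote — a mixed seed lot is
genuinely different material — while two heterogeneous calls count as
equal. Pairs with no co-scored marker are flagged undefined. On complete
data this proportion-mismatch distance is symmetric, zero on the
diagonal, bounded by [0, 1] and satisfies the triangle inequality; the
test suite asserts all four properties on random panels.

The Mantel test correlates the upper triangles of two distance matrices
and permutes rows/columns of the second jointly; the one-sided p-value
uses the add-one correction `(1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
The implementation is deliberately small and seeded; the test suite
cross-checks the statistic against `vegan::mantel` and calibrates the
null rejection rate over 1000 independent trials.

Complete-linkage clustering and LD decay are thin, well-specified layers:
`stats::hclust` on the Rogers matrix (checked against a brute-force
agglomeration oracle), and squared Pearson correlation of dosage columns
within linkage groups against cM distance (composite LD, the appropriate
choice for inbred lines where phase is effectively known).

## Structure inference (DAPC)

`dapc_fit()` composes the standard pipeline: centre/scale the dosage
matrix, project onto the leading `n_pcs` principal components (default
`min(n/3, 100)`, the usual guard against over-fitting the discriminant
step), run k-means (10 starts, seeded) for each candidate k, score with
`BIC = n ln(WSS/n) + k ln(n)`, keep the BIC-minimising k (ties to the
smallest), then fit a linear discriminant analysis on the PC scores with
the k-means labels. Membership probabilities are the LDA posteriors —
Gaussian class-conditional densities with a shared covariance — and an
accession is *admixed at threshold t* when its largest membership falls
below `1 - t`.

Two behaviours of this BIC deserve note. On unstructured data it selects
k = 1 in the large majority of runs (a property test asserts >= 80% over
20 replicates). But because the likelihood term grows linearly in n while
the penalty grows only as `ln(n)`, duplicating a panel can legitimately
raise the chosen k when real within-group substructure exists — as it
does in founder-haplotype simulations, where accessions within a group
share founders. Stability of k under duplication therefore holds for
clean, isotropic clusters (where the suite tests it) and should not be
expected on pedigree-structured data.

An externally produced membership table (e.g. from a Bayesian admixture
program) can be wrapped with `structure_assignment()` and used everywhere
a DAPC fit is accepted; no MCMC admixture model is re-implemented.

## Empirical-Bayes structure adjustment

`combat_adjust()` treats markers as "genes", accessions as "samples" and
structure groups as "batches": each marker is standardised by its
group-size-weighted grand mean and pooled variance (unbiased `n - G`
denominator), per-(group, marker) location and scale estimates are shrunk
toward parametric priors (normal on locations, inverse-gamma on scales,
hyperparameters by method of moments) via the usual iterative posterior
update (tolerance 1e-4 on successive locations, max 1000 iterations), and
the data are adjusted and rescaled. Zero-variance markers are passed
through untouched; singleton groups are an error; degenerate hyperpriors
(all estimates equal, as after a previous adjustment) collapse to no
shrinkage rather than dividing by zero.

Two exactness caveats follow from the model itself, and the test suite
encodes them honestly: a constant group shift is removed *exactly* only
in the no-shrinkage limit (`shrink = FALSE`), because EB shrinkage pulls
each marker's batch effect toward the across-marker mean and leaves an
O(shrinkage) residual; and only the no-shrinkage path is exactly
idempotent. The EB path is checked against `sva::ComBat` (agreement up to
the variance-denominator convention) and against the direct
standardization oracle in the no-shrinkage limit.

Whether such an adjustment should act on genotypes or phenotypes is
ambiguous in practice; this package adjusts the genotype matrix by
default (the batch analogy is cleanest there) and provides
`residualize_phenotype()` as the alternative. Because the genotype
adjustment never sees the trait, refitting it inside every CV repetition
would return the identical matrix; it is therefore computed once per
evaluation, which is equivalent and cheaper.

## Imputation

`ppca_impute()` fits probabilistic PCA (`x = Wz + mu + eps`) by EM with
missing entries treated as latent, initialised from column means with
small random loadings (seeded), and declares convergence when the
relative change in the expected complete-data log-likelihood falls below
1e-5. Observed entries are never modified; imputed entries are
posterior-mean reconstructions, and values falling outside the [0, 2]
dosage range are counted and reported rather than clipped, so downstream
consumers can decide. Five latent components are the default — enough to
capture group structure in a panel with a handful of subpopulations
without fitting noise.

## The six prediction engines

All engines centre marker columns and the phenotype on the training data;
the intercept is the training mean, and every fitted model exposes an
equivalent per-marker effect vector on the original dosage scale, so
predictions, coefficient comparisons between methods and cross-trial
stability all work identically across engines. Columns are *not* scaled
to unit variance by default (a `standardize` flag exists): the engines'
reference implementations centre only.

* **LASSO** — `glmnet` computes the full regularization path; the
  constraint bound is chosen by 10-fold CV minimising MSEP. A fixed
  penalty can be forced (`lasso_lambda`) for calibration; oracle tests
  use it to verify the OLS limit and the soft-thresholding solution on
  orthonormal designs.
* **PLS / sparse PLS** — univariate NIPALS with X and y deflation;
  component count chosen by the same 10-fold CV criterion, capped at 10
  (the cap and criterion are package choices; tuning symmetry across
  methods was preferred over a fixed count). Sparse PLS thresholds each
  weight vector at the (k+1)-th largest |X'y| so that *exactly*
  `vars_per_component` loadings (default 50) are nonzero, ties broken
  toward the lower column index; with the count equal to p it reduces to
  ordinary PLS, and the CV-fold selection is checked against
  `mixOmics::spls`.
* **GBLUP** — VanRaden relationship `G = WW'/(2 sum p_j(1-p_j))` with a
  1e-8 diagonal jitter for numerical stability (for non-dosage inputs the
  scale falls back to `trace(WW')/n`; the scale only calibrates the
  variance ratio). REML profiles the ratio `sigma_g^2/sigma_e^2` over the
  spectral decomposition of G with one-dimensional optimisation of the
  restricted likelihood; GEBVs come from the rotated mixed-model solve
  and per-marker effects from the RR-BLUP back-solve `u = c^-1 W'G^-1 g`
  — the latter is a package choice for making GBLUP comparable with the
  coefficient-based methods, as there is no canonical "GBLUP coefficient
  vector".
* **Bayes A / Bayes B** — a Gibbs sampler in C++ (R's RNG, so chains are
  seed-reproducible). Effects get scaled-inverse-chi-square variance
  priors `chi^-2(nu, S)`; Bayes B adds a per-marker inclusion indicator
  sampled from the marginal likelihood with the effect integrated out
  (prior inclusion `1 - pi`, `pi = 0.95` by default), which mixes far
  better than joint sampling of (indicator, effect). The prior scale S
  defaults so the prior mode of the effect variance corresponds to half
  the phenotypic variance spread over the markers
  (`var(y) * 0.5 / sum 2 p_j (1 - p_j)`) — nu = 4 and this heritability-
   0.5 heuristic are stated, configurable defaults, since no canonical
  values exist. Chains default to 12000 iterations, 2000 burn-in,
  thinning 5.

## Evaluation protocol

Each repetition draws a training set of `round(2n/3)` accessions (round
half away from zero; for n = 367 this gives 245/122) without replacement,
tunes and fits every method on the training set only — hyperparameter
selection is redone inside each repetition to avoid information leakage —
and computes MSEP and `Q^2 = 1 - PRESS/TSS_test` on the held-out third
plus `R^2` on the training set. Results are aggregated as mean (SD) over
repetitions with the n-1 sample SD. 500 repetitions is the full-scale
default; the test suite and the acceptance script use 20-50 repetitions,
which is enough to separate methods at the panel sizes involved while
keeping the default runs short.

Broad-sense heritability is computed from the fixed-effects two-way ANOVA
(genotype + block, no interaction) as `h^2 = 1 - 1/F` on the genotype F
statistic — a line-mean-basis heritability appropriate for replicated
trials of inbred accessions.

## The synthetic panel generator

`simulate_panel()` emulates the data regime the pipeline targets:
372 accessions by default in three groups, 351 SNPs + 29 SSRs + 31 RBIPs,
7 linkage groups of 100 cM, about 1% heterogeneous calls and 1% missing
calls. Ancestral SNP frequencies are Uniform(0.05, 0.95); RBIP
frequencies are Beta(0.4, 1.2) (clipped to [0.02, 0.98]) to skew the RBIP
spectrum toward low MAF, reflecting the slow, presence/absence-like
evolution of retrotransposon insertions; SSRs draw 4-12 alleles from
group-specific Dirichlet-perturbed frequency vectors, which yields the
high PIC values characteristic of microsatellites. Group differentiation
follows the Balding-Nichols Beta model at Fst 0.15 by default
(moderate structure; the structure-recovery tests use 0.4, strong and
cleanly separable). Within-group LD arises mechanistically: each group's
genotypes are gametes recombined from 2 x 30 founder haplotypes along the
map with Haldane's mapping function, so r^2 decays with cM distance
without any tuned correlation parameter.

Traits are additive over a random subset of SNPs (50 QTL by default,
N(0,1) effects); the within-block error variance is set so that the
accession-mean heritability equals the target (0.9 by default, matching a
highly heritable seed trait; block effects have SD 0.25 genetic SDs). The
structure-confounding option adds a shared per-group shift with SD
`group_effect_sd` genetic SDs; the acceptance suite uses 1.0, a strong
but realistic confounding level, with Fst 0.3 — chosen once as the
"confounded trait" study condition.

What the generator does *not* emulate: mutation-rate differences between
marker systems (the contrast between SSR, SNP and RBIP time depth is
represented only through their frequency spectra and allele counts),
genotype-by-environment interaction, non-additive gene action, and
admixed individuals (groups are discrete, so DAPC admixture fractions on
simulated panels are near zero). Passing tests therefore demonstrate
correctness of the machinery and its statistical calibration, not that
any particular real collection behaves identically.

## Numerical choices and degenerate inputs

Fixed seeds propagate explicitly to every stochastic step (k-means
starts, CV folds, Gibbs chains, permutations, the generator), and
repetition r of the evaluation uses seed + r, so whole runs are
reproducible chain-for-chain. Constant phenotypes yield null effect
vectors and mean predictions everywhere; zero-variance markers are
skipped (LD pairs, adjustment) or harmless (encoding, G scale); all-
missing markers carry undefined statistics and are excluded from
summaries; k-means/BIC ties resolve to the smallest k; the lexicographic
tie-break for reference alleles and the lower-index tie-break for sparse
PLS keep every deterministic path order-independent, which the suite
verifies by permuting marker columns.

## Problem sizes in the default test run

The suite keeps single runs small (panels of 150 accessions x 140
markers for structure and calibration work; full 372 x 411 panels for
the scale-dependent checks: Fst recovery, realized heritability, GBLUP
accuracy, heritability monotonicity and the adjustment comparison, at
20-50 repetitions each). These sizes were chosen so each property is
tested at the scale where it is informative while the whole suite stays
fast enough to run routinely.
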