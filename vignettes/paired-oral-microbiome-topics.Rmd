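---
title: "Methods: paired plaque-abscess community analysis with topic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired plaque-abscess community analysis with topic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oraltopics)
```

## The analysis

`oraltopics` analyses paired 16S cohorts in which each patient contributes a
supragingival-plaque specimen and an odontogenic-abscess specimen. Pairing is
the central statistical asset: every between-community comparison is made
within a patient, which removes inter-individual microbiome variability from
the contrast. The pipeline runs, in order: cohort filtering, alpha diversity
with paired tests, an ordination selection sweep, consensus differential
abundance, latent Dirichlet allocation (LDA) of scaled relative abundances,
cross-validated specimen-type classification, and (optionally) hypergeometric
pathway over-representation.

## Filtering and agglomeration

Four retention rules run in a fixed order: listed contaminant taxa are
removed; taxa observed only in PCR/reagent blanks are removed; blanks are
dropped; finally any patient pair in which either member has total reads at
or below 1,000 is dropped entirely (strictly greater than 1,000 retains).
The order matters — the blank-only determination and the recomputed library
sizes both depend on what has already been removed — and is fixed to match
the narrative order of the rules. `filter_cohort()` logs every removal with
its rule and is idempotent.

Counts agglomerate to phylum, genus, or species by summing over taxa that
share the rank label. Taxa unclassified at a rank pool into one placeholder
per parent lineage, so column totals are conserved exactly at every rank.

## Transforms and paired testing

* **TSS** — column proportions; the substrate for distances, effects, and
  classification.
* **CLR** — `ln(x + 0.5)` centered per sample. The half-count pseudocount is
  the standard convention for count data; no value is prescribed by the
  analysis this emulates, so it is fixed here and exposed as a parameter.
* **CSS-log** — counts divided by the cumulative sum of counts up to the
  median of the sample's nonzero counts, times 1,000, then `log(x + 1)`.
  This is a fixed-quantile dialect of cumulative-sum scaling (quantile 0.5,
  scale constant 1,000), stated as a normative contract rather than a
  re-implementation of any particular tool's adaptive variant. The
  resampling DA engine uses the base-10 version (`css_log10()`).

`wilcoxon_signed_rank()` drops zero differences, mid-ranks ties, and uses the
exact signed-rank null for up to 25 tie-free pairs (via the exact
distribution, equivalent to enumerating all `2^n` sign patterns), otherwise a
normal approximation with continuity and tie correction. Tests are two-sided
throughout. FDR control is Benjamini-Hochberg step-up at q < 0.05.

## Ordination and its selection sweep

Candidate ordinations are PCoA on every combination of transform (TSS, CLR)
and distance (Bray-Curtis, binary Jaccard, Euclidean). PCA is covered by
Euclidean-on-centered-data; NMDS is out of scope (its iterative stress
optimization adds machinery without affecting the chosen model). Each
combination is scored by (i) |Spearman rho| between ordination axis 1 and
library size — a depth-artifact alarm, smaller is better; (ii) the median
silhouette width of each specimen type on the full distance matrix, larger
is better. Ranking is lexicographic in that order because no weighting is
prescribed; percent variance of axes 1-2 is reported but not ranked on.
Bray-Curtis on CLR values is skipped (negative inputs) with a logged reason.

Silhouettes are computed on the full distance matrix, not on 2-D
coordinates (a flag on `silhouette_by_group()`'s input lets a caller use
embedding distances instead, as `embed_gamma()` does); singleton groups and
all-coincident points score 0 by convention. Negative PCoA eigenvalues are
reported but excluded from coordinates and percent variance, with no
Cailliez/Lingoes correction — Bray-Curtis on TSS typically produces only a
small negative tail. Axes are oriented so the largest-magnitude coordinate
is positive, making signs reproducible across platforms.

Hierarchical clustering of samples uses average linkage on
`1 - Pearson r` between `ln(tss + pseudocount)` columns, with the
pseudocount set to half the smallest nonzero relative abundance of the
matrix.

## Consensus differential abundance

Three methods vote per taxon:

1. **Paired Wilcoxon** on TSS differences (the reference method; its median
   paired difference is the reported effect).
2. **Resampling engine** — per Monte-Carlo instance each sample's
   composition is drawn from Dirichlet(counts + 0.5) (the established
   half-count prior for this engine family), CSS-scaled and
   log10-transformed, then paired-signed-rank tested; the reported p is the
   mean over instances (128 by default).
3. **Linear-model engine** — OLS of CSS-log abundance on a specimen-type
   indicator plus per-patient intercepts. Ignoring the pairing would be
   anticonservative for matched specimens, so the patient terms are not
   optional.

Tiers: significant in all three methods = high confidence, two = medium,
one = low. Methods disagreeing on direction while each calling the taxon
significant demote it to `none` with a conflict flag — silently coercing a
direction would fabricate a finding. External call-sets (e.g. from a
bias-correction method this package deliberately does not re-implement) can
join the vote via `read_external_calls()`.

## Topic modeling

Samples become documents and taxa become tokens with counts
`round(tss * S)` (half away from zero, for determinism). Scaling equalizes
document lengths so that no sample dominates by depth; `S` is selected from
{10, 100, 1000, 10000} by refitting at fixed K and seed and maximizing the
sum of the per-type median silhouettes on Euclidean distances between
`gamma` rows (gamma space, not the 2-D embedding — the embedding adds a
stochastic step the selection does not need).

The sampler is collapsed Gibbs with the standard full conditional
`P(z=k|.) ∝ (n_dk + α)(n_kw + η)/(n_k + Vη)`, priors α = 50/K, η = 0.1
(classical Gibbs-LDA defaults), 2,000 sweeps with 1,000 burn-in and
thinning 50 for final fits, 800/400/20 for selection sweeps. Collapsed Gibbs
was chosen over variational EM because it supports the harmonic-mean
marginal-likelihood diagnostic natively and is simple to seed exactly: the
sampler runs on a private RNG stream, so identical (corpus, K, seed)
reproduce the model bit for bit. `beta` and `gamma` are posterior-mean
estimates from the final state.

Topic number is selected on a grid (2-12 by default) by four standard
diagnostics: harmonic-mean log marginal likelihood (maximize), mean pairwise
topic cosine (minimize), the symmetric KL divergence between the normalized
singular-value spectrum of `beta` and the length-weighted topic totals of
`gamma` (minimize), and the mean pairwise half-symmetric-KL topic divergence
(maximize; the half-symmetric form matches that metric's common
implementation). Because joint visual inspection of four curves is not a
deterministic rule, `chosen_k` minimizes the signed sum of min-max-normalized
metrics over the grid, and the full curve table is always returned so a
human can override. A caveat worth knowing: the singular-value divergence is
a symmetric KL between two K-dimensional distributions and tends toward its
minimum at the small-K edge of the grid when document lengths are equalized,
so it contributes little to the joint rule here; the other three metrics
peak at the true K on the synthetic conditions below.

Topics are classified plaque-specific, abscess-specific, or shared by a
paired signed-rank test on per-patient gamma differences with BH correction;
`embed_gamma()` provides a seeded UMAP of gamma for visualization, with
per-type silhouettes computed on the embedding.

## Classification and over-representation

Random-forest classification (impurity importance, 500 trees) uses 4-fold
cross-validation with folds partitioned **by patient**: splitting a pair
across train and test would leak patient identity into the test fold. This
is stricter than the emulated analysis documents, and is a deliberate
choice. AUC is the rank-based Mann-Whitney form with half credit for ties;
importances are reported as ranks, which are stable across implementations
where raw impurity scores are not.

Pathway over-representation is a one-sided hypergeometric upper tail with
BH correction and fold enrichment `(k/n)/(K/N)`. The mapping from items to
pathways is a user-supplied TSV; no live database client is included
(version- and network-dependent).

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 25 patients, 150 taxa, 6
latent topics (2 plaque-specific, 1 abscess-specific, 3 shared), topic-taxon
rows drawn from Dirichlet(0.05) (sparse, well-separated polymicrobial
signatures), log-normal library sizes around 20,000 reads, 5 contaminant
taxa spiked uniformly at relative abundance 1e-3, and 2 blanks containing
contaminants only.

Pairing is induced by one Dirichlet(1) base topic-weight draw per patient,
shared by both specimens and then reweighted by type: own-type topics are
multiplied by `type_bias` (default 0.9), other-type topics by
`1 - type_bias`, shared topics by 1/2, then renormalized. Two properties
pinned this mechanism down: at `type_bias = 0.5` the multipliers coincide,
so plaque and abscess members are exchangeable — an exact null for
calibration runs — and as `type_bias → 1` the types' supports become
disjoint. A side effect of renormalization with asymmetric topic counts
(2 plaque vs 1 abscess) is that even shared topics acquire a small
systematic gamma difference between types, which a 25-pair signed-rank test
can detect; type-specific recovery claims are therefore evaluated on the
type-specific topics.

Ground-truth enrichment uses a 4x rule with a detectability floor: a taxon
is truly plaque-enriched when its mean probability across plaque topics
exceeds four times its abscess mean **and** the larger mean reaches
`1/n_taxa`. Without the floor, sparse Dirichlet topics make the bare ratio
true for nearly every taxon at abundances around 1e-6 — orders of magnitude
below what a 20,000-read library can witness — which would define a ground
truth no finite experiment could recover.

What the generator does *not* emulate: sequencing error and chimeras,
amplification bias, overdispersion beyond the multinomial (no
Dirichlet-multinomial noise layer), taxonomic misassignment, or realistic
phylogenetic structure in the taxonomy table. Passing recovery tests
therefore demonstrates the pipeline's correctness and statistical
calibration under a clean compositional model, not robustness to every
artifact of real amplicon data.

## Problem sizes and determinism

Validation experiments run at the study scale: topic recovery fits K = 6 at
2,000/1,000/50 on the 25-pair cohort; topic-number selection sweeps K = 2-12
at 800/400/20 over three seeds; differential-abundance calibration averages
10 generator replicates for both the standard and the null cohort; the
end-to-end pipeline example runs on a packaged 12-patient, 100-taxon
synthetic fixture. All randomness flows from explicit seeds: the pipeline
derives one sub-seed per stage by hashing the stage name with the global
seed, so adding a stage never perturbs another stage's stream, and two runs
at the same seed produce hash-identical artifacts.

## Known limitations

* The two built-in DA engines are deliberately simplified stand-ins for the
  tool family they echo; they share the consensus interface but not the
  tools' full models (no covariates, no bias correction).
* The harmonic-mean marginal-likelihood estimator is known to be
  high-variance; it is used as one of four joint diagnostics, never alone.
* Negative PCoA eigenvalue mass is discarded rather than corrected.
* The UMAP embedding is library-provided; only determinism-at-seed and
  neighborhood preservation are contracted, not the embedding's geometry.
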