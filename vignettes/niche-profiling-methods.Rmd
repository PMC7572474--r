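---
title: "Methods: multi-omic niche profiling of microbial populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic niche profiling of microbial populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`nichescope` characterises the ecological niches of microbial populations
that are tracked through a time series with several omic layers at once:
metagenomic (MG) and metatranscriptomic (MT) sequencing depth,
metaproteomic (MP) spectral counts, and GC-MS meta-metabolomics. The unit
of observation is the representative metagenome-assembled genome (rMAG) —
one dereplicated genome per population, used as a fixed reference across
all time points. This vignette explains the models and rules behind each
stage, the tunable parameters, what the synthetic community generator does
and does not emulate, and the numerical choices a user should know about.

## Fundamental niches: typing genomes by functional repertoire

The *fundamental* niche of a population is approximated by its encoded
capability: the set of KEGG ortholog groups (KOs) carried by its genome. A
binary rMAG × KO presence/absence matrix (`build_ko_presence()`, 1 = at
least one gene with that KO) is turned into pairwise binary Jaccard
distances,

$$ d(a, b) \;=\; 1 - \frac{|a \wedge b|}{|a \vee b|}, $$

projected into the plane by classical multidimensional scaling
(`classical_mds()`, the eigendecomposition of the double-centred
$-\tfrac12 D^2$ matrix), and clustered with k-means. Following the
original analysis procedure, clustering operates on the 2-D embedding
rather than on the raw distance matrix; this is a deliberate fidelity
choice — clustering the distances directly (e.g. by PAM) would be
statistically cleaner but is not what the workflow describes. The number
of centroids is chosen by running k-means for $k = 1..9$ and taking the
elbow of the total within-cluster sum of squares; the elbow is automated
as the point of maximum perpendicular distance to the chord joining the
curve's endpoints ("kneedle" rule), with a manual `k_override` because
elbow reading is classically done by eye. k-means uses k-means++ seeding
with 25 restarts (lowest within-SS wins) since the plain Lloyd iteration
is sensitive to initialisation; results are deterministic given `seed`.

Cluster-wise KO composition is characterised two ways. `ko_set_overlaps()`
computes the UpSet partition: for every subset of clusters, the number of
KOs present in exactly those clusters (the region counts sum to the size
of the global KO union). `fisher_enrichment()` tests every (KO, cluster)
pair for over-representation with the one-sided hypergeometric tail and
adjusts across *all* pairs jointly by Benjamini–Hochberg; a pair is
enriched at adjusted $p < 0.05$. The joint adjustment family is a
documented choice — adjusting within clusters would be less conservative.
`adjusted_prevalence()` divides the fraction of cluster members carrying a
pathway's KOs by the cluster's mean genome completeness (capped at 1),
because incomplete genomes underestimate pathway prevalence.

Agreement between the repertoire-based embedding and an independent
whole-genome distance embedding is quantified by Procrustes
superimposition with a PROTEST permutation test
(`procrustes_protest()`). The *symmetric* convention is used — both
configurations centred and scaled to unit sum of squares — so the residual
$m^2 \in [0, 1]$ and the Procrustes correlation is $\sqrt{1 - m^2}$.
Conventions differ between implementations (asymmetric scaling changes
$m^2$), which is why the choice is stated here. Permutation p-values use
the add-one convention $p = (\#\{m^2_{perm} \le m^2_{obs}\} + 1)/(n_{perm}
+ 1)$ throughout the package, so no p-value is ever exactly zero.

## Community dynamics

Population abundance is inferred from MG depth of coverage: summed
per-base depth over feature length (`compute_depth()`), aggregated to the
rMAG level as a contig-length-weighted mean (`rmag_depth()`; whether to
length-weight was an open choice — a simple mean over contigs would
over-weight short contigs, so length-weighting is used). Columns are
normalised to relative abundances.

Distances between abundance *profiles* use the correlation transform
$d = 1 - (\rho + 1)/2$, mapping $\rho = 1, 0, -1$ to $d = 0, 0.5, 1$. The
association between profile distances and the functional-cluster
assignment is tested by one-factor PERMANOVA (`permanova()`): with
$SS_{total} = \sum_{i<j} d_{ij}^2 / n$ and the within-group analogue
divided by group sizes, $R^2 = 1 - SS_{within}/SS_{total}$ and the
pseudo-F statistic is compared against label permutations. Homogeneity of
dispersion (`dispersion_test()`) embeds the distances (positive
eigenvalue axes only), computes each point's distance to its group
centroid and permutes those distances across groups under a one-way F
statistic. Both are deliberately implemented in-package with seeded
permutations and exact edge-case contracts; the test suite cross-checks
them against `vegan::adonis2` and `vegan::betadisper`.

Temporal stability of a population is the mean over standard deviation
(sample s.d.) of its relative-abundance series. The invariability
literature offers several variants (inverse CV on raw vs log abundances,
detrended versions); mean/s.d. is used as the canonical inverse
coefficient of variation and the function takes an `exclude_window`
argument so stability can be compared with and without a disturbance
period. Undefined values (zero s.d.) are flagged, never silently dropped.

Sample-level ordination uses Bray–Curtis dissimilarity plus classical MDS
(`braycurtis_pcoa()`). Abiotic factors are related to the ordination by
post-hoc least-squares vector fitting (`fit_factors()`): each z-scored
factor is regressed on the two ordination axes; the arrow is the unit
coefficient vector scaled by $\sqrt{R^2}$, with a permutation p-value on
$R^2$. This is an unconstrained ordination with vector fitting rather
than a constrained ordination (dbRDA); it covers the same interpretive
use — which factors align with community turnover — and a constrained
variant is a natural extension point. Population-by-factor associations
use tie-corrected Spearman correlation with BH adjustment across all
pairs (adjustment is on by default and toggleable). Missing abiotic
values are handled pairwise-complete; the only imputation path is the
explicit one for pH gaps, which uses the Stineman (1980) rational
interpolant with circle-based slope estimates (`stineman_impute()`) —
exact on linear segments and free of overshoot between monotone knots;
leading/trailing gaps fall back to nearest-value filling with a warning.

## Realized niches: expression status and its clustering

The *realized* niche is the expressed subset of the fundamental one. A
gene counts as expressed in a sample when

* its MT/MG depth ratio exceeds 1, or
* its MG depth is below 1 and its MT depth itself exceeds 1, or
* at least 2 peptide spectral counts are assigned to it.

The MG < 1 fallback avoids inflating activity calls for lowly abundant
populations, where a tiny MG denominator makes ratios explode. The
fallback comparison value (MT > 1) mirrors the ratio rule; the
strict/non-strict directions of all three comparisons are fixed exactly
as stated and locked by a truth-table unit test. The spectral-count rule
is applied per gene and sample (not summed across a KO), since the
predicate is defined at the gene level. A KO of an rMAG is *active* when
any of its genes is expressed; the activity profile covers every
(rMAG, KO) pair with at least one annotated gene, and genes absent from a
depth table count as depth 0.

Per time point, binary Jaccard distances between the rMAGs' activity
vectors are embedded in 2-D (matching the one-ordination-per-time-point
design) and clustered with HDBSCAN at a minimum cluster size of 5.
HDBSCAN is implemented in the package (`hdbscan_cluster()`): core
distances with `min_samples` equal to the minimum cluster size, mutual
reachability distances, the single-linkage hierarchy (equivalent to the
minimum spanning tree of the mutual-reachability graph), a condensed
cluster tree, and excess-of-mass cluster selection. Points outside every
selected cluster carry an explicit noise label (0); labels are ordered by
descending size. Two boundary behaviours are worth noting: with fewer
points than the minimum cluster size everything is noise, and when the
hierarchy never splits into two viable clusters the root itself is
selected, so a set of identical profiles forms a single cluster rather
than all-noise.

`mtmg_ratio()` summarises per-rMAG activity as MT depth over MG depth per
sample, averaged within conditions and summarised (median, quartiles) by
functional cluster or taxon; samples with MG depth 0 are excluded and
counted. `cluster_ko_frequency()` counts, for a focal rMAG, the time
points at which a KO is active while the rMAG sits in a non-noise
expression cluster, along with the same KO's activity among co-clustered
rMAGs.

## Pathway-level trends

`foam_trend()` aggregates gene MT depth and MP counts by top-level FOAM
category, divides by the per-time-point totals over *all* rMAG genes
(annotated or not — using only FOAM-annotated genes in the denominator
would inflate every category), min–max scales each category's relative
series to [0, 1] per series, and reports the Pearson correlation between
the scaled MT and MP series. Min–max scaling is affine, so it provably
leaves the correlation unchanged (a property test asserts this);
per-series rather than global scaling is used since each category is read
as its own panel. Genes with several FOAM assignments count towards each.

## Metabolomics quality control and normalization

A GC-MS run couples a metabolite × measurement intensity matrix with the
injection-order manifest (roles: sample, pool, blank). Three rules apply,
in any order for the two filters (both are per-metabolite predicates, and
a property test checks they commute):

* **Blank filter** — a metabolite whose mean intensity in blanks exceeds
  75% of its mean in samples is removed as a contaminant. Missing values
  count as 0 in both means by default (conservative removal); a
  `detected_only` switch restricts means to detected values.
* **Prevalence filter** — keep only metabolites detected (> 0) in every
  pool and in at least 25% of samples (90% for correlation workflows).
* **Drift normalization** — every intensity is divided by the mean of
  that metabolite's values in up to two nearest preceding and up to two
  nearest following pool injections (at most four; pools missing the
  metabolite are skipped; a pool measurement excludes itself). "Up to two
  preceding and subsequent" is read as up to two on *each* side; the
  narrower reading (two in total) would halve the smoothing window.
  Metabolites with no usable pool value anywhere are left unnormalized
  and flagged.

Intracellular/extracellular ratios are computed per time point for
metabolites detected in both fractions, each fraction normalized
independently (pools are fraction-specific mixtures). Note that pool
normalization rescales each metabolite to its own pool level, so the
*absolute* intra/extra ratio is only meaningful up to that per-metabolite
scale; downstream use z-scores the ratio series, where only the temporal
pattern matters.

## Consensus taxonomy

Per rMAG and rank, marker-gene assignment probabilities are summed per
candidate taxon; the top taxon wins with confidence = winning score /
total score, and a winner holding less than one third of the total is
discarded as a "low confidence assignment". Scores are scale-invariant
(rescaling all probabilities changes nothing — a property test), so
un-normalized marker weights are acceptable. Whole-genome assignments take
precedence rank by rank; consensus fills only unassigned ranks, and
lineages without a kingdom-level call are flagged for removal. Ranks are
treated independently, as no lineage-consistency rule is part of the
procedure; ties break lexicographically with a warning.

## The synthetic community generator

`simulate_community()` produces a full multi-omic dataset with known
ground truth so every stage is testable without external downloads. Its
defaults *are* the study conditions; they were fixed once, for the
reasons below, and the acceptance checks run against them.

* **Community structure.** 78 rMAGs in four planted functional types of
  sizes 24/23/19/12; a KO universe of 6000 with 1857 core KOs shared by
  all types. Type-specific blocks hold 800 KOs each and form an
  overlapping chain (adjacent types share 300 KOs): fully disjoint blocks
  would make the four types exactly equidistant, and a regular simplex of
  four points needs three MDS dimensions, so the 2-D embedding would
  distort; real functional clusters show unequal similarities, which the
  chain reproduces. Each rMAG adds 30 private accessory KOs and every
  presence cell flips with probability 0.02.
* **Abundance dynamics.** 51 weekly time points from 2011-03-21; each
  rMAG follows a positive seasonal sinusoid (annual period, per-type
  phase) with log-normal noise, scaled so the median population sits at
  ~10× depth of coverage — recovered major populations are well above the
  depth-1 detectability threshold of the activity rule, and placing half
  the community at that edge would conflate detectability with ecology. A
  transient disturbance multiplies the abundance of one type's members by
  10 during time points 34–37, emulating a drastic four-week community
  shift with full dominance turnover.
* **Expression.** The annotation table covers each rMAG's whole
  repertoire; a measured "panel" (30 shared + 20 type-specific + 5
  private KOs + 5 unannotated genes per rMAG) carries MG/MT/MP data. MT
  depth is MG depth times an activity factor: the type's factor
  (2.0/2.5/3.0/3.5) for planted-active KOs, 0.2 otherwise, drawn per gene
  and time point with 5% regime noise. MP counts are Poisson with mean
  0.05 × MT depth — peptide identifications are sparse relative to
  transcript depth in real data. The generator records the analytic
  expectation of each type's rMAG-level MT/MG ratio (length-weighted mean
  of per-gene expectations) for recovery checks.
* **Metabolome.** Four fractions of 60 metabolites (21 shared between the
  fractions of each polarity, so 42 in total); runs bracketed by blanks
  with a pool after every fifth measurement; multiplicative sigmoidal
  drift totalling 1.2× across the run (instrument response settling at
  the start and saturating near the end — under locally flat drift the
  one-sided pool windows at the run edges stay unbiased, which an
  exponential curve violates); pool technical CV 6.5%, within typical
  pooled-QC precision. Five contaminants are planted in blanks above the
  75% level, six metabolites at ~15% sample prevalence and two missing
  from one pool, to exercise each filter branch.
* **Determinism.** Every sub-simulation draws from its own stream derived
  from the master seed by fixed offsets, so adding a stage never perturbs
  earlier draws; identical seeds give bit-identical outputs.

What the generator does *not* emulate: read-level sequencing artefacts
(no FASTQ, no mapping bias), assembly/binning errors beyond the simple
completeness/contamination table, phylogenetic correlation inside types,
compositional coupling between metabolome and community state, and real
mass-spectral structure. Passing recovery tests therefore demonstrates
that the statistical machinery is implemented correctly and behaves as
designed under controlled conditions — not that the pipeline is robust to
every artefact of real multi-omic data.

## Problem sizes and numerical choices

The test-suite and acceptance checks run the full default community (78
rMAGs × 51 time points) across 20 seeds for clustering recovery, 10 seeds
for the disturbance-direction check, and 200 replicates for permutation
null calibration at 99 permutations each; production analyses should use
999+ permutations (the analysis scripts do). Degenerate inputs are
handled explicitly rather than by error where a sensible value exists:
all-zero row pairs get Jaccard distance 0 with a warning; fewer positive
MDS eigenvalues than requested dimensions zero-pad with a warning;
constant series z-score to zeros; k-means with fewer distinct points than
centroids falls back to one cluster per distinct location; ties in
consensus taxonomy break lexicographically. Permutation p-values always
use the add-one convention, so the smallest attainable p is
$1/(n_{perm}+1)$.

## Known limitations

* Clustering on the 2-D embedding discards variation beyond two axes by
  design fidelity; strongly higher-dimensional repertoire structure would
  call for clustering the distance matrix directly.
* The elbow rule can be ambiguous on slowly-bending within-SS curves;
  `k_override` exists for exactly that case.
* The stability statistic is one of several invariability definitions; a
  different variant can change absolute values (the package exposes the
  window argument, not the formula, as the user-facing knob).
* Drift normalization assumes pools behave like samples under drift;
  metabolites absent from pools cannot be normalized and are flagged.
* The dispersion test permutes centroid distances rather than refitting
  centroids per permutation; for very unbalanced groups the two versions
  can differ slightly.
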