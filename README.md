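# nichescope

Multi-omic niche ecology of microbial populations over time.

Microbial communities in engineered ecosystems — activated sludge is the
motivating case — are mixtures of populations whose *fundamental* niches
(what their genomes can do) and *realized* niches (what they actually
express in situ) both shape community resistance and resilience.
`nichescope` implements an integrated pipeline for longitudinal
multi-omic data over representative metagenome-assembled genomes (rMAGs):

* **Fundamental niche typing** — binary KO (KEGG ortholog) repertoires,
  pairwise Jaccard distances `d = 1 − |a∧b|/|a∨b|`, classical MDS,
  k-means with automated elbow (within-SS "kneedle") selection over
  k = 1..9, UpSet-style KO set overlaps, one-sided Fisher enrichment with
  BH correction, completeness-adjusted pathway prevalence, and
  Procrustes/PROTEST comparison against whole-genome distance embeddings
  (symmetric convention, correlation `√(1 − m²)`).
* **Community dynamics** — relative abundance from length-weighted depth
  of coverage, correlation-transform distances `d = 1 − (ρ+1)/2`,
  one-factor PERMANOVA (`R² = 1 − SS_within/SS_total`, permutation
  pseudo-F), multivariate dispersion tests, temporal stability (mean/sd
  of the abundance series, with disturbance-window exclusion),
  Bray–Curtis PCoA with abiotic-factor vector fitting, Spearman
  population–factor associations, and Stineman interpolation for pH gaps.
* **Realized niche profiling** — binary KO expression status per time
  point (gene expressed iff MT/MG ratio > 1, or MT > 1 when MG < 1, or
  ≥ 2 peptide spectral counts), per-time-point HDBSCAN clustering of
  activity profiles (minimum cluster size 5, explicit noise label), and
  MT/MG activity ratios per rMAG, condition and group.
* **Functional trends** — MT depth and MP counts aggregated per FOAM L1
  category, community-total normalised, min–max scaled, and correlated
  between omic layers.
* **Metabolomics QC** — blank-based contaminant removal (75% rule),
  prevalence filtering (all pools + ≥ 25% of samples), pooled-QC drift
  normalization (mean of up to two preceding and two following pools),
  and intracellular/extracellular metabolite ratios.
* **Consensus taxonomy** — marker-gene probability summation per rank
  with the one-third confidence rule, merged with whole-genome calls.
* **Synthetic community generator** — a deterministic multi-omic
  simulator (78 rMAGs, 4 planted functional types, 51 weekly time points,
  seasonal dynamics with one transient disturbance, activity-driven MT,
  Poisson MP, drifting GC-MS runs with pools and blanks) whose ground
  truth makes every stage testable end to end.

See `vignettes/niche-profiling-methods.Rmd` for the full methods account.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
community; each step reads the previous step's tables from `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fundamental_niches.R
Rscript analysis/03_community_dynamics.R
Rscript analysis/04_realized_niches.R
```

Output (seed 1):

```
Functional clusters: k = 4 | sizes: 24/23/19/12
KOs shared by all clusters: 2105
Per-cluster nonredundant KOs: 4306/4262/4010/3691
Enriched (KO, cluster) pairs at adjusted p < 0.05: 3206

PERMANOVA: R2 = 0.866, p = 0.001 (n_perm = 999)
Mean stability: 2.07 full series vs 2.68 excluding S34..S37

Expression clusters per time-point: median 4 (range 4 - 7)
Median MT/MG ratio per functional cluster (in situ): 1.24 / 1.51 / 1.82 / 2.08
```

Reading: the elbow rule recovers the four planted niche types at their
planted sizes; 2105 KOs are shared by all four clusters (the 1857 planted
core plus presence noise pooled over cluster members). Abundance-profile
distances are strongly structured by type (high `R²` here because the
simulated types have coherent seasonal phases), the transient disturbance
at time points 34–37 depresses community-wide temporal stability (2.07 →
2.68 when excluded), and the per-cluster median MT/MG ratios recover the
planted activity factors scaled by the 5% inactive-regime admixture
(expected 1.23 / 1.52 / 1.82 / 2.08).

Equivalent functionality is available programmatically, e.g.:

```r
library(nichescope)
sim <- simulate_community(sim_config(seed = 1))
D   <- jaccard_distances(sim$ko_presence)
emb <- classical_mds(D, 2)
k   <- choose_k_elbow(emb, seed = 1)$k       # 4
cl  <- kmeans_assign(emb, k, seed = 1)$cluster
```

or as one call over a directory of TSV inputs via `run_pipeline()`.

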