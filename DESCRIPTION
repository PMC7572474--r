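Package: nichescope
Title: Multi-Omic Niche Ecology of Microbial Populations over Time
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers fundamental and realized ecological niches of microbial
    populations from longitudinal multi-omic data. Representative
    metagenome-assembled genomes (rMAGs) are typed into functional clusters
    from binary KEGG-ortholog repertoires (Jaccard distances, classical
    multidimensional scaling, k-means with elbow selection, one-sided Fisher
    enrichment, Procrustes/PROTEST against whole-genome distances); community
    dynamics are characterised by correlation-based abundance distances,
    PERMANOVA, dispersion tests, temporal stability and ordination with
    abiotic-factor vector fitting; realized niches are profiled by binary
    expression-status calls from metatranscriptome/metagenome depth ratios and
    peptide spectral counts with per-time-point density-based clustering;
    pathway-level trends aggregate transcript and protein signal by FOAM
    category; GC-MS metabolomics are quality-filtered and drift-normalized
    against pooled QC injections; and marker-gene taxonomies are combined into
    rank-wise consensus calls. A deterministic synthetic multi-omic community
    generator with known ground truth exercises the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
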