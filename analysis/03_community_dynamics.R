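#!/usr/bin/env Rscript
# Community dynamics: relative abundances from length-weighted MG depth,
# correlation-based distances between abundance profiles, PERMANOVA and
# dispersion of those distances against the functional-cluster assignment,
# temporal stability with and without the disturbance window, Bray-Curtis
# PCoA of the samples with abiotic-factor vector fitting, and Spearman
# associations between populations and factors.

library(nichescope)

seed <- 1
quality <- read_quality_table("results/data/quality.tsv")
rmags <- select_rmags(quality[quality$mag_id %in% filter_mags(quality), ])
manifest <- read_tsv_table("results/data/manifest.tsv")
insitu <- manifest$sample_id[manifest$condition == "in_situ"]

contigs <- read_depth_table("results/data/depth_mg_contigs.tsv")
contig_map <- stats::setNames(sub("_c\\d+$", "",
                                  unique(contigs$feature_id)),
                              unique(contigs$feature_id))
rmag_mg <- rmag_depth(contigs, contig_map)
ra <- relative_abundance(rmag_mg[rmags, insitu])

funcs <- read_tsv_table("results/niches/funcs.tsv")
cl <- stats::setNames(funcs$cluster, funcs$rmag_id)

Dc <- correlation_distance_matrix(ra)
pm <- permanova(Dc, cl[rownames(Dc)], n_perm = 999, seed = seed)
dp <- dispersion_test(Dc, cl[rownames(Dc)], n_perm = 999, seed = seed)

# stability with and without the four-week disturbance (time-points 34-37)
window <- colnames(ra)[34:37]
st_full <- temporal_stability(ra)
st_excl <- temporal_stability(ra, exclude_window = window)

bc <- braycurtis_pcoa(ra)
ab <- read_tsv_table("results/data/abiotic.tsv")
abm <- as.matrix(ab[, -1]); rownames(abm) <- ab$sample_id
cat("Imputing", sum(is.na(abm[, "ph"])), "missing pH values\n")
abm[, "ph"] <- stineman_impute(abm[, "ph"])
ef <- suppressWarnings(fit_factors(bc$embedding, abm, n_perm = 999,
                                   seed = seed))
sp <- spearman_associations(ra, abm)

out <- "results/dynamics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_tsv_table(data.frame(rmag_id = rownames(ra), ra, check.names = FALSE),
                file.path(out, "abundance.tsv"))
write_tsv_table(data.frame(stat = c("pseudo_F", "R2", "p"),
                           value = c(pm$pseudo_F, pm$R2, pm$p)),
                file.path(out, "permanova.tsv"))
stab <- st_full[, c("rmag_id", "stability")]
names(stab)[2] <- "stability_full"
stab$stability_excluding <- st_excl$stability
write_tsv_table(stab, file.path(out, "stability.tsv"))
write_tsv_table(ef, file.path(out, "envfit.tsv"))
write_tsv_table(sp[sp$p_adj < 0.05, ], file.path(out, "spearman.tsv"))

cat(sprintf("PERMANOVA: R2 = %.3f, p = %.3f (n_perm = 999)\n", pm$R2, pm$p))
cat(sprintf("Dispersion: F = %.2f, p = %.3f\n", dp$F, dp$p))
cat(sprintf("Mean stability: %.2f full series vs %.2f excluding %s..%s\n",
            mean(st_full$stability, na.rm = TRUE),
            mean(st_excl$stability, na.rm = TRUE),
            window[1], window[length(window)]))
cat("Significant factor fits (p < 0.05):",
    paste(ef$factor[ef$p < 0.05], collapse = ", "), "\n")
cat("Population-factor associations at adjusted p < 0.05:",
    sum(sp$p_adj < 0.05), "of", nrow(sp), "\n")
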