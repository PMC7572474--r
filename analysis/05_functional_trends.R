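#!/usr/bin/env Rscript
# Pathway-level trends: gene MT depth and MP spectral counts summed per
# top-level FOAM category, divided by the per-time-point community totals,
# min-max scaled, and correlated (Pearson) between the two omic layers.

library(nichescope)

ann <- read_annotations("results/data/annotations.tsv")
manifest <- read_tsv_table("results/data/manifest.tsv")
insitu <- manifest$sample_id[manifest$condition == "in_situ"]

gene_mt <- compute_depth(read_depth_table("results/data/depth_mt.tsv"))
mp <- read_tsv_table("results/data/mp_counts.tsv")
mp_mat <- matrix(0, nrow(gene_mt), ncol(gene_mt),
                 dimnames = dimnames(gene_mt))
mp_mat[cbind(match(mp$gene_id, rownames(gene_mt)),
             match(mp$sample_id, colnames(gene_mt)))] <- mp$count

res <- foam_trend(gene_mt[, insitu], mp_mat[, insitu], ann)

out <- "results/trends"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_tsv_table(res$trends, file.path(out, "foam_trends.tsv"))
write_tsv_table(res$correlations, file.path(out, "foam_correlations.tsv"))

cat("FOAM L1 categories:", nrow(res$correlations), "\n")
cat("MT-MP correlation per category (highest MP share first):\n")
print(transform(res$correlations, r = round(r, 3),
                mean_mp_rel = round(mean_mp_rel, 4)))
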