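#!/usr/bin/env Rscript
# Realized niches: per-time-point binary KO expression status from MT/MG
# depth ratios and peptide spectral counts, density-based clustering of the
# per-time-point expression profiles, and MT/MG activity ratios per rMAG
# summarised by functional cluster and condition.

library(nichescope)

ann <- read_annotations("results/data/annotations.tsv")
manifest <- read_tsv_table("results/data/manifest.tsv")
insitu <- manifest$sample_id[manifest$condition == "in_situ"]

gene_mg <- compute_depth(read_depth_table("results/data/depth_mg.tsv"))
gene_mt <- compute_depth(read_depth_table("results/data/depth_mt.tsv"))
mp <- read_tsv_table("results/data/mp_counts.tsv")
mp_mat <- matrix(0, nrow(gene_mg), ncol(gene_mg),
                 dimnames = dimnames(gene_mg))
mp_mat[cbind(match(mp$gene_id, rownames(gene_mg)),
             match(mp$sample_id, colnames(gene_mg)))] <- mp$count

rows <- list()
for (tp in insitu) {
  act <- suppressMessages(ko_activity_call(gene_mg[, tp], gene_mt[, tp],
                                           mp_mat[, tp], ann))
  cl <- cluster_expression_profiles(activity_matrix(act))
  rows[[tp]] <- data.frame(timepoint = tp, rmag_id = names(cl$cluster),
                           label = unname(cl$cluster))
}
clusters <- do.call(rbind, rows)

rmag_mg <- rmag_depth_from_gene_matrix(gene_mg, ann)
rmag_mt <- rmag_depth_from_gene_matrix(gene_mt, ann)
funcs <- read_tsv_table("results/niches/funcs.tsv")
grouping <- stats::setNames(funcs$cluster, funcs$rmag_id)
cond <- stats::setNames(manifest$condition, manifest$sample_id)
ratios <- suppressMessages(
  mtmg_ratio(rmag_mg, rmag_mt, grouping, cond))

out <- "results/expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_tsv_table(clusters, file.path(out, "clusters.tsv"))
write_tsv_table(ratios$per_rmag, file.path(out, "mtmg_ratios.tsv"))
write_tsv_table(ratios$per_group, file.path(out, "mtmg_groups.tsv"))

ncl <- tapply(clusters$label, clusters$timepoint,
              function(v) length(unique(v[v > 0])))
cat("Expression clusters per time-point: median", stats::median(ncl),
    "(range", min(ncl), "-", max(ncl), ")\n")
noise <- mean(clusters$label == 0)
cat(sprintf("Noise fraction across time-points: %.1f%%\n", 100 * noise))
pg <- ratios$per_group[ratios$per_group$condition == "in_situ", ]
cat("Median MT/MG ratio per functional cluster (in situ):",
    paste(round(pg$median, 2), collapse = " / "), "\n")
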