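#!/usr/bin/env Rscript
# Meta-metabolomics QC and normalization per fraction: blank-based
# contaminant removal (75% rule), prevalence filtering (all pools, >= 25%
# of samples), pool-based drift normalization, and intracellular vs
# extracellular ratios for metabolites detected in both fractions.

library(nichescope)

fractions <- c("intra_polar", "intra_nonpolar", "extra_polar",
               "extra_nonpolar")
out <- "results/metabolomics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

runs <- list()
for (fr in fractions) {
  xi <- read_tsv_table(sprintf("results/data/mm_%s.tsv", fr))
  X <- as.matrix(xi[, -1]); rownames(X) <- xi[[1]]
  mf <- read_tsv_table(sprintf("results/data/mm_%s_manifest.tsv", fr))
  run <- metabolite_run(X, mf)
  bf <- blank_filter(run)
  pf <- prevalence_filter(bf$run)
  dn <- suppressWarnings(drift_normalize(pf$run))
  runs[[fr]] <- dn$run
  pc <- which(run$manifest$role == "pool")
  cv <- function(M) mean(apply(M, 1, function(v) sd(v) / mean(v)),
                         na.rm = TRUE)
  cat(sprintf(
    "%s: %d contaminants removed, %d low-prevalence removed, %d kept; ",
    fr, length(bf$removed), length(pf$removed),
    nrow(dn$run$intensities)))
  cat(sprintf("pool CV %.3f -> %.3f\n",
              cv(pf$run$intensities[, pc]), cv(dn$run$intensities[, pc])))
  write_tsv_table(data.frame(metabolite = rownames(dn$run$intensities),
                             dn$run$intensities, check.names = FALSE),
                  file.path(out, sprintf("normalized_%s.tsv", fr)))
}

for (pol in c("polar", "nonpolar")) {
  rt <- intra_extra_ratio(runs[[paste0("intra_", pol)]],
                          runs[[paste0("extra_", pol)]])
  cat(sprintf("%s fraction: %d metabolites detected in both fractions\n",
              pol, length(rt$shared)))
  write_tsv_table(data.frame(metabolite = rownames(rt$ratios), rt$ratios,
                             check.names = FALSE),
                  file.path(out, sprintf("ratios_%s.tsv", pol)))
}
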