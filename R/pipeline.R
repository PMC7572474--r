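#' Run the full niche-profiling pipeline on a directory of input tables
#'
#' Executes the stages in dependency order — input loading and quality
#' filtering, fundamental niche typing, community dynamics, expression
#' profiling, functional trends, metabolomics and (when marker tables are
#' present) taxonomy — on the TSV files written by [write_simulation()] or
#' supplied by the user, writing one output table per result under
#' `out_dir` together with a machine-readable JSON run report (seeds,
#' stage row counts, warnings). Re-running with the same inputs and seed
#' reproduces the outputs exactly.
#'
#' @param in_dir directory with the input TSVs (`annotations.tsv`,
#'   `quality.tsv`, `manifest.tsv`, `depth_mg_contigs.tsv`, `depth_mg.tsv`,
#'   `depth_mt.tsv`, `mp_counts.tsv`, `abiotic.tsv`, `mm_*.tsv`, optionally
#'   `markers.tsv`/`genome_tax.tsv`).
#' @param out_dir output directory (created).
#' @param seed integer seed for every stochastic stage.
#' @param stages character vector of stages to run (default all).
#' @param n_perm permutations for the permutation tests (default 999).
#' @param exclude_window time-point (sample) ids excluded in the
#'   stability-without-disturbance computation, or NULL.
#' @param k_override manual number of functional clusters, or NULL for the
#'   elbow rule.
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(in_dir, out_dir, seed = 1,
                         stages = c("niches", "dynamics", "expression",
                                    "trends", "metabolomics", "taxonomy"),
                         n_perm = 999, exclude_window = NULL,
                         k_override = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = seed, stages = list(),
                 started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  note <- function(stage, ...) {
    report$stages[[stage]] <<- c(report$stages[[stage]], list(...))
  }

  ann <- read_annotations(file.path(in_dir, "annotations.tsv"))
  quality <- read_quality_table(file.path(in_dir, "quality.tsv"))
  manifest <- read_tsv_table(file.path(in_dir, "manifest.tsv"),
                             c("sample_id", "timepoint", "condition"))
  rmags <- select_rmags(quality[quality$mag_id %in%
                                  filter_mags(quality), , drop = FALSE])
  report$n_rmags <- length(rmags)

  gene_map <- stats::setNames(ann$rmag_id[!duplicated(ann$gene_id)],
                              ann$gene_id[!duplicated(ann$gene_id)])
  insitu <- manifest$sample_id[manifest$condition == "in_situ"]

  contig_rec <- read_depth_table(file.path(in_dir, "depth_mg_contigs.tsv"))
  contig_map <- stats::setNames(
    sub("_c\\d+$", "", unique(contig_rec$feature_id)),
    unique(contig_rec$feature_id))
  rmag_mg <- rmag_depth(contig_rec, contig_map)
  mg_rec <- read_depth_table(file.path(in_dir, "depth_mg.tsv"))
  mt_rec <- read_depth_table(file.path(in_dir, "depth_mt.tsv"))
  gene_mg <- compute_depth(mg_rec)
  gene_mt <- compute_depth(mt_rec)
  mp <- read_tsv_table(file.path(in_dir, "mp_counts.tsv"),
                       c("gene_id", "sample_id", "count"))
  genes <- rownames(gene_mg)
  mp_mat <- matrix(0, length(genes), ncol(gene_mg),
                   dimnames = dimnames(gene_mg))
  mp_mat[cbind(match(mp$gene_id, genes),
               match(mp$sample_id, colnames(gene_mg)))] <- mp$count

  M <- NULL; funcs <- NULL

  if ("niches" %in% stages) {
    M <- build_ko_presence(ann, rmags)
    D <- jaccard_distances(M)
    emb <- classical_mds(D, 2)
    ke <- choose_k_elbow(emb, seed = seed, k_override = k_override)
    funcs <- kmeans_assign(emb, ke$k, seed = seed)
    ovl <- ko_set_overlaps(M, funcs$cluster)
    enr <- fisher_enrichment(M, funcs$cluster)
    write_tsv_table(data.frame(rmag_id = names(funcs$cluster),
                               cluster = unname(funcs$cluster)),
                    file.path(out_dir, "funcs.tsv"))
    write_tsv_table(data.frame(rmag_id = rownames(emb), emb,
                               check.names = FALSE),
                    file.path(out_dir, "embedding.tsv"))
    write_tsv_table(enr, file.path(out_dir, "enrichment.tsv"))
    write_tsv_table(ovl$regions, file.path(out_dir, "overlaps.tsv"))
    mash_path <- file.path(in_dir, "genome_dist.tsv")
    if (file.exists(mash_path)) {
      GD <- as.matrix(read_tsv_table(mash_path))
      rownames(GD) <- colnames(GD)
      gemb <- classical_mds(GD[rmags, rmags], 2)
      pro <- procrustes_protest(emb, gemb, n_perm = 9999, seed = seed)
      write_tsv_table(data.frame(m2 = pro$m2,
                                 correlation = pro$correlation,
                                 p = pro$p),
                      file.path(out_dir, "protest.tsv"))
    }
    note("niches", k = ke$k, n_enriched = sum(enr$enriched))
  }

  if ("dynamics" %in% stages) {
    ra <- relative_abundance(rmag_mg[rmags, insitu])
    write_tsv_table(data.frame(rmag_id = rownames(ra), ra,
                               check.names = FALSE),
                    file.path(out_dir, "abundance.tsv"))
    Dc <- correlation_distance_matrix(ra)
    write_tsv_table(data.frame(rmag_id = rownames(Dc), Dc,
                               check.names = FALSE),
                    file.path(out_dir, "dist_corr.tsv"))
    if (!is.null(funcs)) {
      pm <- permanova(Dc, funcs$cluster[rownames(Dc)], n_perm = n_perm,
                      seed = seed)
      dp <- dispersion_test(Dc, funcs$cluster[rownames(Dc)],
                            n_perm = n_perm, seed = seed)
      write_tsv_table(data.frame(pseudo_F = pm$pseudo_F, R2 = pm$R2,
                                 p = pm$p),
                      file.path(out_dir, "permanova.tsv"))
      write_tsv_table(data.frame(F = dp$F, p = dp$p),
                      file.path(out_dir, "dispersion.tsv"))
      note("dynamics", permanova_R2 = pm$R2, permanova_p = pm$p)
    }
    st_all <- temporal_stability(ra)
    st_excl <- if (!is.null(exclude_window))
      temporal_stability(ra, exclude_window) else NULL
    stab <- st_all
    names(stab)[2] <- "stability_full"
    if (!is.null(st_excl)) stab$stability_excluding <- st_excl$stability
    write_tsv_table(stab, file.path(out_dir, "stability.tsv"))
    bc <- braycurtis_pcoa(ra)
    write_tsv_table(data.frame(sample_id = rownames(bc$embedding),
                               bc$embedding, check.names = FALSE),
                    file.path(out_dir, "pcoa.tsv"))
    ab <- read_tsv_table(file.path(in_dir, "abiotic.tsv"))
    abm <- as.matrix(ab[, -1, drop = FALSE])
    rownames(abm) <- ab$sample_id
    if ("ph" %in% colnames(abm))
      abm[, "ph"] <- stineman_impute(abm[, "ph"])
    ef <- fit_factors(bc$embedding, abm, n_perm = n_perm, seed = seed)
    write_tsv_table(ef, file.path(out_dir, "envfit.tsv"))
    sp <- spearman_associations(ra, abm)
    write_tsv_table(sp, file.path(out_dir, "spearman.tsv"))
  }

  if ("expression" %in% stages) {
    rmag_mt <- rmag_depth(
      data.frame(feature_id = mt_rec$feature_id,
                 sample_id = mt_rec$sample_id,
                 summed_depth = mt_rec$summed_depth,
                 length_bp = mt_rec$length_bp, stringsAsFactors = FALSE),
      gene_map)
    rmag_mg_genes <- rmag_depth(mg_rec, gene_map)
    cond <- stats::setNames(manifest$condition, manifest$sample_id)
    grouping <- if (!is.null(funcs)) funcs$cluster else
      stats::setNames(rep(1L, length(rmags)), rmags)
    mm <- mtmg_ratio(rmag_mg_genes[rmags, , drop = FALSE],
                     rmag_mt[rmags, , drop = FALSE], grouping, cond)
    write_tsv_table(mm$per_rmag, file.path(out_dir, "mtmg_ratios.tsv"))
    write_tsv_table(mm$per_group, file.path(out_dir, "mtmg_groups.tsv"))
    clusters <- list()
    rows <- list()
    for (tp in insitu) {
      act <- ko_activity_call(gene_mg[, tp], gene_mt[, tp], mp_mat[, tp],
                              ann)
      A <- activity_matrix(act)
      cl <- cluster_expression_profiles(A)
      clusters[[tp]] <- cl$cluster
      rows[[tp]] <- data.frame(timepoint = tp,
                               rmag_id = names(cl$cluster),
                               label = unname(cl$cluster),
                               stringsAsFactors = FALSE)
    }
    write_tsv_table(do.call(rbind, rows), file.path(out_dir, "clusters.tsv"))
    note("expression", n_timepoints = length(insitu))
  }

  if ("trends" %in% stages) {
    tr <- foam_trend(gene_mt[, insitu, drop = FALSE],
                     mp_mat[, insitu, drop = FALSE], ann)
    write_tsv_table(tr$trends, file.path(out_dir, "foam_trends.tsv"))
    write_tsv_table(tr$correlations,
                    file.path(out_dir, "foam_correlations.tsv"))
  }

  if ("metabolomics" %in% stages) {
    fractions <- c("intra_polar", "intra_nonpolar", "extra_polar",
                   "extra_nonpolar")
    runs <- list()
    removed <- list()
    for (fr in fractions) {
      fx <- file.path(in_dir, paste0("mm_", fr, ".tsv"))
      if (!file.exists(fx)) next
      xi <- read_tsv_table(fx)
      X <- as.matrix(xi[, -1, drop = FALSE])
      rownames(X) <- xi[[1]]
      mf <- read_tsv_table(file.path(in_dir,
                                     paste0("mm_", fr, "_manifest.tsv")),
                           c("measurement_id", "role"))
      run <- metabolite_run(X, mf)
      bf <- blank_filter(run)
      pf <- prevalence_filter(bf$run)
      dn <- suppressWarnings(drift_normalize(pf$run))
      runs[[fr]] <- dn$run
      removed[[fr]] <- data.frame(
        fraction = fr,
        metabolite = c(bf$removed, pf$removed),
        reason = c(rep("blank", length(bf$removed)),
                   rep("prevalence", length(pf$removed))),
        stringsAsFactors = FALSE)
      out <- data.frame(metabolite = rownames(dn$run$intensities),
                        dn$run$intensities, check.names = FALSE)
      write_tsv_table(out, file.path(out_dir,
                                     paste0("normalized_", fr, ".tsv")))
    }
    if (length(removed))
      write_tsv_table(do.call(rbind, removed),
                      file.path(out_dir, "removed_contaminants.tsv"))
    for (pol in c("polar", "nonpolar")) {
      ii <- paste0("intra_", pol); ee <- paste0("extra_", pol)
      if (!is.null(runs[[ii]]) && !is.null(runs[[ee]])) {
        rt <- intra_extra_ratio(runs[[ii]], runs[[ee]])
        write_tsv_table(data.frame(metabolite = rownames(rt$ratios),
                                   rt$ratios, check.names = FALSE),
                        file.path(out_dir, paste0("ratios_", pol, ".tsv")))
      }
    }
    note("metabolomics", n_fractions = length(runs))
  }

  if ("taxonomy" %in% stages &&
      file.exists(file.path(in_dir, "markers.tsv"))) {
    markers <- read_tsv_table(file.path(in_dir, "markers.tsv"),
                              c("rmag_id", "marker_id", "rank", "taxon",
                                "probability"))
    gt_path <- file.path(in_dir, "genome_tax.tsv")
    genome_tax <- if (file.exists(gt_path))
      read_tsv_table(gt_path, c("rmag_id", "rank", "taxon")) else NULL
    lin <- consensus_lineages(markers, genome_tax)
    write_tsv_table(lin, file.path(out_dir, "lineage.tsv"))
    note("taxonomy", n_rmags = length(unique(lin$rmag_id)))
  }

  report$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(report)
}
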