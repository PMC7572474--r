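#' Configuration for the synthetic multi-omic community
#'
#' The generator emulates a weekly-sampled activated-sludge community
#' followed over 14 months with metagenomic (MG), metatranscriptomic (MT),
#' metaproteomic (MP) and meta-metabolomic measurements: 78 populations
#' (rMAGs) of four planted functional types, 51 time-points with seasonal
#' abundance dynamics and one transient disturbance window, MT depth as MG
#' depth times type- and condition-dependent activity, Poisson spectral
#' counts driven by MT, and GC-MS runs with pooled QC injections, blanks
#' and multiplicative instrument drift. All randomness derives from the
#' master `seed` through fixed per-stage offsets, so adding a stage never
#' perturbs earlier draws.
#'
#' @param seed master integer seed.
#' @param n_rmags number of rMAGs (default 78).
#' @param type_sizes members per planted functional type (default
#'   24/23/19/12, summing to `n_rmags`).
#' @param n_timepoints weekly time-points (default 51, starting 2011-03-21).
#' @param ko_universe size of the KO vocabulary (default 6000).
#' @param n_core_kos KOs shared by every type (default 1857).
#' @param type_specific_kos size of each type's specific KO block (default
#'   800).
#' @param type_overlap KOs shared between the specific blocks of adjacent
#'   types (default 300): the blocks form an overlapping chain, so
#'   between-type similarities are unequal, as in real functional clusters.
#' @param n_private_kos accessory KOs drawn per rMAG (default 30).
#' @param flip_noise per-cell presence flip probability (default 0.02).
#' @param disturbance_window time-point indices of the transient
#'   disturbance (default 34:37, emulating four weeks in November).
#' @param disturbance_type planted type whose members spike (default 3).
#' @param spike_factor abundance multiplier inside the window (default 10,
#'   a drastic transient shift in community structure).
#' @param act_factors per-type MT/MG activity factor of expressed genes
#'   (default 2.0/2.5/3.0/3.5).
#' @param inactive_factor MT/MG factor of non-expressed genes (default 0.2).
#' @param p_active expression probability of a planted-active KO per
#'   time-point (default 0.95, i.e. 5% regime noise).
#' @param p_background expression probability of any other KO (default
#'   0.05).
#' @param depth_scale median metagenomic depth of coverage of a population
#'   (default 10): recovered major populations are well above the depth-1
#'   detectability threshold of the expression-status rule.
#' @param mp_scale spectral counts per unit MT depth (default 0.05; peptide
#'   identifications are sparse relative to transcript depth).
#' @param conditions condition labels; the time-series itself is `in_situ`,
#'   the others get short pulse-experiment sample sets.
#' @param n_condition_samples samples per non-in-situ condition (default 3).
#' @param pool_every pooled QC injection after every `pool_every`-th
#'   measurement (default 5).
#' @param n_blanks blank injections per run (default 3).
#' @param total_drift multiplicative instrument drift over a whole run
#'   (default 1.2); the drift curve is sigmoidal and monotone, settling at
#'   the run start and saturating towards the end.
#' @param pool_cv technical coefficient of variation of pooled QC
#'   injections (default 0.065).
#' @param n_metabolites metabolites per fraction (default 60).
#' @param n_shared_metabolites metabolites shared between the intra- and
#'   extracellular fraction of each polarity (default 21, so 42 in total).
#' @param n_contaminants planted contaminant metabolites per fraction
#'   (default 5).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_rmags = 78,
                       type_sizes = c(24, 23, 19, 12),
                       n_timepoints = 51,
                       ko_universe = 6000,
                       n_core_kos = 1857,
                       type_specific_kos = 800,
                       type_overlap = 300,
                       n_private_kos = 30,
                       flip_noise = 0.02,
                       disturbance_window = 34:37,
                       disturbance_type = 3,
                       spike_factor = 10,
                       act_factors = c(2.0, 2.5, 3.0, 3.5),
                       inactive_factor = 0.2,
                       p_active = 0.95,
                       p_background = 0.05,
                       depth_scale = 10,
                       mp_scale = 0.05,
                       conditions = c("in_situ", "aerobic", "anoxic",
                                      "alternating_aerobic",
                                      "alternating_anoxic"),
                       n_condition_samples = 3,
                       pool_every = 5,
                       n_blanks = 3,
                       total_drift = 1.2,
                       pool_cv = 0.065,
                       n_metabolites = 60,
                       n_shared_metabolites = 21,
                       n_contaminants = 5) {
  cfg <- as.list(environment())
  n_types <- length(cfg$type_sizes)
  if (sum(cfg$type_sizes) != cfg$n_rmags)
    stop("type_sizes must sum to n_rmags", call. = FALSE)
  if (cfg$type_overlap >= cfg$type_specific_kos)
    stop("type_overlap must be smaller than type_specific_kos",
         call. = FALSE)
  strip_len <- (n_types - 1) * (cfg$type_specific_kos - cfg$type_overlap) +
    cfg$type_specific_kos
  if (cfg$n_core_kos + strip_len > cfg$ko_universe)
    stop("infeasible KO budget: core + type-specific exceeds the universe",
         call. = FALSE)
  if (length(cfg$disturbance_window) &&
      (min(cfg$disturbance_window) < 1 ||
       max(cfg$disturbance_window) > cfg$n_timepoints))
    stop("disturbance_window outside the time-series", call. = FALSE)
  cfg$n_types <- n_types
  class(cfg) <- "sim_config"
  cfg
}

# Fixed seed offsets for the independent pseudo-random streams.
.sim_offsets <- c(repertoire = 101L, quality = 211L, timeseries = 307L,
                  activity = 401L, metabolome = 503L, abiotic = 601L)

sim_seed <- function(cfg, stage) {
  (as.integer(cfg$seed) + .sim_offsets[[stage]]) %% .Machine$integer.max
}

#' Simulate KO repertoires with planted functional types
#'
#' Every rMAG carries all core KOs, its type's specific KOs, and a private
#' accessory draw; each cell of the resulting presence matrix is then
#' flipped independently with probability `flip_noise`.
#'
#' @param cfg a [sim_config()].
#' @return list with `ko_presence` (binary matrix rMAG x KO), `truth`
#'   (planted types, KO block structure) and `quality` (simulated genome
#'   completeness/contamination table).
#' @export
simulate_repertoires <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  kos <- sprintf("K%05d", seq_len(cfg$ko_universe))
  core <- kos[seq_len(cfg$n_core_kos)]
  step <- cfg$type_specific_kos - cfg$type_overlap
  type_blocks <- lapply(seq_len(cfg$n_types), function(t)
    kos[cfg$n_core_kos + (t - 1) * step + seq_len(cfg$type_specific_kos)])
  strip_len <- (cfg$n_types - 1) * step + cfg$type_specific_kos
  private_pool <- kos[(cfg$n_core_kos + strip_len + 1):cfg$ko_universe]
  rmag_ids <- sprintf("rmag%03d", seq_len(cfg$n_rmags))
  type_of <- rep(seq_len(cfg$n_types), times = cfg$type_sizes)
  names(type_of) <- rmag_ids

  M <- matrix(0L, cfg$n_rmags, cfg$ko_universe,
              dimnames = list(rmag_ids, kos))
  private_of <- with_seed(sim_seed(cfg, "repertoire"), {
    priv <- lapply(rmag_ids, function(r)
      sample(private_pool, min(cfg$n_private_kos, length(private_pool))))
    names(priv) <- rmag_ids
    for (r in rmag_ids) {
      M[r, core] <- 1L
      M[r, type_blocks[[type_of[r]]]] <- 1L
      M[r, priv[[r]]] <- 1L
    }
    if (cfg$flip_noise > 0) {
      flips <- matrix(stats::runif(length(M)) < cfg$flip_noise,
                      nrow(M), ncol(M))
      M <- abs(M - flips * 1L)
    } else {
      M <- M
    }
    priv
  })
  quality <- with_seed(sim_seed(cfg, "quality"), data.frame(
    mag_id = rmag_ids,
    completeness = 0.5 + 0.45 * stats::rbeta(cfg$n_rmags, 2.9, 2.1),
    contamination = stats::rbeta(cfg$n_rmags, 2, 88),
    kingdom = "Bacteria", stringsAsFactors = FALSE))
  truth <- list(type_of_rmag = type_of, core_kos = core,
                type_kos = type_blocks, private_kos = private_of,
                rmag_ids = rmag_ids)
  list(ko_presence = M, truth = truth, quality = quality)
}

# The expressed gene panel: which KOs carry genes in the time-series, and
# which of them are planted active for each type/condition.
sim_panels <- function(cfg, rep_out) {
  truth <- rep_out$truth
  shared_panel <- truth$core_kos[1:30]
  # middle of each specific block: unique to the type even with the
  # chain overlap between adjacent blocks
  type_panel <- lapply(truth$type_kos, function(b) {
    mid <- floor(length(b) / 2)
    b[(mid - 9):(mid + 10)]
  })
  housekeeping <- shared_panel[1:15]  # active in every type
  active_sets <- lapply(seq_len(cfg$n_types), function(t)
    c(housekeeping, type_panel[[t]]))
  list(shared_panel = shared_panel, type_panel = type_panel,
       active_sets = active_sets)
}

#' Simulate the multi-omic time-series
#'
#' Abundances follow a per-type seasonal sinusoid with log-normal noise;
#' members of the disturbance type are multiplied by `spike_factor` inside
#' the disturbance window. Gene-level MG summed depth is proportional to
#' abundance with gamma noise; MT depth is MG depth times a per-gene,
#' per-time-point activity factor (the type's `act_factor` with probability
#' given by the planted activity regime, `inactive_factor` otherwise); MP
#' spectral counts are Poisson with mean `mp_scale` times MT depth. Abiotic
#' factors are linear mixtures of a seasonal and a disturbance latent
#' signal plus noise; the pH factor carries six missing values for the
#' imputation path.
#'
#' @param cfg a [sim_config()].
#' @param rep_out result of [simulate_repertoires()].
#' @return list with annotation table, contig- and gene-level depth records,
#'   depth/count matrices, manifest, abiotic table and augmented truth.
#' @export
simulate_timeseries <- function(cfg, rep_out) {
  truth <- rep_out$truth
  type_of <- truth$type_of_rmag
  rmag_ids <- truth$rmag_ids
  panels <- sim_panels(cfg, rep_out)
  tps <- format(seq(as.Date("2011-03-21"), by = 7,
                    length.out = cfg$n_timepoints))
  samples <- sprintf("S%02d", seq_len(cfg$n_timepoints))

  # -- genes ---------------------------------------------------------------
  # The annotation table covers the whole repertoire (one gene per KO an
  # rMAG carries, plus a few unannotated genes); only the expressed panel
  # genes additionally carry MG/MT/MP measurements — every other gene is
  # simply absent from the depth tables (depth 0 downstream).
  gene_info <- with_seed(sim_seed(cfg, "repertoire") + 1L, {
    foam_cats <- paste0("L1_", sprintf("%02d", 1:8))
    ko_list <- lapply(rmag_ids, function(r)
      c(colnames(rep_out$ko_presence)[rep_out$ko_presence[r, ] == 1L],
        rep(NA_character_, 5L)))  # plus unannotated genes
    panel_list <- lapply(rmag_ids, function(r)
      sample(truth$private_kos[[r]], 5))
    n_per <- lengths(ko_list)
    rmag_col <- rep(rmag_ids, times = n_per)
    ko_col <- unlist(ko_list, use.names = FALSE)
    gene_col <- sprintf("%s_g%04d", rmag_col,
                        unlist(lapply(n_per, seq_len), use.names = FALSE))
    panel_kos <- mapply(function(r, extra)
      c(panels$shared_panel, panels$type_panel[[type_of[r]]], extra),
      rmag_ids, panel_list, SIMPLIFY = FALSE)
    measured <- logical(length(ko_col))
    idx <- split(seq_along(ko_col), rmag_col)
    for (r in rmag_ids)
      measured[idx[[r]]] <- is.na(ko_col[idx[[r]]]) |
        ko_col[idx[[r]]] %in% panel_kos[[r]]
    ko_num <- suppressWarnings(as.integer(sub("^K", "", ko_col)))
    data.frame(
      gene_id = gene_col, rmag_id = rmag_col, ko_id = ko_col,
      foam_l1 = ifelse(is.na(ko_col), NA_character_,
                       foam_cats[(ko_num %% 8L) + 1L]),
      length_bp = as.integer(round(stats::runif(length(ko_col), 600, 1800))),
      measured = measured, stringsAsFactors = FALSE)
  })
  ann <- gene_info[, c("gene_id", "rmag_id", "ko_id", "foam_l1",
                       "length_bp")]
  panel_genes <- gene_info[gene_info$measured, ]

  # -- abundance -----------------------------------------------------------
  abund <- with_seed(sim_seed(cfg, "timeseries"), {
    base <- cfg$depth_scale * stats::rlnorm(cfg$n_rmags, 0, 0.6)
    phase <- stats::runif(cfg$n_types, 0, 2 * pi)[type_of] +
      stats::rnorm(cfg$n_rmags, 0, 0.3)
    amp <- stats::runif(cfg$n_rmags, 0.3, 0.6)
    A <- matrix(0, cfg$n_rmags, cfg$n_timepoints,
                dimnames = list(rmag_ids, samples))
    for (t in seq_len(cfg$n_timepoints)) {
      seasonal <- 1 + amp * sin(2 * pi * t / 52 + phase)
      A[, t] <- base * seasonal * stats::rlnorm(cfg$n_rmags, 0, 0.25)
    }
    spike_rmags <- rmag_ids[type_of == cfg$disturbance_type]
    A[spike_rmags, cfg$disturbance_window] <-
      A[spike_rmags, cfg$disturbance_window] * cfg$spike_factor
    A
  })
  disturbance_rmags <- rmag_ids[type_of == cfg$disturbance_type]

  # -- contig-level MG records --------------------------------------------
  contigs <- with_seed(sim_seed(cfg, "timeseries") + 1L, {
    per <- 4L
    contig_ids <- as.vector(vapply(rmag_ids, function(r)
      sprintf("%s_c%d", r, seq_len(per)), character(per)))
    contig_rmag <- rep(rmag_ids, each = per)
    len <- as.integer(round(stats::runif(length(contig_ids), 3e4, 8e4)))
    rows <- vector("list", cfg$n_timepoints)
    for (t in seq_len(cfg$n_timepoints)) {
      depth <- abund[contig_rmag, t] *
        stats::rlnorm(length(contig_ids), 0, 0.05)
      rows[[t]] <- data.frame(feature_id = contig_ids,
                              sample_id = samples[t],
                              summed_depth = depth * len,
                              length_bp = len, stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, rows),
         map = stats::setNames(contig_rmag, contig_ids))
  })

  # -- gene-level MG / MT / MP (measured panel genes only) -----------------
  genes <- panel_genes$gene_id
  gene_rmag <- panel_genes$rmag_id
  gene_type <- type_of[gene_rmag]
  # planted activity probability of each gene under in-situ conditions
  p_gene <- ifelse(is.na(panel_genes$ko_id), cfg$p_background,
                   ifelse(mapply(function(k, t) k %in% panels$active_sets[[t]],
                                 panel_genes$ko_id, gene_type),
                          cfg$p_active, cfg$p_background))
  cond_mult <- stats::setNames(
    c(1, 1.15, 0.85, 1.05, 0.9)[seq_along(cfg$conditions)], cfg$conditions)

  ng <- length(genes)
  sdlog_f <- 0.2
  omics <- with_seed(sim_seed(cfg, "activity"), {
    MG <- matrix(0, ng, cfg$n_timepoints, dimnames = list(genes, samples))
    MT <- MG; MP <- MG
    act <- cfg$act_factors[gene_type]
    for (t in seq_len(cfg$n_timepoints)) {
      mg <- abund[gene_rmag, t] * stats::rgamma(ng, shape = 25, rate = 25)
      status <- stats::runif(ng) < p_gene
      f <- ifelse(status, act, cfg$inactive_factor) *
        stats::rlnorm(ng, -sdlog_f^2 / 2, sdlog_f)
      mt <- mg * f
      MG[, t] <- mg
      MT[, t] <- mt
      MP[, t] <- stats::rpois(ng, cfg$mp_scale * mt)
    }
    list(MG = MG, MT = MT, MP = MP)
  })

  # pulse-experiment samples for the non-in-situ conditions
  extra <- with_seed(sim_seed(cfg, "activity") + 1L, {
    conds <- setdiff(cfg$conditions, "in_situ")
    if (!length(conds) || cfg$n_condition_samples < 1)
      return(list(MG = NULL, MT = NULL, MP = NULL, manifest = NULL))
    ids <- as.vector(vapply(conds, function(cc)
      sprintf("X_%s_%d", cc, seq_len(cfg$n_condition_samples)),
      character(cfg$n_condition_samples)))
    cond_of <- rep(conds, each = cfg$n_condition_samples)
    MG <- matrix(0, ng, length(ids), dimnames = list(genes, ids))
    MT <- MG; MP <- MG
    base_ab <- rowMeans(abund)
    act <- cfg$act_factors[gene_type]
    for (j in seq_along(ids)) {
      mg <- base_ab[gene_rmag] * stats::rgamma(ng, shape = 25, rate = 25)
      status <- stats::runif(ng) < p_gene
      f <- ifelse(status, act * cond_mult[cond_of[j]],
                  cfg$inactive_factor) *
        stats::rlnorm(ng, -sdlog_f^2 / 2, sdlog_f)
      MG[, j] <- mg
      MT[, j] <- mg * f
      MP[, j] <- stats::rpois(ng, cfg$mp_scale * MG[, j] * f)
    }
    list(MG = MG, MT = MT, MP = MP,
         manifest = data.frame(sample_id = ids, timepoint = NA_character_,
                               condition = cond_of,
                               stringsAsFactors = FALSE))
  })

  # -- abiotic factors -----------------------------------------------------
  abiotic <- with_seed(sim_seed(cfg, "abiotic"), {
    t_idx <- seq_len(cfg$n_timepoints)
    latent_season <- sin(2 * pi * t_idx / 52)
    latent_dist <- as.numeric(t_idx %in% cfg$disturbance_window)
    meta <- data.frame(
      factor_id = c("temperature", "ph", "conductivity", "oxygen",
                    "nitrate", "phosphate", "oleic_acid_ratio",
                    "mannose_extra", "glucose_extra", "dry_matter",
                    "ammonium", "inflow_ph"),
      class = c("pcparams", "pcparams", "pcparams", "pcparams", "pcparams",
                "pcparams", "ratio", "sp", "sp", "pcparams", "pcparams",
                "pcparams"),
      source = c(rep("manual", 6), rep("online", 6)),
      stringsAsFactors = FALSE)
    nf <- nrow(meta)
    alpha <- stats::runif(nf, -1.5, 1.5)
    beta <- c(0, 0, 0.5, -0.5, 1.5, 1.0, 1.2, 2.0, 1.8, 0.3, 0.8, 0.2)
    V <- matrix(0, cfg$n_timepoints, nf,
                dimnames = list(samples, meta$factor_id))
    for (j in seq_len(nf))
      V[, j] <- alpha[j] * latent_season + beta[j] * latent_dist +
        stats::rnorm(cfg$n_timepoints, 0, 0.5)
    V[sample(t_idx[-c(1, cfg$n_timepoints)], 6), "ph"] <- NA
    list(values = V, meta = meta)
  })

  manifest <- data.frame(sample_id = samples, timepoint = tps,
                         condition = "in_situ", stringsAsFactors = FALSE)
  if (!is.null(extra$manifest)) manifest <- rbind(manifest, extra$manifest)

  # analytic expectation of the rMAG-level MT/MG ratio per type
  ef <- p_gene * cfg$act_factors[gene_type] +
    (1 - p_gene) * cfg$inactive_factor
  w <- panel_genes$length_bp
  exp_ratio_rmag <- vapply(rmag_ids, function(r) {
    i <- gene_rmag == r
    sum(w[i] * ef[i]) / sum(w[i])
  }, numeric(1))
  expected_ratio_type <- tapply(exp_ratio_rmag, type_of[rmag_ids], mean)

  truth$abundance <- abund
  truth$disturbance_rmags <- disturbance_rmags
  truth$disturbance_window <- samples[cfg$disturbance_window]
  truth$active_sets <- panels$active_sets
  truth$p_gene <- stats::setNames(p_gene, genes)
  truth$expected_ratio_rmag <- exp_ratio_rmag
  truth$expected_ratio_type <- expected_ratio_type

  list(annotations = ann,
       contig_records = contigs$records, contig_map = contigs$map,
       gene_mg = omics$MG, gene_mt = omics$MT, mp_counts = omics$MP,
       extra_mg = extra$MG, extra_mt = extra$MT, extra_mp = extra$MP,
       manifest = manifest, abiotic = abiotic, truth = truth)
}

#' Simulate the four-fraction GC-MS metabolome run
#'
#' Each fraction's measurement sequence interleaves pooled QC injections
#' after every `pool_every`-th measurement, brackets the run with blanks,
#' and multiplies all intensities by a monotone sigmoidal drift curve
#' (instrument response settling at the run start and saturating towards
#' the end).
#' Planted contaminants appear in blanks above the 75% blank-filter level;
#' a few metabolites are planted at low sample prevalence or missing from
#' one pool to exercise the prevalence filter. Ground-truth intracellular /
#' extracellular ratios are recorded for the shared metabolites.
#'
#' @param cfg a [sim_config()].
#' @return list of four [metabolite_run()]s (`intra_polar`,
#'   `intra_nonpolar`, `extra_polar`, `extra_nonpolar`) plus `truth`
#'   (contaminants, low-prevalence ids, drift curves, planted ratios).
#' @export
simulate_metabolome <- function(cfg) {
  fractions <- c("intra_polar", "intra_nonpolar", "extra_polar",
                 "extra_nonpolar")
  samples <- sprintf("S%02d", seq_len(cfg$n_timepoints))
  truth <- list(contaminants = list(), low_prevalence = list(),
                drift_curve = list(), planted_ratio = list())
  runs <- list()
  with_seed(sim_seed(cfg, "metabolome"), {
    # shared metabolite baselines so intra/extra ratios are well defined
    shared_ids <- function(pol)
      sprintf("met_%s_sh%02d", pol, seq_len(cfg$n_shared_metabolites))
    shared_base <- list(
      polar = stats::rlnorm(cfg$n_shared_metabolites, 12, 1),
      nonpolar = stats::rlnorm(cfg$n_shared_metabolites, 12, 1))
    ratio_true <- list(
      polar = stats::rlnorm(cfg$n_shared_metabolites, 0, 0.8),
      nonpolar = stats::rlnorm(cfg$n_shared_metabolites, 0, 0.8))
    for (fr in fractions) {
      pol <- if (grepl("nonpolar", fr)) "nonpolar" else "polar"
      intra <- grepl("^intra", fr)
      n_own <- cfg$n_metabolites - cfg$n_shared_metabolites
      mets <- c(shared_ids(pol),
                sprintf("met_%s_%02d", fr, seq_len(n_own)))
      base <- c(shared_base[[pol]] *
                  (if (intra) ratio_true[[pol]] else 1),
                stats::rlnorm(n_own, 12, 1))
      names(base) <- mets

      # sequence: 2 blanks, then (pool after every 5th measurement), blank
      seq_roles <- character(0); seq_sample <- character(0)
      k <- 0L
      for (s in samples) {
        seq_roles <- c(seq_roles, "sample"); seq_sample <- c(seq_sample, s)
        k <- k + 1L
        if (k %% cfg$pool_every == 0L) {
          seq_roles <- c(seq_roles, "pool")
          seq_sample <- c(seq_sample, NA_character_)
        }
      }
      n_lead <- max(0L, cfg$n_blanks - 1L)
      seq_roles <- c(rep("blank", n_lead), seq_roles, "blank")
      seq_sample <- c(rep(NA_character_, n_lead), seq_sample, NA_character_)
      npos <- length(seq_roles)
      manifest <- data.frame(
        measurement_id = sprintf("%s_m%03d", fr, seq_len(npos)),
        role = seq_roles, sample_id = seq_sample, stringsAsFactors = FALSE)

      drift <- 1 + (cfg$total_drift - 1) *
        stats::plogis((seq_len(npos) - (npos + 1) / 2) / (npos / 8))
      seasonal <- 1 + 0.3 * sin(2 * pi * seq_len(cfg$n_timepoints) / 52)
      X <- matrix(NA_real_, cfg$n_metabolites, npos,
                  dimnames = list(mets, manifest$measurement_id))
      pool_level <- base * mean(seasonal)
      for (j in seq_len(npos)) {
        X[, j] <- switch(
          manifest$role[j],
          sample = base * seasonal[match(manifest$sample_id[j], samples)] *
            stats::rlnorm(cfg$n_metabolites, 0, 0.4),
          pool = pool_level * stats::rlnorm(cfg$n_metabolites, 0,
                                            cfg$pool_cv),
          blank = rep(0, cfg$n_metabolites)) * drift[j]
      }

      # planted contaminants: blank level 1.2x the sample mean
      contam <- sample(mets[(cfg$n_shared_metabolites + 1):length(mets)],
                       cfg$n_contaminants)
      bl <- manifest$role == "blank"
      X[contam, bl] <- 1.2 * rowMeans(X[contam, manifest$role == "sample",
                                        drop = FALSE]) *
        matrix(stats::rlnorm(length(contam) * sum(bl), 0, 0.05),
               length(contam))
      # low-prevalence metabolites: detected in ~15% of samples only
      lowprev <- sample(setdiff(mets[(cfg$n_shared_metabolites + 1):
                                       length(mets)], contam), 6)
      sm <- which(manifest$role == "sample")
      for (m in lowprev) {
        drop <- sample(sm, round(0.85 * length(sm)))
        X[m, drop] <- NA
      }
      # two metabolites missing from one pool
      pool_cols <- which(manifest$role == "pool")
      misspool <- sample(setdiff(mets, c(contam, lowprev)), 2)
      X[misspool, sample(pool_cols, 1)] <- NA

      runs[[fr]] <- metabolite_run(X, manifest)
      truth$contaminants[[fr]] <- sort(contam)
      truth$low_prevalence[[fr]] <- sort(c(lowprev, misspool))
      truth$drift_curve[[fr]] <- drift
    }
    truth$planted_ratio <- list(
      polar = stats::setNames(ratio_true$polar, shared_ids("polar")),
      nonpolar = stats::setNames(ratio_true$nonpolar,
                                 shared_ids("nonpolar")))
  })
  c(runs, list(truth = truth))
}

#' Simulate the complete synthetic community
#'
#' Runs [simulate_repertoires()], [simulate_timeseries()] and
#' [simulate_metabolome()] under one master seed.
#'
#' @param cfg a [sim_config()].
#' @return list with all generator outputs and the merged ground truth.
#' @export
simulate_community <- function(cfg = sim_config()) {
  rep_out <- simulate_repertoires(cfg)
  ts <- simulate_timeseries(cfg, rep_out)
  mm <- simulate_metabolome(cfg)
  truth <- ts$truth
  truth$metabolome <- mm$truth
  list(config = cfg,
       ko_presence = rep_out$ko_presence,
       quality = rep_out$quality,
       annotations = ts$annotations,
       contig_records = ts$contig_records,
       contig_map = ts$contig_map,
       gene_mg = ts$gene_mg, gene_mt = ts$gene_mt,
       mp_counts = ts$mp_counts,
       extra_mg = ts$extra_mg, extra_mt = ts$extra_mt,
       extra_mp = ts$extra_mp,
       manifest = ts$manifest, abiotic = ts$abiotic,
       metabolome = mm[setdiff(names(mm), "truth")],
       truth = truth)
}

#' Write a simulated community to TSV files
#'
#' Emits every input table of the pipeline (annotations, contig/gene depth
#' records, MP counts, quality, manifest, abiotic factors, metabolite
#' intensity matrices with manifests) plus the ground truth under
#' `dir/truth/`.
#'
#' @param sim result of [simulate_community()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_tsv_table(sim$annotations, file.path(dir, "annotations.tsv"))
  write_tsv_table(sim$quality, file.path(dir, "quality.tsv"))
  write_tsv_table(sim$manifest, file.path(dir, "manifest.tsv"))
  write_tsv_table(sim$contig_records, file.path(dir, "depth_mg_contigs.tsv"))
  gene_len <- stats::setNames(sim$annotations$length_bp,
                              sim$annotations$gene_id)
  long_depth <- function(M) {
    data.frame(feature_id = rep(rownames(M), times = ncol(M)),
               sample_id = rep(colnames(M), each = nrow(M)),
               summed_depth = as.vector(M) * gene_len[rep(rownames(M),
                                                          times = ncol(M))],
               length_bp = gene_len[rep(rownames(M), times = ncol(M))],
               stringsAsFactors = FALSE)
  }
  mg_all <- cbind(sim$gene_mg, sim$extra_mg)
  mt_all <- cbind(sim$gene_mt, sim$extra_mt)
  mp_all <- cbind(sim$mp_counts, sim$extra_mp)
  write_tsv_table(long_depth(mg_all), file.path(dir, "depth_mg.tsv"))
  write_tsv_table(long_depth(mt_all), file.path(dir, "depth_mt.tsv"))
  mp <- data.frame(gene_id = rep(rownames(mp_all), times = ncol(mp_all)),
                   sample_id = rep(colnames(mp_all), each = nrow(mp_all)),
                   count = as.vector(mp_all),
                   stringsAsFactors = FALSE)
  write_tsv_table(mp, file.path(dir, "mp_counts.tsv"))
  ab <- data.frame(sample_id = rownames(sim$abiotic$values),
                   sim$abiotic$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_table(ab, file.path(dir, "abiotic.tsv"))
  write_tsv_table(sim$abiotic$meta, file.path(dir, "abiotic_meta.tsv"))
  for (fr in names(sim$metabolome)) {
    run <- sim$metabolome[[fr]]
    xi <- data.frame(metabolite = rownames(run$intensities),
                     run$intensities, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv_table(xi, file.path(dir, paste0("mm_", fr, ".tsv")))
    write_tsv_table(run$manifest,
                    file.path(dir, paste0("mm_", fr, "_manifest.tsv")))
  }
  tr <- data.frame(rmag_id = names(sim$truth$type_of_rmag),
                   type = unname(sim$truth$type_of_rmag),
                   expected_mtmg_ratio =
                     unname(sim$truth$expected_ratio_rmag[
                       names(sim$truth$type_of_rmag)]),
                   stringsAsFactors = FALSE)
  write_tsv_table(tr, file.path(dir, "truth", "types.tsv"))
  invisible(dir)
}
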