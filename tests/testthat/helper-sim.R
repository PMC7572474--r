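# Shared small simulation fixtures, built once per test run.

small_config <- function(seed = 1, ...) {
  base <- list(seed = seed, n_rmags = 20, type_sizes = c(6, 5, 5, 4),
               n_timepoints = 12, ko_universe = 1200, n_core_kos = 300,
               type_specific_kos = 150, type_overlap = 50,
               n_private_kos = 10, disturbance_window = 8:9,
               n_metabolites = 30, n_shared_metabolites = 10,
               n_contaminants = 3)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# cache across test files (simulating the default community is not free)
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed, small = TRUE) {
  key <- paste0(if (small) "s" else "f", seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- if (small) small_config(seed = seed) else sim_config(seed = seed)
    .sim_cache[[key]] <- simulate_community(cfg)
  }
  .sim_cache[[key]]
}

# gene-level depth matrices -> rMAG depth via the package's record path
rmag_depth_from_genes <- function(depth_mat, annotations) {
  rmag_depth_from_gene_matrix(depth_mat, annotations)
}
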