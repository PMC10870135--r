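# Shared fixtures. Heavy objects are built lazily and cached for the test
# run so several test files can reuse the same simulated scenario.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Permissive QC matched to the desk-scale synthetic fixture.
fixture_qc <- function() qc_config(min_umi = 100, min_genes = 50)

# Small simulated scenario for unit tests.
small_sim <- function() cached("small_sim", {
  simulate_dataset(sim_config(cells_per_cluster = 100, n_disease_genes = 40,
                              n_unlabeled_disease = 20,
                              n_housekeeping_genes = 80, n_noise_genes = 100,
                              seed = 401))
})

small_props <- function() cached("small_props", {
  sim <- small_sim()
  merge_properties(sim$props, gene_gc_features(sim$genome, sim$models))
})

# Default reference scenario and its pipeline fits (used by the acceptance
# suite; built once).
default_sim <- function() cached("default_sim", simulate_dataset(sim_config(seed = 2024)))

default_props <- function() cached("default_props", {
  sim <- default_sim()
  merge_properties(sim$props, gene_gc_features(sim$genome, sim$models))
})

default_fit <- function(mode = "full") cached(paste0("fit_", mode), {
  sim <- default_sim()
  suppressWarnings(run_pipeline(sim$am, default_props(), sim$disease_genes,
                                sim$housekeeping, sim$ref,
                                qc = fixture_qc(), mode = mode, seed = 99))
})

# Hand-built annotated matrix from explicit numbers.
tiny_am <- function(counts, clusters, stages = NULL, pseudotime = NULL) {
  n <- nrow(counts)
  if (is.null(colnames(counts))) colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  meta <- tibble::tibble(
    cell_id = paste0("c", seq_len(n)),
    cluster = clusters,
    stage = stages %||% rep("E9.5", n)
  )
  if (!is.null(pseudotime)) meta$pseudotime <- pseudotime
  ann_matrix(counts, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) pairwise-concordance AUC oracle (ties count one half).
auc_concordance <- function(labels, scores) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
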