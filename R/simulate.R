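# Synthetic developmental scRNA-seq generator with planted ground truth.
# Emulates the statistical structure the prioritization method relies on:
# disease-like genes are expressed in one or two cell clusters with a
# temporal modulation, yet match housekeeping genes in overall (pseudo-bulk)
# abundance, so their signal is only visible to cluster- and
# trajectory-resolved features.

loguniform <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Simulation configuration
#'
#' Defaults define the package's reference synthetic scenario: 3 clusters of
#' 300 cells across 4 developmental stages; 100 labeled disease-like genes
#' (one of them ubiquitously expressed in the reference atlas, so the
#' ubiquity filter drops it), 60 unlabeled disease-like genes planted for
#' recovery measurements, 300 housekeeping-like genes and 600 noise genes;
#' negative-binomial counts with dispersion 0.5 and a 4-fold temporal
#' modulation of the planted signal.
#'
#' @param n_clusters,cells_per_cluster,n_stages Cell-population layout.
#' @param n_disease_genes Labeled disease-like genes (training positives
#'   before the ubiquity filter).
#' @param n_ubiquitous_disease How many of the labeled disease genes get a
#'   flat reference-atlas profile (removed by the ubiquity filter).
#' @param n_unlabeled_disease Disease-like genes kept off the training list,
#'   for recovery measurement.
#' @param n_housekeeping_genes,n_noise_genes Negative-class pool and
#'   background genes.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param disease_effect Within-cluster temporal fold change of the planted
#'   signal (> 1).
#' @param temporal_shape `"bump"`, `"ramp"` or `"switch"`.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 3L, cells_per_cluster = 300L, n_stages = 4L,
                       n_disease_genes = 100L, n_ubiquitous_disease = 1L,
                       n_unlabeled_disease = 60L,
                       n_housekeeping_genes = 300L, n_noise_genes = 600L,
                       nb_dispersion = 0.5, disease_effect = 4.0,
                       temporal_shape = c("bump", "ramp", "switch"),
                       seed = 1L) {
  temporal_shape <- match.arg(temporal_shape)
  cfg <- list(n_clusters = n_clusters, cells_per_cluster = cells_per_cluster,
              n_stages = n_stages, n_disease_genes = n_disease_genes,
              n_ubiquitous_disease = n_ubiquitous_disease,
              n_unlabeled_disease = n_unlabeled_disease,
              n_housekeeping_genes = n_housekeeping_genes,
              n_noise_genes = n_noise_genes, nb_dispersion = nb_dispersion,
              disease_effect = disease_effect, temporal_shape = temporal_shape,
              seed = seed)
  counts <- unlist(cfg[c("n_clusters", "cells_per_cluster", "n_stages",
                         "n_disease_genes", "n_housekeeping_genes", "n_noise_genes")])
  if (any(counts <= 0)) abort("all counts must be positive", class = "scprio_config_error")
  if (disease_effect <= 1) abort("disease_effect must exceed 1", class = "scprio_config_error")
  if (n_ubiquitous_disease >= n_disease_genes) {
    abort("n_ubiquitous_disease must be smaller than n_disease_genes",
          class = "scprio_config_error")
  }
  structure(cfg, class = "sim_config")
}

shape_fun <- function(kind, par) {
  switch(kind,
    bump = function(t) exp(-(t - par)^2 / (2 * 0.12^2)),
    ramp = function(t) t,
    switch = function(t) as.numeric(t > par)
  )
}

#' Simulate a full synthetic input set
#'
#' Generates every input the pipeline consumes: an annotated cells-by-genes
#' count matrix (negative-binomial, with cluster/stage/pseudotime metadata),
#' a gene-constraint table, disease and housekeeping gene lists, a reference
#' pseudobulk for the ubiquity filter, a synthetic genome with gene models
#' for GC features, and per-gene truth labels.
#'
#' Planted structure: disease-like genes are expressed in 1-2 randomly
#' assigned clusters with a `temporal_shape` modulation spanning a
#' `disease_effect`-fold range along pseudotime; their overall abundance is
#' drawn from the same distribution as the housekeeping genes', so pseudo-bulk
#' summaries carry little class signal. Housekeeping genes are flat across
#' clusters and time, LoF-tolerant by construction (`pNull` strictly maximal),
#' and flat in the reference atlas (hence removed as ubiquitous if offered as
#' positives). Disease genes carry intolerant constraint draws
#' (`pLI ~ Beta(5, 1)`, `pNull ~ Beta(1, 5)`) and a tiered (low/mid/high)
#' reference-atlas profile that survives the one-standard-deviation ubiquity
#' band. A tenth of the noise genes lack constraint values entirely, to
#' exercise imputation.
#'
#' @param cfg A [sim_config()].
#' @return A list: `am` ([ann_matrix()]), `props` (gene-property tibble,
#'   constraints + ortholog confidence), `disease_genes`, `housekeeping`
#'   (character vectors), `ref` (reference pseudobulk tibble), `genome`
#'   (`DNAStringSet`), `models` (gene-model tibble), `truth` (tibble `gene`,
#'   `type`), and `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  K <- cfg$n_clusters
  n_cells <- K * cfg$cells_per_cluster
  clusters <- paste0("cluster", seq_len(K))
  cl <- rep(clusters, each = cfg$cells_per_cluster)
  pt <- runif(n_cells)
  stage_idx <- pmin(floor(pt * cfg$n_stages), cfg$n_stages - 1L)
  stages <- paste0("E", 9.5 + seq_len(cfg$n_stages) - 1L)
  gene_sets <- list(
    disease = sprintf("disG%03d", seq_len(cfg$n_disease_genes)),
    disease_unlabeled = if (cfg$n_unlabeled_disease > 0)
      sprintf("udisG%03d", seq_len(cfg$n_unlabeled_disease)) else character(),
    housekeeping = sprintf("hkG%03d", seq_len(cfg$n_housekeeping_genes)),
    noise = sprintf("nseG%03d", seq_len(cfg$n_noise_genes))
  )
  ubiq <- gene_sets$disease[seq_len(cfg$n_ubiquitous_disease)]
  genes <- unname(unlist(gene_sets))
  type <- rep(names(gene_sets), lengths(gene_sets))
  type[genes %in% ubiq] <- "disease_ubiquitous"
  n_genes <- length(genes)

  # Per-cell expected expression. Disease-like genes carry a structured
  # modulation (restricted clusters and/or temporal shape); housekeeping
  # genes are flat in expectation but heavily overdispersed, with a
  # gene-specific negative-binomial size calibrated so their cell-level
  # variance matches that of a structured gene of the same abundance. The
  # two classes therefore look alike to pseudo-bulk summaries (mean,
  # variance, fraction expressing), and only cluster- and
  # trajectory-resolved features can separate them.
  base_low <- 0.02
  mu <- matrix(base_low, n_cells, n_genes, dimnames = list(NULL, genes))
  is_dis <- type %in% c("disease", "disease_unlabeled", "disease_ubiquitous")
  is_hk <- type == "housekeeping"
  overall <- numeric(n_genes)
  overall[is_hk] <- loguniform(sum(is_hk), 0.3, 3)
  overall[is_dis] <- loguniform(sum(is_dis), 0.3, 3)
  overall[type == "noise"] <- loguniform(sum(type == "noise"), 0.01, 0.3)
  zero_noise <- gene_sets$noise[seq_len(max(1, round(0.02 * cfg$n_noise_genes)))]
  overall[genes %in% zero_noise] <- 0

  structured_mu <- function(target) {
    # 1 or 2 clusters carry the signal (or, for ~30% of genes, every cluster
    # is modulated purely in time, so only the trajectory block can see it).
    # Inside a signal cluster the temporal shape rises from baseline to peak;
    # outside, the gene sits at a flat baseline disease_effect-fold below the
    # in-cluster mean. The per-cell means are normalized so the gene's
    # overall abundance equals `target`, drawn from the same distribution as
    # the housekeeping genes' — pseudo-bulk abundance carries no class signal.
    n_cl <- sample(c(1L, 2L, K), 1, prob = c(0.35, 0.35, 0.3))
    cls <- sample(clusters, n_cl)
    par <- switch(cfg$temporal_shape, bump = runif(1, 0.25, 0.75),
                  ramp = NA_real_, switch = runif(1, 0.3, 0.7))
    s <- shape_fun(cfg$temporal_shape, par)(pt)
    inside <- cl %in% cls
    share <- mean(inside)
    mean_in <- target / (share + (1 - share) / cfg$disease_effect)
    amp <- max(mean_in - base_low, 0) / mean(s[inside])
    ifelse(inside, base_low + amp * s, mean_in / cfg$disease_effect)
  }
  size_default <- 1 / cfg$nb_dispersion
  size_gene <- rep(size_default, n_genes)
  for (j in which(type == "noise")) mu[, j] <- overall[j]
  for (j in which(is_dis)) {
    mu[, j] <- structured_mu(overall[j])
  }
  for (j in which(is_hk)) {
    m <- overall[j]
    mu[, j] <- m
    # variance a structured gene of the same abundance would show at cell
    # level; housekeeping genes absorb half of that excess as extra
    # overdispersion (biological burstiness), which blurs the pseudo-bulk
    # variance contrast without turning their temporal profiles noisy
    mu_ref <- structured_mu(m)
    v_struct <- var(mu_ref) + mean(mu_ref + mu_ref^2 / size_default)
    v_target <- m + 0.5 * (v_struct - m)
    size_gene[j] <- if (v_target > m + 1e-9) m^2 / (v_target - m) else size_default
  }

  sf <- exp(rnorm(n_cells, 0, 0.2))
  counts <- matrix(rnbinom(n_cells * n_genes, mu = mu * sf,
                           size = rep(size_gene, each = n_cells)),
                   n_cells, n_genes, dimnames = list(NULL, genes))
  cell_meta <- tibble(
    cell_id = sprintf("cell%04d", seq_len(n_cells)),
    cluster = cl,
    stage = stages[stage_idx + 1L],
    pseudotime = pt,
    doublet_score = runif(n_cells, 0, 0.15),
    pct_mito = runif(n_cells, 0, 8),
    pct_ribo = runif(n_cells, 5, 40)
  )
  am <- ann_matrix(counts, cell_meta)

  props <- simulate_constraints(genes, type)
  ref <- simulate_reference(genes, type)
  gm <- simulate_genome(genes)

  list(am = am, props = props,
       disease_genes = gene_sets$disease,
       housekeeping = gene_sets$housekeeping,
       ref = ref, genome = gm$genome, models = gm$models,
       truth = tibble(gene = genes, type = type),
       cfg = cfg)
}

# Constraint metrics: disease genes skewed intolerant, housekeeping genes
# LoF-tolerant by construction, noise genes uninformative (10% all-missing).
simulate_constraints <- function(genes, type) {
  n <- length(genes)
  p <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("pLI", "pRec", "pNull")))
  syn_z <- rnorm(n); mis_z <- rnorm(n); lof_z <- rnorm(n)
  for (i in seq_len(n)) {
    if (type[i] %in% c("disease", "disease_unlabeled", "disease_ubiquitous")) {
      raw <- c(rbeta(1, 5, 1), rbeta(1, 2, 2), rbeta(1, 1, 5))
      lof_z[i] <- rnorm(1, 3, 1); mis_z[i] <- rnorm(1, 1, 1)
    } else if (type[i] == "housekeeping") {
      raw <- c(rbeta(1, 1, 5), rbeta(1, 1, 5), rbeta(1, 5, 1))
      if (which.max(raw) != 3) raw <- c(sort(raw)[1:2], max(raw)) # pNull strictly maximal
      lof_z[i] <- rnorm(1, -1, 1)
    } else {
      raw <- rexp(3)
    }
    p[i, ] <- raw / sum(raw)
  }
  out <- tibble(gene = genes, pLI = p[, "pLI"], pRec = p[, "pRec"],
                pNull = p[, "pNull"], syn_z = syn_z, mis_z = mis_z, lof_z = lof_z,
                ortholog_confidence = rbeta(n, 5, 1))
  drop <- type == "noise" & runif(n) < 0.1
  out[drop, c("pLI", "pRec", "pNull", "syn_z", "mis_z", "lof_z")] <- NA_real_
  out
}

# Reference pseudobulk over 20 sub-trajectories: housekeeping and
# "ubiquitous disease" genes flat (all 20 within their own 1-sd band ->
# filtered); other disease genes tiered low/mid/high (6 of 20 in band ->
# retained).
simulate_reference <- function(genes, type, n_subtraj = 20L) {
  fams <- rep(c("epithelial", "hepatic", "mesenchyme"), length.out = n_subtraj)
  subtraj <- paste0(fams, stats::ave(seq_len(n_subtraj), fams, FUN = seq_along))
  vals <- matrix(0, length(genes), n_subtraj, dimnames = list(genes, subtraj))
  n_low <- 7L; n_mid <- 6L
  for (i in seq_along(genes)) {
    if (type[i] %in% c("housekeeping", "disease_ubiquitous")) {
      f <- loguniform(1, 0.5, 5)
      vals[i, ] <- f * (1 + rnorm(n_subtraj, 0, 0.02))
    } else if (type[i] %in% c("disease", "disease_unlabeled")) {
      m <- loguniform(1, 0.5, 5)
      tiers <- sample(c(rep(0, n_low), rep(m, n_mid), rep(2 * m, n_subtraj - n_low - n_mid)))
      vals[i, ] <- abs(tiers + rnorm(n_subtraj, 0, 0.02 * m))
    } else {
      vals[i, ] <- rexp(n_subtraj, rate = 2)
    }
  }
  dplyr::bind_cols(tibble(gene = genes), as_tibble(vals))
}

# Synthetic genome: two contigs of random composition with per-gene GC bias;
# 200 bp gene bodies on alternating strands with room for promoters.
simulate_genome <- function(genes) {
  n <- length(genes)
  gene_len <- 200L; spacing <- 900L; margin <- 700L
  per_contig <- ceiling(n / 2)
  contig_len <- margin + per_contig * spacing + margin
  chrom <- rep(c("ctg1", "ctg2"), each = per_contig)[seq_len(n)]
  slot <- unlist(lapply(table(factor(chrom, levels = c("ctg1", "ctg2"))), seq_len))
  gene_start <- margin + (slot - 1L) * spacing + 1L
  gene_end <- gene_start + gene_len - 1L
  strand <- rep(c("+", "-"), length.out = n)
  gc_bias <- rbeta(n, 10, 10)
  seqs <- lapply(c(ctg1 = contig_len, ctg2 = contig_len), function(len) {
    s <- sample(c("A", "T", "G", "C"), len, replace = TRUE)
    s
  })
  for (i in seq_len(n)) {
    p_gc <- gc_bias[i]
    body <- sample(c("G", "C", "A", "T"), gene_len, replace = TRUE,
                   prob = c(p_gc / 2, p_gc / 2, (1 - p_gc) / 2, (1 - p_gc) / 2))
    seqs[[chrom[i]]][gene_start[i]:gene_end[i]] <- body
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  models <- tibble(gene = genes, chrom = chrom, strand = strand,
                   gene_start = as.integer(gene_start), gene_end = as.integer(gene_end),
                   tss = as.integer(ifelse(strand == "+", gene_start, gene_end)))
  list(genome = genome, models = models)
}

#' Write a simulated dataset as on-disk fixtures
#'
#' Writes the exact formats the readers consume: Matrix Market counts (genes
#' as rows, CellRanger convention) with `genes.tsv`/`barcodes.tsv`, a cell
#' metadata TSV, a constraint TSV, a FASTA genome plus BED6 gene models, the
#' two gene-list TSVs, the reference pseudobulk TSV and a truth TSV.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the file paths.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory: %s", dir))
  paths <- c(
    matrix = file.path(dir, "matrix.mtx"), genes = file.path(dir, "genes.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"), cell_meta = file.path(dir, "cell_meta.tsv"),
    constraints = file.path(dir, "constraints.tsv"), genome = file.path(dir, "genome.fa"),
    models = file.path(dir, "genes.bed"), disease = file.path(dir, "disease_genes.tsv"),
    housekeeping = file.path(dir, "housekeeping_genes.tsv"),
    ref = file.path(dir, "ref_pseudobulk.tsv"), truth = file.path(dir, "truth.tsv")
  )
  Matrix::writeMM(Matrix::t(sim$am$counts), paths["matrix"])
  readr::write_tsv(tibble(gene = sim$am$gene_ids), paths["genes"], col_names = FALSE)
  readr::write_tsv(tibble(cell = sim$am$cell_meta$cell_id), paths["barcodes"],
                   col_names = FALSE)
  readr::write_tsv(sim$am$cell_meta, paths["cell_meta"])
  readr::write_tsv(sim$props, paths["constraints"])
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  bed <- tibble(chrom = sim$models$chrom, start = sim$models$gene_start - 1L,
                end = sim$models$gene_end, name = sim$models$gene, score = 0L,
                strand = sim$models$strand)
  readr::write_tsv(bed, paths["models"], col_names = FALSE)
  readr::write_tsv(tibble(gene = sim$disease_genes), paths["disease"])
  readr::write_tsv(tibble(gene = sim$housekeeping), paths["housekeeping"])
  readr::write_tsv(sim$ref, paths["ref"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Read BED6 gene models
#'
#' Converts 0-based half-open BED coordinates to the 1-based inclusive
#' convention used throughout the package and derives the TSS from the
#' strand.
#'
#' @param path Path to a BED6 file.
#' @return A gene-model tibble (`gene`, `chrom`, `strand`, `gene_start`,
#'   `gene_end`, `tss`).
#' @export
read_gene_models_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         show_col_types = FALSE, progress = FALSE)
  tibble(gene = bed$name, chrom = bed$chrom, strand = bed$strand,
         gene_start = as.integer(bed$start + 1L), gene_end = as.integer(bed$end),
         tss = as.integer(ifelse(bed$strand == "+", bed$start + 1L, bed$end)))
}

#' Read a one-gene-per-line list
#'
#' Accepts a single-column TSV with or without a `gene` header.
#'
#' @param path Path to the list file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)[[1]]
  as.character(x[tolower(x) != "gene"])
}
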