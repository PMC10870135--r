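# Gene-intrinsic features: population constraint metrics (pLI/pRec/pNull and
# mutation-class Z scores) and GC content of gene body and promoter.

CONSTRAINT_COLS <- c("pLI", "pRec", "pNull", "syn_z", "mis_z", "lof_z")

#' Load a gene-constraint table
#'
#' Reads a tab-separated constraint table with canonical column names
#' (`gene`, `pLI`, `pRec`, `pNull`, `syn_z`, `mis_z`, `lof_z`; matching is
#' case-insensitive). Duplicate gene rows are resolved by keeping the row
#' with the fewest missing metric fields, ties by first occurrence. Missing
#' metrics stay missing (`NA`) and are imputed downstream, never zero-filled.
#' Where all three of pLI/pRec/pNull are present their sum is checked against
#' 1 (tolerance 0.01 for source-table rounding); violations are warned about,
#' not rejected.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene` and the six constraint metrics.
#' @export
load_constraint_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  lower <- tolower(names(tab))
  gi <- match("gene", lower)
  if (is.na(gi)) abort("constraint table has no 'gene' column", class = "scprio_schema_error")
  out <- tibble(gene = as.character(tab[[gi]]))
  for (col in CONSTRAINT_COLS) {
    j <- match(tolower(col), lower)
    out[[col]] <- if (is.na(j)) NA_real_ else as.numeric(tab[[j]])
  }
  out <- out |>
    dplyr::mutate(.n_missing = rowSums(is.na(dplyr::pick(dplyr::all_of(CONSTRAINT_COLS)))),
                  .ord = dplyr::row_number()) |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(.data$.n_missing, .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".n_missing", -".ord")
  psum <- out$pLI + out$pRec + out$pNull
  bad <- which(!is.na(psum) & abs(psum - 1) > 0.01)
  if (length(bad) > 0) {
    log_warn("%d gene(s) have pLI + pRec + pNull outside [0.99, 1.01]", length(bad))
  }
  out
}

#' GC fraction of a nucleotide sequence
#'
#' Counts G/C bases over non-N bases; `N` is excluded from the denominator
#' (assembly gaps should not bias the estimate). All-N sequences return `NA`.
#'
#' @param seq Character vector of sequences over `A/C/G/T/N` (case
#'   insensitive).
#' @return Numeric vector of GC fractions in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    if (!nzchar(s)) abort("empty sequence", class = "scprio_value_error")
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
    if (length(bad) > 0) {
      abort(sprintf("non-IUPAC character '%s' in sequence", bad[1]),
            class = "scprio_value_error")
    }
    denom <- sum(chars != "N")
    if (denom == 0) return(NA_real_)
    sum(chars %in% c("G", "C")) / denom
  }, numeric(1), USE.NAMES = FALSE)
}

#' Promoter interval around a transcription start site
#'
#' Returns the window spanning `upstream` bases upstream and `downstream`
#' bases downstream of the TSS (the TSS base counts as the first downstream
#' base), in 1-based inclusive coordinates. On the minus strand the window is
#' mirrored. The interval is clipped at chromosome bounds with a warning when
#' `chrom_length` is supplied.
#'
#' @param models Data frame of gene models with columns `gene`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `tss`.
#' @param upstream,downstream Window extents in bp (defaults 500 and 100).
#' @param chrom_lengths Optional named integer vector of chromosome lengths
#'   for clipping.
#' @return A tibble `gene`, `chrom`, `strand`, `start`, `end`.
#' @export
promoter_interval <- function(models, upstream = 500L, downstream = 100L,
                              chrom_lengths = NULL) {
  models <- as_tibble(models)
  plus <- models$strand == "+"
  start <- ifelse(plus, models$tss - upstream, models$tss - downstream + 1L)
  end <- ifelse(plus, models$tss + downstream - 1L, models$tss + upstream)
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[models$chrom])
    if (any(models$tss < 1 | models$tss > len, na.rm = TRUE)) {
      abort("TSS outside chromosome bounds", class = "scprio_coord_error")
    }
    clipped <- start < 1 | end > len
    if (any(clipped, na.rm = TRUE)) {
      log_warn("%d promoter interval(s) clipped at chromosome bounds", sum(clipped, na.rm = TRUE))
    }
    start <- pmax(start, 1L)
    end <- pmin(end, len)
  } else if (any(start < 1)) {
    log_warn("%d promoter interval(s) clipped at position 1", sum(start < 1))
    start <- pmax(start, 1L)
  }
  tibble(gene = models$gene, chrom = models$chrom, strand = models$strand,
         start = as.integer(start), end = as.integer(end))
}

#' GC content of gene bodies and promoters
#'
#' Extracts each gene's body (`gene_start`..`gene_end`) and promoter window
#' from a FASTA genome and computes their GC fractions. Genes on contigs
#' absent from the FASTA get missing values with a warning. GC is
#' strand-symmetric, so minus-strand sequences need no reverse complement for
#' the metric itself.
#'
#' @param fasta Path to a FASTA file (or a `Biostrings::DNAStringSet`).
#' @param models Data frame of gene models with columns `gene`, `chrom`,
#'   `strand`, `tss`, `gene_start`, `gene_end`.
#' @param upstream,downstream Promoter window extents (defaults 500, 100).
#' @return A tibble `gene`, `gc_gene`, `gc_promoter`.
#' @export
gene_gc_features <- function(fasta, models, upstream = 500L, downstream = 100L) {
  genome <- if (inherits(fasta, "DNAStringSet")) fasta else {
    if (!file.exists(fasta)) abort(sprintf("FASTA not found: %s", fasta))
    Biostrings::readDNAStringSet(fasta)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  lens <- setNames(Biostrings::width(genome), names(genome))
  models <- as_tibble(models)
  missing_ctg <- !(models$chrom %in% names(genome))
  if (any(missing_ctg)) {
    log_warn("%d gene(s) on contigs absent from the FASTA; GC set to NA", sum(missing_ctg))
  }
  prom <- promoter_interval(models, upstream, downstream,
                            chrom_lengths = lens[intersect(models$chrom, names(genome))])
  gc_of <- function(chrom, start, end) {
    if (!(chrom %in% names(genome))) return(NA_real_)
    s <- pmax(start, 1L); e <- pmin(end, lens[[chrom]])
    seq <- Biostrings::subseq(genome[[chrom]], s, e)
    counts <- Biostrings::letterFrequency(seq, c("G", "C", "N"))
    denom <- (e - s + 1) - counts[["N"]]
    if (denom == 0) return(NA_real_)
    unname((counts[["G"]] + counts[["C"]]) / denom)
  }
  tibble(
    gene = models$gene,
    gc_gene = purrr::pmap_dbl(list(models$chrom, models$gene_start, models$gene_end), gc_of),
    gc_promoter = purrr::pmap_dbl(list(prom$chrom, prom$start, prom$end), gc_of)
  )
}

#' Merge constraint, GC and ortholog features
#'
#' Full (outer) join on gene id; genes present in one table only appear with
#' missing values in the other block, ready for downstream imputation.
#'
#' @param constraints Tibble from [load_constraint_table()].
#' @param gc Tibble from [gene_gc_features()].
#' @param orthologs Optional tibble with columns `gene` and
#'   `ortholog_confidence`.
#' @return A gene-property tibble (one row per gene in the union).
#' @export
merge_properties <- function(constraints, gc = NULL, orthologs = NULL) {
  out <- as_tibble(constraints)
  if (!is.null(gc)) out <- dplyr::full_join(out, as_tibble(gc), by = "gene")
  if (!is.null(orthologs)) {
    out <- dplyr::full_join(out, as_tibble(orthologs)[c("gene", "ortholog_confidence")],
                            by = "gene")
  }
  out
}
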