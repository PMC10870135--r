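# Training class construction: positive class = disease-associated genes
# passing a tissue-ubiquity filter on reference pseudobulk expression;
# negative class = LoF-tolerant housekeeping genes.

#' Filter ubiquitously expressed genes on reference pseudobulk
#'
#' For each candidate gene, its expression across reference sub-trajectories
#' is summarized by its own mean and standard deviation; sub-trajectories
#' whose expression falls within one standard deviation of the mean count as
#' "same expression". Genes with more than `max_similar` such
#' sub-trajectories are removed as ubiquitous. A flat gene (sd 0) counts all
#' sub-trajectories as same and is removed whenever their number exceeds
#' `max_similar`. Candidates absent from the reference pass through with a
#' warning.
#'
#' @param candidates Character vector of gene ids.
#' @param ref Reference pseudobulk: a data frame with a `gene` column and one
#'   numeric column per sub-trajectory (mean expression).
#' @param max_similar Maximum allowed in-band sub-trajectory count
#'   (default 10).
#' @return Character vector of surviving genes, with a `provenance`
#'   attribute: a tibble `gene`, `n_in_band`, `kept`, `reason`.
#' @export
ubiquity_filter <- function(candidates, ref, max_similar = 10L) {
  ref <- as_tibble(ref)
  mat <- as.matrix(ref[setdiff(names(ref), "gene")])
  rownames(mat) <- ref$gene
  if (ncol(mat) < 11) {
    log_warn("only %d sub-trajectories; the ubiquity rule is weakly informative", ncol(mat))
  }
  prov <- purrr::map_dfr(candidates, function(g) {
    if (!g %in% rownames(mat)) {
      return(tibble(gene = g, n_in_band = NA_integer_, kept = TRUE,
                    reason = "not_in_reference"))
    }
    x <- mat[g, ]
    mu <- mean(x)
    s <- sd(x)
    n_in <- if (is.na(s) || s == 0) length(x) else sum(x >= mu - s & x <= mu + s)
    kept <- n_in <= max_similar
    tibble(gene = g, n_in_band = as.integer(n_in), kept = kept,
           reason = if (kept) "retained" else "ubiquitous")
  })
  absent <- sum(prov$reason == "not_in_reference")
  if (absent > 0) log_warn("%d candidate(s) absent from the reference pseudobulk; retained", absent)
  structure(prov$gene[prov$kept], provenance = prov)
}

#' Select LoF-tolerant housekeeping genes
#'
#' Keeps housekeeping genes with `pNull > pRec` and `pNull > pLI` (strict
#' inequalities). Genes with any of the three probabilities missing are
#' excluded: class eligibility never rests on imputed values.
#'
#' @param housekeeping Character vector of housekeeping gene ids.
#' @param props Gene-property tibble with `gene`, `pLI`, `pRec`, `pNull`.
#' @return Character vector of tolerant genes, with a `provenance` attribute.
#' @export
select_negative_class <- function(housekeeping, props) {
  props <- as_tibble(props)
  prov <- purrr::map_dfr(housekeeping, function(g) {
    row <- props[props$gene == g, , drop = FALSE]
    if (nrow(row) == 0 || anyNA(c(row$pLI, row$pRec, row$pNull))) {
      return(tibble(gene = g, kept = FALSE, reason = "missing_constraint"))
    }
    kept <- row$pNull > row$pRec && row$pNull > row$pLI
    tibble(gene = g, kept = kept,
           reason = if (kept) "lof_tolerant" else "not_tolerant")
  })
  structure(prov$gene[prov$kept], provenance = prov)
}

#' Build the positive and negative training classes
#'
#' Positive class: `disease_genes` surviving the [ubiquity_filter()];
#' negative class: [select_negative_class()] of the housekeeping list. Genes
#' appearing in both lists are assigned to the positive class with a
#' warning. Per-gene provenance records every inclusion/exclusion decision.
#'
#' @param disease_genes Character vector of disease-associated gene ids.
#' @param housekeeping Character vector of housekeeping gene ids.
#' @param ref Reference pseudobulk (see [ubiquity_filter()]).
#' @param props Gene-property tibble.
#' @param max_similar Ubiquity band threshold (default 10).
#' @return A list of class `training_classes`: `positive`, `negative`
#'   (character vectors) and `provenance` (tibble `gene`, `class`, `reason`).
#' @export
build_training_classes <- function(disease_genes, housekeeping, ref, props,
                                   max_similar = 10L) {
  pos <- ubiquity_filter(disease_genes, ref, max_similar)
  neg <- select_negative_class(housekeeping, props)
  pos_prov <- attr(pos, "provenance")
  neg_prov <- attr(neg, "provenance")
  overlap <- intersect(pos, neg)
  if (length(overlap) > 0) {
    log_warn("%d gene(s) in both lists assigned to the positive class", length(overlap))
    neg <- setdiff(neg, overlap)
  }
  if (length(pos) == 0 || length(neg) == 0) {
    abort("a training class is empty", class = "scprio_config_error")
  }
  ppos <- pos_prov |>
    dplyr::transmute(.data$gene, class = ifelse(.data$kept, "positive", "excluded"),
                     .data$reason)
  pneg <- neg_prov |>
    dplyr::filter(!.data$gene %in% ppos$gene) |>
    dplyr::transmute(.data$gene,
                     class = dplyr::case_when(
                       .data$gene %in% overlap ~ "positive",
                       .data$kept ~ "negative",
                       TRUE ~ "excluded"),
                     .data$reason)
  structure(list(positive = as.character(pos),
                 negative = as.character(neg),
                 provenance = dplyr::bind_rows(ppos, pneg)),
            class = "training_classes")
}

#' @export
print.training_classes <- function(x, ...) {
  cat(sprintf("<training_classes> %d positive / %d negative genes\n",
              length(x$positive), length(x$negative)))
  invisible(x)
}
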