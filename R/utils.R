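# Internal helpers shared across modules.

log_info <- function(...) inform(paste0("INFO: ", sprintf(...)))
log_warn <- function(...) warn(paste0(sprintf(...)))

#' Order developmental stage labels
#'
#' Stage labels such as `"E9.5"`, `"E10.5"` or `"day90"` are ordered by the
#' first numeric component they contain, falling back to lexicographic order
#' when no number is present. Returns the unique labels, earliest first.
#'
#' @param stages Character vector of stage labels (repeats allowed).
#' @return Character vector of unique labels in developmental order.
#' @export
#' @examples
#' stage_levels(c("E10.5", "E9.5", "E10.5"))
stage_levels <- function(stages) {
  u <- unique(as.character(stages))
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*([0-9]+\\.?[0-9]*).*$", "\\1", u)))
  if (anyNA(num)) u[order(u)] else u[order(num, u)]
}

# Stratified k-fold assignment: returns integer fold id per observation.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        abort(sprintf("class '%s' has %d members; cannot stratify into %d folds",
                      cl, length(idx), k))
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# Numeric feature columns of a feature matrix tibble (everything except ids).
feature_cols <- function(fm) setdiff(names(fm), c("gene", "label"))

fm_matrix <- function(fm) {
  m <- as.matrix(fm[feature_cols(fm)])
  rownames(m) <- fm$gene
  m
}

assert_annmat <- function(am) {
  if (!inherits(am, "ann_matrix")) abort("expected an `ann_matrix` object")
  invisible(am)
}
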