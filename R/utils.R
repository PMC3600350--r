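stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(class, "pathrank_error")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Validate a phenotype label vector
#'
#' Checks that `labels` is a named vector over exactly the values 1 and 2
#' (phenotype 1 = case/positive class) with at least `min_per_class` samples
#' in each phenotype.
#'
#' @param labels named integer vector with values in \{1, 2\}.
#' @param min_per_class minimum samples required per phenotype.
#' @return the validated labels, invisibly.
#' @export
check_labels <- function(labels, min_per_class = 2L) {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stopf("labels must be a named vector with unique sample ids")
  if (!all(labels %in% c(1L, 2L)))
    stopf("labels must be coded 1 (case) / 2 (control); got: %s",
          paste(unique(labels), collapse = ", "))
  counts <- tabulate(labels, nbins = 2L)
  if (any(counts < min_per_class))
    stopf("each phenotype needs >= %d samples (have %d and %d)",
          min_per_class, counts[1L], counts[2L])
  invisible(labels)
}

# Align labels to the columns of an expression/activity matrix by sample id.
align_labels <- function(expr, labels) {
  ids <- colnames(expr)
  missing <- setdiff(ids, names(labels))
  if (length(missing) > 0L)
    stopf("samples missing from labels: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  labels[ids]
}

# Stratified fold assignment: permutes samples within each class and deals
# them round-robin into k folds. Returns an integer vector parallel to labels.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
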