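#' Enumerate all ordered gene pairs (i, j), i < j
#'
#' Pairs are returned in fixed lexicographic order (1,2), (1,3), ...,
#' (n-1, n) so that screened-pair lists and serialized models are
#' byte-for-byte reproducible.
#'
#' @param n member-gene count (>= 2).
#' @return integer matrix with columns `i`, `j` and n(n-1)/2 rows.
#' @export
enumerate_pairs <- function(n) {
  if (n < 2L) stopf("need at least 2 genes to form a pair (n = %d)", n)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Binary pairwise gene-ranking matrix
#'
#' For each sample k and pair (i, j), the entry is 1 if the i-th member
#' gene's expression is strictly below the j-th gene's in that sample, else
#' 0 (ties fall to 0). Because only within-sample comparisons are made, the
#' result is exactly invariant to any strictly increasing per-sample
#' transformation of the expression values.
#'
#' @param expr numeric matrix restricted to one pathway's member genes, rows
#'   ordered as the pathway's gene list.
#' @param pairs pair matrix from [enumerate_pairs()]; defaults to all pairs.
#' @return integer 0/1 matrix (pairs x samples); rownames `"i<j"`.
#' @export
compute_rank_matrix <- function(expr, pairs = enumerate_pairs(nrow(expr))) {
  stopifnot(is.matrix(expr), max(pairs) <= nrow(expr))
  ranks <- (expr[pairs[, 1L], , drop = FALSE] <
            expr[pairs[, 2L], , drop = FALSE]) + 0L
  dimnames(ranks) <- list(paste0(pairs[, 1L], "<", pairs[, 2L]), colnames(expr))
  ranks
}
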