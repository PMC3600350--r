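# Shared fixture builders (everything generated in code, nothing on disk).

tiny_config <- function(...) {
  simulation_config(n_pathways = 6L, genes_per_pathway = 6L,
                    n_informative = 2L, n_samples_per_class = 30L, ...)
}

# A small deterministic expression matrix with named dims.
toy_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

toy_labels <- function(ids, phen) stats::setNames(as.integer(phen), ids)

# Brute-force AUC oracle: literal double loop over all (pos, neg) pairs.
auc_oracle <- function(pos, neg, ties = "strict") {
  total <- 0
  for (x in pos) for (y in neg) {
    if (x > y) total <- total + 1
    else if (x == y && ties == "half") total <- total + 0.5
  }
  total / (length(pos) * length(neg))
}

# Brute-force pairwise ranking oracle: per-sample double loop.
rank_oracle <- function(expr) {
  n <- nrow(expr)
  pairs <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) pairs <- rbind(pairs, c(i, j))
  out <- matrix(0L, nrow(pairs), ncol(expr))
  for (k in seq_len(ncol(expr)))
    for (p in seq_len(nrow(pairs)))
      out[p, k] <- as.integer(expr[pairs[p, 1], k] < expr[pairs[p, 2], k])
  out
}

write_tsv_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}
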