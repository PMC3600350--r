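#' Read a gene x sample expression matrix from TSV
#'
#' Expects tab-separated text with the sample ids in the first row and gene
#' ids in the first column; the body must be numeric. No between-sample
#' normalization is applied — the method downstream works on within-sample
#' gene orderings, so values are taken on whatever scale the file provides.
#' Duplicate gene ids (e.g. multiple probes per gene) are collapsed by
#' keeping the row with the highest mean value.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (genes x samples) with unique dimnames.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stopf("empty file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sample_ids <- fields[[1L]][-1L]
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample id in header of %s: %s", path,
          sample_ids[duplicated(sample_ids)][1L])
  body <- fields[-1L]
  body <- body[vapply(body, function(f) length(f) > 0L && nzchar(f[1L]), TRUE)]
  gene_ids <- vapply(body, `[[`, "", 1L)
  nsamp <- length(sample_ids)
  vals <- matrix(NA_real_, nrow = length(body), ncol = nsamp,
                 dimnames = list(gene_ids, sample_ids))
  for (r in seq_along(body)) {
    row <- body[[r]][-1L]
    if (length(row) != nsamp)
      stopf("row '%s' has %d values, expected %d", gene_ids[r], length(row), nsamp)
    num <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(num))
    if (length(bad) > 0L)
      stopf("non-numeric value '%s' at gene '%s', sample '%s'",
            row[bad[1L]], gene_ids[r], sample_ids[bad[1L]])
    vals[r, ] <- num
  }
  if (anyDuplicated(gene_ids)) {
    # probe collapse: keep the highest-mean row per gene id
    means <- rowMeans(vals)
    keep <- unlist(lapply(split(seq_along(gene_ids), gene_ids), function(ix) {
      ix[which.max(means[ix])]
    }), use.names = FALSE)
    keep <- sort(keep)
    vals <- vals[keep, , drop = FALSE]
  }
  vals
}

#' Construct a gene set
#'
#' @param name pathway name.
#' @param genes character vector of member gene ids (made unique).
#' @param description free-text description (GMT column 2).
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) genes <- unique(genes)
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Within-set duplicate genes are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return named list of [gene_set] objects, in file order.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stopf("GMT line %d has %d fields; need name, description and >= 1 gene",
            i, length(f))
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warnf("gene set '%s': dropping %d duplicate gene id(s)",
            f[1L], sum(duplicated(genes)))
      genes <- unique(genes)
    }
    sets[[i]] <- gene_set(f[1L], genes, f[2L])
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets in GMT format
#'
#' @param gene_sets list of [gene_set] objects.
#' @param path output path.
#' @export
write_gene_sets <- function(gene_sets, path) {
  lines <- vapply(gene_sets, function(gs) {
    paste(c(gs$name, gs$description, gs$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read two-class phenotype labels
#'
#' Two-column TSV (sample_id, label) without a header; exactly two distinct
#' label strings must be present. `case_label` names the string recoded to
#' phenotype 1 (the case / positive class); the other becomes phenotype 2.
#'
#' @param path path to the label file.
#' @param case_label label string mapped to phenotype 1.
#' @return named integer vector of 1s and 2s (names = sample ids).
#' @export
read_phenotype_labels <- function(path, case_label) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) != 2L)
    stopf("label file must have 2 columns (sample_id, label); got %d", ncol(tab))
  lev <- unique(tab[[2L]])
  if (length(lev) != 2L)
    stopf("expected exactly 2 distinct labels, got %d: %s",
          length(lev), paste(utils::head(lev, 5L), collapse = ", "))
  if (!case_label %in% lev)
    stopf("case_label '%s' not among labels: %s", case_label,
          paste(lev, collapse = ", "))
  if (anyDuplicated(tab[[1L]]))
    stopf("duplicate sample id in label file: %s",
          tab[[1L]][duplicated(tab[[1L]])][1L])
  labels <- ifelse(tab[[2L]] == case_label, 1L, 2L)
  names(labels) <- tab[[1L]]
  check_labels(labels)
}

#' Write phenotype labels
#'
#' @param labels named vector coded 1/2.
#' @param path output path.
#' @param label_names length-2 character vector giving the strings written
#'   for phenotypes 1 and 2.
#' @export
write_phenotype_labels <- function(labels, path, label_names = c("case", "control")) {
  utils::write.table(
    data.frame(sample = names(labels), label = label_names[labels]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict gene sets to genes shared by all datasets
#'
#' Each set is reduced to the genes present in every supplied matrix
#' (relative gene order preserved); sets left with fewer than 2 genes are
#' dropped with a warning, since the rank method needs at least one pair.
#'
#' @param gene_sets list of [gene_set] objects.
#' @param matrices a single expression matrix or a list of them.
#' @return filtered list of gene sets.
#' @export
restrict_to_common_genes <- function(gene_sets, matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  universe <- Reduce(intersect, lapply(matrices, rownames))
  out <- lapply(gene_sets, function(gs) {
    gs$genes <- gs$genes[gs$genes %in% universe]
    gs
  })
  keep <- vapply(out, function(gs) length(gs$genes) >= 2L, TRUE)
  if (any(!keep))
    warnf("dropping %d gene set(s) with < 2 genes after intersection: %s",
          sum(!keep), paste(utils::head(names(out)[!keep], 5L), collapse = ", "))
  out[keep]
}

#' Write a pathway x sample activity matrix as TSV
#'
#' Same layout as the expression input (header row of sample ids, first
#' column of pathway names); values round-trip through
#' [read_activity_matrix()] to at least 12 significant digits.
#'
#' @param activities numeric matrix, rows = pathways, columns = samples.
#' @param path output path.
#' @export
write_activity_matrix <- function(activities, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("pathway", colnames(activities)), collapse = "\t"), con)
  for (r in seq_len(nrow(activities))) {
    writeLines(paste(c(rownames(activities)[r],
                       format(activities[r, ], digits = 15, trim = TRUE,
                              scientific = NA)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a pathway x sample activity matrix written by [write_activity_matrix()]
#'
#' @param path path to the TSV file.
#' @return numeric matrix (pathways x samples).
#' @export
read_activity_matrix <- function(path) read_expression_matrix(path)

#' Write an expression matrix as TSV (same layout as the reader expects)
#'
#' @param expr numeric matrix, rows = genes, columns = samples.
#' @param path output path.
#' @export
write_expression_matrix <- function(expr, path) write_activity_matrix(expr, path)
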