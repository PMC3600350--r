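#' Smoothed Bernoulli PMFs of pair rankings, conditional on phenotype
#'
#' For each pair, estimates the probability that the pair-order bit equals 1
#' under each phenotype, with a pseudocount added to both outcomes:
#' p_l = (count of r = 1 in phenotype l + alpha) / (K_l + 2 alpha).
#' Any alpha > 0 keeps both probabilities strictly inside (0, 1), which in
#' turn keeps every log-likelihood ratio finite — the failure mode of
#' expression-level LLRs on variability-free genes cannot occur here.
#'
#' @param ranks 0/1 matrix (pairs x samples) from [compute_rank_matrix()].
#' @param labels per-column phenotype vector coded 1/2.
#' @param alpha pseudocount (default 0.5, Jeffreys-style).
#' @return data.frame with columns `p1`, `p2`, one row per pair.
#' @export
estimate_pair_pmfs <- function(ranks, labels, alpha = 0.5) {
  stopifnot(ncol(ranks) == length(labels), alpha >= 0)
  k1 <- sum(labels == 1L); k2 <- sum(labels == 2L)
  if (k1 == 0L || k2 == 0L) stopf("both phenotypes must be present")
  c1 <- rowSums(ranks[, labels == 1L, drop = FALSE])
  c2 <- rowSums(ranks[, labels == 2L, drop = FALSE])
  data.frame(p1 = (c1 + alpha) / (k1 + 2 * alpha),
             p2 = (c2 + alpha) / (k2 + 2 * alpha),
             row.names = rownames(ranks))
}

# Plug-in mutual information (nats) between each binary row of `ranks` and
# the binary phenotype, from the raw empirical 2x2 joint (0 log 0 = 0).
pairwise_mutual_information <- function(ranks, labels) {
  k <- length(labels)
  k1 <- sum(labels == 1L); k2 <- k - k1
  c1 <- rowSums(ranks[, labels == 1L, drop = FALSE])  # r=1, phen 1
  c2 <- rowSums(ranks[, labels == 2L, drop = FALSE])  # r=1, phen 2
  joint <- cbind(c1, k1 - c1, c2, k2 - c2) / k
  pr <- rowSums(joint[, c(1L, 3L), drop = FALSE])     # P(r = 1)
  marg <- cbind(pr * (k1 / k), (1 - pr) * (k1 / k),
                pr * (k2 / k), (1 - pr) * (k2 / k))
  term <- joint * log(joint / marg)
  term[joint == 0] <- 0
  rowSums(term)
}

#' Prescreen gene pairs by mutual information with the phenotype
#'
#' Keeps the top `ceiling(fraction * P)` pairs (never fewer than 1) ranked
#' by plug-in mutual information between the pair-order bit and the
#' phenotype; ties at the cutoff are broken by lexicographic pair order.
#'
#' @param ranks 0/1 matrix (pairs x samples).
#' @param labels phenotype vector coded 1/2.
#' @param fraction fraction of pairs to keep, in (0, 1] (default 0.10).
#' @return integer indices of the selected rows of `ranks`, in decreasing
#'   mutual-information order.
#' @export
mutual_information_screen <- function(ranks, labels, fraction = 0.1) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  if (nrow(ranks) == 0L) stopf("no pairs to screen")
  mi <- pairwise_mutual_information(ranks, labels)
  k <- max(1L, as.integer(ceiling(fraction * nrow(ranks))))
  order(mi, decreasing = TRUE)[seq_len(k)]  # order() breaks ties by index
}

#' Log-likelihood ratio table for a pair PMF
#'
#' @param p1,p2 probabilities of r = 1 under phenotypes 1 and 2 (vectors).
#' @return list with `llr0` = log((1-p1)/(1-p2)) and `llr1` = log(p1/p2),
#'   the LLR of observing r = 0 / r = 1 (natural log).
#' @export
compute_pair_llr <- function(p1, p2) {
  list(llr0 = log((1 - p1) / (1 - p2)), llr1 = log(p1 / p2))
}

#' Z-normalize per-pair LLR values across training samples
#'
#' Centers and scales each pair's LLR stream by its training mean and
#' sample standard deviation (K-1 divisor), reducing sensitivity to small
#' ranking perturbations. Pairs with zero spread are flagged for removal,
#' not an error.
#'
#' @param llr_values numeric matrix (pairs x training samples) of raw LLRs.
#' @return list: `values` (normalized matrix), `mu`, `sigma` (per-pair), and
#'   `degenerate` (logical, sigma == 0).
#' @export
normalize_llrs <- function(llr_values) {
  stopifnot(ncol(llr_values) >= 2L)
  mu <- rowMeans(llr_values)
  sigma <- apply(llr_values, 1L, stats::sd)
  degenerate <- sigma == 0
  vals <- (llr_values - mu) / ifelse(degenerate, 1, sigma)
  list(values = vals, mu = mu, sigma = sigma, degenerate = degenerate)
}

#' Fit a rank-LLR pathway activity model
#'
#' The training pipeline for one pathway: build the pairwise ranking matrix,
#' screen pairs by mutual information with the phenotype, estimate smoothed
#' per-pair Bernoulli PMFs under each phenotype, tabulate the pairwise LLRs,
#' and freeze per-pair normalization constants (training mean / sd of the
#' LLR). The fitted model scores unseen samples with no re-estimation.
#'
#' A pathway whose screened pairs all have zero LLR spread yields a
#' *degenerate* model whose activity is 0 for every sample; it fits without
#' error so cross-validation loops never crash, and its |t| of 0 means it
#' can never be selected as a feature.
#'
#' @param expr expression matrix (genes x samples) containing the pathway's
#'   genes.
#' @param labels named phenotype vector coded 1/2 (aligned by sample id).
#' @param pathway a [gene_set].
#' @param alpha PMF pseudocount (default 0.5).
#' @param fraction mutual-information screening fraction (default 0.10).
#' @return object of class `rank_activity_model`.
#' @export
fit_rank_activity_model <- function(expr, labels, pathway,
                                    alpha = 0.5, fraction = 0.1) {
  genes <- pathway$genes
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    stopf("pathway '%s': gene(s) missing from expression matrix: %s",
          pathway$name, paste(utils::head(missing, 5L), collapse = ", "))
  if (length(genes) < 2L)
    stopf("pathway '%s' has fewer than 2 genes", pathway$name)
  labels <- align_labels(expr, labels)
  check_labels(labels, min_per_class = 1L)

  pairs <- enumerate_pairs(length(genes))
  ranks <- compute_rank_matrix(expr[genes, , drop = FALSE], pairs)
  sel <- mutual_information_screen(ranks, labels, fraction)
  pairs <- pairs[sel, , drop = FALSE]
  ranks <- ranks[sel, , drop = FALSE]

  pmf <- estimate_pair_pmfs(ranks, labels, alpha)
  llr <- compute_pair_llr(pmf$p1, pmf$p2)
  lam <- llr$llr0 + ranks * (llr$llr1 - llr$llr0)
  norm <- normalize_llrs(lam)
  keep <- !norm$degenerate

  model <- structure(list(
    pathway_name = pathway$name,
    genes = genes,
    pairs = pairs[keep, , drop = FALSE],
    p1 = pmf$p1[keep], p2 = pmf$p2[keep],
    llr0 = llr$llr0[keep], llr1 = llr$llr1[keep],
    norm_mu = unname(norm$mu[keep]), norm_sigma = unname(norm$sigma[keep]),
    alpha = alpha, fraction = fraction,
    degenerate = !any(keep),
    estimation_samples = colnames(expr)
  ), class = "rank_activity_model")
  model
}

#' @export
print.rank_activity_model <- function(x, ...) {
  cat(sprintf("<rank_activity_model> %s: %d genes, %d pairs%s\n",
              x$pathway_name, length(x$genes), nrow(x$pairs),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Infer per-sample pathway activity
#'
#' @param model a fitted activity model.
#' @param expr expression matrix (genes x samples) containing the model's
#'   genes.
#' @param ... passed to methods.
#' @return named numeric vector of activities, one per sample.
#' @export
infer_activity <- function(model, expr, ...) UseMethod("infer_activity")

#' @describeIn infer_activity sum of frozen-normalized pairwise-rank LLRs:
#'   a_k = sum over screened pairs of (lambda(r) - mu) / sigma, using the
#'   training-time constants. Deterministic, and exactly invariant to
#'   strictly increasing per-sample transforms of `expr`.
#' @export
infer_activity.rank_activity_model <- function(model, expr, ...) {
  if (model$degenerate)
    return(stats::setNames(numeric(ncol(expr)), colnames(expr)))
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing) > 0L)
    stopf("pathway '%s': gene(s) missing from expression matrix: %s",
          model$pathway_name, paste(utils::head(missing, 5L), collapse = ", "))
  ranks <- compute_rank_matrix(expr[model$genes, , drop = FALSE], model$pairs)
  lam <- model$llr0 + ranks * (model$llr1 - model$llr0)
  colSums((lam - model$norm_mu) / model$norm_sigma)
}

#' Serialize a rank activity model to JSON
#'
#' Writes every quantity needed to score new samples (gene list, screened
#' pairs, per-pair PMFs, LLR table, normalization constants) at full
#' precision, so fitted models are portable across datasets.
#'
#' @param model a `rank_activity_model`.
#' @param path output path.
#' @export
write_rank_model <- function(model, path) {
  obj <- unclass(model)
  obj$pairs <- as.data.frame(obj$pairs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rank activity model written by [write_rank_model()]
#'
#' @param path path to the JSON model file.
#' @return a `rank_activity_model`.
#' @export
read_rank_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$pairs <- as.matrix(obj$pairs)
  storage.mode(obj$pairs) <- "integer"
  dimnames(obj$pairs) <- list(NULL, c("i", "j"))
  structure(obj, class = "rank_activity_model")
}
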