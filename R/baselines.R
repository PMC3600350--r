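#' Mean-based pathway activity
#'
#' The simplest comparison scheme: a sample's activity is the arithmetic
#' mean expression of the pathway's member genes.
#'
#' @param expr expression matrix (genes x samples).
#' @param pathway a [gene_set].
#' @return named numeric activity vector.
#' @export
mean_activity <- function(expr, pathway) {
  summary_activity(expr, pathway, colMeans)
}

#' Median-based pathway activity
#'
#' As [mean_activity()] but with the per-sample median of member-gene
#' expression (even counts use the midpoint of the two central values).
#'
#' @inheritParams mean_activity
#' @return named numeric activity vector.
#' @export
median_activity <- function(expr, pathway) {
  summary_activity(expr, pathway, function(m) apply(m, 2L, stats::median))
}

summary_activity <- function(expr, pathway, fun) {
  genes <- pathway$genes
  if (length(genes) == 0L) stopf("pathway '%s' is empty", pathway$name)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    stopf("pathway '%s': gene(s) missing from expression matrix: %s",
          pathway$name, paste(utils::head(missing, 5L), collapse = ", "))
  fun(expr[genes, , drop = FALSE])
}

# Lightweight model wrapper so mean/median plug into the same fit/score
# machinery as the probabilistic methods (no parameters are estimated).
summary_activity_model <- function(pathway, fun_name) {
  structure(list(pathway_name = pathway$name, genes = pathway$genes,
                 fun = fun_name, estimation_samples = character(0)),
            class = "summary_activity_model")
}

#' @export
infer_activity.summary_activity_model <- function(model, expr, ...) {
  gs <- gene_set(model$pathway_name, model$genes)
  switch(model$fun,
         mean = mean_activity(expr, gs),
         median = median_activity(expr, gs))
}

#' Fit the expression-level Gaussian LLR baseline
#'
#' The earlier probabilistic inference scheme this package's rank method is
#' compared against: each member gene gets phenotype-conditional normal
#' densities (sample mean and sd, K-1 divisor), the per-gene evidence is
#' the log-likelihood ratio lambda_i(x) = log N(x; mu1, s1) - log N(x; mu2, s2),
#' and each gene's lambda stream is z-normalized across training samples.
#'
#' Genes that lose variability make the density degenerate and the LLR
#' infinite; a variance floor guards against this. `sigma_floor` is a
#' relative factor: each sd is clamped below at
#' sqrt(sigma_floor x mean pooled within-class variance) over the pathway's
#' genes. With `sigma_floor = 0` a zero-sd gene raises a classed
#' "degenerate density" error (condition class
#' `pathrank_degenerate_density`) instead of silently producing infinities.
#'
#' @param expr expression matrix (genes x samples).
#' @param labels named phenotype vector coded 1/2.
#' @param pathway a [gene_set].
#' @param sigma_floor relative variance floor (default 1e-6).
#' @return object of class `gaussian_llr_model`.
#' @export
fit_gaussian_llr_model <- function(expr, labels, pathway, sigma_floor = 1e-6) {
  genes <- pathway$genes
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    stopf("pathway '%s': gene(s) missing from expression matrix: %s",
          pathway$name, paste(utils::head(missing, 5L), collapse = ", "))
  labels <- align_labels(expr, labels)
  check_labels(labels)
  x <- expr[genes, , drop = FALSE]
  x1 <- x[, labels == 1L, drop = FALSE]
  x2 <- x[, labels == 2L, drop = FALSE]
  k1 <- ncol(x1); k2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  s1 <- apply(x1, 1L, stats::sd); s2 <- apply(x2, 1L, stats::sd)
  pooled_var <- ((k1 - 1) * s1^2 + (k2 - 1) * s2^2) / (k1 + k2 - 2)
  floor_sd <- sqrt(sigma_floor * mean(pooled_var))
  if (min(s1, s2) == 0 && floor_sd == 0)
    stopf(paste0("pathway '%s': degenerate density — a member gene has zero ",
                 "within-phenotype variability and no variance floor applies"),
          pathway$name, class = "pathrank_degenerate_density")
  s1 <- pmax(s1, floor_sd); s2 <- pmax(s2, floor_sd)

  lam <- t(vapply(seq_along(genes), function(g) {
    stats::dnorm(x[g, ], m1[g], s1[g], log = TRUE) -
      stats::dnorm(x[g, ], m2[g], s2[g], log = TRUE)
  }, numeric(ncol(x))))
  mu <- rowMeans(lam)
  sig <- apply(lam, 1L, stats::sd)
  keep <- sig > 0

  structure(list(
    pathway_name = pathway$name,
    genes = genes[keep],
    mu1 = m1[keep], sd1 = s1[keep], mu2 = m2[keep], sd2 = s2[keep],
    norm_mu = mu[keep], norm_sigma = sig[keep],
    sigma_floor = sigma_floor, floor_sd = floor_sd,
    degenerate = !any(keep),
    estimation_samples = colnames(expr)
  ), class = "gaussian_llr_model")
}

#' @describeIn fit_gaussian_llr_model score samples with frozen training
#'   normalization: a_k = sum over retained genes of
#'   (lambda_i(x_k^i) - mu_i) / sigma_i.
#' @param model a fitted `gaussian_llr_model`.
#' @export
infer_gaussian_llr_activity <- function(model, expr) {
  infer_activity.gaussian_llr_model(model, expr)
}

#' @export
infer_activity.gaussian_llr_model <- function(model, expr, ...) {
  if (model$degenerate)
    return(stats::setNames(numeric(ncol(expr)), colnames(expr)))
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing) > 0L)
    stopf("pathway '%s': gene(s) missing from expression matrix: %s",
          model$pathway_name, paste(utils::head(missing, 5L), collapse = ", "))
  x <- expr[model$genes, , drop = FALSE]
  lam <- t(vapply(seq_along(model$genes), function(g) {
    stats::dnorm(x[g, ], model$mu1[g], model$sd1[g], log = TRUE) -
      stats::dnorm(x[g, ], model$mu2[g], model$sd2[g], log = TRUE)
  }, numeric(ncol(x))))
  colSums((lam - model$norm_mu) / model$norm_sigma)
}
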