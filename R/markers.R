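#' Two-sample t-type score of a pathway activity marker
#'
#' Measures how well an activity vector separates the two phenotypes. The
#' default is Welch's form
#' t = (mu1 - mu2) / sqrt(s1^2/K1 + s2^2/K2) with sample sds (K-1 divisor).
#' `formula = "printed"` instead uses the denominator (s1/K1 + s2/K2)
#' without squares or square root, kept for comparison with sources that
#' state the statistic that way.
#'
#' If both classes are constant the denominator is zero and t is defined as
#' 0 with a warning, so degenerate markers rank last instead of crashing.
#'
#' @param activities named numeric activity vector.
#' @param labels named phenotype vector coded 1/2 (matched by sample id
#'   when both are named, else by position).
#' @param formula `"welch"` (default) or `"printed"`.
#' @return signed t value (numeric scalar).
#' @export
t_score <- function(activities, labels, formula = c("welch", "printed")) {
  formula <- match.arg(formula)
  if (!is.null(names(activities)) && !is.null(names(labels)))
    labels <- labels[names(activities)]
  stopifnot(length(activities) == length(labels))
  a1 <- activities[labels == 1L]; a2 <- activities[labels == 2L]
  if (length(a1) < 2L || length(a2) < 2L)
    stopf("each phenotype needs >= 2 samples for a t-score")
  s1 <- stats::sd(a1); s2 <- stats::sd(a2)
  denom <- switch(formula,
                  welch = sqrt(s1^2 / length(a1) + s2^2 / length(a2)),
                  printed = s1 / length(a1) + s2 / length(a2))
  if (denom == 0) {
    warnf("zero-variance activities in both phenotypes; t set to 0")
    return(0)
  }
  (mean(a1) - mean(a2)) / denom
}

#' t-scores for every row of an activity matrix
#'
#' @param activities pathway x sample activity matrix.
#' @param labels named phenotype vector coded 1/2.
#' @param formula passed to [t_score()].
#' @return data.frame with columns `pathway`, `t`, `abs_t` (file order).
#' @export
score_markers <- function(activities, labels, formula = c("welch", "printed")) {
  formula <- match.arg(formula)
  labels <- align_labels(activities, labels)
  t <- vapply(seq_len(nrow(activities)), function(r) {
    suppressWarnings(t_score(activities[r, ], labels, formula))
  }, numeric(1L))
  data.frame(pathway = rownames(activities), t = t, abs_t = abs(t),
             row.names = NULL)
}

#' Sort markers by discriminative power
#'
#' Descending absolute t; ties broken by pathway name (lexicographic, C
#' collation) so rankings are deterministic.
#'
#' @param scores data.frame from [score_markers()].
#' @return the same data.frame, sorted, with a `rank` column.
#' @export
rank_markers <- function(scores) {
  ord <- order(-scores$abs_t, scores$pathway, method = "radix")
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Mean absolute t of the top P% markers
#'
#' @param sorted_scores data.frame sorted by [rank_markers()].
#' @param P percentage in (0, 100]; the top `ceiling(P/100 * N)` markers
#'   (minimum 1) are averaged.
#' @return mean absolute t over the selected markers.
#' @export
top_fraction_power <- function(sorted_scores, P) {
  if (P <= 0 || P > 100) stopf("P must be in (0, 100]")
  n <- nrow(sorted_scores)
  if (n == 0L) stopf("empty marker list")
  k <- max(1L, as.integer(ceiling(P / 100 * n)))
  mean(sorted_scores$abs_t[seq_len(k)])
}

#' Cross-dataset discriminative-power curve
#'
#' Ranks pathway markers by |t| on the first dataset, then re-evaluates the
#' top P% markers' mean |t| on a second dataset, refitting the activity
#' models on dataset 2 per the method's own fit procedure. Measures how
#' well markers found in one cohort retain discriminative power in another.
#'
#' @param expr1,labels1 training/ranking dataset.
#' @param expr2,labels2 evaluation dataset.
#' @param gene_sets list of [gene_set] objects (intersected with both
#'   matrices internally).
#' @param method one of `"rank-llr"`, `"llr"`, `"mean"`, `"median"`.
#' @param P_grid percentages to evaluate.
#' @param ... method parameters passed to [pathway_activities()].
#' @param t_formula passed to [score_markers()].
#' @return data.frame with columns `P`, `n_markers`, `mean_abs_t`.
#' @export
cross_dataset_power <- function(expr1, labels1, expr2, labels2, gene_sets,
                                method = "rank-llr",
                                P_grid = c(10, 25, 50, 100), ...,
                                t_formula = "welch") {
  gene_sets <- suppressWarnings(
    restrict_to_common_genes(gene_sets, list(expr1, expr2)))
  if (length(gene_sets) == 0L) stopf("no shared gene sets after intersection")
  act1 <- pathway_activities(expr1, labels1, gene_sets, method, ...)$activities
  act2 <- pathway_activities(expr2, labels2, gene_sets, method, ...)$activities
  ranked1 <- rank_markers(score_markers(act1, labels1, t_formula))
  abs2 <- score_markers(act2, labels2, t_formula)
  abs2 <- stats::setNames(abs2$abs_t, abs2$pathway)
  n <- nrow(ranked1)
  do.call(rbind, lapply(P_grid, function(P) {
    k <- max(1L, as.integer(ceiling(P / 100 * n)))
    top <- ranked1$pathway[seq_len(k)]
    data.frame(P = P, n_markers = k, mean_abs_t = mean(abs2[top]))
  }))
}

#' Fit activity models for a pathway collection and score samples
#'
#' Dispatches on `method` to fit one activity model per gene set on the
#' supplied samples and returns both the models and the pathway x sample
#' activity matrix for those samples.
#'
#' @param expr expression matrix (genes x samples).
#' @param labels named phenotype vector coded 1/2 (ignored by `mean` /
#'   `median`, which estimate nothing).
#' @param gene_sets list of [gene_set] objects.
#' @param method `"rank-llr"`, `"llr"`, `"mean"`, or `"median"`.
#' @param alpha pseudocount for `"rank-llr"`.
#' @param fraction screening fraction for `"rank-llr"`.
#' @param sigma_floor variance-floor factor for `"llr"`.
#' @return list with `models` (named list) and `activities` (matrix).
#' @export
pathway_activities <- function(expr, labels, gene_sets,
                               method = c("rank-llr", "llr", "mean", "median"),
                               alpha = 0.5, fraction = 0.1,
                               sigma_floor = 1e-6) {
  method <- match.arg(method)
  models <- lapply(gene_sets, function(gs) {
    switch(method,
           "rank-llr" = fit_rank_activity_model(expr, labels, gs,
                                                alpha = alpha,
                                                fraction = fraction),
           "llr" = fit_gaussian_llr_model(expr, labels, gs,
                                          sigma_floor = sigma_floor),
           "mean" = summary_activity_model(gs, "mean"),
           "median" = summary_activity_model(gs, "median"))
  })
  names(models) <- vapply(gene_sets, `[[`, "", "name")
  list(models = models, activities = score_activities(models, expr))
}

#' Score a list of fitted activity models on an expression matrix
#'
#' @param models named list of fitted activity models.
#' @param expr expression matrix containing each model's genes.
#' @return pathway x sample activity matrix.
#' @export
score_activities <- function(models, expr) {
  act <- t(vapply(models, function(m) infer_activity(m, expr),
                  numeric(ncol(expr))))
  rownames(act) <- names(models)
  colnames(act) <- colnames(expr)
  act
}
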