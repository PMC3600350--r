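#' Area under the ROC curve from classifier scores
#'
#' A = (1/mn) sum_i sum_j I(x_i > y_j) over all positive-negative score
#' pairs. Ties contribute 0 under the default strict indicator; `ties =
#' "half"` gives each tied pair 1/2 credit (the Mann-Whitney convention).
#' LDA scores are continuous, so the choice rarely matters in practice.
#'
#' @param pos_scores scores of the m positive (phenotype-1) samples.
#' @param neg_scores scores of the n negative (phenotype-2) samples.
#' @param ties `"strict"` (default) or `"half"`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pos_scores, neg_scores, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  m <- length(pos_scores); n <- length(neg_scores)
  if (m < 1L || n < 1L) stopf("both classes need at least one score")
  wins <- vapply(pos_scores, function(x) sum(x > neg_scores), numeric(1L))
  total <- sum(wins)
  if (ties == "half") {
    total <- total +
      0.5 * sum(vapply(pos_scores, function(x) sum(x == neg_scores), numeric(1L)))
  }
  total / (m * n)
}

#' Two-class linear discriminant with diagonal covariance shrinkage
#'
#' Standard LDA on a sample x feature matrix: pooled within-class
#' covariance S, shrunk to S + epsilon * (tr(S)/d) * I on the diagonal, and
#' projection w = S^-1 (mu1 - mu2). Scores are oriented so higher means
#' phenotype 1. The shrinkage keeps the fit well-posed when features are
#' collinear (e.g. a duplicated pathway column), a situation nested
#' feature-selection loops routinely create.
#'
#' @param x numeric matrix, samples x features, with column names.
#' @param labels phenotype vector coded 1/2, parallel to rows of `x`.
#' @param shrinkage epsilon >= 0 (default 1e-3).
#' @return object of class `lda_model` with `weights`, `threshold`,
#'   `feature_names`.
#' @export
fit_lda <- function(x, labels, shrinkage = 1e-3) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  x1 <- x[labels == 1L, , drop = FALSE]
  x2 <- x[labels == 2L, , drop = FALSE]
  if (nrow(x1) < 2L || nrow(x2) < 2L)
    stopf("LDA needs >= 2 samples per class")
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  s <- ((nrow(x1) - 1) * stats::cov(x1) + (nrow(x2) - 1) * stats::cov(x2)) /
    (nrow(x1) + nrow(x2) - 2)
  d <- ncol(x)
  s_shr <- s + diag(shrinkage * sum(diag(s)) / d, d)
  w <- tryCatch(solve(s_shr, m1 - m2),
                error = function(e) stopf(
                  "singular pooled covariance even after shrinkage: %s",
                  conditionMessage(e), class = "pathrank_singular_lda"))
  structure(list(weights = w,
                 threshold = sum(w * (m1 + m2) / 2),
                 feature_names = colnames(x),
                 shrinkage = shrinkage),
            class = "lda_model")
}

#' Discriminant scores for new samples
#'
#' @param object an `lda_model`.
#' @param newdata samples x feature matrix with the model's features.
#' @param ... unused.
#' @return numeric vector of scalar scores (higher = phenotype 1).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  drop(newdata %*% object$weights) - object$threshold
}

#' Greedy forward feature selection maximizing held-out AUC
#'
#' Starts from the top-ranked marker (always selected), then walks down the
#' candidate list; each candidate joins the feature set only if the LDA
#' trained on the marker-evaluation split and scored on the
#' feature-selection split strictly increases the AUC.
#'
#' @param candidates character vector of pathway names, ordered by
#'   decreasing |t| (at most the top-50 cap upstream).
#' @param train_x,train_labels marker-evaluation split (samples x pathway
#'   activity matrix and phenotype vector) used for LDA training.
#' @param eval_x,eval_labels feature-selection split used for AUC scoring.
#' @param shrinkage LDA shrinkage.
#' @param ties AUC tie mode.
#' @return list with `features` (selected names, in selection order) and
#'   `auc` (the best feature-selection AUC reached).
#' @export
greedy_feature_selection <- function(candidates, train_x, train_labels,
                                     eval_x, eval_labels,
                                     shrinkage = 1e-3, ties = "strict") {
  stopifnot(length(candidates) >= 1L)
  eval_auc <- function(features) {
    fit <- fit_lda(train_x[, features, drop = FALSE], train_labels, shrinkage)
    sc <- predict(fit, eval_x[, features, drop = FALSE])
    auc(sc[eval_labels == 1L], sc[eval_labels == 2L], ties)
  }
  selected <- candidates[1L]
  best <- tryCatch(eval_auc(selected), error = function(e) 0)
  for (cand in candidates[-1L]) {
    a <- tryCatch(eval_auc(c(selected, cand)), error = function(e) NA_real_)
    if (!is.na(a) && a > best) {
      selected <- c(selected, cand)
      best <- a
    }
  }
  list(features = selected, auc = best)
}

# Inner worker shared by the CV protocols: given training activities and
# labels, rank markers on the marker-evaluation subfold, cap candidates,
# and run greedy selection scored on the feature-selection subfold.
select_features_nested <- function(act_train, labels_train, inner_folds,
                                   top_k, t_formula, shrinkage, ties) {
  inner <- stratified_folds(labels_train, inner_folds)
  me <- inner < inner_folds   # marker-evaluation: first (inner_folds - 1) folds
  fs <- !me                   # feature-selection: last fold
  ok <- min(tabulate(labels_train[me], 2L)) >= 2L &&
    min(tabulate(labels_train[fs], 2L)) >= 1L
  if (!ok) return(NULL)
  ranked <- rank_markers(score_markers(act_train[, me, drop = FALSE],
                                       labels_train[me], t_formula))
  candidates <- utils::head(ranked$pathway, top_k)
  sel <- greedy_feature_selection(
    candidates,
    t(act_train[, me, drop = FALSE]), labels_train[me],
    t(act_train[, fs, drop = FALSE]), labels_train[fs],
    shrinkage, ties)
  sel$marker_eval_ids <- colnames(act_train)[me]
  sel$feature_sel_ids <- colnames(act_train)[fs]
  sel
}

new_cv_report <- function(rows, log, config, n_redraws) {
  aucs <- do.call(rbind, rows)
  structure(list(aucs = aucs,
                 mean_auc = mean(aucs$auc),
                 sd_auc = stats::sd(aucs$auc),
                 folds_log = log,
                 n_redraws = n_redraws,
                 config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: mean AUC %.4f (sd %.4f) over %d fold evaluations\n",
              x$config$method, x$mean_auc, x$sd_auc, nrow(x$aucs)))
  invisible(x)
}

#' Within-dataset nested cross-validation
#'
#' For each of `n_partitions` random partitions: a stratified `n_folds`-fold
#' split; each fold in turn is the test set and the rest the training set.
#' Activity models are estimated on the *entire* training set; the training
#' set is further split into `inner_folds` stratified subfolds, of which all
#' but one form the marker-evaluation set (markers ranked there by |t| and
#' capped at `top_k` candidates) and the last the feature-selection set
#' (greedy selection scored there by AUC). The final LDA is trained on the
#' full training set with the selected features and evaluated by AUC on the
#' held-out test fold. Test-fold sample ids never enter any estimation
#' step; the per-fold log records estimation and test ids so this is
#' auditable.
#'
#' Partitions that produce a degenerate split (a fold or subfold missing a
#' class, or too few samples for a t-score) are rejected and redrawn, with
#' the redraw count reported.
#'
#' @param expr expression matrix (genes x samples).
#' @param labels named phenotype vector coded 1/2.
#' @param gene_sets list of [gene_set] objects.
#' @param method activity inference method (see [pathway_activities()]).
#' @param n_partitions number of random partitions (the full protocol uses
#'   100; smaller values are appropriate for exploratory runs).
#' @param n_folds outer folds (default 5).
#' @param inner_folds inner subfolds (default 3: 2 marker-evaluation + 1
#'   feature-selection).
#' @param top_k candidate-marker cap (default 50).
#' @param seed integer seed fixing every split (the global RNG state is
#'   left untouched).
#' @param alpha,fraction,sigma_floor method parameters.
#' @param shrinkage LDA shrinkage.
#' @param t_formula t-score form (see [t_score()]).
#' @param auc_ties AUC tie mode (see [auc()]).
#' @param max_redraws redraw budget per partition.
#' @return a `cv_report`: per-partition/fold AUCs, mean, sd, fold log,
#'   config echo.
#' @export
within_dataset_cv <- function(expr, labels, gene_sets, method = "rank-llr",
                              n_partitions = 100L, n_folds = 5L,
                              inner_folds = 3L, top_k = 50L, seed = 1L,
                              alpha = 0.5, fraction = 0.1, sigma_floor = 1e-6,
                              shrinkage = 1e-3, t_formula = "welch",
                              auc_ties = "strict", max_redraws = 100L) {
  labels <- align_labels(expr, labels)
  check_labels(labels)
  config <- list(method = method, n_partitions = n_partitions,
                 n_folds = n_folds, inner_folds = inner_folds, top_k = top_k,
                 seed = seed, alpha = alpha, fraction = fraction,
                 sigma_floor = sigma_floor, shrinkage = shrinkage,
                 t_formula = t_formula, auc_ties = auc_ties)
  withr::with_seed(seed, {
    rows <- list(); log <- list(); n_redraws <- 0L
    for (p in seq_len(n_partitions)) {
      part <- NULL
      for (try in seq_len(max_redraws)) {
        cand <- run_within_partition(expr, labels, gene_sets, method, n_folds,
                                     inner_folds, top_k, alpha, fraction,
                                     sigma_floor, shrinkage, t_formula,
                                     auc_ties)
        if (!is.null(cand)) { part <- cand; break }
        n_redraws <- n_redraws + 1L
      }
      if (is.null(part))
        stopf("could not draw a non-degenerate partition in %d tries", max_redraws)
      part$rows$partition <- p
      rows[[p]] <- part$rows[, c("partition", "fold", "auc", "n_features")]
      log[[p]] <- part$log
    }
    new_cv_report(rows, log, config, n_redraws)
  })
}

# One candidate partition of the within-dataset protocol; NULL if any fold
# is degenerate (caller redraws).
run_within_partition <- function(expr, labels, gene_sets, method, n_folds,
                                 inner_folds, top_k, alpha, fraction,
                                 sigma_floor, shrinkage, t_formula, auc_ties) {
  folds <- stratified_folds(labels, n_folds)
  for (f in seq_len(n_folds)) {
    if (min(tabulate(labels[folds == f], 2L)) < 1L) return(NULL)
    if (min(tabulate(labels[folds != f], 2L)) < inner_folds) return(NULL)
  }
  rows <- vector("list", n_folds); log <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train <- folds != f
    expr_tr <- expr[, train, drop = FALSE]
    lab_tr <- labels[train]
    fitted <- pathway_activities(expr_tr, lab_tr, gene_sets, method,
                                 alpha = alpha, fraction = fraction,
                                 sigma_floor = sigma_floor)
    sel <- select_features_nested(fitted$activities, lab_tr, inner_folds,
                                  top_k, t_formula, shrinkage, auc_ties)
    if (is.null(sel)) return(NULL)
    final <- fit_lda(t(fitted$activities[sel$features, , drop = FALSE]),
                     lab_tr, shrinkage)
    act_te <- score_activities(fitted$models[sel$features],
                               expr[, !train, drop = FALSE])
    sc <- predict(final, t(act_te))
    lab_te <- labels[!train]
    rows[[f]] <- data.frame(fold = f,
                            auc = auc(sc[lab_te == 1L], sc[lab_te == 2L],
                                      auc_ties),
                            n_features = length(sel$features))
    log[[f]] <- list(fold = f,
                     estimation_ids = colnames(expr_tr),
                     test_ids = colnames(expr)[!train],
                     features = sel$features,
                     marker_eval_ids = sel$marker_eval_ids,
                     feature_sel_ids = sel$feature_sel_ids)
  }
  list(rows = do.call(rbind, rows), log = log)
}

#' Cross-dataset cross-validation
#'
#' Marker ranking and greedy feature selection are done entirely on the
#' first dataset (activity models fitted on all of it; a stratified 3-way
#' split gives 2 marker-evaluation folds and 1 feature-selection fold,
#' drawn once). Then, for each of `n_partitions` stratified 5-fold
#' partitions of the second dataset, an LDA on the dataset-1-selected
#' pathway features is trained on 4 folds and evaluated by AUC on the
#' held-out fold.
#'
#' `transfer_mode` controls where the activity models used on dataset 2 are
#' estimated: `"refit"` (default) re-estimates them on each dataset-2
#' training split (only the selected pathways), while `"frozen"` applies
#' the dataset-1 models as-is, probing how portable the fitted models
#' themselves are.
#'
#' @param expr1,labels1 marker-selection dataset.
#' @param expr2,labels2 classification dataset.
#' @param gene_sets list of [gene_set] objects; intersected with both
#'   matrices internally.
#' @param transfer_mode `"refit"` or `"frozen"`.
#' @inheritParams within_dataset_cv
#' @return a `cv_report`; `$selected_features` holds the dataset-1 feature
#'   list.
#' @export
cross_dataset_cv <- function(expr1, labels1, expr2, labels2, gene_sets,
                             method = "rank-llr", n_partitions = 100L,
                             n_folds = 5L, inner_folds = 3L, top_k = 50L,
                             seed = 1L, transfer_mode = c("refit", "frozen"),
                             alpha = 0.5, fraction = 0.1, sigma_floor = 1e-6,
                             shrinkage = 1e-3, t_formula = "welch",
                             auc_ties = "strict", max_redraws = 100L) {
  transfer_mode <- match.arg(transfer_mode)
  labels1 <- align_labels(expr1, labels1); check_labels(labels1)
  labels2 <- align_labels(expr2, labels2); check_labels(labels2)
  gene_sets <- suppressWarnings(
    restrict_to_common_genes(gene_sets, list(expr1, expr2)))
  if (length(gene_sets) == 0L) stopf("no shared gene sets after intersection")
  config <- list(method = method, n_partitions = n_partitions,
                 n_folds = n_folds, inner_folds = inner_folds, top_k = top_k,
                 seed = seed, transfer_mode = transfer_mode, alpha = alpha,
                 fraction = fraction, sigma_floor = sigma_floor,
                 shrinkage = shrinkage, t_formula = t_formula,
                 auc_ties = auc_ties)
  withr::with_seed(seed, {
    # stage 1: feature selection on dataset 1
    fitted1 <- pathway_activities(expr1, labels1, gene_sets, method,
                                  alpha = alpha, fraction = fraction,
                                  sigma_floor = sigma_floor)
    sel <- NULL
    for (try in seq_len(max_redraws)) {
      sel <- select_features_nested(fitted1$activities, labels1, inner_folds,
                                    top_k, t_formula, shrinkage, auc_ties)
      if (!is.null(sel)) break
    }
    if (is.null(sel)) stopf("could not split dataset 1 without a degenerate fold")
    features <- sel$features
    sets2 <- gene_sets[features]

    # stage 2: classification on dataset 2
    rows <- list(); log <- list(); n_redraws <- 0L
    for (p in seq_len(n_partitions)) {
      folds <- NULL
      for (try in seq_len(max_redraws)) {
        cand <- stratified_folds(labels2, n_folds)
        bad <- any(vapply(seq_len(n_folds), function(f) {
          min(tabulate(labels2[cand == f], 2L)) < 1L ||
            min(tabulate(labels2[cand != f], 2L)) < 2L
        }, TRUE))
        if (!bad) { folds <- cand; break }
        n_redraws <- n_redraws + 1L
      }
      if (is.null(folds))
        stopf("could not draw a non-degenerate dataset-2 partition")
      prows <- vector("list", n_folds); plog <- vector("list", n_folds)
      for (f in seq_len(n_folds)) {
        train <- folds != f
        if (transfer_mode == "refit") {
          models <- pathway_activities(expr2[, train, drop = FALSE],
                                       labels2[train], sets2, method,
                                       alpha = alpha, fraction = fraction,
                                       sigma_floor = sigma_floor)$models
          est_ids <- colnames(expr2)[train]
        } else {
          models <- fitted1$models[features]
          est_ids <- colnames(expr1)
        }
        act_tr <- score_activities(models, expr2[, train, drop = FALSE])
        final <- fit_lda(t(act_tr), labels2[train], shrinkage)
        act_te <- score_activities(models, expr2[, !train, drop = FALSE])
        sc <- predict(final, t(act_te))
        lab_te <- labels2[!train]
        prows[[f]] <- data.frame(partition = p, fold = f,
                                 auc = auc(sc[lab_te == 1L],
                                           sc[lab_te == 2L], auc_ties),
                                 n_features = length(features))
        plog[[f]] <- list(partition = p, fold = f,
                          estimation_ids = est_ids,
                          lda_train_ids = colnames(expr2)[train],
                          test_ids = colnames(expr2)[!train])
      }
      rows[[p]] <- do.call(rbind, prows)
      log[[p]] <- plog
    }
    rep <- new_cv_report(rows, log, config, n_redraws)
    rep$selected_features <- features
    rep
  })
}

#' Write the per-fold AUCs of a `cv_report` as TSV
#'
#' @param report a `cv_report`.
#' @param path output path.
#' @export
write_cv_report <- function(report, path) {
  utils::write.table(report$aucs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
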