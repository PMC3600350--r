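test_that("AUC matches its definition and the brute-force oracle", {
  expect_equal(auc(c(3, 4), c(1, 2)), 1)
  expect_equal(auc(c(1, 2), c(3, 4)), 0)
  expect_equal(auc(c(2, 4), c(1, 3)), 0.75)
  # tie handling: the two tied cross-pairs get 0 credit (strict) or 1/2
  expect_equal(auc(c(1, 1), c(1, 0)), 0.5)
  expect_equal(auc(c(1, 1), c(1, 0), ties = "half"), 0.75)
  expect_error(auc(numeric(0), 1), "at least one")

  withr::local_seed(33)
  for (rep in 1:25) {
    m <- sample(1:50, 1); n <- sample(1:50, 1)
    pos <- round(rnorm(m), 1); neg <- round(rnorm(n), 1)  # rounding forces ties
    expect_identical(auc(pos, neg), auc_oracle(pos, neg))
    expect_identical(auc(pos, neg, "half"), auc_oracle(pos, neg, "half"))
    # complement identity holds under half-credit tie handling
    expect_equal(auc(pos, neg, "half") + auc(neg, pos, "half"), 1)
  }
})

test_that("shrinkage LDA separates, orients, survives collinearity, and matches MASS when well-posed", {
  withr::local_seed(71)
  n <- 60
  labels <- rep(1:2, each = n / 2)
  x <- cbind(f1 = rnorm(n, mean = ifelse(labels == 1, 1, -1)),
             f2 = rnorm(n))
  m <- fit_lda(x, labels)
  sc <- predict(m, x)
  expect_gt(mean(sc[labels == 1]), mean(sc[labels == 2]))
  # 1-D symmetric case: score sign equals the sample's side of the midpoint
  x1 <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1,
               dimnames = list(NULL, "f"))
  m1 <- fit_lda(x1, c(2, 2, 2, 1, 1, 1))
  expect_identical(sign(predict(m1, x1)), sign(x1[, 1]))
  # label swap negates scores
  m_sw <- fit_lda(x, 3L - labels)
  expect_equal(predict(m_sw, x), -sc)
  # duplicated feature column: shrinkage keeps the fit well-posed
  xdup <- cbind(x, f3 = x[, "f1"])
  expect_silent(mdup <- fit_lda(xdup, labels))
  expect_true(all(is.finite(predict(mdup, xdup))))
  # all-constant features are irrecoverably singular
  expect_error(fit_lda(matrix(1, n, 2, dimnames = list(NULL, c("a", "b"))),
                       labels),
               class = "pathrank_singular_lda")
  # independent cross-check: without shrinkage the discriminant direction
  # is proportional to MASS::lda's, so scores correlate to |r| = 1
  skip_if_not_installed("MASS")
  ml <- MASS::lda(x, grouping = factor(labels))
  mass_scores <- predict(ml, as.data.frame(x))$x[, 1]
  ours <- predict(fit_lda(x, labels, shrinkage = 0), x)
  expect_equal(abs(cor(ours, mass_scores)), 1, tolerance = 1e-10)
})

test_that("greedy selection starts from the top marker and only accepts strict AUC gains", {
  withr::local_seed(81)
  n <- 40
  labels <- rep(1:2, each = n / 2)
  good <- rnorm(n, ifelse(labels == 1, 2, -2), 0.5)
  x <- cbind(M1 = good, M2 = rnorm(n), M3 = good)  # M3 duplicates M1
  half <- rep(c(TRUE, FALSE), n / 2)
  # single candidate: always selected
  one <- greedy_feature_selection("M2", x[half, , drop = FALSE], labels[half],
                                  x[!half, , drop = FALSE], labels[!half])
  expect_identical(one$features, "M2")
  # duplicate of an already-selected feature cannot strictly increase AUC
  sel <- greedy_feature_selection(c("M1", "M3", "M2"),
                                  x[half, ], labels[half],
                                  x[!half, ], labels[!half])
  expect_false("M3" %in% sel$features)
  expect_identical(sel$features[1], "M1")
  expect_true(sel$auc >= one$auc)
})

test_that("greedy selection isolates a noise-free marker among noise candidates", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s, {
      n <- 400  # 200/class
      labels <- rep(1:2, each = n / 2)
      x <- cbind(SIG = ifelse(labels == 1, 1, -1) + rnorm(n, sd = 0.05),
                 matrix(rnorm(n * 20), n,
                        dimnames = list(NULL, paste0("N", 1:20))))
      half <- rep(c(TRUE, FALSE), n / 2)
      sel <- greedy_feature_selection(colnames(x), x[half, ], labels[half],
                                      x[!half, ], labels[!half])
      identical(sel$features, "SIG")
    })
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("within-dataset CV is deterministic, leak-free, and shaped as partitions x folds", {
  ds <- generate_dataset(tiny_config(seed = 61))
  cv1 <- within_dataset_cv(ds$expr, ds$labels, ds$gene_sets,
                           n_partitions = 2, seed = 5)
  cv2 <- within_dataset_cv(ds$expr, ds$labels, ds$gene_sets,
                           n_partitions = 2, seed = 5)
  expect_identical(cv1$aucs, cv2$aucs)
  expect_identical(nrow(cv1$aucs), 10L)          # 2 partitions x 5 folds
  expect_true(all(cv1$aucs$auc >= 0 & cv1$aucs$auc <= 1))
  expect_equal(cv1$mean_auc, mean(cv1$aucs$auc))
  # no leakage: test ids never appear in estimation or inner-split ids
  for (part in cv1$folds_log) for (fl in part) {
    expect_length(intersect(fl$test_ids, fl$estimation_ids), 0)
    expect_length(intersect(fl$test_ids, fl$marker_eval_ids), 0)
    expect_length(intersect(fl$test_ids, fl$feature_sel_ids), 0)
    # inner splits partition the training set
    expect_setequal(c(fl$marker_eval_ids, fl$feature_sel_ids),
                    fl$estimation_ids)
  }
  # different seeds draw different partitions
  cv3 <- within_dataset_cv(ds$expr, ds$labels, ds$gene_sets,
                           n_partitions = 2, seed = 6)
  expect_false(identical(cv1$aucs$auc, cv3$aucs$auc))
})

test_that("cross-dataset CV transfers dataset-1 features and reports both modes", {
  ds1 <- generate_dataset(tiny_config(seed = 62))
  ds2 <- generate_dataset(tiny_config(seed = 63))
  cv <- cross_dataset_cv(ds1$expr, ds1$labels, ds2$expr, ds2$labels,
                         ds1$gene_sets, n_partitions = 2, seed = 9)
  expect_identical(nrow(cv$aucs), 10L)
  expect_true(length(cv$selected_features) >= 1)
  expect_true(all(cv$selected_features %in% names(ds1$gene_sets)))
  # informative pathways shared across datasets: features should hit them
  expect_true(any(cv$selected_features %in% ds1$truth$informative_pathways))
  # frozen mode runs and stays deterministic under the same seed
  fz1 <- cross_dataset_cv(ds1$expr, ds1$labels, ds2$expr, ds2$labels,
                          ds1$gene_sets, n_partitions = 1, seed = 9,
                          transfer_mode = "frozen")
  fz2 <- cross_dataset_cv(ds1$expr, ds1$labels, ds2$expr, ds2$labels,
                          ds1$gene_sets, n_partitions = 1, seed = 9,
                          transfer_mode = "frozen")
  expect_identical(fz1$aucs, fz2$aucs)
  # frozen-mode estimation ids come from dataset 1
  expect_setequal(fz1$folds_log[[1]][[1]]$estimation_ids, names(ds1$labels))
})

test_that("self-transfer matches within-dataset performance to sampling noise", {
  ds <- generate_dataset(tiny_config(seed = 64))
  within <- within_dataset_cv(ds$expr, ds$labels, ds$gene_sets,
                              n_partitions = 3, seed = 11)
  self <- cross_dataset_cv(ds$expr, ds$labels, ds$expr, ds$labels,
                           ds$gene_sets, n_partitions = 3, seed = 11)
  expect_lt(abs(within$mean_auc - self$mean_auc), 0.1)
})
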