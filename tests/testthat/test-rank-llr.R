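test_that("smoothed pair PMFs match the pseudocount estimator and stay inside (0,1)", {
  # phenotype 1: 8 ones of 10; phenotype 2: 0 ones of 10
  ranks <- matrix(c(rep(1L, 8), 0L, 0L, rep(0L, 10)), nrow = 1)
  colnames(ranks) <- paste0("S", 1:20)
  labels <- toy_labels(colnames(ranks), rep(1:2, each = 10))
  pmf <- estimate_pair_pmfs(ranks, labels, alpha = 0.5)
  expect_equal(pmf$p1, 8.5 / 11)
  expect_equal(pmf$p2, 0.5 / 11)
  expect_gt(pmf$p2, 0)

  # alpha = 0 on balanced counts is the raw frequency
  ranks2 <- matrix(rep(c(1L, 0L), 10), nrow = 1)
  colnames(ranks2) <- colnames(ranks)
  expect_equal(estimate_pair_pmfs(ranks2, labels, alpha = 0)$p1, 0.5)
})

test_that("mutual-information screening ranks perfect dependence first and obeys the ceil rule", {
  labels <- toy_labels(paste0("S", 1:20), rep(1:2, each = 10))
  perfect <- as.integer(labels == 1L)
  constant <- rep(1L, 20)
  withr::local_seed(5)
  noise <- replicate(43, sample(0:1, 20, replace = TRUE))
  ranks <- rbind(constant, t(noise), perfect)
  colnames(ranks) <- names(labels)

  mi <- pathrank:::pairwise_mutual_information(ranks, labels)
  expect_equal(mi[[1]], 0)                  # zero-entropy row
  expect_equal(mi[[45]], log(2))            # identical to phenotype, balanced

  sel <- mutual_information_screen(ranks, labels, fraction = 0.10)
  expect_length(sel, 5L)                    # ceil(0.1 * 45)
  expect_identical(sel[1L], 45L)
  # minimum-1 rule and tie-breaking by pair order
  tied <- matrix(0L, 3, 20, dimnames = list(NULL, names(labels)))
  expect_identical(mutual_information_screen(tied, labels, 0.01), 1L)
  expect_error(mutual_information_screen(ranks, labels, 0), "fraction")
})

test_that("pair LLRs are the log odds-ratios of the PMFs and always finite", {
  llr <- compute_pair_llr(0.8, 0.2)
  expect_equal(llr$llr1, log(4))
  expect_equal(llr$llr0, log(0.25))
  expect_equal(unlist(compute_pair_llr(0.3, 0.3)), c(llr0 = 0, llr1 = 0))
  # chained from the smoothing example: p1 = 8.5/11, p2 = 0.5/11
  expect_equal(compute_pair_llr(8.5 / 11, 0.5 / 11)$llr1, log(17))
  # smoothed extremes stay finite
  extreme <- compute_pair_llr(0.5 / 11, 10.5 / 11)
  expect_true(all(is.finite(unlist(extreme))))
})

test_that("LLR normalization centers/scales with the K-1 divisor and flags zero spread", {
  norm <- normalize_llrs(matrix(c(1, 2, 3), nrow = 1))
  expect_equal(unname(norm$values[1, ]), c(-1, 0, 1))
  expect_equal(unname(norm$mu), 2)
  expect_equal(unname(norm$sigma), 1)
  expect_false(norm$degenerate)

  const <- normalize_llrs(matrix(c(5, 5, 5), nrow = 1))
  expect_true(const$degenerate)

  withr::local_seed(8)
  x <- matrix(rnorm(40), 4, 10)
  n <- normalize_llrs(x)
  expect_equal(rowMeans(n$values), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(n$values, 1, sd), rep(1, 4), tolerance = 1e-12)
})

test_that("fitted models recover planted informative pairs and drop degenerate ones", {
  ds <- generate_dataset(simulation_config(n_pathways = 1L,
                                           genes_per_pathway = 10L,
                                           n_informative = 1L,
                                           n_samples_per_class = 50L,
                                           seed = 21))
  m <- fit_rank_activity_model(ds$expr, ds$labels, ds$gene_sets[[1]])
  planted <- ds$truth$informative_pairs
  sel_keys <- paste(m$pairs[, "i"], m$pairs[, "j"])
  expect_true(all(paste(planted[, "i"], planted[, "j"]) %in% sel_keys))
  expect_false(m$degenerate)
  expect_true(all(m$norm_sigma > 0))
  expect_true(all(is.finite(c(m$llr0, m$llr1))))

  # a phenotype-independent pathway fits without error, |t| near 0
  null <- generate_null_dataset(10L, 100L, seed = 22)
  gs <- gene_set("NULLPW", rownames(null$expr))
  mn <- fit_rank_activity_model(null$expr, null$labels, gs)
  a <- infer_activity(mn, null$expr)
  # in-sample MI screening inflates the null |t| somewhat above the nominal
  # N(0,1) scale; it stays an order of magnitude below planted markers (~30)
  expect_lt(abs(t_score(a, null$labels)), 8)

  # n = 2 pathway: exactly one pair regardless of fraction
  gs2 <- gene_set("TWO", rownames(null$expr)[1:2])
  m2 <- fit_rank_activity_model(null$expr, null$labels, gs2, fraction = 0.1)
  expect_identical(nrow(m2$pairs), 1L)
})

test_that("activity scoring matches hand arithmetic and a naive per-sample loop", {
  # single-pair model, frozen constants chosen by hand
  model <- structure(list(pathway_name = "P", genes = c("g1", "g2"),
                          pairs = cbind(i = 1L, j = 2L),
                          p1 = 0.8, p2 = 0.2,
                          llr0 = -log(4), llr1 = log(4),
                          norm_mu = 0, norm_sigma = log(4),
                          alpha = 0.5, fraction = 1, degenerate = FALSE,
                          estimation_samples = character(0)),
                     class = "rank_activity_model")
  expr <- toy_expr(c(1, 2, 2, 1), c("g1", "g2"), c("up", "down"))
  a <- infer_activity(model, expr)
  expect_equal(unname(a), c(1, -1))

  # naive loop oracle on a fitted model
  ds <- generate_dataset(tiny_config(seed = 31))
  m <- fit_rank_activity_model(ds$expr, ds$labels, ds$gene_sets[[1]])
  got <- infer_activity(m, ds$expr)
  naive <- vapply(colnames(ds$expr), function(s) {
    tot <- 0
    for (q in seq_len(nrow(m$pairs))) {
      xi <- ds$expr[m$genes[m$pairs[q, "i"]], s]
      xj <- ds$expr[m$genes[m$pairs[q, "j"]], s]
      lam <- if (xi < xj) m$llr1[q] else m$llr0[q]
      tot <- tot + (lam - m$norm_mu[q]) / m$norm_sigma[q]
    }
    tot
  }, numeric(1))
  expect_equal(got, naive)

  # training-set activities sum to zero (per-pair mean-0 contributions)
  expect_equal(sum(infer_activity(m, ds$expr)), 0, tolerance = 1e-9)

  # rank invariance propagates to activities, exactly
  expect_identical(infer_activity(m, exp(ds$expr)), got)

  # missing gene is a named error
  expect_error(infer_activity(m, ds$expr[-1, , drop = FALSE]), "missing")
})

test_that("expected activity gap grows with single-pair PMF separation", {
  gap <- function(p1, p2) {
    llr <- compute_pair_llr(p1, p2)
    # E[lambda | phen l] before normalization; normalization is monotone
    e1 <- p1 * llr$llr1 + (1 - p1) * llr$llr0
    e2 <- p2 * llr$llr1 + (1 - p2) * llr$llr0
    e1 - e2
  }
  seps <- seq(0.55, 0.95, by = 0.1)
  gaps <- vapply(seps, function(p) gap(p, 1 - p), numeric(1))
  expect_true(all(diff(gaps) > 0))
  # verified by simulation on generated data
  aucs <- vapply(c(0.7, 0.9), function(ph) {
    ds <- generate_dataset(simulation_config(
      n_pathways = 1, genes_per_pathway = 4, n_informative = 1,
      p_high = ph, p_low = 1 - ph, n_samples_per_class = 100, seed = 77))
    m <- fit_rank_activity_model(ds$expr, ds$labels, ds$gene_sets[[1]])
    a <- infer_activity(m, ds$expr)
    mean(a[ds$labels == 1]) - mean(a[ds$labels == 2])
  }, numeric(1))
  expect_gt(aucs[2], aucs[1])
})

test_that("models serialize to JSON and round-trip at full precision", {
  ds <- generate_dataset(tiny_config(seed = 41))
  m <- fit_rank_activity_model(ds$expr, ds$labels, ds$gene_sets[[2]])
  path <- tempfile(fileext = ".json")
  withr::defer(unlink(path))
  write_rank_model(m, path)
  back <- read_rank_model(path)
  expect_identical(back$pairs, m$pairs)
  expect_identical(back$genes, m$genes)
  expect_equal(back$norm_mu, m$norm_mu, tolerance = 1e-14)
  expect_equal(back$norm_sigma, m$norm_sigma, tolerance = 1e-14)
  expect_equal(infer_activity(back, ds$expr), infer_activity(m, ds$expr),
               tolerance = 1e-12)
})
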