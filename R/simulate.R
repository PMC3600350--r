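#' Simulation configuration for planted-pathway expression data
#'
#' Defines a two-phenotype expression dataset in which a subset of pathways
#' carries phenotype-dependent *pair-ordering* signal: within each
#' informative pathway, designated gene pairs (i, j) are generated so that
#' P(x_i < x_j) = `p_high` under phenotype 1 and `p_low` under phenotype 2.
#' This is signal at the level the rank method models — member-gene means
#' are phenotype-independent, so expression-level summaries see nothing
#' unless `signal_mode = "mean_shift"` is chosen, which instead shifts the
#' informative genes' means by `shift` under phenotype 1 (so that
#' expression-level baselines are not strawmen).
#'
#' @param n_pathways total pathways (disjoint gene blocks).
#' @param genes_per_pathway member genes per pathway.
#' @param n_informative pathways carrying signal.
#' @param p_high probability a designated pair is ascending under
#'   phenotype 1 (default 0.9).
#' @param p_low same under phenotype 2 (default 0.1).
#' @param n_samples_per_class samples per phenotype (default 100).
#' @param noise_sd additive Gaussian expression noise (default 0.1; the
#'   pair offset is 1.0, so noise virtually never flips a planted order).
#' @param distortion `"none"` or `"monotone"`: whether to pass each sample
#'   through an independent random strictly increasing map after
#'   generation (emulating per-chip normalization/batch differences).
#' @param signal_mode `"rank"` (default) or `"mean_shift"`.
#' @param shift mean shift for `signal_mode = "mean_shift"` (default 0.5).
#' @param seed RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_pathways = 20L, genes_per_pathway = 10L,
                              n_informative = 5L, p_high = 0.9, p_low = 0.1,
                              n_samples_per_class = 100L, noise_sd = 0.1,
                              distortion = c("none", "monotone"),
                              signal_mode = c("rank", "mean_shift"),
                              shift = 0.5, seed = 1L) {
  distortion <- match.arg(distortion)
  signal_mode <- match.arg(signal_mode)
  if (!(p_low >= 0 && p_low < p_high && p_high <= 1))
    stopf("need 0 <= p_low < p_high <= 1 (got p_low=%g, p_high=%g)",
          p_low, p_high)
  if (n_pathways < 1L || genes_per_pathway < 2L || n_samples_per_class < 1L)
    stopf("counts must be positive (and >= 2 genes per pathway)")
  if (n_informative > n_pathways)
    stopf("n_informative (%d) exceeds n_pathways (%d)",
          n_informative, n_pathways)
  structure(list(n_pathways = n_pathways,
                 genes_per_pathway = genes_per_pathway,
                 n_informative = n_informative,
                 p_high = p_high, p_low = p_low,
                 n_samples_per_class = n_samples_per_class,
                 noise_sd = noise_sd, distortion = distortion,
                 signal_mode = signal_mode, shift = shift, seed = seed),
            class = "simulation_config")
}

#' Generate a planted-pathway two-phenotype expression dataset
#'
#' Pathways occupy disjoint gene blocks. In each informative pathway the
#' designated pairs are the disjoint consecutive pairs (1,2), (3,4), ...
#' (so `floor(genes_per_pathway / 2)` per pathway); for each such pair and
#' sample, a shared latent level b ~ N(0,1) is drawn and a signed offset of
#' 1.0 placed so the pair is ascending with the phenotype's probability,
#' after which N(0, noise_sd) noise is added per gene. All other genes are
#' exchangeable N(0,1) noise. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `expr` (genes x samples matrix), `labels` (named 1/2
#'   vector), `gene_sets` (list of [gene_set]), and `truth` (informative
#'   pathway names, their designated pairs, and the config echo).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    m <- config$genes_per_pathway
    npw <- config$n_pathways
    k <- 2L * config$n_samples_per_class
    labels <- rep(c(1L, 2L), each = config$n_samples_per_class)
    sample_ids <- sprintf("S%03d", seq_len(k))
    names(labels) <- sample_ids

    gene_ids <- as.vector(vapply(seq_len(npw), function(p)
      sprintf("PW%02dG%02d", p, seq_len(m)), character(m)))
    expr <- matrix(stats::rnorm(npw * m * k), nrow = npw * m, ncol = k,
                   dimnames = list(gene_ids, sample_ids))

    informative <- sprintf("PW%02d", seq_len(config$n_informative))
    pair_starts <- seq(1L, m - 1L, by = 2L)
    pairs <- cbind(i = pair_starts, j = pair_starts + 1L)
    for (p in seq_len(config$n_informative)) {
      base_row <- (p - 1L) * m
      if (config$signal_mode == "rank") {
        p_asc <- ifelse(labels == 1L, config$p_high, config$p_low)
        for (q in seq_len(nrow(pairs))) {
          b <- stats::rnorm(k)
          asc <- stats::runif(k) < p_asc
          off <- ifelse(asc, 0.5, -0.5)
          expr[base_row + pairs[q, "i"], ] <-
            b - off + stats::rnorm(k, sd = config$noise_sd)
          expr[base_row + pairs[q, "j"], ] <-
            b + off + stats::rnorm(k, sd = config$noise_sd)
        }
      } else {
        rows <- base_row + seq_len(m)
        expr[rows, labels == 1L] <- expr[rows, labels == 1L] + config$shift
      }
    }

    gene_sets <- lapply(seq_len(npw), function(p) {
      gene_set(sprintf("PW%02d", p), gene_ids[(p - 1L) * m + seq_len(m)],
               sprintf("synthetic pathway %d", p))
    })
    names(gene_sets) <- vapply(gene_sets, `[[`, "", "name")

    if (config$distortion == "monotone")
      expr <- apply_monotone_distortion(expr, seed = config$seed + 1L)

    list(expr = expr, labels = labels, gene_sets = gene_sets,
         truth = list(informative_pathways = informative,
                      informative_pairs = pairs,
                      config = config))
  })
}

#' Apply an independent strictly increasing distortion to each sample
#'
#' Passes each sample's values through a random positive-slope
#' piecewise-linear map (5 knots spanning the sample's range), emulating
#' per-chip normalization or batch differences. Within-sample value
#' ordering — and hence every rank-based quantity — is preserved exactly;
#' absolute values, and with them mean/median/Gaussian-LLR activities, are
#' not.
#'
#' @param expr expression matrix (genes x samples).
#' @param seed RNG seed.
#' @param n_knots knots per map (>= 3).
#' @return distorted matrix with the same dimnames.
#' @export
apply_monotone_distortion <- function(expr, seed = 1L, n_knots = 5L) {
  stopifnot(n_knots >= 3L)
  withr::with_seed(seed, {
    out <- expr
    for (s in seq_len(ncol(expr))) {
      v <- expr[, s]
      rng <- range(v)
      if (rng[1L] == rng[2L]) {           # constant sample: random shift
        out[, s] <- v + stats::runif(1L, -1, 1)
        next
      }
      kx <- seq(rng[1L], rng[2L], length.out = n_knots)
      slopes <- stats::runif(n_knots - 1L, 0.2, 2)
      ky <- stats::runif(1L, -1, 1) + c(0, cumsum(slopes * diff(kx)))
      out[, s] <- stats::approx(kx, ky, xout = v)$y
    }
    out
  })
}

#' Generate a signal-free null dataset
#'
#' i.i.d. N(0,1) expression with labels carrying no information; used for
#' permutation-null and type-I-error style checks.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_class samples per phenotype.
#' @param seed RNG seed.
#' @return list with `expr` and `labels`.
#' @export
generate_null_dataset <- function(n_genes, n_samples_per_class, seed = 1L) {
  stopifnot(n_genes >= 1L, n_samples_per_class >= 1L)
  withr::with_seed(seed, {
    k <- 2L * n_samples_per_class
    ids <- sprintf("S%03d", seq_len(k))
    expr <- matrix(stats::rnorm(n_genes * k), nrow = n_genes,
                   dimnames = list(sprintf("G%04d", seq_len(n_genes)), ids))
    labels <- stats::setNames(rep(c(1L, 2L), each = n_samples_per_class), ids)
    list(expr = expr, labels = labels)
  })
}
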