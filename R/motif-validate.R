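#' Support of a motif against column-permuted versions of itself
#'
#' The discovered matrix is compared with `n_perm` motifs obtained by
#' shuffling its column order, which preserves per-column base
#' composition and total information content. The test statistic is the
#' median over sequences of the per-sequence maximum weight score; the
#' support is the fraction of permuted motifs whose statistic falls
#' strictly below the real motif's. Scores are computed over the cluster
#' promoters plus an optional second promoter set (e.g. orthologous
#' promoters from a related species).
#'
#' @param x a [pfm()].
#' @param cluster_promoters cluster promoter sequences.
#' @param second_promoter_set optional additional sequences.
#' @param n_perm number of column permutations (default 100).
#' @param seed integer RNG seed.
#' @param background_freqs background base frequencies for scoring.
#' @return numeric support fraction in [0, 1], with attributes
#'   `real_statistic` and `perm_statistics`. A matrix whose columns are
#'   all identical has no meaningful permutations; support is 0 with a
#'   warning.
#' @export
permutation_support <- function(x, cluster_promoters,
                                second_promoter_set = NULL,
                                n_perm = 100, seed = 1,
                                background_freqs = rep(0.25, 4)) {
  stopifnot(inherits(x, "pfm"), n_perm >= 1)
  seqs <- c(promoter_sequences(cluster_promoters),
            promoter_sequences(second_promoter_set))
  if (nrow(unique(t(x$counts))) == 1L) {
    warning("all matrix columns identical: permutation support undefined")
    out <- 0
    attr(out, "real_statistic") <- NA_real_
    attr(out, "perm_statistics") <- rep(NA_real_, n_perm)
    return(out)
  }
  set.seed(seed)
  stat <- function(m) {
    s <- best_scores(m, seqs, background_freqs)
    stats::median(s, na.rm = TRUE)
  }
  real <- stat(x)
  w <- ncol(x$counts)
  perm <- vapply(seq_len(n_perm), function(i) {
    cc <- x$counts[, sample.int(w), drop = FALSE]
    stat(pfm(cc, x$pseudocount, id = paste0(x$id, "_perm")))
  }, numeric(1))
  out <- mean(perm < real)
  attr(out, "real_statistic") <- real
  attr(out, "perm_statistics") <- perm
  out
}

#' Compare a cluster's motif significance against random gene clusters
#'
#' Draws `n_random` gene sets of the same size (without replacement
#' within each draw) from the promoter universe, reruns the same
#' discovery on each, and declares the real motif supported when its top
#' significance exceeds the given quantile of the negative-control top
#' significances.
#'
#' @param cluster_genes gene ids of the real cluster.
#' @param promoter_universe named character vector (or `promoter_set`)
#'   covering all candidate genes, including the cluster.
#' @param discovery_fn function(cluster_seqs, universe) -> top sig
#'   (numeric scalar). Default: best [oligo_analysis()] sig over
#'   `k_values` 6:8 (background precomputed once from the universe).
#' @param n_random number of random clusters (default 50, >= 1).
#' @param quantile quantile of negative sigs to beat (default 0.95).
#' @param seed integer RNG seed.
#' @param k_values word lengths for the default discovery function.
#' @return list: real_sig, negative_sigs, threshold, supported.
#' @export
negative_control_support <- function(cluster_genes, promoter_universe,
                                     discovery_fn = NULL, n_random = 50,
                                     quantile = 0.95, seed = 1,
                                     k_values = 6:8) {
  if (n_random < 1) stop("n_random must be >= 1")
  universe <- promoter_sequences(promoter_universe)
  stopifnot(all(cluster_genes %in% names(universe)))
  if (length(universe) < 2 * length(cluster_genes))
    warning("universe smaller than twice the cluster: ",
            "negative controls overlap the cluster heavily")
  if (is.null(discovery_fn)) {
    bg <- word_background(universe, k_values)
    discovery_fn <- function(cluster_seqs, universe_seqs) {
      res <- oligo_analysis(cluster_seqs, bg, k_values = k_values,
                            sig_threshold = -Inf)
      if (nrow(res) == 0) -Inf else max(res$sig)
    }
  }
  real_sig <- discovery_fn(universe[cluster_genes], universe)
  set.seed(seed)
  negative_sigs <- vapply(seq_len(n_random), function(i) {
    draw <- sample(names(universe), length(cluster_genes))
    discovery_fn(universe[draw], universe)
  }, numeric(1))
  threshold <- stats::quantile(negative_sigs, quantile, names = FALSE)
  list(real_sig = real_sig, negative_sigs = negative_sigs,
       threshold = threshold, supported = real_sig > threshold)
}
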