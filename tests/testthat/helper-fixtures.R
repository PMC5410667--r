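# shared fixtures, generated once per session and cached
.fixtures <- new.env(parent = emptyenv())

# 200-gene promoter universe with an 8-mer planted upstream of the first
# 15 genes at fraction 0.8; word backgrounds for k = 6:8
planted_universe <- function() {
  if (is.null(.fixtures$planted)) {
    gen <- make_promoter_genome(n_genes = 200,
                                planted_motif = "TTGACCGA",
                                planting_fraction = 0.8,
                                target_genes = sprintf("gene%03d", 1:15),
                                seed = 101)
    ps <- extract_promoters(gen$genome, gen$genes)
    .fixtures$planted <- list(
      gen = gen, ps = ps,
      bg = word_background(ps, 6:8),
      cluster = sprintf("gene%03d", 1:15))
  }
  .fixtures$planted
}

# motif-free universe of the same shape, for null calibration
null_universe <- function() {
  if (is.null(.fixtures$null)) {
    gen <- make_promoter_genome(n_genes = 200, planted_motif = NULL,
                                seed = 202)
    ps <- extract_promoters(gen$genome, gen$genes)
    .fixtures$null <- list(gen = gen, ps = ps,
                           bg = word_background(ps, 6:8))
  }
  .fixtures$null
}

# small deterministic expression matrix from explicit values
toy_expression <- function(values, unit = "TPM") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("iso%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  expression_matrix(values, unit = unit)
}

# two same-shape isoform groups offset by `offset` log2 units;
# values are already on the log scale (use log_transform = FALSE)
magnitude_groups <- function(n_per_group = 20, offset = 4) {
  shape <- c(3, 7, 4, 9, 5, 3, 7, 4, 9, 5, 6, 2, 8, 5)
  v <- rbind(matrix(rep(shape, n_per_group), n_per_group, byrow = TRUE),
             matrix(rep(shape + offset, n_per_group), n_per_group,
                    byrow = TRUE))
  toy_expression(v)
}

# one-hot PFM spelling a word, zero pseudocount
one_hot_pfm <- function(word, n_sites = 20) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  mat <- vapply(ch, function(b) {
    col <- stats::setNames(rep(0, 4), c("A", "C", "G", "T"))
    col[b] <- n_sites
    col
  }, numeric(4))
  pfm(mat, pseudocount = 0, id = paste0("onehot_", word))
}

random_pfm <- function(w = 8, n = 20, seed = 1) {
  set.seed(seed)
  cc <- matrix(stats::rmultinom(w, n, rep(0.25, 4)), 4,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm(cc, id = sprintf("rand_w%d_s%d", w, seed))
}
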