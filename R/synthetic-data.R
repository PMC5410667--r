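#' Simulate a clustered TPM expression matrix with known labels
#'
#' Profiles are generated on the log2 scale (Gaussian cluster centers,
#' per-isoform magnitude offsets, Gaussian noise) and exponentiated to
#' TPM, mimicking the multiplicative noise of RNA-seq abundances.
#' Isoforms in one cluster share a profile shape up to their magnitude
#' offset and noise.
#'
#' @param n_isoforms,n_samples matrix dimensions.
#' @param n_clusters number of planted clusters (assigned cyclically).
#' @param between_cluster_sep scale (log2 units) of cluster-center
#'   separation; centers are drawn N(0, (sep/2)^2) per sample around a
#'   baseline of 5.
#' @param magnitude_spread SD (log2 units) of per-isoform additive
#'   offsets (same shape, different magnitude).
#' @param noise_sd SD (log2 units) of i.i.d. Gaussian noise.
#' @param seed integer RNG seed.
#' @return list with `matrix` (an [expression_matrix], unit TPM) and
#'   `truth` (cluster labels, per-cluster mean profiles, offsets,
#'   noise_sd).
#' @export
make_expression_matrix <- function(n_isoforms = 60, n_samples = 14,
                                   n_clusters = 3, between_cluster_sep = 4,
                                   magnitude_spread = 0.5, noise_sd = 0.25,
                                   seed = 1) {
  if (n_isoforms < 1 || n_samples < 1 || n_clusters < 1)
    stop("dimensions must be positive")
  if (n_isoforms < n_clusters)
    stop("n_isoforms must be >= n_clusters")
  if (noise_sd < 0 || magnitude_spread < 0)
    stop("spreads must be non-negative")
  set.seed(seed)
  ids <- sprintf("iso%03d", seq_len(n_isoforms))
  smp <- sprintf("S%02d", seq_len(n_samples))
  labels <- stats::setNames(rep(seq_len(n_clusters),
                                length.out = n_isoforms), ids)
  centers <- matrix(5 + stats::rnorm(n_clusters * n_samples,
                                     sd = between_cluster_sep / 2),
                    n_clusters, n_samples,
                    dimnames = list(NULL, smp))
  offsets <- stats::setNames(stats::rnorm(n_isoforms,
                                          sd = magnitude_spread), ids)
  log2tpm <- centers[labels, , drop = FALSE] + offsets +
    matrix(stats::rnorm(n_isoforms * n_samples, sd = noise_sd),
           n_isoforms, n_samples)
  v <- 2^log2tpm
  dimnames(v) <- list(ids, smp)
  samples <- data.frame(
    sample = smp,
    genotype = rep(c("landrace", "cultivar"), length.out = n_samples),
    tissue = rep(rep(c("leaf", "inflorescence"), each = 2),
                 length.out = n_samples),
    treatment = rep(c("control", "stress"), length.out = n_samples),
    replicate = seq_len(n_samples),
    stringsAsFactors = FALSE
  )
  list(matrix = expression_matrix(v, samples, unit = "TPM"),
       truth = list(cluster_labels = labels,
                    profile_means = centers,
                    magnitude_offsets = offsets,
                    noise_sd = noise_sd))
}

random_dna <- function(n, base_freqs = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_freqs),
        collapse = "")
}

replace_at <- function(seq, pos, word) {
  substr(seq, pos, pos + nchar(word) - 1L) <- word
  seq
}

#' Simulate a genome with genes and planted promoter motifs
#'
#' Builds contigs of ~`genes_per_contig` genes with intergenic spacers of
#' at least `spacer` nt so that promoter windows never overlap a
#' neighbouring gene. Genes land on both strands. A fraction of a target
#' gene set carries one instance of `planted_motif` (an IUPAC string,
#' instantiated per instance) at a random offset within the upstream part
#' of the promoter window, on a random strand. Background sequence is an
#' order-0 Markov chain (i.i.d. bases at `base_freqs`); higher orders are
#' not supported.
#'
#' Promoter-relative offsets use position 1 = most upstream base of the
#' (-upstream, +downstream) window around the TSS, matching
#' [extract_promoters()].
#'
#' @param n_genes number of genes.
#' @param upstream,downstream promoter window (defaults 1000 / 200 nt).
#' @param planted_motif IUPAC string, or NULL for no planting.
#' @param planting_fraction fraction of `target_genes` receiving one
#'   instance.
#' @param target_genes character gene ids (default: first 15 genes).
#' @param background_order Markov order of the background (only 0).
#' @param base_freqs background base composition (A,C,G,T).
#' @param gene_len gene body length (>= downstream).
#' @param spacer intergenic spacer length (>= 2000 recommended).
#' @param genes_per_contig genes per contig.
#' @param seed integer RNG seed.
#' @param dir if non-NULL, write `genome.fa`, `genes.gff3`, `truth.json`
#'   there and include the paths in the result.
#' @return list with `genome` (named character, one element per contig),
#'   `genes` (data.frame: gene, contig, start, end, strand), and `truth`
#'   (planted_motif, planted_positions, planting_fraction,
#'   background_order).
#' @export
make_promoter_genome <- function(n_genes = 60, upstream = 1000,
                                 downstream = 200, planted_motif = NULL,
                                 planting_fraction = 0.8,
                                 target_genes = NULL,
                                 background_order = 0,
                                 base_freqs = rep(0.25, 4),
                                 gene_len = 600, spacer = 2000,
                                 genes_per_contig = 20, seed = 1,
                                 dir = NULL) {
  stopifnot(n_genes >= 1, upstream >= 1, downstream >= 0,
            gene_len >= downstream,
            planting_fraction >= 0, planting_fraction <= 1)
  if (background_order != 0)
    stop("only an order-0 (i.i.d.) background is supported")
  if (!is.null(planted_motif)) {
    check_iupac(planted_motif)
    if (nchar(planted_motif) > upstream)
      stop("planted motif is longer than the upstream promoter segment")
  }
  set.seed(seed)
  ids <- sprintf("gene%03d", seq_len(n_genes))
  if (is.null(target_genes))
    target_genes <- ids[seq_len(min(15L, n_genes))]
  stopifnot(all(target_genes %in% ids))

  planted <- character(0)
  if (!is.null(planted_motif) && planting_fraction > 0) {
    n_plant <- round(planting_fraction * length(target_genes))
    planted <- sample(target_genes, n_plant)
  }
  wlen <- if (is.null(planted_motif)) 0L else nchar(planted_motif)

  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  contig_of <- rep(seq_len(ceiling(n_genes / genes_per_contig)),
                   each = genes_per_contig)[seq_len(n_genes)]
  contig_names <- sprintf("contig%02d", sort(unique(contig_of)))

  genes <- data.frame(gene = ids, contig = contig_names[contig_of],
                      start = NA_integer_, end = NA_integer_,
                      strand = strands, stringsAsFactors = FALSE)
  planted_positions <- list()
  genome <- stats::setNames(vector("list", length(contig_names)),
                            contig_names)

  for (ci in seq_along(contig_names)) {
    chunks <- character(0)
    cursor <- 0L
    for (gi in which(contig_of == ci)) {
      chunks <- c(chunks, random_dna(spacer, base_freqs))
      cursor <- cursor + spacer
      up <- random_dna(upstream, base_freqs)
      body <- random_dna(gene_len, base_freqs)
      if (ids[gi] %in% planted) {
        off <- sample.int(upstream - wlen + 1L, 1L)
        inst_strand <- sample(c("+", "-"), 1L)
        word <- sample_iupac_instance(planted_motif)
        up <- replace_at(up, off,
                         if (inst_strand == "+") word else revcomp(word))
        planted_positions[[ids[gi]]] <-
          data.frame(offset = off, strand = inst_strand, word = word,
                     stringsAsFactors = FALSE)
      }
      chunk <- paste0(up, body)  # promoter orientation
      if (strands[gi] == "+") {
        genes$start[gi] <- cursor + upstream + 1L
        genes$end[gi] <- cursor + upstream + gene_len
      } else {
        chunk <- revcomp(chunk)
        genes$start[gi] <- cursor + 1L
        genes$end[gi] <- cursor + gene_len
      }
      chunks <- c(chunks, chunk)
      cursor <- cursor + nchar(chunk)
    }
    chunks <- c(chunks, random_dna(spacer, base_freqs))
    genome[[ci]] <- paste(chunks, collapse = "")
  }
  genome <- unlist(genome)

  truth <- list(planted_motif = planted_motif,
                planted_positions = planted_positions,
                planting_fraction = planting_fraction,
                background_order = background_order)
  out <- list(genome = genome, genes = genes, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$genome_fasta <- file.path(dir, "genome.fa")
    out$gff3 <- file.path(dir, "genes.gff3")
    Biostrings::writeXStringSet(Biostrings::BStringSet(genome),
                                out$genome_fasta)
    write_gff3(genes, out$gff3)
    out$truth_json <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, out$truth_json, auto_unbox = TRUE,
                         digits = NA)
  }
  out
}

write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tcoexcis\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     genes$contig, genes$start, genes$end, genes$strand,
                     genes$gene, genes$gene))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a pair of differential-expression tables
#'
#' Emulates DE calls from two independent methods over the same isoforms.
#' Concordant true calls are significant in both tables with the same
#' fold-change sign; a `discordance_rate` fraction of the true set is
#' made irreproducible (opposite sign or non-significant in table B).
#'
#' @param true_de_ids ids of truly DE isoforms.
#' @param n_background number of additional non-DE isoforms.
#' @param fdr_alpha significance threshold used to assign FDR values.
#' @param discordance_rate fraction of true calls broken in table B.
#' @param seed integer RNG seed.
#' @return list with data.frames `a`, `b` (columns id, logFC, fdr,
#'   method) and `truth$concordant_ids`.
#' @export
make_de_tables <- function(true_de_ids, n_background = 50,
                           fdr_alpha = 0.001, discordance_rate = 0,
                           seed = 1) {
  stopifnot(discordance_rate >= 0, discordance_rate <= 1)
  if (length(true_de_ids) == 0 && n_background == 0)
    stop("nothing to simulate: empty true set and no background")
  set.seed(seed)
  nde <- length(true_de_ids)
  bg_ids <- if (n_background > 0)
    sprintf("bg%04d", seq_len(n_background)) else character(0)

  sign_a <- sample(c(-1, 1), nde, replace = TRUE)
  lfc_a <- sign_a * stats::runif(nde, 1, 6)
  n_disc <- round(discordance_rate * nde)
  disc <- if (n_disc > 0) sample(seq_len(nde), n_disc) else integer(0)
  concordant <- setdiff(seq_len(nde), disc)

  # table B reproduces the call with jitter but guaranteed-equal sign
  lfc_b <- sign_a * pmax(0.5, abs(lfc_a + stats::rnorm(nde, sd = 0.2)))
  fdr_b <- stats::runif(nde, 0, fdr_alpha / 2)
  drop_b <- rep(FALSE, nde)
  for (i in disc) {
    if (stats::runif(1) < 0.5) lfc_b[i] <- -lfc_b[i]  # opposite direction
    else drop_b[i] <- TRUE                            # not called by B
  }

  # method-private false positives, disjoint between the two tables
  n_fp <- min(length(bg_ids) %/% 2, round(0.05 * length(bg_ids)))
  fp <- if (n_fp > 0) sample(bg_ids, 2 * n_fp) else character(0)
  fp_a <- fp[seq_len(n_fp)]
  fp_b <- setdiff(fp, fp_a)

  fp_rows <- function(ids, method) {
    data.frame(id = ids,
               logFC = sample(c(-1, 1), length(ids), TRUE) *
                 stats::runif(length(ids), 1, 3),
               fdr = stats::runif(length(ids), 0, fdr_alpha / 2),
               method = method, stringsAsFactors = FALSE)
  }
  a <- rbind(data.frame(id = true_de_ids, logFC = lfc_a,
                        fdr = stats::runif(nde, 0, fdr_alpha / 2),
                        method = "methodA", stringsAsFactors = FALSE),
             fp_rows(fp_a, "methodA"))
  b <- rbind(data.frame(id = true_de_ids[!drop_b],
                        logFC = lfc_b[!drop_b], fdr = fdr_b[!drop_b],
                        method = "methodB", stringsAsFactors = FALSE),
             fp_rows(fp_b, "methodB"))
  list(a = a, b = b,
       truth = list(concordant_ids = sort(true_de_ids[concordant])))
}

#' Simulate a gene-to-term annotation map with one enriched term
#'
#' Every term annotates each gene independently with probability
#' `base_prob`; for `enriched_term` on `target_cluster` genes the
#' annotation odds are multiplied by `enrichment_odds`.
#'
#' @param n_genes universe size (ids gene001...).
#' @param n_terms number of terms (TERM001...).
#' @param enriched_term term id to enrich (must be among the terms).
#' @param target_cluster character gene ids forming the cluster.
#' @param enrichment_odds odds multiplier (>= 1; 1 = null).
#' @param base_prob baseline annotation probability.
#' @param seed integer RNG seed.
#' @return list with `annotations` (data.frame gene, term, description),
#'   `universe` (gene ids) and `truth`.
#' @export
make_annotation_map <- function(n_genes = 60, n_terms = 40,
                                enriched_term = "TERM001",
                                target_cluster = NULL,
                                enrichment_odds = 1, base_prob = 0.3,
                                seed = 1) {
  stopifnot(enrichment_odds >= 1, base_prob > 0, base_prob < 1)
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  terms <- sprintf("TERM%03d", seq_len(n_terms))
  stopifnot(enriched_term %in% terms)
  if (is.null(target_cluster))
    target_cluster <- genes[seq_len(min(15L, n_genes))]
  odds0 <- base_prob / (1 - base_prob)
  odds1 <- odds0 * enrichment_odds
  p1 <- odds1 / (1 + odds1)
  rows <- lapply(terms, function(tm) {
    p <- ifelse(tm == enriched_term & genes %in% target_cluster,
                p1, base_prob)
    hit <- stats::runif(n_genes) < p
    if (!any(hit)) return(NULL)
    data.frame(gene = genes[hit], term = tm,
               description = paste("description of", tm),
               stringsAsFactors = FALSE)
  })
  list(annotations = do.call(rbind, rows), universe = genes,
       truth = list(enriched_term = enriched_term,
                    target_cluster = target_cluster,
                    enrichment_odds = enrichment_odds))
}

#' Simulate an RT-qPCR Ct plate from known expression ratios
#'
#' Reference genes have identical Ct in control and treated samples by
#' construction; target genes have `Ct_treated = Ct_control -
#' log(ratio)/log(E)`, so the efficiency-corrected ratio recovers
#' `true_ratios` exactly when `ct_noise_sd = 0`.
#'
#' @param true_ratios named numeric vector of treated/control expression
#'   ratios for target genes (> 0).
#' @param efficiencies named amplification efficiencies in (1, 2] for all
#'   genes; genes not named get 2.
#' @param n_ref_genes number of reference genes (>= 3; named REF1...).
#' @param ct_noise_sd SD of Gaussian noise added to each well.
#' @param n_replicates technical replicates per condition.
#' @param seed integer RNG seed.
#' @return list with `plate` (data.frame gene, condition, replicate, Ct),
#'   `efficiencies` (full named vector) and `truth`.
#' @export
make_qpcr_plate <- function(true_ratios, efficiencies = NULL,
                            n_ref_genes = 3, ct_noise_sd = 0,
                            n_replicates = 3, seed = 1) {
  if (any(true_ratios <= 0)) stop("expression ratios must be positive")
  stopifnot(n_ref_genes >= 3, ct_noise_sd >= 0)
  set.seed(seed)
  refs <- sprintf("REF%d", seq_len(n_ref_genes))
  genes <- c(names(true_ratios), refs)
  eff <- stats::setNames(rep(2, length(genes)), genes)
  if (!is.null(efficiencies)) {
    if (any(efficiencies <= 1 | efficiencies > 2))
      stop("efficiencies must lie in (1, 2]")
    eff[names(efficiencies)] <- efficiencies
  }
  ratios <- c(true_ratios, stats::setNames(rep(1, n_ref_genes), refs))
  base_ct <- stats::setNames(stats::runif(length(genes), 18, 26), genes)
  rows <- lapply(genes, function(g) {
    dct <- log(ratios[[g]]) / log(eff[[g]])   # Ct_control - Ct_treated
    data.frame(
      gene = g,
      condition = rep(c("control", "treated"), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2),
      Ct = c(base_ct[[g]] + stats::rnorm(n_replicates, sd = ct_noise_sd),
             base_ct[[g]] - dct +
               stats::rnorm(n_replicates, sd = ct_noise_sd)),
      stringsAsFactors = FALSE)
  })
  list(plate = do.call(rbind, rows), efficiencies = eff,
       truth = list(true_ratios = true_ratios, reference_genes = refs,
                    ct_noise_sd = ct_noise_sd))
}
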