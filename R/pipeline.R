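#' Pipeline configuration with field-standard defaults
#'
#' Collects every tunable of the analysis. Defaults encode the anchored
#' values of the protocol: CPM filter 0.4 in at least half of the
#' samples; dendrogram pruned when 95% of clusters fall below 0.001% of
#' the initial average distance; clusters of 10 or more genes analysed;
#' promoters -1000/+200 around the TSS; word lengths 6-8; 50 random
#' negative-control clusters at the 0.95 quantile; 100 matrix
#' permutations; Fisher enrichment at p < 0.01; three reference genes;
#' dilution-series r-squared of at least 0.99.
#'
#' @param ... overrides for any default listed below.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_cpm = 0.4, min_fraction = 0.5,
    distance_alpha = 0.5, log_transform = TRUE,
    prune_fraction = 0.95, prune_rel_threshold = 1e-5,
    min_cluster_size = 10,
    upstream = 1000, downstream = 200,
    k_values = 6:8, sig_threshold = 0,
    dyad_monad_len = 3, dyad_spacings = 0:20,
    n_random = 50, negative_quantile = 0.95,
    n_perm = 100,
    enrichment_alpha = 0.01,
    n_reference_genes = 3, r2_threshold = 0.99,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the co-expression / cis-regulatory pipeline
#'
#' Stages: intersect the two DE tables (concordant direction), cluster
#' the DE isoforms' TPM profiles with the hybrid distance, prune the
#' dendrogram, map isoforms to genes, extract promoters for clusters of
#' at least `min_cluster_size` genes, discover over-represented oligos
#' and dyads against the whole-universe background, build a matrix per
#' cluster, validate it against negative controls and column-permuted
#' matrices, annotate it against a motif library by Ncor, and test the
#' cluster for term enrichment. Per-stage tables and a JSON summary per
#' cluster are written to `out_dir`.
#'
#' @param tpm [expression_matrix] of isoform TPM profiles.
#' @param de_table_a,de_table_b thresholded DE tables (id, logFC, fdr).
#' @param genome named contig sequences or FASTA path.
#' @param annotation gene table or GFF3 path (see [extract_promoters()]).
#' @param isoform_gene_map data.frame (isoform, gene) or TSV path.
#' @param annotations gene-term table for [fisher_enrichment()], or NULL.
#' @param motif_library list of `pfm` / TRANSFAC path, or NULL.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return list: de_ids, cluster_set, eligible clusters and per-cluster
#'   reports (invisibly also written to `out_dir`).
#' @export
run_pipeline <- function(tpm, de_table_a, de_table_b, genome, annotation,
                         isoform_gene_map, annotations = NULL,
                         motif_library = NULL,
                         config = pipeline_config(),
                         out_dir = tempfile("coexcis_run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  logf("coexcis %s | seed %d", as.character(utils::packageVersion("coexcis")),
       config$seed)

  de_ids <- intersect_de_tags(de_table_a, de_table_b)
  logf("DE intersection: %d isoforms", length(de_ids))
  writeLines(de_ids, file.path(out_dir, "de_ids.txt"))
  de_ids <- intersect(de_ids, rownames(tpm$values))

  sub <- expression_matrix(tpm$values[de_ids, , drop = FALSE],
                           tpm$samples, unit = tpm$unit)
  dm <- pairwise_distance(sub, alpha = config$distance_alpha,
                          log_transform = config$log_transform)
  dend <- build_dendrogram(dm)
  write_dendrogram_newick(dend, file.path(out_dir, "dendrogram.nwk"))
  cs <- prune_to_clusters(dend, dm, fraction = config$prune_fraction,
                          rel_threshold = config$prune_rel_threshold)
  write_cluster_tsv(cs, file.path(out_dir, "clusters.tsv"))
  logf("clusters: %d", length(cs$clusters))

  if (is.character(isoform_gene_map))
    isoform_gene_map <- read_tsv_file(isoform_gene_map)
  eligible <- clusters_for_motif_search(cs, isoform_gene_map,
                                        min_size = config$min_cluster_size)
  logf("clusters with >= %d genes: %d", config$min_cluster_size,
       length(eligible))

  promoters <- extract_promoters(genome, annotation,
                                 upstream = config$upstream,
                                 downstream = config$downstream)
  universe <- promoter_sequences(promoters)
  bg <- word_background(universe, config$k_values)
  dbg <- dyad_background(universe, config$dyad_monad_len,
                         config$dyad_spacings)
  if (is.character(motif_library) && length(motif_library) == 1L)
    motif_library <- read_transfac(motif_library)

  reports <- list()
  for (cl in eligible) {
    genes <- map_isoforms_to_genes(isoform_gene_map, cs$clusters[[cl]])
    genes <- intersect(genes, names(universe))
    if (length(genes) < config$min_cluster_size) next
    cl_seqs <- universe[genes]
    oligos <- oligo_analysis(cl_seqs, bg, k_values = config$k_values,
                             sig_threshold = config$sig_threshold)
    dyads <- dyad_analysis(cl_seqs, dbg,
                           monad_len = config$dyad_monad_len,
                           spacings = config$dyad_spacings,
                           sig_threshold = config$sig_threshold)
    write_tsv_file(oligos, file.path(out_dir,
                                     sprintf("cluster%s_oligos.tsv", cl)))
    write_tsv_file(dyads, file.path(out_dir,
                                    sprintf("cluster%s_dyads.tsv", cl)))
    rep <- list(cluster = cl, n_genes = length(genes),
                profile_mean_log2tpm =
                  unname(colMeans(log2(sub$values[cs$clusters[[cl]], ,
                                                  drop = FALSE] + 1))),
                top_oligos = utils::head(oligos, 5),
                top_dyads = utils::head(dyads, 5))
    if (nrow(oligos) > 0) {
      mot <- build_pfm(oligos, cl_seqs,
                       id = sprintf("cluster%s_motif", cl))
      write_transfac(mot, file.path(out_dir,
                                    sprintf("cluster%s_motif.tf", cl)))
      write_meme(mot, file.path(out_dir,
                                sprintf("cluster%s_motif.meme", cl)))
      neg <- negative_control_support(genes, universe,
                                      n_random = config$n_random,
                                      quantile = config$negative_quantile,
                                      seed = config$seed,
                                      k_values = config$k_values)
      perm <- permutation_support(mot, cl_seqs, n_perm = config$n_perm,
                                  seed = config$seed)
      rep$consensus <- mot$consensus
      rep$n_sites <- length(mot$sites)
      rep$negative_control <- list(real_sig = neg$real_sig,
                                   threshold = neg$threshold,
                                   supported = neg$supported)
      rep$permutation_support <- as.numeric(perm)
      if (!is.null(motif_library) && length(motif_library)) {
        ann <- annotate_motif(mot, motif_library)
        rep$best_library_match <- as.list(ann[1, ])
      }
    }
    if (!is.null(annotations)) {
      enr <- fisher_enrichment(genes, names(universe), annotations,
                               alpha = config$enrichment_alpha)
      write_tsv_file(enr, file.path(out_dir,
                                    sprintf("cluster%s_enrichment.tsv",
                                            cl)))
      rep$enriched_terms <- enr$term[enr$enriched]
    }
    reports[[cl]] <- rep
    logf("cluster %s: %d genes, consensus %s", cl, length(genes),
         if (is.null(rep$consensus)) "-" else rep$consensus)
  }
  jsonlite::write_json(reports, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(de_ids = de_ids, distance = dm, dendrogram = dend,
                 cluster_set = cs, eligible = eligible,
                 promoters = promoters, reports = reports,
                 out_dir = out_dir))
}

#' Demonstration run on synthetic data
#'
#' Generates a fully synthetic study (clustered TPM matrix, genome with
#' a planted promoter motif in one cluster, concordant DE tables,
#' annotation map with one enriched term, qPCR plate), runs
#' [run_pipeline()] on it, and quantifies the qPCR ratios. All
#' randomness derives from `seed`.
#'
#' @param seed integer RNG seed.
#' @param out_dir output directory.
#' @param config a [pipeline_config()]; sizes of the synthetic study are
#'   fixed (3 co-expression clusters of 20 isoforms; a 200-gene promoter
#'   universe; 1:1 isoform-gene map; a motif planted upstream of
#'   cluster-1 genes).
#' @return the [run_pipeline()] result, plus `truth` and `qpcr`.
#' @export
demo_pipeline <- function(seed = 1, out_dir = tempfile("coexcis_demo"),
                          config = pipeline_config(seed = seed)) {
  n_iso <- 60L
  n_genes <- 200L
  expr <- make_expression_matrix(n_isoforms = n_iso, n_samples = 14,
                                 n_clusters = 3,
                                 between_cluster_sep = 4,
                                 magnitude_spread = 0,
                                 noise_sd = 1e-6, seed = seed)
  ids <- rownames(expr$matrix$values)
  mapping <- data.frame(isoform = ids,
                        gene = sprintf("gene%03d", seq_along(ids)),
                        stringsAsFactors = FALSE)
  target <- mapping$gene[expr$truth$cluster_labels == 1]
  gen <- make_promoter_genome(n_genes = n_genes,
                              planted_motif = "TTGACCGA",
                              planting_fraction = 0.8,
                              target_genes = target, seed = seed)
  de <- make_de_tables(ids, n_background = 40, seed = seed)
  ann <- make_annotation_map(n_genes = n_genes,
                             enriched_term = "TERM001",
                             target_cluster = target,
                             enrichment_odds = 20, seed = seed)
  lib <- synthetic_motif_library(seed = seed)
  res <- run_pipeline(expr$matrix, de$a, de$b, gen$genome, gen$genes,
                      mapping, annotations = ann$annotations,
                      motif_library = lib, config = config,
                      out_dir = out_dir)
  plate <- make_qpcr_plate(c(target1 = 4), ct_noise_sd = 0, seed = seed)
  res$qpcr <- pfaffl_from_plate(plate$plate, "target1",
                                plate$truth$reference_genes,
                                plate$efficiencies)
  res$truth <- list(expression = expr$truth, promoters = gen$truth,
                    de = de$truth, annotation = ann$truth,
                    qpcr = plate$truth)
  res
}

#' Small synthetic motif library for annotation demonstrations
#'
#' Random count matrices plus a few fixed consensus-derived motifs;
#' synthetic stand-ins, not curated plant motifs.
#'
#' @param n_random number of random 8-column motifs.
#' @param seed integer RNG seed.
#' @return named list of `pfm`.
#' @export
synthetic_motif_library <- function(n_random = 10, seed = 1) {
  set.seed(seed)
  consensus_pfm <- function(cons, id, weight = 10) {
    check_iupac(cons)
    ch <- toupper(strsplit(cons, "", fixed = TRUE)[[1]])
    mat <- vapply(ch, function(b) {
      col <- stats::setNames(rep(0, 4), DNA_BASES)
      col[IUPAC_SETS[[b]]] <- weight / length(IUPAC_SETS[[b]])
      col
    }, numeric(4))
    pfm(mat, id = id)
  }
  fixed <- list(
    synthWRKY = consensus_pfm("TTGACY", "synthWRKY"),
    synthABRE = consensus_pfm("ACGTGKC", "synthABRE"),
    synthMYB = consensus_pfm("WAACCA", "synthMYB")
  )
  rand <- lapply(seq_len(n_random), function(i) {
    counts <- matrix(stats::rmultinom(8, 10, rep(0.25, 4)), nrow = 4,
                     dimnames = list(DNA_BASES, NULL))
    pfm(counts, id = sprintf("synthRandom%02d", i))
  })
  names(rand) <- vapply(rand, `[[`, character(1), "id")
  c(fixed, rand)
}
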