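test_that("generators are deterministic under a fixed seed", {
  a <- make_expression_matrix(seed = 5)
  b <- make_expression_matrix(seed = 5)
  expect_identical(a$matrix$values, b$matrix$values)
  g1 <- make_promoter_genome(n_genes = 10, planted_motif = "ACGTACGT",
                             target_genes = sprintf("gene%03d", 1:5),
                             seed = 5)
  g2 <- make_promoter_genome(n_genes = 10, planted_motif = "ACGTACGT",
                             target_genes = sprintf("gene%03d", 1:5),
                             seed = 5)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth, g2$truth)
  p1 <- make_qpcr_plate(c(g = 2), seed = 5)
  p2 <- make_qpcr_plate(c(g = 2), seed = 5)
  expect_identical(p1$plate, p2$plate)
})

test_that("noise-free equal-magnitude expression gives exactly zero within-cluster distance", {
  ex <- make_expression_matrix(n_isoforms = 9, n_samples = 6,
                               n_clusters = 3, magnitude_spread = 0,
                               noise_sd = 0, seed = 4)
  dm <- pairwise_distance(ex$matrix)
  labs <- ex$truth$cluster_labels
  for (cl in unique(labs)) {
    ids <- names(labs)[labs == cl]
    expect_equal(max(dm$d[ids, ids]), 0)
  }
  expect_true(all(ex$matrix$values > 0))
  expect_error(make_expression_matrix(n_isoforms = 0), "positive")
  expect_error(make_expression_matrix(n_isoforms = 2, n_clusters = 5),
               ">= n_clusters")
})

test_that("synthetic genomes place genes on both strands and round-trip planted instances", {
  fix <- planted_universe()
  gen <- fix$gen; ps <- fix$ps
  expect_setequal(unique(gen$genes$strand), c("+", "-"))
  truth <- gen$truth$planted_positions
  expect_length(truth, round(0.8 * 15))
  for (g in names(truth)) {
    pp <- truth[[g]]
    got <- substr(ps$sequences[[g]], pp$offset, pp$offset + 7)
    want <- if (pp$strand == "+") pp$word else revcomp(pp$word)
    expect_equal(got, want)
  }
  # minus-strand promoter equals the reverse complement of its window
  minus <- gen$genes[gen$genes$strand == "-", ][1, ]
  win <- substr(gen$genome[[minus$contig]],
                minus$end - 200 + 1, minus$end + 1000)
  expect_equal(ps$sequences[[minus$gene]], revcomp(win))
  # full promoter window length, never clipped in these layouts
  expect_true(all(nchar(ps$sequences) == 1200))
  expect_error(make_promoter_genome(n_genes = 2, upstream = 6,
                                    planted_motif = "ACGTACGTA"),
               "longer than")
})

test_that("unplanted genomes contain the motif only at chance rates", {
  gen <- make_promoter_genome(n_genes = 30, planted_motif = "TTGACCGA",
                              planting_fraction = 0, seed = 13)
  expect_length(gen$truth$planted_positions, 0)
  ps <- extract_promoters(gen$genome, gen$genes)
  hits <- sum(vapply(ps$sequences, function(s)
    length(gregexpr("TTGACCGA", s, fixed = TRUE)[[1]]) *
      (gregexpr("TTGACCGA", s, fixed = TRUE)[[1]][1] != -1),
    numeric(1)))
  # ~36000 windows at p = 4^-8 per strand: expect ~1, allow slack
  expect_lte(hits, 4)
})

test_that("generated files parse back through the standard readers", {
  dir <- withr::local_tempdir()
  gen <- make_promoter_genome(n_genes = 8, planted_motif = "ACGTTGCA",
                              target_genes = sprintf("gene%03d", 1:4),
                              seed = 3, dir = dir)
  ps_mem <- extract_promoters(gen$genome, gen$genes)
  ps_file <- extract_promoters(gen$genome_fasta, gen$gff3)
  expect_equal(ps_file$sequences, ps_mem$sequences)
  expect_equal(ps_file$info, ps_mem$info)
  truth <- jsonlite::read_json(gen$truth_json)
  expect_equal(truth$planted_motif, "ACGTTGCA")
})

test_that("DE table generator bookkeeping matches the intersection", {
  ids <- sprintf("de%02d", 1:20)
  de0 <- make_de_tables(ids, n_background = 40, discordance_rate = 0,
                        seed = 8)
  expect_equal(intersect_de_tags(de0$a, de0$b), sort(ids))
  de1 <- make_de_tables(ids, n_background = 40, discordance_rate = 1,
                        seed = 8)
  expect_length(intersect_de_tags(de1$a, de1$b), 0)
  demid <- make_de_tables(ids, n_background = 40, discordance_rate = 0.4,
                          seed = 8)
  expect_equal(intersect_de_tags(demid$a, demid$b),
               demid$truth$concordant_ids)
  expect_length(demid$truth$concordant_ids, 12)
  expect_error(make_de_tables(character(0), n_background = 0),
               "nothing to simulate")
})

test_that("annotation generator plants an enriched term", {
  target <- sprintf("gene%03d", 1:15)
  ann <- make_annotation_map(n_genes = 60, enriched_term = "TERM001",
                             target_cluster = target,
                             enrichment_odds = 30, seed = 6)
  res <- fisher_enrichment(target, ann$universe, ann$annotations)
  expect_equal(res$term[1], "TERM001")  # smallest p
  expect_true(res$enriched[1])
})

test_that("qPCR plates encode the planted ratios exactly when noiseless", {
  pl <- make_qpcr_plate(c(up = 4, dn = 0.25), ct_noise_sd = 0, seed = 10)
  for (g in c("up", "dn")) {
    r <- pfaffl_from_plate(pl$plate, g, pl$truth$reference_genes,
                           pl$efficiencies)
    expect_equal(r$ratio, unname(pl$truth$true_ratios[g]),
                 tolerance = 1e-9)
  }
  # reference genes have identical Ct in both conditions
  refs <- pl$plate[pl$plate$gene %in% pl$truth$reference_genes, ]
  dct <- tapply(refs$Ct, list(refs$gene, refs$condition), mean)
  expect_equal(unname(dct[, "control"]), unname(dct[, "treated"]))
  expect_error(make_qpcr_plate(c(bad = -1)), "positive")
  expect_error(make_qpcr_plate(c(g = 2), efficiencies = c(g = 2.5)),
               "efficiencies")
})

test_that("noisy qPCR plates recover the true log2 ratio on average", {
  errs <- vapply(1:100, function(s) {
    pl <- make_qpcr_plate(c(g = 4), ct_noise_sd = 0.2, seed = s)
    r <- pfaffl_from_plate(pl$plate, "g", pl$truth$reference_genes,
                           pl$efficiencies)
    r$log2_ratio - 2
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.2)
})
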