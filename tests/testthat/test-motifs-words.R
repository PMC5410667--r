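test_that("word counting merges strands and suppresses overlapping occurrences", {
  # single window, key merged with its reverse complement
  cnt <- count_words(c(s = "AAAAAA"), k = 6)
  expect_equal(as.vector(cnt["AAAAAA"]), 1L)
  expect_equal(attr(cnt, "windows"), 1L)
  # 7 nt: two windows of the same word, only one counted
  cnt2 <- count_words(c(s = "AAAAAAA"), k = 6)
  expect_equal(as.vector(cnt2["AAAAAA"]), 1L)
  cnt2o <- count_words(c(s = "AAAAAAA"), k = 6, no_overlap = FALSE)
  expect_equal(as.vector(cnt2o["AAAAAA"]), 2L)
  # non-overlapping repeats both count
  cnt3 <- count_words(c(s = "AAAAAACAAAAAA"), k = 6)
  expect_equal(as.vector(cnt3["AAAAAA"]), 2L)
  # reverse-complement merging: TTTTTT counts under AAAAAA
  cnt4 <- count_words(c(s = "TTTTTT"), k = 6)
  expect_equal(names(cnt4), "AAAAAA")
  # a sequence and its reverse complement give identical tables
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  expect_equal(count_words(c(a = s), 6), count_words(c(a = revcomp(s)), 6),
               ignore_attr = TRUE)
  expect_length(count_words(character(0), 6), 0)
  expect_length(count_words(c(s = "ACG"), 6), 0)
})

test_that("masked and ambiguous windows neither count nor add trials", {
  cnt <- count_words(c(s = "AAAAAAcgAAAAAA"), k = 6)
  expect_equal(as.vector(cnt["AAAAAA"]), 2L)
  expect_equal(attr(cnt, "windows"), 2L)  # only the two clean windows
  cntN <- count_words(c(s = "AAANAAA"), k = 6)
  expect_length(cntN, 0)
})

test_that("binomial word significance equals a direct tail summation", {
  # spec anchor: P[Bin(10, 0.5) >= 8]
  ws <- word_significance(8, 10, 0.5, n_tested = 1)
  expect_equal(ws$p_value, 0.0546875)
  # enumeration oracle over a parameter grid
  for (n in c(5, 12, 20)) for (p in c(0.05, 0.3, 0.7)) for (x in 0:n) {
    oracle <- sum(choose(n, x:n) * p^(x:n) * (1 - p)^(n - (x:n)))
    expect_equal(word_significance(x, n, p)$p_value, oracle,
                 tolerance = 1e-12)
  }
  # observed 0: p = 1, sig = -log10(n_tested)
  w0 <- word_significance(0, 10, 0.2, n_tested = 50)
  expect_equal(w0$p_value, 1)
  expect_equal(w0$e_value, 50)
  expect_equal(w0$sig, -log10(50))
  # doubling n_tested lowers sig by log10(2)
  s1 <- word_significance(8, 10, 0.5, 10)$sig
  s2 <- word_significance(8, 10, 0.5, 20)$sig
  expect_equal(s1 - s2, log10(2))
  # degenerate prior
  wd <- word_significance(3, 10, 0, 5)
  expect_true(wd$degenerate)
  expect_equal(wd$p_value, 0)
  expect_equal(wd$sig, Inf)
})

test_that("a planted 8-mer is the top oligo-analysis word", {
  fix <- planted_universe()
  res <- oligo_analysis(fix$ps$sequences[fix$cluster], fix$bg)
  expect_gt(nrow(res), 0)
  expect_true(res$word[1] %in% c("TTGACCGA", revcomp("TTGACCGA")))
  expect_true(all(diff(res$sig) <= 0))  # sorted by sig
  expect_error(oligo_analysis(character(0), fix$bg), "empty cluster")
})

test_that("a planted dyad is recovered with the correct spacer", {
  gen <- make_promoter_genome(n_genes = 150,
                              planted_motif = "AAANNNNNTCT",
                              planting_fraction = 1,
                              target_genes = sprintf("gene%03d", 1:30),
                              seed = 21)
  ps <- extract_promoters(gen$genome, gen$genes)
  cl <- ps$sequences[sprintf("gene%03d", 1:30)]
  res <- dyad_analysis(cl, promoter_sequences(ps))
  expect_gt(nrow(res), 0)
  expect_equal(res$dyad[1], "AAA.5.TCT")
  expect_equal(res$spacing[1], 5L)
  expect_error(dyad_analysis(character(0), ps), "empty cluster")
})

test_that("a zero-spacing dyad agrees with hexamer counting", {
  set.seed(9)
  seqs <- setNames(vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
    character(1)), paste0("s", 1:10))
  dy <- count_dyads(seqs, monad_len = 3, spacings = 0)
  words <- count_words(seqs, 6)
  for (key in sample(names(dy), 25)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    hex <- paste0(parts[1], parts[3])
    hex <- min(hex, revcomp(hex))
    expect_equal(as.vector(dy[key]), as.vector(words[hex]))
  }
  expect_equal(unname(attr(dy, "windows")["0"]),
               as.numeric(attr(words, "windows")))
})

test_that("E-values are calibrated on background-only clusters", {
  fix <- null_universe()
  set.seed(77)
  counts <- vapply(1:20, function(i) {
    cl <- sample(names(fix$ps$sequences), 15)
    nrow(oligo_analysis(fix$ps$sequences[cl], fix$bg, sig_threshold = 0))
  }, numeric(1))
  expect_lte(mean(counts), 1)
})
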