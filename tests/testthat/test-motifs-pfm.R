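test_that("PFMs from identical sites are one-hot and consensus follows IUPAC rules", {
  # four identical ACGT sites, no pseudocount: one-hot columns
  m <- pfm(matrix(c(4, 0, 0, 0, 0, 4, 0, 0, 0, 0, 4, 0, 0, 0, 0, 4), 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL)),
           pseudocount = 0)
  expect_equal(unname(pfm_freq(m)[cbind(1:4, 1:4)]), rep(1, 4))
  expect_equal(m$consensus, "ACGT")
  # sites {AAAT, AAAA} equally frequent: consensus AAAw (W = A/T, weak)
  m2 <- pfm(matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 1, 0, 0, 1), 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL)),
            pseudocount = 1)
  expect_equal(m2$consensus, "AAAw")
  # published-style consensi parse as valid IUPAC
  for (cons in c("AAAATATCTy", "aAAAkaTCTw", "yaCGTACGtr", "smACACTbm",
                 "wtATAAAAGw"))
    expect_true(check_iupac(cons))
  expect_error(check_iupac("ACGU"), "IUPAC")
  # unequal column sums are rejected
  bad <- matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0), 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(pfm(bad), "column sums")
})

test_that("PFM assembly collects planted sites from cluster promoters", {
  fix <- planted_universe()
  cl <- fix$ps$sequences[fix$cluster]
  res <- oligo_analysis(cl, fix$bg)
  mot <- build_pfm(res, cl, id = "planted")
  expect_equal(ncol(mot$counts), 8)
  expect_gte(length(mot$sites), 10)
  # consensus spells the planted word (merged orientation)
  expect_true(toupper(mot$consensus) %in%
                c("TTGACCGA", revcomp("TTGACCGA")))
  expect_error(build_pfm("ACGTACGT", cl[0]), "no sites")
})

test_that("matrix scan matches the closed form and a hand oracle", {
  oh <- one_hot_pfm("ACGT")
  hits <- matrix_scan(oh, c(s = "ACGT"))
  # one-hot width-4 PFM on uniform background: 4 * log2(4) = 8 bits
  expect_equal(hits$score[1], 8)
  # hand oracle on every offset of a toy sequence
  m <- random_pfm(w = 4, seed = 11)
  seq <- "ACGTAC"
  got <- matrix_scan(m, c(s = seq), score_threshold = -Inf)
  f <- pfm_freq(m)
  ch <- strsplit(seq, "")[[1]]
  for (o in 1:3) {
    fwd <- sum(log2(f[cbind(match(ch[o:(o + 3)], rownames(f)), 1:4)] / 0.25))
    rcw <- strsplit(revcomp(substr(seq, o, o + 3)), "")[[1]]
    rev <- sum(log2(f[cbind(match(rcw, rownames(f)), 1:4)] / 0.25))
    expect_equal(got$score[got$offset == o & got$strand == "+"], fwd)
    expect_equal(got$score[got$offset == o & got$strand == "-"], rev)
  }
  # strand symmetry: reverse-complemented sequence scores the same
  best_f <- max(matrix_scan(m, c(s = seq), score_threshold = -Inf)$score)
  best_r <- max(matrix_scan(m, c(s = revcomp(seq)),
                            score_threshold = -Inf)$score)
  expect_equal(best_f, best_r)
  # too-short sequences give no hits, masked windows are skipped
  expect_equal(nrow(matrix_scan(m, c(s = "ACG"))), 0)
  expect_equal(nrow(matrix_scan(oh, c(s = "acgtACGT"),
                                score_threshold = -Inf)), 2)
})

test_that("half-matrix scores add up to the full-matrix score", {
  m <- random_pfm(w = 8, seed = 4)
  left <- pfm(m$counts[, 1:4], m$pseudocount, id = "L")
  right <- pfm(m$counts[, 5:8], m$pseudocount, id = "R")
  seq <- c(s = "TTGACCGATT")
  full <- matrix_scan(m, seq, score_threshold = -Inf)
  l <- matrix_scan(left, seq, score_threshold = -Inf)
  r <- matrix_scan(right, seq, score_threshold = -Inf)
  for (o in 1:3) {
    expect_equal(full$score[full$offset == o & full$strand == "+"],
                 l$score[l$offset == o & l$strand == "+"] +
                   r$score[r$offset == o + 4 & r$strand == "+"])
  }
})

test_that("TRANSFAC and MEME writers produce parseable motifs", {
  dir <- withr::local_tempdir()
  m1 <- random_pfm(w = 8, seed = 1)
  m2 <- random_pfm(w = 6, seed = 2)
  tf <- file.path(dir, "lib.tf")
  write_transfac(list(m1, m2), tf)
  back <- read_transfac(tf)
  expect_length(back, 2)
  expect_equal(back[[m1$id]]$counts, m1$counts, ignore_attr = TRUE)
  expect_equal(back[[m2$id]]$counts, m2$counts, ignore_attr = TRUE)
  # corrupt middle entry is skipped with a warning
  lines <- readLines(tf)
  lines[7] <- "01  not  a  number  row"
  writeLines(lines, tf)
  expect_warning(part <- read_transfac(tf), "unparseable")
  expect_length(part, 1)
  meme <- file.path(dir, "lib.meme")
  write_meme(m1, meme)
  txt <- readLines(meme)
  expect_true(any(grepl("^MOTIF", txt)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 8",
                        txt)))
})
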