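test_that("hybrid distance matches a brute-force reimplementation", {
  set.seed(7)
  v <- matrix(2^runif(24, 0, 10), 4, 6,
              dimnames = list(paste0("i", 1:4), paste0("s", 1:6)))
  m <- toy_expression(v)
  alpha <- 0.3
  dm <- pairwise_distance(m, alpha = alpha)
  # independent oracle: per-pair loops on log2(x+1) profiles
  x <- log2(v + 1)
  emax <- 0
  for (i in 1:3) for (j in (i + 1):4)
    emax <- max(emax, sqrt(sum((x[i, ] - x[j, ])^2)))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    e <- sqrt(sum((x[i, ] - x[j, ])^2))
    r <- cor(x[i, ], x[j, ])
    expect_equal(dm$d[i, j],
                 (1 - alpha) * (1 - r) / 2 + alpha * e / emax,
                 tolerance = 1e-12)
  }
  expect_true(all(dm$d >= 0 & dm$d <= 1))
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 4))
})

test_that("identical profiles are at distance zero; shifted shapes keep only the Euclidean term", {
  x <- c(1, 5, 2, 8, 3, 4)
  v <- rbind(a = x, b = x, c = x + 2, d = c(9, 1, 7, 2, 8, 1))
  m <- toy_expression(v)
  dm <- pairwise_distance(m, alpha = 0.5, log_transform = FALSE)
  expect_equal(dm$d["a", "b"], 0)
  # same shape, shifted magnitude: correlation term exactly 0
  emax <- max(as.matrix(dist(v)))
  expect_equal(dm$d["a", "c"],
               0.5 * sqrt(sum((x - (x + 2))^2)) / emax)
  expect_gt(dm$d["a", "c"], 0)
})

test_that("zero-variance profiles get the maximal correlation term with a warning", {
  v <- rbind(flat = rep(4, 5), up = c(1, 2, 3, 4, 5), dn = c(5, 4, 3, 2, 1))
  m <- toy_expression(v)
  expect_warning(dm <- pairwise_distance(m, alpha = 0, log_transform = FALSE),
                 "zero-variance")
  expect_equal(dm$d["flat", "up"], 1)  # (1 - r)/2 forced to its maximum
})

test_that("complete linkage merges in the hand-traced order", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.9
  d["B", "C"] <- d["C", "B"] <- 0.8
  dm <- structure(list(ids = c("A", "B", "C"), d = d),
                  class = "distance_matrix")
  hc <- build_dendrogram(dm)
  expect_equal(hc$height, c(0.1, 0.9))  # (A,B) first, then +C at max dist
  # two leaves: single merge at their distance
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  hc2 <- build_dendrogram(structure(list(ids = c("x", "y"), d = d2),
                                    class = "distance_matrix"))
  expect_equal(hc2$height, 0.3)
  # heights are non-decreasing on random matrices
  set.seed(5)
  for (rep in 1:3) {
    n <- 8
    dd <- as.matrix(dist(matrix(runif(n * 3), n)))
    dimnames(dd) <- list(paste0("p", 1:n), paste0("p", 1:n))
    hcr <- build_dendrogram(structure(list(ids = rownames(dd), d = dd),
                                      class = "distance_matrix"))
    expect_true(all(diff(hcr$height) >= 0))
  }
})

test_that("pruning returns one cluster for identical items and splits tight blocks", {
  ids <- paste0("i", 1:6)
  zero <- matrix(0, 6, 6, dimnames = list(ids, ids))
  dmz <- structure(list(ids = ids, d = zero), class = "distance_matrix")
  csz <- prune_to_clusters(build_dendrogram(dmz), dmz)
  expect_length(csz$clusters, 1)
  # two tight blocks: within < 1e-5 * D0, between large
  d <- matrix(1, 6, 6, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 1e-7
  d[4:6, 4:6] <- 1e-7
  diag(d) <- 0
  dm2 <- structure(list(ids = ids, d = d), class = "distance_matrix")
  cs2 <- prune_to_clusters(build_dendrogram(dm2), dm2)
  expect_length(cs2$clusters, 2)
  expect_setequal(cs2$clusters[[1]], ids[1:3])
  # output is always a partition
  expect_setequal(unlist(cs2$clusters), ids)
  expect_equal(unname(cs2$internal_distance), rep(1e-7, 2))
})

test_that("planted clusters are recovered and the labels agree with an external ARI", {
  ex <- make_expression_matrix(n_isoforms = 30, n_samples = 10,
                               n_clusters = 3, between_cluster_sep = 4,
                               magnitude_spread = 0, noise_sd = 1e-6,
                               seed = 9)
  dm <- pairwise_distance(ex$matrix)
  cs <- prune_to_clusters(build_dendrogram(dm), dm)
  truth <- ex$truth$cluster_labels
  got <- cs$membership[names(truth)]
  expect_gte(adjusted_rand_index(got, truth), 0.9)
  expect_equal(adjusted_rand_index(got, truth),
               mclust::adjustedRandIndex(got, truth))
})

test_that("cluster size eligibility is counted at the gene level", {
  memb <- setNames(rep(1:2, c(12, 9)), sprintf("iso%02d", 1:21))
  ids <- names(memb)
  d <- matrix(0.5, 21, 21, dimnames = list(ids, ids)); diag(d) <- 0
  dm <- structure(list(ids = ids, d = d), class = "distance_matrix")
  cs <- structure(list(membership = memb,
                       clusters = split(names(memb), memb),
                       internal_distance = c(`1` = 0, `2` = 0)),
                  class = "cluster_set")
  expect_equal(clusters_for_motif_search(cs, min_size = 10), "1")
  expect_equal(clusters_for_motif_search(cs, min_size = 9), c("1", "2"))
  # 12 isoforms collapsing to 8 genes: excluded at min_size 10
  mapping <- data.frame(isoform = ids,
                        gene = c(sprintf("g%d", rep(1:8, length.out = 12)),
                                 sprintf("h%d", 1:9)))
  expect_equal(clusters_for_motif_search(cs, mapping, min_size = 10),
               character(0))
  empty <- structure(list(membership = integer(0), clusters = list(),
                          internal_distance = numeric(0)),
                     class = "cluster_set")
  expect_length(clusters_for_motif_search(empty), 0)
})

test_that("dendrograms export to newick", {
  ex <- make_expression_matrix(12, 6, 2, seed = 2)
  dm <- pairwise_distance(ex$matrix)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(build_dendrogram(dm), path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(ex$matrix$values))
})
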