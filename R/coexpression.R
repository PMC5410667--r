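#' Hybrid Pearson/Euclidean distance between expression profiles
#'
#' Correlation alone merges isoforms that share a profile shape but differ
#' in magnitude; their promoters could then be analysed together even
#' though their absolute expression differs strongly. The hybrid distance
#' therefore weights the correlation distance with a Euclidean component:
#'
#' \deqn{d_{ij} = (1-\alpha)\,\frac{1-r_{ij}}{2} + \alpha\,\frac{E_{ij}}{\max E}}
#'
#' where `r` is the Pearson correlation and `E` the Euclidean distance of
#' the (optionally log2(x+1)-transformed) profiles. Both terms, and hence
#' `d`, lie in [0, 1].
#'
#' @param m [expression_matrix] (TPM expected when `log_transform`).
#' @param alpha weight of the Euclidean term in [0, 1]; `alpha = 0` is
#'   pure correlation distance.
#' @param log_transform apply log2(x + 1) before computing distances.
#' @return object of class `distance_matrix`: list with `ids` and the
#'   symmetric matrix `d`.
#' @export
pairwise_distance <- function(m, alpha = 0.5, log_transform = TRUE) {
  stopifnot(inherits(m, "expression_matrix"),
            alpha >= 0, alpha <= 1)
  x <- m$values
  if (nrow(x) < 2L) stop("need at least 2 isoforms")
  if (ncol(x) < 3L) stop("need at least 3 samples")
  if (log_transform) x <- log2(x + 1)

  vars <- apply(x, 1, stats::var)
  r <- suppressWarnings(stats::cor(t(x)))
  corterm <- (1 - r) / 2
  if (any(vars == 0)) {
    warning("zero-variance profile(s): ",
            paste(rownames(x)[vars == 0], collapse = ", "),
            "; correlation term set to its maximum for those pairs")
    zv <- which(vars == 0)
    corterm[zv, ] <- 1
    corterm[, zv] <- 1
  }
  diag(corterm) <- 0

  e <- as.matrix(stats::dist(x))
  emax <- max(e)
  eterm <- if (emax > 0) e / emax else e  # all-identical profiles -> 0

  d <- (1 - alpha) * corterm + alpha * eterm
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(list(ids = rownames(x), d = d), class = "distance_matrix")
}

#' Complete-linkage dendrogram from a distance matrix
#'
#' @param dm a `distance_matrix` (see [pairwise_distance()]).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return an `hclust` object.
#' @export
build_dendrogram <- function(dm, linkage = "complete") {
  stopifnot(inherits(dm, "distance_matrix"))
  if (length(dm$ids) < 2L) stop("need at least 2 leaves")
  stats::hclust(stats::as.dist(dm$d), method = linkage)
}

#' Export a dendrogram as Newick
#' @param dend `hclust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}

#' Prune a dendrogram into clusters by relative internal distance
#'
#' Let `D0` be the mean of all pairwise distances. The tree is cut at
#' k = 1, 2, ... clusters (descending merge heights) and the smallest k is
#' returned for which at least `fraction` of the k clusters have an
#' internal average pairwise distance (recomputed from the distance
#' matrix, not from cophenetic heights; singletons count as 0) below
#' `rel_threshold * D0`. Defaults encode the rule "95% of clusters below
#' 0.001% of the initial average distance". Termination is guaranteed at
#' k = n (all singletons).
#'
#' @param dend `hclust` over the same ids as `dm`.
#' @param dm `distance_matrix`.
#' @param fraction required fraction of qualifying clusters (default 0.95).
#' @param rel_threshold internal-distance threshold relative to `D0`
#'   (default 1e-5).
#' @return object of class `cluster_set`: list with `membership` (named
#'   integer vector), `clusters` (list of id vectors) and
#'   `internal_distance` per cluster.
#' @export
prune_to_clusters <- function(dend, dm, fraction = 0.95,
                              rel_threshold = 1e-5) {
  stopifnot(inherits(dend, "hclust"), inherits(dm, "distance_matrix"))
  if (!setequal(dend$labels, dm$ids))
    stop("dendrogram and distance matrix cover different ids")
  n <- length(dm$ids)
  d0 <- mean(dm$d[upper.tri(dm$d)])
  if (d0 == 0) {
    memb <- stats::setNames(rep(1L, n), dm$ids)
    return(new_cluster_set(memb, dm))
  }
  thr <- rel_threshold * d0
  for (k in seq_len(n)) {
    memb <- stats::cutree(dend, k = k)
    memb <- memb[dm$ids]  # align order
    intd <- internal_distances(memb, dm)
    if (mean(intd < thr) >= fraction)
      return(new_cluster_set(memb, dm))
  }
  new_cluster_set(stats::cutree(dend, k = n)[dm$ids], dm)
}

internal_distances <- function(membership, dm) {
  vapply(split(names(membership), membership), function(ids) {
    if (length(ids) < 2L) return(0)
    sub <- dm$d[ids, ids]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
}

new_cluster_set <- function(membership, dm) {
  structure(list(
    membership = membership,
    clusters = split(names(membership), membership),
    internal_distance = internal_distances(membership, dm)
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("cluster_set: %d clusters over %d isoforms (sizes %s)\n",
              length(x$clusters), length(x$membership),
              paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Clusters eligible for motif discovery
#'
#' Only clusters with at least `min_size` distinct genes are taken to
#' promoter analysis. When an isoform-to-gene mapping is supplied, cluster
#' size is counted at the gene level with duplicates collapsed.
#'
#' @param cs `cluster_set`.
#' @param mapping optional data.frame with columns `isoform`, `gene`.
#' @param min_size minimum gene count (default 10).
#' @return character vector of eligible cluster ids.
#' @export
clusters_for_motif_search <- function(cs, mapping = NULL, min_size = 10) {
  stopifnot(inherits(cs, "cluster_set"))
  sizes <- vapply(cs$clusters, function(ids) {
    if (is.null(mapping)) return(length(unique(ids)))
    g <- mapping$gene[match(ids, mapping$isoform)]
    length(unique(g[!is.na(g)]))
  }, integer(1))
  names(sizes)[sizes >= min_size]
}

#' Write cluster membership to TSV
#' @param cs `cluster_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(cs, path) {
  write_tsv_file(data.frame(isoform = names(cs$membership),
                            cluster = unname(cs$membership)), path)
  invisible(path)
}
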