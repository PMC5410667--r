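#' Fisher-exact term over-representation in a gene cluster
#'
#' For every annotation term present on at least one cluster gene, a
#' 2 x 2 contingency table (cluster/not-cluster vs with-term/without) is
#' tested one-sided for over-representation with the exact Fisher test.
#' Raw p-values are compared with `alpha` (default 0.01); no multiple
#' testing correction is applied by default, though a
#' Benjamini-Hochberg column can be requested.
#'
#' @param cluster_genes character gene ids (must all be in the universe).
#' @param universe_genes character gene ids of the reference universe.
#' @param annotations data.frame with columns `gene`, `term` (and
#'   optionally `description`), or the `annotations` element of
#'   [make_annotation_map()].
#' @param alpha enrichment threshold on the raw p-value (default 0.01).
#' @param correct add a BH-adjusted p-value column (default FALSE).
#' @return data.frame: term, description, cluster_with, cluster_size,
#'   universe_with, universe_size, odds_ratio (sample estimate), p_value,
#'   enriched (p < alpha); sorted by p.
#' @export
fisher_enrichment <- function(cluster_genes, universe_genes, annotations,
                              alpha = 0.01, correct = FALSE) {
  if (!all(cluster_genes %in% universe_genes))
    stop("cluster genes must be a subset of the universe")
  cluster_genes <- unique(cluster_genes)
  universe_genes <- unique(universe_genes)
  ann <- annotations[annotations$gene %in% universe_genes, , drop = FALSE]
  terms <- split(unique(ann[, c("gene", "term")])$gene,
                 unique(ann[, c("gene", "term")])$term)
  desc <- if ("description" %in% names(ann))
    ann$description[match(names(terms), ann$term)] else NA_character_
  n <- length(universe_genes)
  k <- length(cluster_genes)
  rows <- mapply(function(genes, dsc) {
    a <- length(intersect(genes, cluster_genes))     # cluster, with term
    if (a == 0) return(NULL)
    m <- length(genes)                               # universe with term
    b <- k - a
    c2 <- m - a
    d <- n - k - c2
    p <- stats::fisher.test(matrix(c(a, b, c2, d), 2),
                            alternative = "greater")$p.value
    or <- (a * d) / (b * c2)  # sample odds ratio (may be Inf)
    data.frame(term = NA_character_, description = dsc,
               cluster_with = a, cluster_size = k, universe_with = m,
               universe_size = n, odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  }, terms, desc, SIMPLIFY = FALSE)
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  if (is.null(out))
    out <- data.frame(term = character(0), description = character(0),
                      cluster_with = integer(0), cluster_size = integer(0),
                      universe_with = integer(0), universe_size = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0))
  out$term <- names(terms)[keep]
  out$enriched <- out$p_value < alpha
  if (correct) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
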