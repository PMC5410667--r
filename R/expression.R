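#' Construct an expression matrix with sample metadata
#'
#' Container for an isoform-by-sample abundance table. The unit tag records
#' whether values are raw counts, counts per million (CPM) or transcripts
#' per million (TPM); downstream operations check it.
#'
#' @param values numeric matrix, isoforms in rows (rownames required),
#'   samples in columns (colnames required); no negative values.
#' @param samples data.frame of per-sample metadata with one row per column
#'   of `values` (e.g. genotype, tissue, treatment, replicate). Optional.
#' @param unit one of `"count"`, `"CPM"`, `"TPM"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples = NULL,
                              unit = c("count", "CPM", "TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("values must have row (isoform) names")
  if (is.null(colnames(values)))
    stop("values must have column (sample) names")
  if (anyDuplicated(colnames(values)))
    stop("sample IDs must be unique")
  if (anyDuplicated(rownames(values)))
    stop("isoform IDs must be unique")
  if (any(values < 0)) stop("negative abundance values are not allowed")
  if (is.null(samples))
    samples <- data.frame(sample = colnames(values),
                          stringsAsFactors = FALSE)
  if (nrow(samples) != ncol(values))
    stop("samples metadata must have one row per sample column")
  structure(list(values = values, samples = samples, unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d isoforms x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Counts per million normalization
#'
#' Scales each library so its column sums to one million.
#'
#' @param counts an [expression_matrix] with unit `"count"`.
#' @return an [expression_matrix] with unit `"CPM"`.
#' @export
compute_cpm <- function(counts) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "count")
    stop("compute_cpm expects unit 'count', got '", counts$unit, "'")
  libsize <- colSums(counts$values)
  if (any(libsize <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts$values)[libsize <= 0], collapse = ", "))
  cpm <- sweep(counts$values, 2, libsize, "/") * 1e6
  expression_matrix(cpm, counts$samples, unit = "CPM")
}

#' Filter low-expression isoforms
#'
#' Keeps an isoform when its CPM reaches `min_cpm` in at least
#' `ceiling(min_fraction * n_samples)` samples, so that "at least half"
#' is satisfied for odd sample numbers. Defaults are CPM >= 0.4 in at
#' least half of the samples.
#'
#' @param m [expression_matrix] with unit `"CPM"`.
#' @param min_cpm minimum CPM required (default 0.4).
#' @param min_fraction minimum fraction of samples (default 0.5).
#' @return character vector of kept isoform IDs.
#' @export
filter_low_expression <- function(m, min_cpm = 0.4, min_fraction = 0.5) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "CPM")
    stop("filter_low_expression expects unit 'CPM', got '", m$unit, "'")
  if (nrow(m$values) == 0L) return(character(0))
  need <- ceiling(min_fraction * ncol(m$values))
  keep <- rowSums(m$values >= min_cpm) >= need
  rownames(m$values)[keep]
}

#' Intersect two differential-expression tables
#'
#' The final DE set is the intersection of calls from two independent
#' methods; by default a call must also have the same fold-change sign in
#' both tables to count as reproduced.
#'
#' @param a,b data.frames with columns `id`, `logFC`, `fdr` (each already
#'   thresholded by its own method's FDR rule).
#' @param require_same_direction require `sign(logFC)` to agree (default
#'   TRUE).
#' @return sorted character vector of intersected ids.
#' @export
intersect_de_tags <- function(a, b, require_same_direction = TRUE) {
  for (tb in list(a, b)) {
    stopifnot(all(c("id", "logFC") %in% names(tb)))
    if (anyDuplicated(tb$id))
      stop("duplicate ids within a DE table: ",
           paste(unique(tb$id[duplicated(tb$id)]), collapse = ", "))
  }
  common <- intersect(a$id, b$id)
  if (require_same_direction && length(common)) {
    sa <- sign(a$logFC[match(common, a$id)])
    sb <- sign(b$logFC[match(common, b$id)])
    common <- common[sa == sb]
  }
  sort(common)
}

#' Select stable reference isoforms for qPCR normalization
#'
#' Ranks isoforms that were not called differentially expressed by their
#' coefficient of variation (sd/mean across all samples) and returns the
#' `n` most stable ones. Ties break toward higher mean expression, then
#' lexicographic id.
#'
#' @param m [expression_matrix] (any unit; the CV is computed on the unit
#'   supplied, sample-wise).
#' @param de_ids isoform ids called DE; never returned.
#' @param n number of references wanted (default 3).
#' @return character vector of `n` isoform ids, most stable first.
#' @export
select_reference_isoforms <- function(m, de_ids, n = 3) {
  stopifnot(inherits(m, "expression_matrix"), n >= 1)
  v <- m$values[!rownames(m$values) %in% de_ids, , drop = FALSE]
  mu <- rowMeans(v)
  v <- v[mu > 0, , drop = FALSE]
  mu <- mu[mu > 0]
  if (nrow(v) < n)
    stop("fewer than ", n, " eligible (non-DE, expressed) isoforms")
  cv <- apply(v, 1, stats::sd) / mu
  ord <- order(cv, -mu, rownames(v))
  rownames(v)[ord][seq_len(n)]
}

#' Read an expression matrix from TSV
#'
#' First column holds isoform IDs; remaining columns are samples.
#'
#' @param path TSV file.
#' @param unit unit tag of the stored values.
#' @param samples optional sample metadata data.frame.
#' @return an [expression_matrix].
#' @export
read_expression_tsv <- function(path, unit = "TPM", samples = NULL) {
  df <- read_tsv_file(path)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- as.character(df[[1]])
  expression_matrix(v, samples, unit = unit)
}

#' Write an expression matrix to TSV
#' @param m [expression_matrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
  invisible(path)
}
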