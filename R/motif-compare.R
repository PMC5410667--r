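#' Width-normalized correlation (Ncor) between two motifs
#'
#' Slides the target motif (and, optionally, its reverse complement)
#' along the query over all ungapped offsets with at least `min_overlap`
#' aligned columns. At each offset, `r` is the Pearson correlation of
#' the concatenated frequency-matrix entries of the aligned columns and
#' `ncor = r * overlap / max(w_query, w_target)`, so partial overlaps
#' are penalized. The offset maximizing ncor is returned.
#'
#' @param query,target [pfm()] objects with width >= 4.
#' @param try_revcomp also try the target's reverse complement.
#' @param min_overlap minimum aligned columns (default 4).
#' @return list (class `motif_match`): query, target, offset (target
#'   relative to query), strand, overlap, correlation, ncor.
#' @export
compare_motifs_ncor <- function(query, target, try_revcomp = TRUE,
                                min_overlap = 4) {
  stopifnot(inherits(query, "pfm"), inherits(target, "pfm"))
  wq <- ncol(query$counts)
  wt <- ncol(target$counts)
  if (wq < min_overlap || wt < min_overlap)
    stop("overlap constraint unsatisfiable: motif narrower than ",
         min_overlap, " columns")
  qf <- pfm_freq(query)
  wmax <- max(wq, wt)
  best <- NULL
  strands <- if (try_revcomp) c("+", "-") else "+"
  for (strand in strands) {
    tf <- if (strand == "+") pfm_freq(target)
          else pfm_freq(pfm_revcomp(target))
    for (off in seq(-(wt - min_overlap), wq - min_overlap)) {
      iq <- max(1L, 1L + off)
      it <- iq - off
      len <- min(wq - iq, wt - it) + 1L
      if (len < min_overlap) next
      a <- as.vector(qf[, iq:(iq + len - 1L)])
      b <- as.vector(tf[, it:(it + len - 1L)])
      r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
           else stats::cor(a, b)
      ncor <- r * len / wmax
      if (is.null(best) || ncor > best$ncor)
        best <- list(query = query$id, target = target$id,
                     offset = off, strand = strand, overlap = len,
                     correlation = r, ncor = ncor)
    }
  }
  structure(best, class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf(
    "motif_match: %s vs %s  ncor %.3f (r %.3f, overlap %d, offset %+d%s)\n",
    x$query, x$target, x$ncor, x$correlation, x$overlap, x$offset,
    if (x$strand == "-") ", revcomp" else ""))
  invisible(x)
}

#' Annotate a motif against a TRANSFAC-format library
#'
#' Every library motif is scored with [compare_motifs_ncor()]; the
#' result is sorted by decreasing ncor, so the first row is the best
#' hit.
#'
#' @param query a [pfm()].
#' @param library named list of `pfm` (e.g. from [read_transfac()]) or a
#'   path to a TRANSFAC file.
#' @param try_revcomp also try reverse complements.
#' @return data.frame: library_id, ncor, correlation, overlap, offset,
#'   strand.
#' @export
annotate_motif <- function(query, library, try_revcomp = TRUE) {
  if (is.character(library) && length(library) == 1L)
    library <- read_transfac(library)
  if (!length(library)) stop("empty motif library")
  rows <- lapply(library, function(m) {
    mm <- compare_motifs_ncor(query, m, try_revcomp)
    data.frame(library_id = m$id, ncor = mm$ncor,
               correlation = mm$correlation, overlap = mm$overlap,
               offset = mm$offset, strand = mm$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ncor, out$library_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
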