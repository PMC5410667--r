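#' Extract strand-aware promoter windows around transcription start sites
#'
#' For a plus-strand gene the genomic window is
#' `[TSS - upstream, TSS + downstream - 1]` with TSS = feature start; for
#' a minus-strand gene it is `[end - downstream + 1, end + upstream]`,
#' reverse-complemented so that position 1 of every returned sequence is
#' its most upstream base and the TSS sits at position `upstream + 1`.
#' Windows are clipped at contig boundaries (and flagged). Lowercase
#' (repeat-masked) bases are preserved; masked positions are later
#' excluded from word counting and scanning but kept in the output.
#'
#' @param genome named character vector of contig sequences, or path to a
#'   FASTA file (read case-preserving).
#' @param annotation data.frame with columns gene, contig, start, end,
#'   strand (1-based inclusive), or path to a GFF3 file whose `gene`
#'   features are used.
#' @param upstream,downstream window sizes in nt (defaults 1000 / 200).
#' @return object of class `promoter_set`: list with `sequences` (named
#'   character, promoter orientation), `info` (data.frame gene, contig,
#'   start, end, strand, clipped) and the window sizes.
#' @export
extract_promoters <- function(genome, annotation, upstream = 1000,
                              downstream = 200) {
  stopifnot(upstream >= 1, downstream >= 0)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  stopifnot(is.character(genome), !is.null(names(genome)))
  genes <- if (is.character(annotation)) read_gff3_genes(annotation)
           else annotation
  stopifnot(all(c("gene", "contig", "start", "end", "strand")
                %in% names(genes)))

  keep <- genes$strand %in% c("+", "-")
  if (any(!keep)) {
    warning("skipping gene(s) without strand: ",
            paste(genes$gene[!keep], collapse = ", "))
    genes <- genes[keep, , drop = FALSE]
  }
  missing <- setdiff(genes$contig, names(genome))
  if (length(missing))
    stop("contig(s) absent from genome for gene(s): ",
         paste(genes$gene[genes$contig %in% missing], collapse = ", "))

  clen <- nchar(genome)[genes$contig]
  plus <- genes$strand == "+"
  ws <- ifelse(plus, genes$start - upstream,
               genes$end - downstream + 1L)
  we <- ifelse(plus, genes$start + downstream - 1L,
               genes$end + upstream)
  cs <- pmax(ws, 1L)
  ce <- pmin(we, clen)
  clipped <- cs != ws | ce != we

  seqs <- substr(genome[genes$contig], cs, ce)
  seqs[!plus] <- revcomp(seqs[!plus])
  names(seqs) <- genes$gene

  structure(list(sequences = seqs,
                 info = data.frame(gene = genes$gene,
                                   contig = genes$contig,
                                   start = cs, end = ce,
                                   strand = genes$strand,
                                   clipped = clipped,
                                   stringsAsFactors = FALSE),
                 upstream = upstream, downstream = downstream),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters (-%d, +%d around TSS)\n",
              length(x$sequences), x$upstream, x$downstream))
  invisible(x)
}

#' Promoter sequences as a named character vector
#' @param x `promoter_set` (or already a named character vector).
#' @return named character vector.
#' @export
promoter_sequences <- function(x) {
  if (inherits(x, "promoter_set")) x$sequences else x
}

# case-preserving FASTA reader (masking matters downstream)
read_genome_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene"))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  data.frame(gene = as.character(ids),
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write promoter sequences to FASTA
#' @param ps `promoter_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(ps, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(ps$sequences), path)
  invisible(path)
}

#' Write promoter coordinates as BED (0-based, half-open)
#' @param ps `promoter_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(ps, path) {
  bed <- data.frame(ps$info$contig, ps$info$start - 1L, ps$info$end,
                    ps$info$gene, 0L, ps$info$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map isoform ids to gene ids through a mapping table
#'
#' Many isoforms may map to one gene; an isoform mapped to two genes is
#' an error (ambiguous). Unmapped isoforms are reported in the
#' `"unmapped"` attribute, not fatal.
#'
#' @param mapping data.frame with columns isoform, gene (or a TSV path).
#' @param isoform_ids character vector.
#' @return character vector of unique gene ids, with attribute
#'   `unmapped` listing isoforms absent from the mapping.
#' @export
map_isoforms_to_genes <- function(mapping, isoform_ids) {
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- read_tsv_file(mapping)
  stopifnot(all(c("isoform", "gene") %in% names(mapping)))
  amb <- unique(mapping$isoform[duplicated(
    unique(mapping[, c("isoform", "gene")])$isoform)])
  amb <- intersect(amb, isoform_ids)
  if (length(amb))
    stop("ambiguous isoform-to-gene mapping for: ",
         paste(amb, collapse = ", "))
  hit <- match(isoform_ids, mapping$isoform)
  unmapped <- isoform_ids[is.na(hit)]
  genes <- sort(unique(mapping$gene[hit[!is.na(hit)]]))
  attr(genes, "unmapped") <- unmapped
  genes
}

#' Fraction of masked (lowercase) bases in sequences
#' @param seqs named character vector or `promoter_set`.
#' @return numeric scalar in [0, 1].
#' @export
masked_fraction <- function(seqs) {
  s <- paste(promoter_sequences(seqs), collapse = "")
  if (nchar(s) == 0) return(0)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  mean(ch %in% letters)
}
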