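#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy table; lowercase handled separately (weak preference)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' Case-preserving (lowercase marks repeat-masked bases) and vectorized.
#' Ambiguity codes other than N are complemented through the IUPAC table.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Validate an IUPAC consensus string
#'
#' @param x single consensus string (case-insensitive).
#' @return `TRUE` invisibly, or an error if a symbol is not IUPAC DNA.
#' @export
check_iupac <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) >= 1L)
  ch <- toupper(strsplit(x, "", fixed = TRUE)[[1]])
  bad <- setdiff(ch, names(IUPAC_SETS))
  if (length(bad))
    stop("not an IUPAC DNA consensus, offending symbols: ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Draw a concrete word from an IUPAC consensus
#'
#' Each degenerate position is sampled uniformly from its base set.
#'
#' @param consensus IUPAC string.
#' @return single DNA word over ACGT.
#' @export
sample_iupac_instance <- function(consensus) {
  check_iupac(consensus)
  ch <- toupper(strsplit(consensus, "", fixed = TRUE)[[1]])
  paste(vapply(ch, function(b) {
    s <- IUPAC_SETS[[b]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

# map a set of bases (sorted) back to its IUPAC code
iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""),
                  character(1))
  names(codes)[match(key, codes)]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar; 1 for identical partitions, ~0 at random.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (sij - expected) / (mx - expected)
}

# simple TSV helpers used across module I/O
read_tsv_file <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
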