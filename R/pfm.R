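#' Position frequency matrix objects
#'
#' A `pfm` wraps a 4 x w count matrix (rows A, C, G, T), a pseudocount,
#' the source sites it was built from, and an IUPAC consensus.
#'
#' @param counts 4 x w numeric matrix with rownames A, C, G, T (w >= 4).
#' @param pseudocount total pseudocount added per column, spread equally
#'   over the four bases (default 1).
#' @param sites character vector of source sites (optional).
#' @param id motif identifier.
#' @return object of class `pfm`.
#' @export
pfm <- function(counts, pseudocount = 1, sites = character(0),
                id = "motif") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 4,
            !is.null(rownames(counts)), pseudocount >= 0)
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (any(counts < 0)) stop("counts must be non-negative")
  cs <- colSums(counts)
  if (length(unique(round(cs, 9))) != 1L)
    stop("column sums must be equal across columns")
  structure(list(counts = counts, pseudocount = pseudocount,
                 sites = sites, id = id,
                 consensus = pfm_consensus_string(counts, pseudocount)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("pfm '%s': %d columns, %d sites, consensus %s\n",
              x$id, ncol(x$counts), length(x$sites), x$consensus))
  invisible(x)
}

#' Column frequencies of a PFM (pseudocount-normalized)
#' @param x `pfm`.
#' @return 4 x w matrix of frequencies; columns sum to 1.
#' @export
pfm_freq <- function(x) {
  stopifnot(inherits(x, "pfm"))
  n <- colSums(x$counts) + x$pseudocount
  sweep(x$counts + x$pseudocount / 4, 2, n, "/")
}

# IUPAC consensus: include every base with frequency >= 0.25; lowercase
# when the best base is below 0.5 (weak preference)
pfm_consensus_string <- function(counts, pseudocount) {
  n <- colSums(counts) + pseudocount
  f <- sweep(counts + pseudocount / 4, 2, n, "/")
  paste(vapply(seq_len(ncol(f)), function(j) {
    col <- f[, j]
    sel <- names(col)[col >= 0.25]
    if (!length(sel)) sel <- names(col)[which.max(col)]
    code <- iupac_code_for(sel)
    if (max(col) < 0.5) tolower(code) else code
  }, character(1)), collapse = "")
}

#' Reverse complement of a PFM
#' @param x `pfm`.
#' @return `pfm` with reversed columns and complemented rows.
#' @export
pfm_revcomp <- function(x) {
  cc <- x$counts[c("T", "G", "C", "A"), rev(seq_len(ncol(x$counts))),
                 drop = FALSE]
  rownames(cc) <- DNA_BASES
  pfm(cc, x$pseudocount, revcomp(x$sites), paste0(x$id, "_rc"))
}

# best ungapped overlap alignment of word b against word a (both ACGT);
# returns list(offset, matches, strand) or NULL if below min_overlap
align_word <- function(a, b, min_overlap) {
  best <- NULL
  for (strand in c("+", "-")) {
    w <- if (strand == "+") b else revcomp(b)
    la <- nchar(a); lb <- nchar(w)
    for (off in seq(-(lb - min_overlap), la - min_overlap)) {
      ia <- max(1L, 1L + off); ib <- ia - off
      len <- min(la - ia, lb - ib) + 1L
      if (len < min_overlap) next
      sa <- strsplit(substr(a, ia, ia + len - 1L), "")[[1]]
      sb <- strsplit(substr(w, ib, ib + len - 1L), "")[[1]]
      m <- sum(sa == sb)
      if (is.null(best) || m > best$matches)
        best <- list(offset = off, matches = m, overlap = len,
                     strand = strand)
    }
  }
  best
}

# occurrences of an exact word in sequences, both strands; returns
# data.frame(seq, pos, strand) with pos on the forward strand
word_occurrences <- function(word, seqs) {
  k <- nchar(word)
  rows <- lapply(names(seqs), function(nm) {
    ww <- word_windows(seqs[[nm]], k, merge_revcomp = FALSE)
    if (is.null(ww)) return(NULL)
    L <- nchar(seqs[[nm]])
    rcseq <- revcomp(seqs[[nm]])
    rcw <- substring(rcseq, L + 2L - ww$pos - k, L + 1L - ww$pos)
    fwd <- ww$key == word
    rev <- rcw == word & !fwd  # palindromes counted once
    if (!any(fwd | rev)) return(NULL)
    data.frame(seq = nm,
               pos = ww$pos[fwd | rev],
               strand = ifelse(fwd[fwd | rev], "+", "-"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a position frequency matrix from significant words
#'
#' All occurrences (sites) of the top-ranked word are collected from the
#' cluster promoters, together with occurrences of other significant
#' words that align to the top word (on either strand) with at most two
#' mismatches over their overlap; each aligned occurrence contributes
#' the full-width sequence window in the top word's frame, so shorter
#' overlapping words extend naturally with their genomic context. Words
#' without an acceptable alignment are dropped with a warning.
#'
#' @param words character vector of significant words, best first, or an
#'   [oligo_analysis()] result data.frame (its `word` column is used).
#' @param cluster_promoters promoters the words were discovered in.
#' @param pseudocount total pseudocount per column (default 1).
#' @param id motif identifier.
#' @return a [pfm()].
#' @export
build_pfm <- function(words, cluster_promoters, pseudocount = 1,
                      id = "motif") {
  if (is.data.frame(words)) words <- words$word
  stopifnot(length(words) >= 1)
  seqs <- promoter_sequences(cluster_promoters)
  top <- words[1]
  k <- nchar(top)
  sites <- character(0)
  for (w in unique(words)) {
    if (w == top) {
      occ <- word_occurrences(w, seqs)
      if (is.null(occ)) next
      use <- data.frame(occ, offset = 0L, wlen = k,
                        stringsAsFactors = FALSE)
    } else {
      min_ov <- min(k, nchar(w)) - 2L
      al <- align_word(top, w, min_overlap = max(4L, min_ov))
      if (is.null(al) || al$matches < al$overlap - 2L ||
          al$matches < min_ov) {
        warning("word ", w, " does not align to the top word; skipped")
        next
      }
      occ <- word_occurrences(if (al$strand == "+") w else revcomp(w),
                              seqs)
      if (is.null(occ)) next
      use <- data.frame(occ, offset = al$offset, wlen = nchar(w),
                        stringsAsFactors = FALSE)
    }
    # extract the k-mer in the top word's frame
    for (i in seq_len(nrow(use))) {
      nm <- use$seq[i]
      L <- nchar(seqs[[nm]])
      if (use$strand[i] == "+") {
        start <- use$pos[i] - use$offset[i]
        if (start < 1L || start + k - 1L > L) next
        site <- substr(seqs[[nm]], start, start + k - 1L)
      } else {
        start <- use$pos[i] + use$offset[i] + use$wlen[i] - k
        if (start < 1L || start + k - 1L > L) next
        site <- revcomp(substr(seqs[[nm]], start, start + k - 1L))
      }
      if (grepl("[^ACGT]", site)) next
      sites <- c(sites, site)
    }
  }
  if (!length(sites))
    stop("no sites found for the given words in the cluster promoters")
  mat <- matrix(0, 4, k, dimnames = list(DNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  for (j in seq_len(k)) {
    tb <- table(factor(chars[, j], levels = DNA_BASES))
    mat[, j] <- as.numeric(tb)
  }
  pfm(mat, pseudocount = pseudocount, sites = sites, id = id)
}

#' Scan sequences with a position weight matrix
#'
#' The weight (bit) score at each offset is
#' `sum_i log2(f[b_i, i] / p[b_i])` with `f` the pseudocount-normalized
#' PFM frequencies and `p` the background base frequencies. Both strands
#' are scanned; windows containing N or masked bases are skipped. Hit
#' offsets are 1-based positions of the window start on the forward
#' strand.
#'
#' @param x a [pfm()].
#' @param seqs named character vector (or `promoter_set`).
#' @param background_freqs background base frequencies (A, C, G, T; must
#'   sum to 1).
#' @param score_threshold minimum score to report (default 0).
#' @return data.frame: seq, offset, strand, score; sorted by score desc.
#' @export
matrix_scan <- function(x, seqs, background_freqs = rep(0.25, 4),
                        score_threshold = 0) {
  stopifnot(inherits(x, "pfm"),
            abs(sum(background_freqs) - 1) < 1e-6)
  seqs <- promoter_sequences(seqs)
  w <- ncol(x$counts)
  lw <- log2(pfm_freq(x) / background_freqs)
  hits <- lapply(names(seqs), function(nm) {
    sc <- scan_one(seqs[[nm]], lw)
    if (is.null(sc)) return(NULL)
    keep <- !is.na(sc$score) & sc$score >= score_threshold
    if (!any(keep)) return(NULL)
    data.frame(seq = nm, offset = sc$offset[keep],
               strand = sc$strand[keep], score = sc$score[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(seq = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0))
  out[order(-out$score, out$seq, out$offset), , drop = FALSE]
}

# scores at all offsets/strands of one sequence; NA where the window is
# not scannable (masked or ambiguous base)
scan_one <- function(seq, lw) {
  w <- ncol(lw)
  L <- nchar(seq)
  if (L < w) return(NULL)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(ch, DNA_BASES)  # NA for masked / N
  n_off <- L - w + 1L
  fwd <- numeric(n_off)
  rev <- numeric(n_off)
  for (j in seq_len(w)) {
    b <- code[j:(j + n_off - 1L)]
    fwd <- fwd + lw[cbind(b, j)]
    rev <- rev + lw[cbind(5L - b, w - j + 1L)]  # complement, mirrored col
  }
  list(offset = rep(seq_len(n_off), 2L),
       strand = rep(c("+", "-"), each = n_off),
       score = c(fwd, rev))
}

#' Best hit score per sequence
#' @param x `pfm`.
#' @param seqs sequences.
#' @param background_freqs background base frequencies.
#' @return named numeric vector (NA for unscannable sequences).
#' @export
best_scores <- function(x, seqs, background_freqs = rep(0.25, 4)) {
  seqs <- promoter_sequences(seqs)
  lw <- log2(pfm_freq(x) / background_freqs)
  vapply(seqs, function(s) {
    sc <- scan_one(s, lw)
    if (is.null(sc) || all(is.na(sc$score))) return(NA_real_)
    max(sc$score, na.rm = TRUE)
  }, numeric(1))
}

# TRANSFAC-style count matrix I/O ---------------------------------------

#' Write motifs in TRANSFAC count-matrix format
#' @param motifs a `pfm` or list of `pfm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(motifs, path) {
  if (inherits(motifs, "pfm")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(c(sprintf("AC  %s", m$id), "XX",
                 sprintf("ID  %s", m$id), "XX",
                 "P0      A      C      G      T"), con)
    for (j in seq_len(ncol(m$counts)))
      writeLines(sprintf("%02d  %5g  %5g  %5g  %5g", j,
                         m$counts["A", j], m$counts["C", j],
                         m$counts["G", j], m$counts["T", j]), con)
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Read motifs from a TRANSFAC count-matrix file
#'
#' Unparseable entries are skipped with a warning.
#'
#' @param path TRANSFAC file.
#' @param pseudocount pseudocount assigned to the read motifs.
#' @return named list of `pfm`.
#' @export
read_transfac <- function(path, pseudocount = 1) {
  lines <- readLines(path)
  entries <- split(lines, cumsum(grepl("^//", c("", lines[-length(lines)]))))
  out <- list()
  for (en in entries) {
    en <- en[nzchar(trimws(en))]
    if (!length(en) || all(grepl("^//", en))) next
    id_line <- grep("^(AC|ID)", en, value = TRUE)
    id <- if (length(id_line)) trimws(sub("^(AC|ID)\\s+", "", id_line[1]))
          else sprintf("motif%03d", length(out) + 1L)
    rows <- grep("^\\d+\\s", en, value = TRUE)
    m <- try(suppressWarnings({
      vals <- lapply(strsplit(trimws(rows), "\\s+"), function(p)
        as.numeric(p[2:5]))
      cc <- t(do.call(rbind, vals))
      if (anyNA(cc)) stop("non-numeric counts")
      rownames(cc) <- DNA_BASES
      pfm(cc, pseudocount = pseudocount, id = id)
    }), silent = TRUE)
    if (inherits(m, "try-error")) {
      warning("skipping unparseable TRANSFAC entry '", id, "'")
      next
    }
    out[[id]] <- m
  }
  out
}

#' Write motifs in MEME minimal format
#' @param motifs a `pfm` or list of `pfm`.
#' @param path output file.
#' @param background_freqs background base frequencies for the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background_freqs = rep(0.25, 4)) {
  if (inherits(motifs, "pfm")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background_freqs[1], background_freqs[2],
                       background_freqs[3], background_freqs[4]), ""),
             con)
  for (m in motifs) {
    f <- pfm_freq(m)
    nsites <- max(1, length(m$sites))
    writeLines(c(sprintf("MOTIF %s", m$id),
                 sprintf(
                   "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                   ncol(f), nsites)), con)
    for (j in seq_len(ncol(f)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         f["A", j], f["C", j], f["G", j], f["T", j]),
                 con)
    writeLines("", con)
  }
  invisible(path)
}
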