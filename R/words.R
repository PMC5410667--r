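# Strand-merged, non-overlapping word counting in the style of
# oligo-analysis: every valid window contributes one occurrence of the
# lexicographically smaller of (word, reverse complement), so counting a
# single pass over the forward strand is equivalent to double-strand
# counting with reverse-complement merging. Windows containing N or
# lowercase (repeat-masked) bases are skipped.

# per-sequence window table: positions and merged keys
word_windows <- function(seq, k, merge_revcomp = TRUE) {
  L <- nchar(seq)
  if (L < k) return(NULL)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- cumsum(!(ch %in% DNA_BASES))  # lowercase and N are invalid
  i <- seq_len(L - k + 1L)
  ok <- (bad[i + k - 1L] - c(0L, bad)[i]) == 0L
  i <- i[ok]
  if (!length(i)) return(NULL)
  w <- substring(seq, i, i + k - 1L)
  if (merge_revcomp) {
    rcseq <- revcomp(seq)
    rcw <- substring(rcseq, L + 2L - i - k, L + 1L - i)
    w <- pmin(w, rcw)
  }
  list(pos = i, key = w)
}

# greedy count of non-overlapping occurrences; pos ascending
greedy_nonoverlap <- function(pos, span) {
  n <- 0L
  last <- -span
  for (p in pos) {
    if (p >= last + span) {
      n <- n + 1L
      last <- p
    }
  }
  n
}

# count keys at positions within one sequence honouring the overlap rule
count_keys <- function(pos, key, span, no_overlap = TRUE) {
  if (!length(pos)) return(integer(0))
  if (!no_overlap) {
    tab <- table(key)
    return(stats::setNames(as.integer(tab), names(tab)))
  }
  ord <- order(key, pos)
  key <- key[ord]; pos <- pos[ord]
  same <- c(FALSE, key[-1] == key[-length(key)])
  close <- same & c(FALSE, diff(pos) < span)
  if (!any(close)) {  # common case: no same-key overlapping windows
    tab <- table(key)
    return(stats::setNames(as.integer(tab), names(tab)))
  }
  simple <- !(key %in% unique(key[close]))
  counts <- integer(0)
  if (any(simple)) {
    tab <- table(key[simple])
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  hard <- split(pos[!simple], key[!simple])
  c(counts, vapply(hard, greedy_nonoverlap, integer(1), span = span))
}

sum_named <- function(a, b) {
  keys <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(keys)), keys)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out
}

#' Count k-mers with strand merging and non-overlapping occurrences
#'
#' A word and its reverse complement are counted under the
#' lexicographically smaller key; occurrences of the same word that
#' overlap a previously counted occurrence are skipped when
#' `no_overlap`. Windows containing N or masked (lowercase) bases do not
#' count, neither as occurrences nor as trials.
#'
#' @param seqs named character vector of sequences (or `promoter_set`).
#' @param k word length (>= 2).
#' @param merge_revcomp merge each word with its reverse complement.
#' @param no_overlap suppress overlapping occurrences of the same word.
#' @return named integer vector of counts with attribute `windows` = the
#'   total number of countable positions (binomial trials).
#' @export
count_words <- function(seqs, k, merge_revcomp = TRUE, no_overlap = TRUE) {
  stopifnot(k >= 2)
  seqs <- promoter_sequences(seqs)
  total <- numeric(0)
  windows <- 0L
  for (s in seqs) {
    ww <- word_windows(s, k, merge_revcomp)
    if (is.null(ww)) next
    windows <- windows + length(ww$pos)
    total <- sum_named(total, count_keys(ww$pos, ww$key, span = k,
                                         no_overlap = no_overlap))
  }
  out <- stats::setNames(as.integer(total), names(total))
  if (length(out)) out <- out[order(names(out))]
  attr(out, "windows") <- windows
  out
}

dyad_key <- function(m1, s, m2) sprintf("%s.%d.%s", m1, s, m2)

format_dyad <- function(key) {
  parts <- strsplit(key, ".", fixed = TRUE)
  vapply(parts, function(p) {
    s <- as.integer(p[2])
    if (s == 0) paste0(p[1], p[3])
    else sprintf("%sN{%d}%s", p[1], s, p[3])
  }, character(1))
}

# reverse complement of a dyad key: rc(m2) . s . rc(m1)
revcomp_dyad_key <- function(key) {
  parts <- strsplit(key, ".", fixed = TRUE)
  vapply(parts, function(p)
    dyad_key(revcomp(p[3]), as.integer(p[2]), revcomp(p[1])),
    character(1))
}

#' Count spaced dyads (monad1 - N{s} - monad2)
#'
#' Dyads are pairs of trinucleotides separated by a fixed spacer of
#' 0-`max(spacings)` unspecified bases. Counting merges each dyad with
#' its reverse complement and applies the same masked-window and
#' non-overlap rules as [count_words()], with span = 2*monad_len + s.
#'
#' @param seqs named character vector (or `promoter_set`).
#' @param monad_len monad length (default 3).
#' @param spacings integer vector of spacer lengths (default 0:20).
#' @param no_overlap suppress overlapping same-dyad occurrences.
#' @return named numeric vector of counts (keys `"AAA.5.TCT"`), with
#'   attribute `windows`: named vector of countable positions per
#'   spacing.
#' @export
count_dyads <- function(seqs, monad_len = 3, spacings = 0:20,
                        no_overlap = TRUE) {
  seqs <- promoter_sequences(seqs)
  total <- numeric(0)
  windows <- stats::setNames(numeric(length(spacings)),
                             as.character(spacings))
  for (sq in seqs) {
    L <- nchar(sq)
    if (L < 2 * monad_len) next
    ch <- strsplit(sq, "", fixed = TRUE)[[1]]
    bad <- cumsum(!(ch %in% DNA_BASES))
    im <- seq_len(L - monad_len + 1L)
    mono_ok <- (bad[im + monad_len - 1L] - c(0L, bad)[im]) == 0L
    monads <- substring(sq, im, im + monad_len - 1L)
    for (s in spacings) {
      span <- 2L * monad_len + s
      if (L < span) next
      i <- seq_len(L - span + 1L)
      j <- i + monad_len + s
      ok <- mono_ok[i] & mono_ok[j]
      i <- i[ok]
      if (!length(i)) next
      windows[as.character(s)] <- windows[as.character(s)] + length(i)
      key <- dyad_key(monads[i], s, monads[i + monad_len + s])
      rckey <- revcomp_dyad_key(key)
      key <- pmin(key, rckey)
      total <- sum_named(total, count_keys(i, key, span = span,
                                           no_overlap = no_overlap))
    }
  }
  out <- if (length(total)) total[order(names(total))] else total
  attr(out, "windows") <- windows
  out
}

#' Binomial over-representation statistics for one word
#'
#' Exact upper-tail binomial probability of observing at least `observed`
#' occurrences in `trials` countable positions given a background
#' probability `prior_p`; the E-value corrects for the number of words
#' tested and the significance index is `-log10(E)`.
#'
#' @param observed occurrence count (>= 0).
#' @param trials number of countable positions (>= observed).
#' @param prior_p background occurrence probability per position.
#' @param n_tested number of distinct words tested.
#' @return list: observed, expected, p_value, e_value, sig, and
#'   `degenerate` flag (TRUE when `prior_p = 0` with observed > 0, which
#'   gives p = 0 and infinite sig).
#' @export
word_significance <- function(observed, trials, prior_p, n_tested = 1) {
  stopifnot(prior_p >= 0, prior_p <= 1, trials >= observed, observed >= 0)
  degenerate <- prior_p == 0 && observed > 0
  p <- stats::pbinom(observed - 1, trials, prior_p, lower.tail = FALSE)
  e <- p * n_tested
  list(observed = observed, expected = trials * prior_p,
       p_value = p, e_value = e, sig = -log10(e), degenerate = degenerate)
}

# shared background container ------------------------------------------

#' Precompute background word statistics for over-representation tests
#'
#' Counting the background once and reusing it across clusters (and
#' negative controls) avoids recounting the whole promoter universe.
#'
#' @param seqs background promoter universe (named character or
#'   `promoter_set`).
#' @param k_values word lengths (default 6:8).
#' @return object of class `word_background`.
#' @export
word_background <- function(seqs, k_values = 6:8) {
  seqs <- promoter_sequences(seqs)
  per_k <- lapply(k_values, function(k) {
    cnt <- count_words(seqs, k)
    list(k = k, counts = cnt, windows = attr(cnt, "windows"),
         n_tested = length(cnt))
  })
  structure(list(k_values = k_values,
                 per_k = stats::setNames(per_k, as.character(k_values))),
            class = "word_background")
}

#' Over-represented oligonucleotides in cluster promoters
#'
#' For each strand-merged word of each length, the occurrence prior comes
#' from its relative frequency in the background universe, the number of
#' trials is the number of countable positions in the cluster promoters,
#' and significance is the exact binomial upper tail corrected by the
#' number of distinct background words of that length. With the default
#' `sig_threshold = 0`, reported words have E-value <= 1.
#'
#' @param cluster_promoters promoters of the co-expressed cluster.
#' @param background_promoters the promoter universe (ideally a superset
#'   of the cluster), or a precomputed [word_background()].
#' @param k_values word lengths (default 6:8).
#' @param sig_threshold minimum sig = -log10(E) (default 0). Use `-Inf`
#'   to keep every observed word.
#' @return data.frame: word, k, observed, expected, p_value, e_value,
#'   sig; sorted by decreasing sig.
#' @export
oligo_analysis <- function(cluster_promoters, background_promoters,
                           k_values = 6:8, sig_threshold = 0) {
  cl <- promoter_sequences(cluster_promoters)
  if (length(cl) == 0) stop("empty cluster")
  bg <- if (inherits(background_promoters, "word_background"))
    background_promoters else word_background(background_promoters,
                                              k_values)
  if (!all(as.character(k_values) %in% names(bg$per_k)))
    stop("background lacks counts for some requested word lengths")
  res <- lapply(as.character(k_values), function(kk) {
    b <- bg$per_k[[kk]]
    cnt <- count_words(cl, b$k)
    if (!length(cnt)) return(NULL)
    prior <- as.numeric(b$counts[names(cnt)]) / b$windows
    prior[is.na(prior)] <- 0
    trials <- attr(cnt, "windows")
    p <- stats::pbinom(as.numeric(cnt) - 1, trials, prior,
                       lower.tail = FALSE)
    e <- p * b$n_tested
    data.frame(word = names(cnt), k = b$k, observed = as.integer(cnt),
               expected = trials * prior, p_value = p, e_value = e,
               sig = -log10(e), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[res$sig >= sig_threshold, , drop = FALSE]
  res <- res[order(-res$sig, res$word), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Precompute background monad frequencies and dyad inventory
#'
#' @param seqs background promoter universe.
#' @param monad_len monad length (default 3).
#' @param spacings spacer lengths (default 0:20).
#' @return object of class `dyad_background`.
#' @export
dyad_background <- function(seqs, monad_len = 3, spacings = 0:20) {
  seqs <- promoter_sequences(seqs)
  mono <- count_words(seqs, monad_len, merge_revcomp = FALSE,
                      no_overlap = FALSE)
  # strand-symmetric monad frequencies: f(m) = f(revcomp(m))
  keys <- names(mono)
  rc <- revcomp(keys)
  m2 <- stats::setNames(as.numeric(mono), keys)
  f <- (m2 + ifelse(rc %in% keys, m2[rc], 0)) / (2 * sum(m2))
  dy <- count_dyads(seqs, monad_len, spacings)
  structure(list(monad_len = monad_len, spacings = spacings,
                 monad_freq = f, dyads = dy,
                 n_tested = length(dy)),
            class = "dyad_background")
}

#' Over-represented spaced dyads in cluster promoters
#'
#' The expected frequency of a dyad is the product of its two monad
#' background frequencies (the spacer carries no information), doubled
#' when the dyad differs from its reverse complement because counting is
#' strand-merged. The same exact binomial machinery as
#' [oligo_analysis()] applies; the E-value correction uses the number of
#' distinct merged dyads observed in the background.
#'
#' @param cluster_promoters cluster promoters.
#' @param background_promoters promoter universe or a precomputed
#'   [dyad_background()].
#' @param monad_len monad length (default 3).
#' @param spacings spacer lengths (default 0:20).
#' @param sig_threshold minimum sig (default 0).
#' @return data.frame: word (display form), dyad (key), spacing,
#'   observed, expected, p_value, e_value, sig; sorted by decreasing sig.
#' @export
dyad_analysis <- function(cluster_promoters, background_promoters,
                          monad_len = 3, spacings = 0:20,
                          sig_threshold = 0) {
  cl <- promoter_sequences(cluster_promoters)
  if (length(cl) == 0) stop("empty cluster")
  bg <- if (inherits(background_promoters, "dyad_background"))
    background_promoters else dyad_background(background_promoters,
                                              monad_len, spacings)
  cnt <- count_dyads(cl, monad_len, spacings)
  if (!length(cnt)) {
    return(data.frame(word = character(0), dyad = character(0),
                      spacing = integer(0), observed = integer(0),
                      expected = numeric(0), p_value = numeric(0),
                      e_value = numeric(0), sig = numeric(0)))
  }
  keys <- names(cnt)
  parts <- strsplit(keys, ".", fixed = TRUE)
  m1 <- vapply(parts, `[`, character(1), 1)
  sp <- as.integer(vapply(parts, `[`, character(1), 2))
  m2 <- vapply(parts, `[`, character(1), 3)
  f <- bg$monad_freq
  g <- function(m) ifelse(m %in% names(f), f[m], 0)
  prior <- as.numeric(g(m1)) * as.numeric(g(m2))
  palindromic <- keys == revcomp_dyad_key(keys)
  prior <- prior * ifelse(palindromic, 1, 2)
  trials <- attr(cnt, "windows")[as.character(sp)]
  p <- stats::pbinom(as.numeric(cnt) - 1, trials, prior,
                     lower.tail = FALSE)
  e <- p * bg$n_tested
  res <- data.frame(word = format_dyad(keys), dyad = keys, spacing = sp,
                    observed = as.integer(cnt),
                    expected = trials * prior, p_value = p, e_value = e,
                    sig = -log10(e), stringsAsFactors = FALSE)
  res <- res[res$sig >= sig_threshold, , drop = FALSE]
  res <- res[order(-res$sig, res$word), , drop = FALSE]
  rownames(res) <- NULL
  res
}
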