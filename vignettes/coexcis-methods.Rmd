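---
title: "Methods: co-expression clustering and cis-regulatory motif discovery"
author: "coexcis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression clustering and cis-regulatory motif discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coexcis)
```

`coexcis` implements the downstream analysis of a bulk RNA-seq stress
experiment — for instance a cereal crop under drought and heat — from
differential-expression (DE) calls to candidate cis-regulatory
elements. This vignette explains each model and procedure, the
parameters that matter, the numerical choices, and what the synthetic
data generators do and do not emulate.

## From DE tables to the final isoform set

Two DE tables from independent quantification/testing methods (for
example an alignment-based count pipeline and a pseudo-alignment
bootstrap pipeline) arrive pre-thresholded by their own FDR rules. The
final DE set is their intersection (`intersect_de_tags()`). The tables
only guarantee shared identifiers; we additionally require the log2
fold change to have the same sign in both, because a transcript called
"up" by one method and "down" by the other is not a reproducible call.
This direction requirement is configurable (`require_same_direction`)
since intersection protocols do not always state it.

Upstream filtering follows the standard counts-per-million rule:
isoforms are kept when CPM ≥ 0.4 in at least half of the samples
(`filter_low_expression()`). "At least half" is implemented as
`ceiling(0.5 * n_samples)` so the criterion reads correctly for odd
sample numbers.

## Hybrid distance and dendrogram pruning

DE isoforms are clustered on their TPM profiles. Pure correlation
distance treats `x` and `x + c` as identical; two isoforms with the
same shape but a 16-fold abundance difference would always co-cluster,
although their promoters may sustain very different outputs and deserve
separate motif analysis. The hybrid distance therefore mixes the two
metrics as a convex combination:

$$ d_{ij} = (1-\alpha)\frac{1-r_{ij}}{2} + \alpha\frac{E_{ij}}{\max E} $$

* `alpha` (default 0.5) weights the max-normalized Euclidean term.
  A multiplicative combination was rejected: it collapses to zero for
  perfectly correlated profiles of different magnitude, which is
  exactly the case the Euclidean term exists to separate.
* Profiles are log2(TPM + 1)-transformed by default
  (`log_transform = TRUE`) to tame the dynamic range of TPM. With
  profiles already on a log scale, pass `log_transform = FALSE`.
* A zero-variance profile has no defined correlation; its correlation
  term is set to the maximum (1) with a warning rather than erroring,
  so a single flat profile cannot abort a run.
* Both terms lie in [0, 1], hence `d` does too; `max E` over the data
  set is the normalizer, so distances are relative to the data at hand.

Trees are built with complete linkage (`stats::hclust`), whose merge
heights are monotone; ties between equal heights resolve by leaf order,
which is fixed by the input, so runs are deterministic.

**Pruning.** With `D0` the mean of all pairwise distances, the tree is
cut at k = 1, 2, … clusters and the smallest k is returned for which at
least 95% of the clusters have an internal average pairwise distance
(recomputed from the distance matrix, not from cophenetic heights,
because "internal average distance" most naturally means the average
over member pairs; singletons count 0) below `1e-5 * D0`. The procedure
always terminates: at k = n every cluster is a singleton.

A consequence worth stating plainly: `1e-5 * D0` is a very strict
threshold. Clusters only qualify when their members are nearly
identical after transformation, so under realistic within-cluster noise
the rule drives k toward many small clusters. The planted-cluster
recovery test therefore uses near-noiseless profiles
(`noise_sd = 1e-6`, `magnitude_spread = 0`, separation 4 log2 units) —
values chosen from this closed-form analysis of the rule, not from the
data: the within-cluster Euclidean term is about
`alpha * noise_sd * sqrt(2 n_samples) / max E` and must fall below
`1e-5 * D0`. With realistic noise (the generator's default
`noise_sd = 0.25`) the pruning rule does not recover planted clusters,
which we regard as a property of the published rule itself, not of this
implementation.

Only clusters with at least 10 distinct genes (after isoform-to-gene
mapping, duplicates collapsed) are taken to motif discovery.

## Promoters

`extract_promoters()` takes the window −1000/+200 nt around the TSS:
for a plus-strand gene `[start − 1000, start + 199]`, for a
minus-strand gene `[end − 199, end + 1000]` reverse-complemented, so
that position 1 of every returned sequence is its most upstream base.
The TSS is defined as position `upstream + 1` of the returned window
(the first base of the downstream segment); conventions differ on
whether "+200" includes the TSS base, so ours is stated here and used
consistently by the generator and the extractor. Windows are clipped at
contig bounds and flagged. Lowercase (repeat-masked) bases are kept in
the output but excluded from all counting and scanning. The
isoform-to-gene step uses a precomputed mapping table; producing that
table (e.g. by high-identity BLAST against a genome assembly) is out of
scope, which keeps the package free of an aligner dependency.

## Word and dyad over-representation

Counting (`count_words()`, `count_dyads()`) is strand-merged: every
valid window contributes one occurrence of the lexicographically
smaller of (word, reverse complement), which is equivalent to scanning
both strands and merging complementary words — and avoids double
counting. Occurrences of the same word overlapping a previously counted
occurrence are skipped (a poly-A run of length 7 counts one hexamer,
not two); windows containing N or masked bases contribute neither
occurrences nor trials.

Significance (`word_significance()`) is the exact binomial upper tail
with the occurrence prior taken from the whole promoter universe — the
organism-wide upstream-frequency background in spirit, computed from
the supplied universe in practice. For dyads the prior is the product
of the two monad background frequencies (doubled for non-palindromic
merged dyads), so a dyad is judged against what its parts predict, and
a planted spacing shows up against that compositional null. The E-value
multiplies by `n_tested`, the number of distinct merged words of that
length (or distinct merged dyads over all spacings) actually observed
in the background, which matches the words actually tested rather than
the theoretical 4^k/2 inventory. Reported `sig = -log10(E)`, and the
default threshold `sig >= 0` keeps words with E ≤ 1.

Two calibration properties are tested: on background-only clusters the
mean number of words with E ≤ 1 stays below 1 (the binomial tail is
conservative under discreteness, and the cluster being part of the
background adds slight extra conservatism), and cluster sizes of ~15
promoters of 1200 nt against a universe of 200 recover an 8-mer planted
in 80% of the cluster as the top word.

## Matrix construction, scanning and validation

`build_pfm()` collects all occurrences of the top word, plus
occurrences of other significant words that align to it with at most
two mismatches over their overlap (either strand); each aligned
occurrence contributes the full-width genomic window re-framed on the
top word, so shorter words extend with their real context. Counts get a
total pseudocount of 1 per column, spread equally. The IUPAC consensus
includes every base with column frequency ≥ 0.25 and is lowercased
where the best base stays below 0.5, giving the familiar mixed-case
degenerate strings.

`matrix_scan()` scores every window on both strands with
`sum_i log2(f[b_i, i] / p[b_i])` in bits. Two evidences support a
discovered motif:

1. **Negative controls** (`negative_control_support()`): random gene
   sets of identical size are drawn from the universe and re-analysed;
   the motif is supported when the real top significance exceeds the
   0.95 quantile of the negative tops. The quantile operationalizes the
   visual "real bar above the control bars" comparison and is
   configurable.
2. **Permuted matrices** (`permutation_support()`): the null motifs are
   column-order shuffles of the matrix, preserving per-column
   composition and total information content — the standard reading of
   matrix-permutation nulls. The statistic is the median over sequences
   of the per-sequence best score (optionally including a second
   promoter set, e.g. orthologous promoters of a related species);
   support is the fraction of permutations scoring strictly below the
   real motif. An information-free matrix (all columns identical) has
   no meaningful permutations and returns 0 with a warning.

`compare_motifs_ncor()` slides one frequency matrix along the other
(and its reverse complement) over all ungapped offsets with ≥ 4
aligned columns, correlates the concatenated aligned entries, and
normalizes by width: `Ncor = r * overlap / max(w)`. This penalizes
short spurious overlaps and is symmetric in its arguments. Library
annotation simply ranks all library motifs by Ncor; the library ships
in TRANSFAC count-matrix format (a simple reader/writer is included, as
is a MEME-minimal writer).

## Enrichment and qPCR

`fisher_enrichment()` runs a one-sided (greater) Fisher exact test per
term on the cluster-vs-universe 2×2 table, flagging raw p < 0.01. No
multiple-testing correction is applied by default, matching common
practice for exploratory cluster annotation; `correct = TRUE` adds a BH
column. Graph-aware GO algorithms are deliberately not reproduced —
this is the classic per-term test, and the annotation universe is an
explicit argument because protocols differ on whether it should be all
DE genes or all expressed genes.

`fit_efficiency()` fits `Ct = a log10(conc) + b` and reports
`E = 10^(-1/a)` with a validity flag at r² ≥ 0.99 (at least four
distinct dilution points, as in a 1:5 series). `pfaffl_ratio()`
computes `E_t^dCt / NF` with NF the geometric mean of `E_r^dCt_r` over
at least three reference genes. The dCt sign convention is
`Ct(control) − Ct(treated)` so that up-regulation under treatment gives
a ratio above 1; replicate Cts are averaged arithmetically before dCt.
Reference genes are selected as the non-DE isoforms with the smallest
coefficient of variation across samples
(`select_reference_isoforms()`), ties broken toward higher mean.

## Synthetic data: what it emulates, what it does not

* **Expression** (`make_expression_matrix()`): Gaussian cluster-center
  profiles on the log2 scale, per-isoform magnitude offsets, Gaussian
  noise, exponentiated to TPM — multiplicative noise, planted labels.
  Defaults (60 isoforms, 14 samples, 3 clusters, separation 4,
  magnitude spread 0.5, noise 0.25) are sized like one tissue of a
  two-genotype stress study. Not emulated: count overdispersion,
  library-size effects, correlated replicates.
* **Genomes** (`make_promoter_genome()`): contigs of ~20 genes on both
  strands with ≥ 2 kb spacers so promoter windows never overlap
  neighbouring genes; background is an order-0 (i.i.d.) base
  composition — the order-k option collapses to i.i.d. when fitted to a
  base composition, so higher orders are rejected rather than silently
  approximated. Planted IUPAC motifs are instantiated per occurrence,
  on random strands, within the upstream segment, and recorded
  promoter-relative. Not emulated: repeats (masking is exercised with
  hand-written fixtures), GC heterogeneity, real TSS uncertainty —
  so passing tests show the machinery is correct, not that real
  promoters are this easy.
* **DE tables, annotations, qPCR plates**: concordant/discordant call
  bookkeeping; per-term Bernoulli annotation with one odds-multiplied
  term; Ct values constructed from known ratios and efficiencies so the
  noiseless round-trip is exact.

All generators are deterministic given `seed`, and every generated file
parses back through the corresponding reader without loss.

## Problem sizes and determinism

The bundled tests and the acceptance script run desk-scale versions of
each analysis: 200-promoter universes of 1200 nt, 15-gene clusters, 50
negative controls, 100 matrix permutations, 50 calibration draws, 100
null annotation maps. These sizes were chosen so the full statistical
behaviour (recovery, calibration, type-I rates) is visible while a
complete run stays within a few minutes on a single CPU. Every
stochastic stage takes an explicit seed, and identical seeds give
byte-identical outputs end to end.

## Known limitations

* The pruning threshold interacts with noise as discussed above; users
  clustering noisy data may want a larger `rel_threshold` and should
  treat the default as the published rule rather than a robust one.
* The exact functional form of the published Pearson/Euclidean
  weighting is not recorded anywhere we could verify; the convex
  combination with `alpha` is this package's documented choice, not an
  assertion about the original.
* Motif comparison is ungapped; motifs related by indels will score
  low.
* The dyad prior assumes monad independence; strongly autocorrelated
  backgrounds would need a higher-order background than the generator
  provides.
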