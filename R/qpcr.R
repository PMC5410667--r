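#' Amplification efficiency from a dilution series
#'
#' Fits `Ct = a * log10(concentration) + b` by least squares and derives
#' the efficiency `E = 10^(-1/a)`. An assay is flagged valid when the fit
#' has r-squared of at least `r2_threshold` (default 0.99, the usual
#' calibration-curve requirement for a 1:5 dilution series with at least
#' four points).
#'
#' @param log10_conc log10 relative concentrations (>= 4 distinct
#'   points).
#' @param ct measured Ct values, same length.
#' @param r2_threshold validity threshold on r-squared.
#' @return list (class `dilution_series`): slope, intercept, r_squared,
#'   efficiency, valid.
#' @export
fit_efficiency <- function(log10_conc, ct, r2_threshold = 0.99) {
  stopifnot(length(log10_conc) == length(ct))
  if (length(unique(log10_conc)) < 4)
    stop("need at least 4 distinct dilution points")
  fit <- stats::lm(ct ~ log10_conc)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("invalid assay: non-negative slope (Ct must fall with ",
         "concentration)")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ct - mean(ct))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope),
                 valid = r2 >= r2_threshold),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf(
    "dilution_series: slope %.4f, E = %.4f, r2 = %.5f (%s)\n",
    x$slope, x$efficiency, x$r_squared,
    if (x$valid) "valid" else "below r2 threshold"))
  invisible(x)
}

#' Efficiency-corrected relative expression ratio
#'
#' Relative quantification with per-gene amplification efficiencies,
#' normalized by the geometric mean of (at least three) reference genes:
#'
#' \deqn{ratio = E_t^{\Delta Ct_t} / \sqrt[n]{\prod_i E_{r,i}^{\Delta Ct_{r,i}}}}
#'
#' with `dCt = Ct_control - Ct_treated`, so up-regulation under
#' treatment gives a ratio above 1.
#'
#' @param e_target target-gene efficiency (> 1).
#' @param dct_target target-gene delta-Ct (control minus treated).
#' @param e_refs numeric vector of reference efficiencies (>= 3, > 1).
#' @param dct_refs reference delta-Ct values, same length.
#' @return list: ratio, log2_ratio, normalization_factor.
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_refs, dct_refs) {
  stopifnot(length(e_refs) == length(dct_refs))
  if (length(e_refs) < 3)
    stop("at least three reference genes are required")
  if (e_target <= 1 || any(e_refs <= 1))
    stop("all amplification efficiencies must exceed 1")
  nf <- exp(mean(dct_refs * log(e_refs)))   # geometric mean of E^dCt
  ratio <- e_target^dct_target / nf
  list(ratio = ratio, log2_ratio = log2(ratio),
       normalization_factor = nf)
}

#' Relative expression from a Ct plate
#'
#' Averages replicate Ct values per gene and condition, forms
#' `dCt = Ct(control) - Ct(treated)` and applies [pfaffl_ratio()].
#'
#' @param plate data.frame with columns gene, condition
#'   ("control"/"treated"), Ct (replicate rows allowed), e.g. from
#'   [make_qpcr_plate()].
#' @param target_gene gene to quantify.
#' @param reference_genes character vector (>= 3).
#' @param efficiencies named efficiencies covering target and
#'   references.
#' @return list as [pfaffl_ratio()], plus `dct_target`.
#' @export
pfaffl_from_plate <- function(plate, target_gene, reference_genes,
                              efficiencies) {
  stopifnot(all(c("gene", "condition", "Ct") %in% names(plate)))
  genes <- c(target_gene, reference_genes)
  stopifnot(all(genes %in% plate$gene),
            all(genes %in% names(efficiencies)))
  mean_ct <- function(g, cond)
    mean(plate$Ct[plate$gene == g & plate$condition == cond])
  dct <- vapply(genes, function(g)
    mean_ct(g, "control") - mean_ct(g, "treated"), numeric(1))
  out <- pfaffl_ratio(efficiencies[[target_gene]], dct[[target_gene]],
                      unname(efficiencies[reference_genes]),
                      unname(dct[reference_genes]))
  out$dct_target <- dct[[target_gene]]
  out
}
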