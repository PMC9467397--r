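#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, `q_(i) = min_(j >= i) ( p_(j) * m / j )` capped at
#' 1 and mapped back to input order (delegates to [stats::p.adjust()]).
#' Multiple-testing correction in the pipelines is applied within result
#' family only (heritability, Spearman, phenotypic, genetic, environmental
#' correlations each form their own family).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
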