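## Numerically stable log-space helpers used by the colocalization engine.

#' Log-sum-exp
#'
#' Computes `log(sum(exp(x)))` without overflow. Per-SNP log Bayes factors in
#' strong eQTL regions reach several hundred (z up to ~40), so hypothesis sums
#' must never leave log space.
#'
#' @param x Numeric vector.
#' @return A length-1 numeric.
#' @keywords internal
logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log of a difference of exponentials
#'
#' `log(exp(a) - exp(b))` for `a >= b`; returns `-Inf` when the difference
#' underflows (used for the cross term L1*L2 - L12, which is exactly zero for
#' a single-SNP region).
#'
#' @keywords internal
logDiffExp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

## Two-sided normal tail probability for a z statistic.
#' @keywords internal
zToP <- function(z) 2 * stats::pnorm(-abs(z))

## Strip an optional "chr" prefix so chromosome labels compare consistently.
#' @keywords internal
normChrom <- function(chrom) sub("^chr", "", as.character(chrom), ignore.case = TRUE)
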