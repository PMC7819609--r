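#' @import methods
NULL

#' LD reference panel for a region
#'
#' Holds the signed pairwise correlation (r, not r-squared) between variants,
#' as produced from a reference haplotype panel or constructed analytically by
#' [simulateLd()]. r-squared is derived on demand by squaring.
#'
#' @slot variantIds Ordered character vector of variant identifiers.
#' @slot r Symmetric numeric matrix of signed correlations with unit diagonal,
#'   dimnames equal to `variantIds`.
#' @slot buildTag Genome build label carried for provenance (e.g. "hg19");
#'   never used for liftover.
#'
#' @export
setClass("LdReference",
  representation(variantIds = "character", r = "matrix", buildTag = "character"),
  prototype(buildTag = "hg19")
)

setValidity("LdReference", function(object) {
  msg <- character(0)
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "r matrix must be square")
  if (length(object@variantIds) != nrow(r)) {
    msg <- c(msg, "length(variantIds) must equal nrow(r)")
  }
  if (anyDuplicated(object@variantIds)) msg <- c(msg, "variantIds must be unique")
  if (nrow(r) > 0) {
    if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "r matrix must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) msg <- c(msg, "r diagonal must be 1")
    if (max(abs(r)) > 1 + 1e-8) msg <- c(msg, "|r| must be <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Colocalization result for one region pair
#'
#' Posterior probabilities of the five colocalization hypotheses for a pair of
#' traits over a shared set of region variants: H0 (neither trait associated),
#' H1 (trait 1 only), H2 (trait 2 only), H3 (both, distinct causal variants),
#' H4 (both, one shared causal variant).
#'
#' @slot pp Named numeric of length 5 (`PP0`..`PP4`) summing to one.
#' @slot nSnps Number of variants common to both traits that entered the sums.
#' @slot labf1,labf2 Per-SNP log approximate Bayes factors for each trait.
#' @slot window Character description of the region (chrom:start-end), may be
#'   `NA` when the inputs carried no coordinates.
#'
#' @export
setClass("ColocResult",
  representation(pp = "numeric", nSnps = "integer",
                 labf1 = "numeric", labf2 = "numeric", window = "character")
)

setValidity("ColocResult", function(object) {
  msg <- character(0)
  if (length(object@pp) != 5L) msg <- c(msg, "pp must have length 5")
  if (any(object@pp < -1e-12)) msg <- c(msg, "posteriors must be non-negative")
  if (abs(sum(object@pp) - 1) > 1e-9) msg <- c(msg, "posteriors must sum to 1 (tol 1e-9)")
  if (length(object@labf1) != length(object@labf2)) {
    msg <- c(msg, "labf1 and labf2 must have equal length")
  }
  if (length(msg)) msg else TRUE
})

#' Fixed-effects meta-analysis result
#'
#' Inverse-variance-weighted pooled effect with Cochran's Q heterogeneity
#' statistic. `hetFlag` applies the strict P < 0.001 heterogeneity call used
#' when comparing eQTL effects across brain tissues.
#'
#' @slot betaFixed,seFixed Pooled effect and its standard error.
#' @slot q,qDf,qP Cochran's Q, its degrees of freedom (k - 1) and p-value.
#' @slot hetFlag Logical, `qP < 0.001`.
#' @export
setClass("MetaResult",
  representation(betaFixed = "numeric", seFixed = "numeric",
                 q = "numeric", qDf = "integer", qP = "numeric",
                 hetFlag = "logical")
)

setValidity("MetaResult", function(object) {
  msg <- character(0)
  if (object@seFixed <= 0) msg <- c(msg, "seFixed must be positive")
  if (object@q < -1e-12) msg <- c(msg, "Q must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Steiger directionality test result
#'
#' Compares the magnitude of the instrument-exposure correlation with the
#' instrument-outcome correlation to assess whether the causal direction runs
#' from exposure to outcome.
#'
#' @slot rGx,rGy Instrument-exposure and instrument-outcome correlations.
#' @slot nX,nY Sample sizes behind each correlation.
#' @slot directionCorrect Logical, `rGx^2 > rGy^2`.
#' @slot z Two-sample Fisher-z statistic on `|rGx|` vs `|rGy|`.
#' @slot p Two-sided p-value for the correlation difference.
#' @export
setClass("SteigerResult",
  representation(rGx = "numeric", rGy = "numeric", nX = "integer", nY = "integer",
                 directionCorrect = "logical", z = "numeric", p = "numeric")
)

#' Permutation test outcome for cross-trait effect sharing
#'
#' Null distribution of the proportion of nominally significant Wald ratios
#' obtained by repeatedly drawing trait subsets from a non-brain pool.
#'
#' @slot observedCount,observedProp Observed hit count and proportion.
#' @slot nullProps Numeric vector of null proportions, one per iteration.
#' @slot empiricalP `(1 + #{null >= observed}) / (nIter + 1)`.
#' @slot ci95 2.5 and 97.5 percentiles of the null proportions.
#' @slot nIter,subsetSize,poolSize,seed Permutation settings.
#' @export
setClass("PermutationOutcome",
  representation(observedCount = "numeric", observedProp = "numeric",
                 nullProps = "numeric", empiricalP = "numeric",
                 ci95 = "numeric", nIter = "integer", subsetSize = "integer",
                 poolSize = "integer", seed = "integer")
)

setValidity("PermutationOutcome", function(object) {
  msg <- character(0)
  if (object@empiricalP < 0 || object@empiricalP > 1) {
    msg <- c(msg, "empiricalP must lie in [0, 1]")
  }
  if (length(object@ci95) != 2L || object@ci95[1] > object@ci95[2]) {
    msg <- c(msg, "ci95 must be (low, high) with low <= high")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LdReference", function(object) {
  cat(sprintf("LdReference: %d variants (%s)\n",
              length(object@variantIds), object@buildTag))
  if (length(object@variantIds) > 1) {
    off <- abs(object@r[upper.tri(object@r)])
    cat(sprintf("  |r| off-diagonal: mean %.3f, max %.3f\n", mean(off), max(off)))
  }
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("ColocResult over %d SNPs (%s)\n", object@nSnps, object@window))
  pp <- object@pp
  for (i in seq_along(pp)) {
    cat(sprintf("  %s (%s): %.4f\n", names(pp)[i],
                c("no association", "trait 1 only", "trait 2 only",
                  "distinct causal variants", "shared causal variant")[i], pp[i]))
  }
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult: beta %.4g (se %.4g); Q = %.3f on %d df, p = %.3g%s\n",
              object@betaFixed, object@seFixed, object@q, object@qDf, object@qP,
              if (object@hetFlag) " [heterogeneous]" else ""))
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf("SteigerResult: r_gx %.4f (n %d), r_gy %.4f (n %d); %s, z %.2f, p %.3g\n",
              object@rGx, object@nX, object@rGy, object@nY,
              if (object@directionCorrect) "direction exposure->outcome" else
                "direction suspect (outcome->exposure?)",
              object@z, object@p))
})

setMethod("show", "PermutationOutcome", function(object) {
  cat(sprintf(paste0("PermutationOutcome: observed %g/%g = %.3f; null mean %.3f, ",
                     "95%% CI [%.3f, %.3f]; empirical p %.3g (%d iterations)\n"),
              object@observedCount, object@observedCount / max(object@observedProp, 1e-300),
              object@observedProp, mean(object@nullProps),
              object@ci95[1], object@ci95[2], object@empiricalP, object@nIter))
})
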