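## Bayesian colocalization over a cis region: per-SNP log approximate Bayes
## factors (Wakefield ABFs) and posterior probabilities of the five
## hypotheses H0..H4, evaluated entirely in log space because strong eQTLs
## reach |z| ~ 40 and the naive exponentials overflow.

#' Colocalization priors
#'
#' Per-SNP prior probabilities of association: `p1` (trait 1 only), `p2`
#' (trait 2 only), `p12` (shared causal variant), plus the prior standard
#' deviations of true effects used in the ABFs: `wQuant` for quantitative
#' traits (per-SD scale) and `wCc` for case-control traits (log-odds scale).
#'
#' Defaults for the p-priors are 5e-4 / 5e-4 / 5e-5. Note these are the
#' values used by the analysis this package implements; the reference
#' implementation of the ABF method ships 1e-4 / 1e-4 / 1e-5, so results are
#' not directly comparable to runs under those defaults.
#'
#' @param p1,p2,p12 Per-SNP prior fractions; a warning is issued when
#'   `p12 > min(p1, p2)`, which is rarely a sensible prior.
#' @param wQuant,wCc Prior effect SDs (defaults 0.15 and 0.2).
#' @return Named list of priors.
#' @export
colocPriors <- function(p1 = 5e-4, p2 = 5e-4, p12 = 5e-5,
                        wQuant = 0.15, wCc = 0.2) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, wQuant > 0, wCc > 0)
  if (p12 > min(p1, p2)) {
    warning("p12 exceeds min(p1, p2); shared-variant prior larger than single-trait priors",
            call. = FALSE)
  }
  list(p1 = p1, p2 = p2, p12 = p12, wQuant = wQuant, wCc = wCc)
}

#' Extract the region around an anchor variant
#'
#' Returns records on the anchor's chromosome whose position lies within
#' `halfWindowBp` of the anchor (boundaries inclusive). The analysis window
#' around an instrument is anchor +/- 500 kb by default.
#'
#' @param sumstats Data frame of canonical records.
#' @param anchorVariant Variant id present in `sumstats`.
#' @param halfWindowBp Half-window in bp (default 5e5).
#' @return The records inside the window.
#' @export
extractRegion <- function(sumstats, anchorVariant, halfWindowBp = 5e5) {
  i <- match(anchorVariant, sumstats$variant_id)
  if (is.na(i)) stop("anchor variant ", anchorVariant, " not found in summary statistics")
  keep <- normChrom(sumstats$chrom) == normChrom(sumstats$chrom[i]) &
    abs(sumstats$pos - sumstats$pos[i]) <= halfWindowBp
  out <- sumstats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP log approximate Bayes factor
#'
#' Wakefield's approximate Bayes factor against the null for a single
#' variant, on the log scale. With `V = se^2`, `W = priorSd^2` and
#' `z = beta/se`:
#' \deqn{\log ABF = \frac{1}{2}\left[\log\frac{V}{V+W} + z^2\frac{W}{V+W}\right]}
#'
#' @param beta,se Effect and standard error (vectorized).
#' @param priorSd Prior SD of the true effect (see [colocPriors()]).
#' @return Numeric vector of log ABFs.
#' @export
logAbf <- function(beta, se, priorSd) {
  stopifnot(all(se > 0), priorSd >= 0)
  V <- se^2
  W <- priorSd^2
  z2 <- (beta / se)^2
  0.5 * (log(V / (V + W)) + z2 * W / (V + W))
}

#' Posterior probabilities of the five colocalization hypotheses
#'
#' Combines per-SNP log ABFs for two traits over the same ordered variant set
#' into posteriors for H0 (neither associated), H1/H2 (one trait only),
#' H3 (both, distinct variants), H4 (both, shared variant). Writing
#' `L1 = sum(exp(labf1))`, `L2 = sum(exp(labf2))`,
#' `L12 = sum(exp(labf1 + labf2))`, the unnormalized hypothesis weights are
#' `1`, `p1 L1`, `p2 L2`, `p1 p2 (L1 L2 - L12)` and `p12 L12`; all sums are
#' evaluated with log-sum-exp.
#'
#' @param labf1,labf2 Equal-length log-ABF vectors over the common variants.
#' @param priors A [colocPriors()] list.
#' @param window Optional region label carried into the result.
#' @return A [ColocResult-class] object.
#' @export
colocPosteriors <- function(labf1, labf2, priors = colocPriors(),
                            window = NA_character_) {
  if (length(labf1) != length(labf2)) {
    stop("labf1 and labf2 must cover the same variants (length mismatch)")
  }
  if (length(labf1) == 0) stop("no variants to colocalize")
  l1 <- logSumExp(labf1)
  l2 <- logSumExp(labf2)
  l12 <- logSumExp(labf1 + labf2)
  lw <- c(
    0,
    log(priors$p1) + l1,
    log(priors$p2) + l2,
    log(priors$p1) + log(priors$p2) + logDiffExp(l1 + l2, l12),
    log(priors$p12) + l12
  )
  pp <- exp(lw - logSumExp(lw))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  new("ColocResult", pp = pp, nSnps = length(labf1),
      labf1 = as.numeric(labf1), labf2 = as.numeric(labf2),
      window = as.character(window))
}

#' Run colocalization for two traits around an anchor
#'
#' Extracts the +/- `halfWindowBp` region around the anchor from both traits,
#' intersects to the variants present in both, computes per-SNP log ABFs with
#' the trait-appropriate prior SD, and returns the hypothesis posteriors.
#'
#' @param trait1,trait2 Data frames of canonical records (trait 1 is
#'   conventionally the eQTL / quantitative trait).
#' @param anchorVariant Variant id present in `trait1`.
#' @param halfWindowBp Half-window in bp (default 5e5).
#' @param priors A [colocPriors()] list.
#' @param traitTypes Length-2 character, each `"quant"` or `"cc"`, selecting
#'   `wQuant` or `wCc` as the ABF prior SD per trait.
#' @return A [ColocResult-class] object.
#' @export
runColoc <- function(trait1, trait2, anchorVariant, halfWindowBp = 5e5,
                     priors = colocPriors(), traitTypes = c("quant", "cc")) {
  traitTypes <- match.arg(traitTypes, c("quant", "cc"), several.ok = TRUE)
  stopifnot(length(traitTypes) == 2)
  r1 <- extractRegion(trait1, anchorVariant, halfWindowBp)
  common <- intersect(r1$variant_id, trait2$variant_id)
  if (length(common) == 0) stop("no variants shared between the two traits in the region")
  r1 <- r1[match(common, r1$variant_id), , drop = FALSE]
  r2 <- trait2[match(common, trait2$variant_id), , drop = FALSE]
  sdFor <- function(type) if (type == "quant") priors$wQuant else priors$wCc
  i <- match(anchorVariant, r1$variant_id)
  win <- if (!is.na(i)) {
    sprintf("%s:%d-%d", r1$chrom[i],
            max(1, r1$pos[i] - halfWindowBp), r1$pos[i] + halfWindowBp)
  } else NA_character_
  colocPosteriors(
    logAbf(r1$beta, r1$se, sdFor(traitTypes[1])),
    logAbf(r2$beta, r2$se, sdFor(traitTypes[2])),
    priors = priors, window = win
  )
}

#' Does a region pass the colocalization threshold?
#'
#' Strict comparison: the pair colocalizes when the posterior probability of
#' a shared causal variant exceeds the threshold (`PP4 > threshold`,
#' default 0.70).
#'
#' @param result A [ColocResult-class] object.
#' @param threshold Posterior threshold in (0, 1).
#' @return Logical.
#' @export
colocPass <- function(result, threshold = 0.70) {
  unname(posteriors(result)["PP4"] > threshold)
}
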