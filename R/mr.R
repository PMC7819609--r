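## Mendelian randomization estimators: single-SNP Wald ratio (the primary
## analysis, since each gene is instrumented by one clumped cis-eQTL) and
## the multi-SNP IVW / Egger / weighted-median estimators used for reverse MR.

#' Wald ratio estimate
#'
#' Single-instrument MR estimator: the outcome effect divided by the exposure
#' effect. With a standardized eQTL exposure and a log-odds outcome, the
#' ratio is the log odds change in disease risk per SD change in gene
#' expression; a positive value means higher expression raises risk.
#'
#' The default standard error is the first-order delta approximation
#' `se_outcome / |beta_exposure|`. Supplying `seExposure` adds the
#' exposure-uncertainty term,
#' `se = sqrt(se_o^2/b_x^2 + b_o^2 se_x^2 / b_x^4)`, which matters for
#' confidence-interval coverage when the instrument z-statistic is modest
#' (below ~10); see the package vignette.
#'
#' @param betaExposure Exposure effect (per-SD expression), non-zero.
#' @param betaOutcome Outcome effect (log-odds).
#' @param seOutcome Outcome standard error.
#' @param seExposure Optional exposure standard error enabling the
#'   second-order delta SE.
#' @return Data frame with columns `wr`, `se`, `p` (two-sided normal).
#'   Vectorized over all arguments.
#' @export
waldRatio <- function(betaExposure, betaOutcome, seOutcome, seExposure = NULL) {
  if (any(betaExposure == 0)) stop("undefined ratio: exposure effect is zero")
  wr <- betaOutcome / betaExposure
  se <- seOutcome / abs(betaExposure)
  if (!is.null(seExposure)) {
    se <- sqrt(seOutcome^2 / betaExposure^2 +
               betaOutcome^2 * seExposure^2 / betaExposure^4)
  }
  data.frame(wr = wr, se = se, p = zToP(wr / se))
}

#' Wald ratios for a harmonized table
#'
#' Applies [waldRatio()] to each row of a [harmonizeSumstats()] result whose
#' exposure has been standardized, and flags Bonferroni survivors.
#'
#' @param harmonized Data frame with columns `beta_std` (exposure),
#'   `beta_outcome`, `se_outcome` and identifiers.
#' @param alpha Family-wise error rate (default 0.05).
#' @param nTests Number of MR tests behind the Bonferroni correction
#'   (default: number of rows).
#' @param seExposure Logical; include the exposure-uncertainty SE term using
#'   `se_std` (default FALSE, the plain first-order ratio SE).
#' @return Data frame of Wald results with `passes_bonferroni`.
#' @export
mrWald <- function(harmonized, alpha = 0.05, nTests = nrow(harmonized),
                   seExposure = FALSE) {
  w <- waldRatio(harmonized$beta_std, harmonized$beta_outcome,
                 harmonized$se_outcome,
                 seExposure = if (seExposure) harmonized$se_std else NULL)
  ids <- intersect(c("gene_id", "variant_id"), names(harmonized))
  out <- harmonized[, ids, drop = FALSE]
  traitCol <- intersect(c("trait_id_outcome", "trait_id"), names(harmonized))[1]
  if (!is.na(traitCol)) out$trait_id <- harmonized[[traitCol]]
  out <- cbind(out, w)
  out$passes_bonferroni <- out$p < bonferroniThreshold(alpha, nTests)
  rownames(out) <- NULL
  out
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param nTests Number of tests (>= 1).
#' @return `alpha / nTests`, at full precision (display rounding is left to
#'   reports).
#' @examples
#' bonferroniThreshold(0.05, 80557)   # ~6.2e-7
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  stopifnot(nTests >= 1)
  alpha / nTests
}

#' @keywords internal
.checkPairs <- function(bx, by, seBy, minN, method) {
  if (length(bx) < minN) {
    stop(sprintf("%s requires at least %d instruments, got %d",
                 method, minN, length(bx)))
  }
  stopifnot(length(by) == length(bx), length(seBy) == length(bx),
            all(seBy > 0))
}

#' Inverse-variance weighted MR
#'
#' Zero-intercept regression of outcome effects on exposure effects with
#' weights `1/se_outcome^2`. The SE uses the multiplicative random-effects
#' residual scale, floored at 1 so that under-dispersion never shrinks it
#' below the fixed-effects value.
#'
#' @param bx,by Exposure and outcome effects per instrument.
#' @param seBy Outcome standard errors.
#' @return One-row data frame: `method`, `slope`, `slope_se`, `p`, `n_snps`.
#' @export
mrIvw <- function(bx, by, seBy) {
  .checkPairs(bx, by, seBy, 2L, "IVW")
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / seBy^2)
  sm <- summary(fit)
  se <- sm$coefficients[1, 2] / min(1, sm$sigma)
  slope <- sm$coefficients[1, 1]
  data.frame(method = "ivw", slope = slope, slope_se = se,
             p = zToP(slope / se), n_snps = length(bx),
             intercept = NA_real_, intercept_se = NA_real_)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free intercept;
#' a non-zero intercept indicates directional horizontal pleiotropy.
#' Instruments are oriented so all exposure effects are positive before
#' fitting. Inference uses the t distribution on n - 2 df.
#'
#' @inheritParams mrIvw
#' @return One-row data frame with `intercept` and `intercept_se` filled.
#' @export
mrEgger <- function(bx, by, seBy) {
  .checkPairs(bx, by, seBy, 3L, "MR-Egger")
  s <- sign(bx); s[s == 0] <- 1
  byO <- by * s; bxO <- abs(bx)
  fit <- stats::lm(byO ~ bxO, weights = 1 / seBy^2)
  sm <- summary(fit)
  scale <- min(1, sm$sigma)
  slope <- sm$coefficients[2, 1]
  slopeSe <- sm$coefficients[2, 2] / scale
  int <- sm$coefficients[1, 1]
  intSe <- sm$coefficients[1, 2] / scale
  df <- length(bx) - 2L
  data.frame(method = "egger", slope = slope, slope_se = slopeSe,
             p = 2 * stats::pt(-abs(slope / slopeSe), df = df),
             n_snps = length(bx), intercept = int, intercept_se = intSe)
}

#' @keywords internal
weightedMedianEstimate <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(r[1])
  if (cs[length(cs)] <= 0.5) return(r[length(r)])
  below <- max(which(cs < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - cs[below]) / (cs[below + 1] - cs[below])
}

#' Weighted-median MR
#'
#' Inverse-variance-weighted median of the per-SNP Wald ratios; consistent
#' when instruments contributing at least half the weight are valid, so a
#' single gross outlier does not move it the way it moves IVW. The SE comes
#' from a seeded parametric bootstrap that redraws the outcome (and, when
#' `seBx` is given, the exposure) effects from their sampling distributions.
#'
#' @inheritParams mrIvw
#' @param seBx Optional exposure standard errors (bootstrap redraws exposure
#'   effects too when supplied).
#' @param nBoot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap; required for reproducibility.
#' @return One-row data frame as for [mrIvw()].
#' @export
mrWeightedMedian <- function(bx, by, seBy, seBx = NULL, nBoot = 1000L, seed) {
  .checkPairs(bx, by, seBy, 2L, "weighted median")
  if (missing(seed)) stop("weighted-median bootstrap requires an explicit seed")
  ratios <- by / bx
  w <- (bx / seBy)^2          # 1 / var(ratio) to first order
  est <- weightedMedianEstimate(ratios, w)
  set.seed(seed)
  ests <- vapply(seq_len(nBoot), function(i) {
    byB <- stats::rnorm(length(by), by, seBy)
    bxB <- if (is.null(seBx)) bx else stats::rnorm(length(bx), bx, seBx)
    bxB[bxB == 0] <- .Machine$double.eps
    weightedMedianEstimate(byB / bxB, (bxB / seBy)^2)
  }, numeric(1))
  se <- stats::sd(ests)
  p <- if (se == 0) ifelse(est == 0, 1, 0) else zToP(est / se)
  data.frame(method = "weighted_median", slope = est, slope_se = se,
             p = p, n_snps = length(bx),
             intercept = NA_real_, intercept_se = NA_real_)
}
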