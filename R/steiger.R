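## Directionality assessment: Steiger filtering (does the instrument explain
## more variance in the exposure than in the outcome?) and reverse MR
## (instrumenting on the disease and testing its effect on expression).

#' Steiger directionality test
#'
#' Compares the instrument-exposure correlation `rGx` with the
#' instrument-outcome correlation `rGy`. The causal direction is taken to run
#' exposure -> outcome when `rGx^2 > rGy^2`. The p-value is a two-sample
#' z-test on the Fisher-transformed absolute correlations, with variance
#' `1/(nX - 3) + 1/(nY - 3)`; it is invariant to the sign of either
#' correlation and antisymmetric in the two inputs.
#'
#' @param rGx,rGy Correlations, strictly inside (-1, 1).
#' @param nX,nY Sample sizes (>= 4).
#' @return A [SteigerResult-class] object.
#' @export
steigerTest <- function(rGx, nX, rGy, nY) {
  if (abs(rGx) >= 1 || abs(rGy) >= 1) stop("correlations must lie strictly inside (-1, 1)")
  stopifnot(nX >= 4, nY >= 4)
  z <- (atanh(abs(rGx)) - atanh(abs(rGy))) / sqrt(1 / (nX - 3) + 1 / (nY - 3))
  new("SteigerResult", rGx = rGx, rGy = rGy,
      nX = as.integer(nX), nY = as.integer(nY),
      directionCorrect = rGx^2 > rGy^2, z = z, p = zToP(z))
}

#' Instrument-trait correlation from summary statistics
#'
#' Converts a single variant's association into a signed correlation suitable
#' for [steigerTest()]. For quantitative traits the correlation is
#' `sign(beta) * sqrt(PVE)` with `PVE = beta^2/(beta^2 + se^2 n)` (the
#' formula is scale-invariant, so raw or standardized effects give the same
#' value). For binary traits the observed-scale approximation `z / sqrt(n)`
#' is used; it preserves the ordering of correlation magnitudes, which is all
#' the directionality filter needs.
#'
#' @param beta,se Effect and standard error (vectorized).
#' @param n Sample size.
#' @param traitKind `"quantitative"` or `"binary"`.
#' @return Numeric vector of signed correlations.
#' @export
rFromAssoc <- function(beta, se, n, traitKind = c("quantitative", "binary")) {
  traitKind <- match.arg(traitKind)
  z <- beta / se
  if (traitKind == "quantitative") {
    sign(beta) * sqrt(beta^2 / (beta^2 + se^2 * n))
  } else {
    z / sqrt(n)
  }
}

#' Steiger filtering for a harmonized instrument table
#'
#' Runs [steigerTest()] per row of a harmonized exposure/outcome table with a
#' standardized exposure.
#'
#' @param harmonized Output of [harmonizeSumstats()] after
#'   [standardizeEffects()] on the exposure side: columns `beta_std`,
#'   `se_std`, `n`, `beta_outcome`, `se_outcome`, `n_outcome`.
#' @param outcomeKind Trait kind of the outcome (default `"binary"`).
#' @return Data frame with `r_gx`, `r_gy`, `direction_correct`, `p_steiger`.
#' @export
steigerFilter <- function(harmonized, outcomeKind = "binary") {
  rGx <- rFromAssoc(harmonized$beta_std, harmonized$se_std, harmonized$n,
                    "quantitative")
  rGy <- rFromAssoc(harmonized$beta_outcome, harmonized$se_outcome,
                    harmonized$n_outcome, outcomeKind)
  res <- mapply(function(gx, gy, nx, ny) {
    s <- steigerTest(gx, nx, gy, ny)
    c(direction_correct = s@directionCorrect, p_steiger = s@p)
  }, rGx, rGy, harmonized$n, harmonized$n_outcome)
  cbind(harmonized, r_gx = rGx, r_gy = rGy,
        direction_correct = as.logical(res["direction_correct", ]),
        p_steiger = as.numeric(res["p_steiger", ]))
}

#' Reverse MR: disease as exposure, gene expression as outcome
#'
#' Selects instruments for the disease from its GWAS (strict genome-wide
#' significance then greedy LD clumping), harmonizes them against the eQTL
#' dataset, and estimates the effect of the disease on each gene's expression
#' with the requested multi-SNP estimators. With a single surviving
#' instrument the Wald ratio is used and flagged.
#'
#' @param gwas Data frame of canonical disease GWAS records.
#' @param eqtl Data frame of canonical eQTL records (must carry `gene_id`).
#' @param ld An [LdReference-class] for clumping the GWAS instruments.
#' @param pThreshold Instrument significance threshold (default 5e-8).
#' @param r2Threshold,windowBp Clumping parameters.
#' @param methods Estimators to run, subset of `c("ivw", "egger",
#'   "weighted_median")`.
#' @param nBoot,seed Weighted-median bootstrap settings.
#' @return Data frame of multi-SNP results, one row per gene x method, with
#'   a `single_snp` flag; zero rows (with a message) when no instrument
#'   survives selection.
#' @export
reverseMr <- function(gwas, eqtl, ld, pThreshold = 5e-8, r2Threshold = 0.001,
                      windowBp = 1e7, methods = c("ivw", "egger", "weighted_median"),
                      nBoot = 1000L, seed = 1L) {
  methods <- match.arg(methods, c("ivw", "egger", "weighted_median"),
                       several.ok = TRUE)
  inst <- clumpVariants(significanceFilter(gwas, pThreshold), ld,
                        r2Threshold, windowBp)
  empty <- data.frame(gene_id = character(0), method = character(0),
                      slope = numeric(0), slope_se = numeric(0), p = numeric(0),
                      n_snps = integer(0), intercept = numeric(0),
                      intercept_se = numeric(0), single_snp = logical(0))
  if (nrow(inst) == 0) {
    message("reverse MR: no instruments survive selection")
    return(empty)
  }
  out <- lapply(split(eqtl, eqtl$gene_id), function(gene) {
    h <- harmonizeSumstats(inst, gene)
    if (is.null(h) || nrow(h) == 0) return(NULL)
    bx <- h$beta; by <- h$beta_outcome; seBy <- h$se_outcome
    if (nrow(h) == 1) {
      w <- waldRatio(bx, by, seBy)
      return(data.frame(gene_id = gene$gene_id[1], method = "wald_ratio",
                        slope = w$wr, slope_se = w$se, p = w$p, n_snps = 1L,
                        intercept = NA_real_, intercept_se = NA_real_,
                        single_snp = TRUE))
    }
    res <- list()
    if ("ivw" %in% methods) res <- c(res, list(mrIvw(bx, by, seBy)))
    if ("egger" %in% methods && nrow(h) >= 3) {
      res <- c(res, list(mrEgger(bx, by, seBy)))
    }
    if ("weighted_median" %in% methods) {
      res <- c(res, list(mrWeightedMedian(bx, by, seBy, nBoot = nBoot, seed = seed)))
    }
    res <- do.call(rbind, res)
    cbind(gene_id = gene$gene_id[1], res, single_snp = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
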