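## Cis-eQTL instrument selection: MHC masking, genome-wide significance
## filtering, greedy LD clumping, standardization of effects to a per-SD
## expression scale, and Cragg-Donald instrument strength.

#' Remove variants inside the MHC region
#'
#' The extended major histocompatibility complex has LD structure too complex
#' for reliable instrument selection and colocalization; variants inside it
#' are excluded up front. Default bounds are chr6:24,000,000-36,000,000
#' (hg19), inclusive.
#'
#' @param records Data frame of canonical records.
#' @param chrom Chromosome holding the mask.
#' @param startBp,endBp Inclusive 1-based bounds.
#' @return The records outside the masked interval.
#' @export
maskMhc <- function(records, chrom = "6", startBp = 24e6, endBp = 36e6) {
  if (nrow(records) == 0) return(records)
  inside <- normChrom(records$chrom) == normChrom(chrom) &
    records$pos >= startBp & records$pos <= endBp
  records[!inside, , drop = FALSE]
}

#' Keep genome-wide significant records
#'
#' Strict inequality: a record at exactly the threshold is excluded.
#'
#' @param records Data frame of canonical records.
#' @param pThreshold Significance threshold (default 5e-8).
#' @return Records with `p < pThreshold`.
#' @export
significanceFilter <- function(records, pThreshold = 5e-8) {
  records[records$p < pThreshold, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining record with the lowest p-value (the index
#' SNP) and removes all records with `r^2 > r2Threshold` to it that lie within
#' half the window on either side, until no records remain. Ties on p are
#' broken by (chrom, pos, variant_id) order for determinism. Records absent
#' from the LD reference are dropped with a warning before clumping, since
#' their correlation to the index SNPs cannot be assessed.
#'
#' @param records Data frame of canonical records (one gene's cis region).
#' @param ld An [LdReference-class] covering the retained variants.
#' @param r2Threshold Pairwise r-squared above which a record is removed
#'   (default 0.001).
#' @param windowBp Total window width in bp centred on the index SNP
#'   (default 1e7, i.e. +/- 5 Mb).
#' @return The clumped, approximately independent records.
#' @export
clumpVariants <- function(records, ld, r2Threshold = 0.001, windowBp = 1e7) {
  if (nrow(records) == 0) return(records)
  known <- records$variant_id %in% variantIds(ld)
  if (!all(known)) {
    warning(sprintf("dropping %d variant(s) absent from the LD reference before clumping",
                    sum(!known)), call. = FALSE)
    records <- records[known, , drop = FALSE]
  }
  if (nrow(records) == 0) return(records)
  ord <- order(records$p, records$chrom, records$pos, records$variant_id)
  records <- records[ord, , drop = FALSE]
  r2 <- ldMatrix(ld, squared = TRUE)
  keep <- integer(0)
  alive <- rep(TRUE, nrow(records))
  half <- windowBp / 2
  while (any(alive)) {
    i <- which(alive)[1]
    keep <- c(keep, i)
    alive[i] <- FALSE
    cand <- which(alive)
    inWindow <- normChrom(records$chrom[cand]) == normChrom(records$chrom[i]) &
      abs(records$pos[cand] - records$pos[i]) <= half
    rr <- r2[records$variant_id[i], records$variant_id[cand[inWindow]]]
    drop <- cand[inWindow][rr > r2Threshold]
    alive[drop] <- FALSE
  }
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize eQTL effects to a per-SD expression scale
#'
#' Rescales each per-allele effect so that it represents the change in gene
#' expression in standard-deviation units, making MR effect sizes comparable
#' across genes. With `z = beta/se` and `maf = min(eaf, 1 - eaf)`:
#' \deqn{\beta_{std} = z / \sqrt{2\,maf(1-maf)\,(n + z^2)}}
#' \deqn{se_{std} = 1 / \sqrt{2\,maf(1-maf)\,(n + z^2)}}
#'
#' @param records Data frame of canonical records with `eaf` strictly inside
#'   (0, 1) and positive `n`.
#' @return The records with added columns `z`, `beta_std`, `se_std`.
#' @export
standardizeEffects <- function(records) {
  if (any(records$eaf <= 0 | records$eaf >= 1)) {
    stop("degenerate allele frequency: eaf must lie strictly inside (0, 1)")
  }
  z <- records$beta / records$se
  maf <- pmin(records$eaf, 1 - records$eaf)
  denom <- sqrt(2 * maf * (1 - maf) * (records$n + z^2))
  records$z <- z
  records$beta_std <- z / denom
  records$se_std <- 1 / denom
  records
}

#' Instrument strength: PVE and Cragg-Donald F
#'
#' Proportion of exposure variance explained by the instrument and the
#' derived F-statistic:
#' \deqn{PVE = \beta^2 / (\beta^2 + se^2 n)}
#' \deqn{F = PVE (n - 1 - k) / ((1 - PVE) k)}
#' where `k` is the number of instruments in the MR estimate (1 for
#' single-SNP Wald ratios). Both formulas are scale-invariant, so
#' standardized or raw beta/se give the same result. For k = 1 and large n,
#' F approaches z-squared.
#'
#' @param beta,se Effect and standard error (vectorized).
#' @param n Sample size.
#' @param k Number of instruments (default 1).
#' @return Data frame with columns `pve` and `f_stat`.
#' @export
instrumentStrength <- function(beta, se, n, k = 1L) {
  stopifnot(k >= 1)
  pve <- beta^2 / (beta^2 + se^2 * n)
  if (any(pve >= 1)) {
    warning("PVE >= 1 numerically; clipping", call. = FALSE)
    pve <- pmin(pve, 1 - 1e-12)
  }
  f <- pve * (n - 1 - k) / ((1 - pve) * k)
  data.frame(pve = pve, f_stat = f)
}

#' Select cis-eQTL instruments for every gene
#'
#' Full instrument-selection flow: MHC masking, strict significance
#' filtering, per-gene greedy LD clumping, standardization, and instrument
#' strength.
#'
#' @param eqtl Data frame of canonical eQTL records carrying `gene_id`.
#' @param ld An [LdReference-class] covering the cis region(s).
#' @param pThreshold Significance threshold (default 5e-8).
#' @param r2Threshold,windowBp Clumping parameters (defaults 0.001 and 1e7).
#' @param maskMhcRegion Apply the MHC mask first (default TRUE).
#' @return Data frame of instruments: canonical columns plus `z`, `beta_std`,
#'   `se_std`, `pve`, `f_stat`.
#' @export
selectInstruments <- function(eqtl, ld, pThreshold = 5e-8, r2Threshold = 0.001,
                              windowBp = 1e7, maskMhcRegion = TRUE) {
  if (!"gene_id" %in% names(eqtl)) stop("eQTL records must carry gene_id")
  x <- if (maskMhcRegion) maskMhc(eqtl) else eqtl
  x <- significanceFilter(x, pThreshold)
  if (nrow(x) == 0) return(x)
  perGene <- lapply(split(x, x$gene_id), clumpVariants, ld = ld,
                    r2Threshold = r2Threshold, windowBp = windowBp)
  x <- do.call(rbind, perGene)
  if (is.null(x) || nrow(x) == 0) return(x)
  rownames(x) <- NULL
  x <- standardizeEffects(x)
  cbind(x, instrumentStrength(x$beta_std, x$se_std, x$n, k = 1L))
}
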