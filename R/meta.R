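## Fixed-effects inverse-variance meta-analysis with Cochran's Q, used for
## (i) heterogeneity of eQTL effects across brain tissues and (ii) combining
## a case-control GWAS with a rescaled GWAS-by-proxy. Also the cross-dataset
## instrument comparison (Pearson correlation, sign agreement).

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools k effect estimates with weights `1/se^2`. Cochran's Q is
#' `sum(w (beta - beta_fixed)^2)` on k - 1 degrees of freedom; heterogeneity
#' is flagged at the strict threshold `q_p < 0.001`.
#'
#' @param beta,se Per-study effects and standard errors (k >= 2).
#' @return A [MetaResult-class] object.
#' @examples
#' fixedEffectsMeta(c(0.1, 0.2), c(0.02, 0.02))  # beta 0.15, Q = 12.5
#' @export
fixedEffectsMeta <- function(beta, se) {
  if (length(beta) < 2) stop("meta-analysis requires at least 2 effects")
  stopifnot(length(se) == length(beta), all(se > 0))
  w <- 1 / se^2
  bf <- sum(w * beta) / sum(w)
  sef <- 1 / sqrt(sum(w))
  q <- sum(w * (beta - bf)^2)
  df <- length(beta) - 1L
  qp <- stats::pchisq(q, df = df, lower.tail = FALSE)
  new("MetaResult", betaFixed = bf, seFixed = sef, q = q, qDf = df,
      qP = qp, hetFlag = qp < 0.001)
}

#' Compare instrument effects between two eQTL datasets
#'
#' Matches records on (variant, gene), harmonizes dataset B's alleles to
#' dataset A, and reports the Pearson correlation of effect sizes with a
#' Fisher-z 95% CI, the number of B effects reaching `sigThreshold`, and the
#' sign agreement among B effects with nominal evidence (p < 0.05).
#'
#' @param setA,setB Data frames of canonical records with `gene_id`.
#' @param sigThreshold Significance threshold for the "replicated" count
#'   (default 5e-8).
#' @return List with `r`, `ci95`, `n_matched`, `n_sig`, `n_sign_agree`,
#'   `n_sign_disagree`.
#' @export
crossDatasetCompare <- function(setA, setB, sigThreshold = 5e-8) {
  keyA <- paste(setA$variant_id, setA$gene_id)
  keyB <- paste(setB$variant_id, setB$gene_id)
  shared <- intersect(keyA, keyB)
  a <- setA[match(shared, keyA), , drop = FALSE]
  b <- setB[match(shared, keyB), , drop = FALSE]
  if (length(shared) > 0) {
    # fast path: records already on the same effect allele need no work
    aligned <- toupper(a$effect_allele) == toupper(b$effect_allele) &
      toupper(a$other_allele) == toupper(b$other_allele) &
      !isPalindromic(a$effect_allele, a$other_allele)
    h <- lapply(which(!aligned), function(i) harmonizePair(a[i, ], b[i, ]))
    keepH <- !vapply(h, function(x) startsWith(x$action, "dropped"), logical(1))
    bBeta <- c(b$beta[aligned],
               vapply(h[keepH], function(x) x$outcome$beta, numeric(1)))
    bP <- c(b$p[aligned], vapply(h[keepH], function(x) x$outcome$p, numeric(1)))
    a <- rbind(a[aligned, , drop = FALSE],
               a[which(!aligned)[keepH], , drop = FALSE])
  } else {
    bBeta <- numeric(0); bP <- numeric(0)
  }
  n <- nrow(a)
  if (n <= 3) stop("need more than 3 matched pairs for a Fisher-z CI")
  r <- stats::cor(a$beta, bBeta)
  zr <- atanh(r)
  halfWidth <- stats::qnorm(0.975) / sqrt(n - 3)
  ci <- tanh(c(zr - halfWidth, zr + halfWidth))
  nominal <- bP < 0.05
  agree <- sign(a$beta) == sign(bBeta)
  list(r = r, ci95 = ci, n_matched = n,
       n_sig = sum(bP < sigThreshold),
       n_sign_agree = sum(nominal & agree),
       n_sign_disagree = sum(nominal & !agree))
}

#' Rescale GWAS-by-proxy effects to the case-control scale
#'
#' A family-history ("by proxy") GWAS dilutes the log-odds effect roughly by
#' half, so effect sizes and standard errors are both multiplied by two
#' before meta-analysis with a conventional case-control GWAS. The z-score,
#' and hence the p-value, is unchanged.
#'
#' @param records Data frame of canonical records on the log-odds scale.
#' @param factor Rescaling factor (default 2).
#' @return The records with `beta` and `se` rescaled.
#' @export
proxyGwasScale <- function(records, factor = 2) {
  records$beta <- records$beta * factor
  records$se <- records$se * factor
  records
}

#' Meta-analyze a case-control GWAS with a rescaled proxy GWAS
#'
#' Per-variant fixed-effects meta-analysis of the two studies after allele
#' harmonization. Variants present in only one study are passed through
#' unchanged with `meta_status = "single_study"` rather than dropped, so the
#' combined GWAS keeps full coverage.
#'
#' @param caseGwas Data frame of canonical case-control records.
#' @param proxyGwas Data frame of canonical records already rescaled with
#'   [proxyGwasScale()].
#' @return Data frame of canonical records with `meta_status` (`"meta"` or
#'   `"single_study"`); for meta-analyzed variants `n` is the sum of the two
#'   study sizes and `p` comes from the pooled z.
#' @export
proxyMeta <- function(caseGwas, proxyGwas) {
  cols <- intersect(intersect(sumstatsColumns(), names(caseGwas)),
                    names(proxyGwas))
  h <- harmonizeSumstats(caseGwas, proxyGwas)
  sharedIds <- if (is.null(h)) character(0) else h$variant_id
  metaRows <- if (length(sharedIds)) {
    do.call(rbind, lapply(seq_len(nrow(h)), function(i) {
      m <- fixedEffectsMeta(c(h$beta[i], h$beta_outcome[i]),
                            c(h$se[i], h$se_outcome[i]))
      row <- h[i, cols, drop = FALSE]
      row$beta <- m@betaFixed
      row$se <- m@seFixed
      row$p <- zToP(m@betaFixed / m@seFixed)
      row$n <- h$n[i] + h$n_outcome[i]
      row$meta_status <- "meta"
      row
    }))
  } else NULL
  only <- function(x) {
    x <- x[!x$variant_id %in% sharedIds, cols, drop = FALSE]
    x$meta_status <- rep("single_study", nrow(x))
    x
  }
  out <- rbind(metaRows, only(caseGwas), only(proxyGwas))
  rownames(out) <- NULL
  out
}
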