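## Phenome-wide pleiotropy assessment: MR-PheWAS scan of every instrument
## against a panel of traits, enrichment of colocalization among
## brain-related traits, a permutation null for cross-disease effect
## sharing, and the molecular (multi-gene, cis) pleiotropy scan.

#' MR-PheWAS scan
#'
#' Computes a Wald ratio for every instrument x trait cell, labels each cell
#' with its trait category (brain-related vs other), and optionally runs
#' colocalization for cells with nominal MR evidence (`p < alpha`); cells
#' above `alpha` are never colocalized.
#'
#' @param instruments Data frame of standardized instruments (`beta_std`,
#'   `se_std`, canonical columns, `gene_id`).
#' @param traits Named list of canonical summary-statistics data frames, one
#'   per trait.
#' @param categories Named character vector mapping trait names to
#'   `"brain"` or `"other"`; category membership is configuration, not
#'   computation.
#' @param alpha Nominal threshold gating colocalization follow-up
#'   (default 0.05).
#' @param colocCfg Optional list enabling per-cell colocalization:
#'   `eqtl` (regional eQTL records for the instruments' genes),
#'   `halfWindowBp`, `priors`, `threshold`.
#' @return Data frame with one row per instrument x trait cell present in
#'   the trait data: identifiers, `category`, `wr`, `se`, `p`, `pp4`,
#'   `coloc_pass` (`NA` when colocalization was not attempted).
#' @export
phewasScan <- function(instruments, traits, categories, alpha = 0.05,
                       colocCfg = NULL) {
  stopifnot(is.list(traits), !is.null(names(traits)))
  missingCat <- setdiff(names(traits), names(categories))
  if (length(missingCat)) {
    stop("no category label for trait(s): ", paste(missingCat, collapse = ", "))
  }
  cells <- list()
  for (traitName in names(traits)) {
    tdf <- traits[[traitName]]
    h <- harmonizeSumstats(instruments, tdf)
    if (is.null(h) || nrow(h) == 0) next
    w <- waldRatio(h$beta_std, h$beta_outcome, h$se_outcome)
    cell <- data.frame(gene_id = h$gene_id, variant_id = h$variant_id,
                       trait_id = traitName,
                       category = unname(categories[traitName]),
                       wr = w$wr, se = w$se, p = w$p,
                       pp4 = NA_real_, coloc_pass = NA,
                       stringsAsFactors = FALSE)
    if (!is.null(colocCfg)) {
      for (i in which(cell$p < alpha)) {
        gene <- colocCfg$eqtl[colocCfg$eqtl$gene_id == cell$gene_id[i], ,
                              drop = FALSE]
        cr <- tryCatch(
          runColoc(gene, tdf, anchorVariant = cell$variant_id[i],
                   halfWindowBp = colocCfg$halfWindowBp %||% 5e5,
                   priors = colocCfg$priors %||% colocPriors()),
          error = function(e) NULL)
        if (!is.null(cr)) {
          cell$pp4[i] <- posteriors(cr)["PP4"]
          cell$coloc_pass[i] <- colocPass(cr, colocCfg$threshold %||% 0.70)
        }
      }
    }
    cells[[traitName]] <- cell
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Enrichment of colocalization among brain-related traits
#'
#' Builds, at each MR p-value threshold, the 2x2 table of colocalized vs
#' not-colocalized cells split by brain-related vs other traits, and tests it
#' with Fisher's exact test (two-sided: sum of hypergeometric table
#' probabilities no larger than the observed table's).
#'
#' A plain 2x2 matrix can be supplied instead of a PheWAS table, in which
#' case it is tested directly.
#'
#' @param x A [phewasScan()] result with `coloc_pass` filled, or a 2x2
#'   integer matrix (rows: brain/other; columns: colocalized/not).
#' @param strictAlpha,looseAlpha MR thresholds at which a cell counts as
#'   colocalized (given `coloc_pass`); defaults 6e-6 and 0.05.
#' @return For a matrix: list with `table` and `p`. For a PheWAS table: list
#'   with elements `strict` and `loose`, each such a list.
#' @export
enrichmentTest <- function(x, strictAlpha = 6e-6, looseAlpha = 0.05) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == 2))
    return(list(table = x, p = stats::fisher.test(x)$p.value))
  }
  if (!all(c("brain", "other") %in% x$category)) {
    stop("both trait categories must be non-empty")
  }
  at <- function(alpha) {
    hit <- x$p < alpha & !is.na(x$coloc_pass) & x$coloc_pass
    tab <- rbind(brain = c(coloc = sum(hit & x$category == "brain"),
                           not = sum(!hit & x$category == "brain")),
                 other = c(coloc = sum(hit & x$category == "other"),
                           not = sum(!hit & x$category == "other")))
    list(table = tab, p = stats::fisher.test(tab)$p.value)
  }
  list(strict = at(strictAlpha), loose = at(looseAlpha))
}

#' Permutation null for cross-trait effect sharing
#'
#' Asks whether the observed proportion of nominally significant Wald ratios
#' among the primary (brain) outcomes could arise by chance, by repeatedly
#' drawing the same number of traits from the non-brain PheWAS pool and
#' recording the proportion of cells at p < 0.05. The empirical p-value uses
#' the add-one estimator `(1 + #{null >= observed}) / (nIter + 1)`, which
#' cannot return zero.
#'
#' @param phewas A [phewasScan()] result (the pool is its non-brain cells).
#' @param observedCount,observedTotal Observed hits and total Wald ratios
#'   among the primary outcomes (e.g. 141 of 551).
#' @param subsetSize Traits drawn per iteration (default 12).
#' @param nIter Iterations (default 10000).
#' @param seed RNG seed (required: results must be reproducible).
#' @param alpha Per-cell hit threshold (default 0.05).
#' @return A [PermutationOutcome-class] object.
#' @export
sharingPermutation <- function(phewas, observedCount, observedTotal,
                               subsetSize = 12L, nIter = 10000L, seed,
                               alpha = 0.05) {
  if (missing(seed)) stop("sharingPermutation requires an explicit seed")
  if (observedTotal <= 0) stop("observed total must be positive")
  pool <- phewas[phewas$category != "brain", , drop = FALSE]
  traitNames <- unique(pool$trait_id)
  if (subsetSize > length(traitNames)) {
    stop("subsetSize exceeds the number of pool traits")
  }
  hitsPerTrait <- tapply(pool$p < alpha, pool$trait_id, sum)
  cellsPerTrait <- tapply(pool$p, pool$trait_id, length)
  set.seed(seed)
  nullProps <- vapply(seq_len(nIter), function(i) {
    pick <- sample(traitNames, subsetSize)
    sum(hitsPerTrait[pick]) / sum(cellsPerTrait[pick])
  }, numeric(1))
  obsProp <- observedCount / observedTotal
  new("PermutationOutcome",
      observedCount = as.numeric(observedCount),
      observedProp = obsProp,
      nullProps = nullProps,
      empiricalP = (1 + sum(nullProps >= obsProp)) / (nIter + 1),
      ci95 = unname(stats::quantile(nullProps, c(0.025, 0.975))),
      nIter = as.integer(nIter), subsetSize = as.integer(subsetSize),
      poolSize = length(traitNames), seed = as.integer(seed))
}

#' Molecular (cis) pleiotropy of one instrument
#'
#' Extracts every gene's expression effect for the instrument variant with no
#' p-value filter, applies a Bonferroni correction over the number of
#' transcripts extracted, and colocalizes each passing gene's cis signal
#' against the primary outcome.
#'
#' @param variantId Instrument variant.
#' @param eqtlAll Data frame of canonical multi-gene eQTL records.
#' @param outcome Data frame of canonical outcome GWAS records.
#' @param alpha Family-wise rate for the Bonferroni correction (default 0.05).
#' @param priors A [colocPriors()] list.
#' @param pp4Threshold Colocalization pass threshold (default 0.70).
#' @param halfWindowBp Colocalization half-window (default 5e5).
#' @return Data frame with one row per gene carrying the variant: effect,
#'   `p`, `bonferroni`, `passes`, `pp4`, `coloc_pass`. Zero rows (with a
#'   message) when the variant is absent.
#' @export
molecularPleiotropy <- function(variantId, eqtlAll, outcome, alpha = 0.05,
                                priors = colocPriors(), pp4Threshold = 0.70,
                                halfWindowBp = 5e5) {
  rows <- eqtlAll[eqtlAll$variant_id == variantId, , drop = FALSE]
  if (nrow(rows) == 0) {
    message("variant ", variantId, " absent from the multi-gene eQTL data")
    return(data.frame(gene_id = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), bonferroni = numeric(0),
                      passes = logical(0), pp4 = numeric(0),
                      coloc_pass = logical(0)))
  }
  thr <- bonferroniThreshold(alpha, nrow(rows))
  out <- data.frame(gene_id = rows$gene_id, beta = rows$beta, se = rows$se,
                    p = rows$p, bonferroni = thr, passes = rows$p < thr,
                    pp4 = NA_real_, coloc_pass = NA, stringsAsFactors = FALSE)
  for (i in which(out$passes)) {
    gene <- eqtlAll[eqtlAll$gene_id == out$gene_id[i], , drop = FALSE]
    cr <- tryCatch(
      runColoc(gene, outcome, anchorVariant = variantId,
               halfWindowBp = halfWindowBp, priors = priors),
      error = function(e) NULL)
    if (!is.null(cr)) {
      out$pp4[i] <- posteriors(cr)["PP4"]
      out$coloc_pass[i] <- colocPass(cr, pp4Threshold)
    }
  }
  rownames(out) <- NULL
  out
}
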