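## Final target triage: direction-of-intervention from the MR sign, the
## three-criterion prioritization (allelic series, druggability, safety
## profile from the PheWAS), and report tables.

#' Recommended drug action from a Wald ratio
#'
#' A positive Wald ratio (higher expression raises risk) points to
#' inhibition of the gene product; a negative ratio points to promotion.
#' Intended for estimates that are significant and colocalized.
#'
#' @param wr Wald ratio estimate(s), non-zero.
#' @return Character vector, `"inhibition"` or `"promotion"`.
#' @export
deriveAction <- function(wr) {
  if (any(wr == 0)) stop("action undefined for a zero Wald ratio")
  ifelse(wr > 0, "inhibition", "promotion")
}

#' Prioritize candidate drug-target genes
#'
#' Applies the three prioritization criteria to MR + colocalization hits:
#' an allelic series (coding variants causing a related monogenic
#' phenotype), druggability (clinical-stage target), and a satisfying safety
#' profile (no colocalized adverse PheWAS trait). Genes meeting
#' `(allelic_series OR druggable) AND safety_ok` are ranked first. Safety
#' flags are reported, not hard-excluded: the judgement of whether a flagged
#' trait disqualifies a target is left to the analyst. Genes missing from
#' the annotation table get all criteria `FALSE`.
#'
#' @param hits Data frame of gate-passing hits with at least `gene_id`,
#'   `trait_id`, `wr`.
#' @param annotations Data frame with columns `gene_id`, `allelic_series`,
#'   `druggable` (logicals) and optionally `adverse_traits` (comma-separated
#'   trait list; non-empty means the safety criterion fails).
#' @return The hits with `action`, `allelic_series`, `druggable`,
#'   `safety_ok`, `criteria_met` (comma-separated) and `prioritized`,
#'   ordered with prioritized genes first.
#' @export
prioritizeTargets <- function(hits, annotations) {
  i <- match(hits$gene_id, annotations$gene_id)
  getFlag <- function(col) {
    v <- if (col %in% names(annotations)) annotations[[col]][i] else NA
    ifelse(is.na(v), FALSE, as.logical(v))
  }
  hits$action <- deriveAction(hits$wr)
  hits$allelic_series <- getFlag("allelic_series")
  hits$druggable <- getFlag("druggable")
  adverse <- if ("adverse_traits" %in% names(annotations)) {
    a <- annotations$adverse_traits[i]
    !is.na(a) & nzchar(trimws(a))
  } else rep(FALSE, nrow(hits))
  hits$safety_ok <- !is.na(i) & !adverse
  hits$criteria_met <- vapply(seq_len(nrow(hits)), function(j) {
    met <- c("allelic_series", "druggable", "safety_ok")[
      c(hits$allelic_series[j], hits$druggable[j], hits$safety_ok[j])]
    paste(met, collapse = ",")
  }, character(1))
  hits$prioritized <- (hits$allelic_series | hits$druggable) & hits$safety_ok
  out <- hits[order(!hits$prioritized, hits$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format hit tables for reporting
#'
#' Renders MR + colocalization hits in the standard report layout (outcome,
#' gene, SNP, Wald ratio, SE, P, coloc), with the colocalization posterior
#' as a percentage with one decimal. Writes a TSV when `path` is given;
#' an empty hit set produces a header-only file.
#'
#' @param hits Data frame with `trait_id`, `gene_id`, `variant_id`, `wr`,
#'   `se`, `p`, `pp4`.
#' @param path Optional output TSV path.
#' @return The formatted data frame (columns `outcome`, `gene`, `SNP`, `WR`,
#'   `SE`, `P`, `coloc`), invisibly when writing.
#' @export
targetReport <- function(hits, path = NULL) {
  out <- data.frame(outcome = character(0), gene = character(0),
                    SNP = character(0), WR = numeric(0), SE = numeric(0),
                    P = character(0), coloc = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(hits) > 0) {
    out <- data.frame(outcome = hits$trait_id, gene = hits$gene_id,
                      SNP = hits$variant_id,
                      WR = round(hits$wr, 3), SE = round(hits$se, 3),
                      P = formatC(hits$p, format = "e", digits = 2),
                      coloc = sprintf("%.1f", 100 * hits$pp4),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
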