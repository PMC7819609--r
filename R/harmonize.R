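## Allele harmonization between an exposure (eQTL) record and an outcome
## (GWAS) record, so both effects refer to the same effect allele. Handles
## direct matches, swapped alleles (sign flip), strand-complement reporting,
## and palindromic (A/T, C/G) variants whose strand cannot be resolved when
## the allele frequency is near 0.5.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' @keywords internal
complementAllele <- function(a) {
  a <- toupper(a)
  out <- .COMPLEMENT[a]
  out[is.na(out)] <- a[is.na(out)]   # non-ACGT alleles (indels) pass through
  unname(out)
}

#' @keywords internal
isPalindromic <- function(ea, oa) {
  toupper(oa) == complementAllele(ea) & toupper(ea) %in% names(.COMPLEMENT)
}

#' Harmonize one exposure-outcome record pair
#'
#' Re-expresses the outcome association relative to the exposure's effect
#' allele. Swapped alleles flip the outcome beta sign and frequency;
#' strand-complement reports are resolved by complementing the outcome
#' alleles first. Palindromic variants are dropped when the effect-allele
#' frequency is within `palindromeEafBand` of 0.5 in either study (strand
#' unresolvable); otherwise their orientation is inferred from frequency.
#'
#' @param exposure,outcome Single records (1-row data.frames or named lists)
#'   for the same variant.
#' @param palindromeEafBand Half-width of the frequency exclusion band around
#'   0.5 (default 0.08, i.e. drop when min(eaf, 1-eaf) > 0.42).
#' @return List with elements `exposure`, `outcome` (re-signed copy) and
#'   `action`, one of `"unchanged"`, `"sign_flipped"`, `"strand_flipped"`,
#'   `"dropped_palindromic"`, `"dropped_unmatched"`. For dropped pairs the
#'   outcome is returned unmodified.
#' @export
harmonizePair <- function(exposure, outcome, palindromeEafBand = 0.08) {
  exposure <- as.list(exposure)
  outcome <- as.list(outcome)
  if (!identical(as.character(exposure$variant_id),
                 as.character(outcome$variant_id))) {
    stop("harmonizePair requires records for the same variant")
  }
  eaE <- toupper(exposure$effect_allele); oaE <- toupper(exposure$other_allele)
  eaO <- toupper(outcome$effect_allele); oaO <- toupper(outcome$other_allele)

  done <- function(action, flip = FALSE) {
    out <- outcome
    if (flip) {
      out$beta <- -out$beta
      out$eaf <- 1 - out$eaf
      out$effect_allele <- exposure$effect_allele
      out$other_allele <- exposure$other_allele
    } else if (!startsWith(action, "dropped")) {
      out$effect_allele <- exposure$effect_allele
      out$other_allele <- exposure$other_allele
    }
    list(exposure = exposure, outcome = out, action = action)
  }

  if (isPalindromic(eaE, oaE)) {
    nearHalf <- function(f) min(f, 1 - f) > 0.5 - palindromeEafBand
    if (!setequal(c(eaO, oaO), c(eaE, oaE))) return(done("dropped_unmatched"))
    if (nearHalf(exposure$eaf) || nearHalf(outcome$eaf)) {
      return(done("dropped_palindromic"))
    }
    ## Allele letters carry no strand information for palindromes; frequency
    ## is the only usable signal. The outcome effect allele is taken to be the
    ## exposure effect allele iff both frequencies fall on the same side of 0.5.
    sameSide <- (exposure$eaf - 0.5) * (outcome$eaf - 0.5) >= 0
    return(if (sameSide) done("unchanged") else done("sign_flipped", flip = TRUE))
  }

  if (eaO == eaE && oaO == oaE) return(done("unchanged"))
  if (eaO == oaE && oaO == eaE) return(done("sign_flipped", flip = TRUE))
  ## Try the complementary strand.
  eaC <- complementAllele(eaO); oaC <- complementAllele(oaO)
  if (eaC == eaE && oaC == oaE) return(done("strand_flipped"))
  if (eaC == oaE && oaC == eaE) return(done("sign_flipped", flip = TRUE))
  done("dropped_unmatched")
}

#' Harmonize two summary-statistics tables
#'
#' Joins exposure and outcome records on `variant_id` and applies
#' [harmonizePair()] to each shared variant.
#'
#' @param exposure,outcome Data frames of canonical records.
#' @param palindromeEafBand See [harmonizePair()].
#' @param dropRemoved Drop pairs with a `dropped_*` action (default TRUE).
#' @return Data frame with the exposure columns, outcome columns suffixed
#'   `_outcome` (beta/eaf re-signed to the exposure effect allele), and an
#'   `action` column.
#' @export
harmonizeSumstats <- function(exposure, outcome, palindromeEafBand = 0.08,
                              dropRemoved = TRUE) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  rows <- lapply(shared, function(v) {
    e <- exposure[match(v, exposure$variant_id), , drop = FALSE]
    o <- outcome[match(v, outcome$variant_id), , drop = FALSE]
    h <- harmonizePair(e, o, palindromeEafBand)
    oc <- as.data.frame(h$outcome, stringsAsFactors = FALSE)
    keep <- intersect(c("effect_allele", "other_allele", "eaf", "beta",
                        "se", "p", "n", "trait_id"), names(oc))
    oc <- oc[, keep, drop = FALSE]
    names(oc) <- paste0(keep, "_outcome")
    cbind(e, oc, action = h$action, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  rownames(out) <- NULL
  if (dropRemoved) out <- out[!startsWith(out$action, "dropped"), , drop = FALSE]
  out
}
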