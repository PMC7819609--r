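## Reading, validating and writing GWAS / eQTL summary statistics, plus the LD
## reference loaders. The canonical in-memory representation is a data.frame
## with one row per variant-trait record and the columns listed in
## `sumstatsColumns()`; files are named-column TSVs with a configurable
## column map (the "dialect").

.CANON <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "p", "n", "trait_id", "gene_id")
.MANDATORY <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "p")

#' Canonical summary-statistics columns
#'
#' @return Character vector of canonical column names. `trait_id` and
#'   `gene_id` are optional (`gene_id` is expected for eQTL files); `n` may be
#'   supplied study-wide via the `studyN` argument of [readSumstats()].
#' @export
sumstatsColumns <- function() .CANON

#' Default file dialect for summary-statistics TSVs
#'
#' Maps canonical column names to the column headers used on disk.
#'
#' @param ... Named overrides, e.g. `variant_id = "SNP"`.
#' @return Named character vector (canonical name -> file header).
#' @examples
#' sumstatsDialect(p = "pval", n = "samplesize")
#' @export
sumstatsDialect <- function(...) {
  d <- c(variant_id = "rsid", chrom = "chrom", pos = "pos",
         effect_allele = "ea", other_allele = "oa", eaf = "eaf",
         beta = "beta", se = "se", p = "p", n = "n",
         trait_id = "trait", gene_id = "gene")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(over)] <- over
  }
  d
}

#' Validate summary-statistics records
#'
#' Checks each row against the record invariants: positive `se`, `eaf` in
#' \[0, 1\], distinct alleles, `p` in (0, 1\], positive `n`, finite `beta`.
#'
#' @param x Data frame with canonical columns.
#' @return Logical vector (TRUE = valid) with a `reasons` attribute: a
#'   character vector of per-row diagnostics, `NA` for valid rows.
#' @export
validateSumstats <- function(x) {
  n <- nrow(x)
  reasons <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- why
  }
  flag(!is.finite(x$beta), "non-numeric or missing beta")
  flag(!is.finite(x$se) | x$se <= 0, "se must be positive")
  flag(!is.finite(x$eaf) | x$eaf < 0 | x$eaf > 1, "eaf outside [0, 1]")
  flag(!is.finite(x$p) | x$p <= 0 | x$p > 1, "p outside (0, 1]")
  flag(is.na(x$effect_allele) | is.na(x$other_allele) |
         toupper(x$effect_allele) == toupper(x$other_allele),
       "effect and other allele must differ")
  flag(!is.finite(x$pos) | x$pos < 1, "pos must be a positive 1-based coordinate")
  if ("n" %in% names(x)) flag(!is.finite(x$n) | x$n <= 0, "n must be positive")
  ok <- is.na(reasons)
  attr(ok, "reasons") <- reasons
  ok
}

#' Read a summary-statistics TSV
#'
#' Reads a tab-separated file with a header row, renames columns through the
#' dialect, validates every row, and returns the valid records. Invalid rows
#' are dropped with a warning listing row numbers and reasons.
#'
#' @param path File path.
#' @param dialect Column map from [sumstatsDialect()].
#' @param studyN Study-wide sample size used when the file has no `n` column
#'   (per-variant n takes precedence when present).
#' @param traitId Trait label to attach when the file has no trait column.
#' @return Data frame of validated records in canonical columns.
#' @export
readSumstats <- function(path, dialect = sumstatsDialect(), studyN = NULL,
                         traitId = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA, comment.char = "")
  missing <- setdiff(dialect[.MANDATORY], names(raw))
  if (length(missing)) {
    stop("summary-statistics file ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  present <- dialect[dialect %in% names(raw)]
  x <- raw[, unname(present), drop = FALSE]
  names(x) <- names(present)

  for (col in c("pos", "eaf", "beta", "se", "p", "n")) {
    if (col %in% names(x)) x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  x$chrom <- normChrom(x$chrom)
  x$variant_id <- as.character(x$variant_id)
  if (!"n" %in% names(x)) {
    if (is.null(studyN)) {
      stop("file has no sample-size column and no studyN fallback was given")
    }
    x$n <- as.numeric(studyN)
  }
  if (!"trait_id" %in% names(x) && !is.null(traitId)) x$trait_id <- traitId

  ok <- validateSumstats(x)
  if (!all(ok)) {
    reasons <- attr(ok, "reasons")
    bad <- which(!ok)
    show <- utils::head(bad, 5)
    warning(sprintf("dropped %d invalid row(s) in %s: %s%s",
                    length(bad), basename(path),
                    paste(sprintf("row %d (%s)", show, reasons[show]), collapse = "; "),
                    if (length(bad) > 5) " ..." else ""), call. = FALSE)
    x <- x[ok, , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' Write summary statistics as a TSV
#'
#' Inverse of [readSumstats()]: canonical columns are renamed through the
#' dialect and written tab-separated with a header. Read-write-read is a
#' fixed point on valid records.
#'
#' @param x Data frame of canonical records.
#' @param path Output path.
#' @param dialect Column map from [sumstatsDialect()].
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(x, path, dialect = sumstatsDialect()) {
  keep <- intersect(.CANON, names(x))
  out <- x[, keep, drop = FALSE]
  names(out) <- unname(dialect[keep])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an LD reference
#'
#' @param r Symmetric signed correlation matrix with unit diagonal.
#' @param variantIds Variant identifiers (defaults to the matrix dimnames).
#' @param buildTag Genome build label.
#' @return An [LdReference-class] object.
#' @export
LdReference <- function(r, variantIds = rownames(r), buildTag = "hg19") {
  r <- as.matrix(r)
  if (is.null(variantIds)) stop("variantIds required when matrix has no dimnames")
  dimnames(r) <- list(variantIds, variantIds)
  new("LdReference", variantIds = as.character(variantIds), r = r,
      buildTag = buildTag)
}

#' Read an LD reference from file
#'
#' Two plain-text layouts are accepted: a square matrix TSV whose header row
#' and first column carry variant ids, or a plink-style triplet list with
#' columns `id1`, `id2`, `r` which is densified (missing pairs treated as
#' r = 0, diagonal set to 1).
#'
#' @param path File path.
#' @param format `"auto"` (sniff from the header), `"matrix"` or `"triplet"`.
#' @param buildTag Genome build label to attach.
#' @return An [LdReference-class] object.
#' @export
readLdReference <- function(path, format = c("auto", "matrix", "triplet"),
                            buildTag = "hg19") {
  format <- match.arg(format)
  if (format == "auto") {
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    format <- if (length(hdr) == 3L && identical(tolower(hdr), c("id1", "id2", "r")))
      "triplet" else "matrix"
  }
  if (format == "matrix") {
    m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
    m <- as.matrix(m)
    return(LdReference(m, variantIds = rownames(m), buildTag = buildTag))
  }
  trip <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  ids <- sort(unique(c(trip$id1, trip$id2)))
  r <- diag(length(ids))
  dimnames(r) <- list(ids, ids)
  i <- match(trip$id1, ids); j <- match(trip$id2, ids)
  r[cbind(i, j)] <- trip$r
  r[cbind(j, i)] <- trip$r
  diag(r) <- 1
  LdReference(r, variantIds = ids, buildTag = buildTag)
}

#' Write an LD reference as a square matrix TSV
#'
#' @param ld An [LdReference-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLdReference <- function(ld, path) {
  m <- ldMatrix(ld)
  df <- data.frame(id = variantIds(ld), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
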