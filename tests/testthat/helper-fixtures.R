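# Small programmatic fixtures shared across the suite.

# One canonical summary-statistics row with overridable fields.
makeRecord <- function(...) {
  rec <- list(variant_id = "rs1", chrom = "1", pos = 1000000L,
              effect_allele = "A", other_allele = "G", eaf = 0.3,
              beta = 0.1, se = 0.02, p = zp(0.1 / 0.02), n = 1000)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

zp <- function(z) 2 * pnorm(-abs(z))

# A small table of m valid records on one chromosome.
makeSumstats <- function(m, chrom = "1", startPos = 1e6, spacing = 1e4,
                         geneId = NULL, seed = 1) {
  set.seed(seed)
  beta <- rnorm(m, 0, 0.1)
  se <- runif(m, 0.01, 0.05)
  out <- data.frame(variant_id = sprintf("rs%04d", seq_len(m)),
                    chrom = chrom, pos = startPos + spacing * (seq_len(m) - 1),
                    effect_allele = "A", other_allele = "G",
                    eaf = runif(m, 0.05, 0.95), beta = beta, se = se,
                    p = zp(beta / se), n = 1000,
                    stringsAsFactors = FALSE)
  if (!is.null(geneId)) out$gene_id <- geneId
  out
}

# Dense LD reference from an explicit correlation matrix.
makeLd <- function(r, ids) LdReference(as.matrix(r), variantIds = ids)
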