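## Synthetic summary-statistics generator. Marginal z-scores for a cis
## region are drawn at the summary level from the multivariate normal
## implied by the LD matrix (z ~ MVN(R lambda sqrt(n), R), the standard
## summary-statistics likelihood), so every downstream stage sees exactly
## the LD structure that clumping and colocalization consume, at desk-scale
## speed and with known ground truth.

.SCENARIOS <- c("null", "eqtl_only", "gwas_only", "distinct_variants",
                "shared_variant", "reverse_causation", "horizontal_pleiotropy")

#' Define a simulation scenario
#'
#' Encodes one causal configuration for a cis region shared by an eQTL study
#' and a disease GWAS:
#' \describe{
#'   \item{null}{no association with either trait (coloc H0)}
#'   \item{eqtl_only}{a causal eQTL, no effect on disease (H1; the
#'     true causal effect of expression on disease is zero)}
#'   \item{gwas_only}{a disease locus with no expression effect (H2)}
#'   \item{distinct_variants}{independent causal variants for the two traits
#'     in the same region (H3)}
#'   \item{shared_variant}{one causal variant; the disease effect runs
#'     through expression with log-odds-per-SD effect `gamma` (H4)}
#'   \item{reverse_causation}{the causal variant acts on disease liability
#'     directly and expression responds to disease with effect `gamma`}
#'   \item{horizontal_pleiotropy}{one variant affects expression and disease
#'     through separate pathways (the Wald ratio is confounded)}
#' }
#'
#' @param kind One of the scenario kinds above.
#' @param gamma Causal effect of expression on disease liability, log-odds
#'   per SD expression (default 0.2); reused as the disease-to-expression
#'   effect under `reverse_causation`.
#' @param eqtlPve Fraction of expression variance explained by the causal
#'   eQTL (default 0.05).
#' @param gwasPve Liability variance explained by a direct disease locus
#'   (default 0.01, a strong genome-wide-significant hit: z about 22 at
#'   n = 50,000); used by the scenarios with a direct disease effect.
#' @param nEqtl,nGwas Study sample sizes (defaults 1286 and 50000; the GWAS
#'   n is an effective sample size on the log-odds scale).
#' @param mSnps Variants in the region (default 100).
#' @param ldRho AR(1) adjacent-variant LD correlation in \[0, 1) (default 0.9).
#' @param causalIndices 1-based causal variant index(es); defaults to the
#'   region centre, or for `distinct_variants` to positions 30% and 70%
#'   through the region (well below r-squared 0.1 apart at the default rho).
#' @param mafRange Uniform range for minor allele frequencies.
#' @param seed RNG seed for [simulateRegion()].
#' @return A `Scenario` list.
#' @export
makeScenario <- function(kind = .SCENARIOS, gamma = 0.2, eqtlPve = 0.05,
                         gwasPve = 0.01, nEqtl = 1286L, nGwas = 50000L,
                         mSnps = 100L, ldRho = 0.9, causalIndices = NULL,
                         mafRange = c(0.05, 0.5), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(eqtlPve > 0, eqtlPve < 1, gwasPve > 0, gwasPve < 1,
            ldRho >= 0, ldRho < 1, mSnps >= 1)
  if (is.null(causalIndices)) {
    causalIndices <- if (kind == "distinct_variants") {
      unique(pmax(1L, c(round(0.3 * mSnps), round(0.7 * mSnps))))
    } else {
      as.integer(ceiling(mSnps / 2))
    }
  }
  if (any(causalIndices < 1L | causalIndices > mSnps)) {
    stop("causalIndices must lie in 1..mSnps")
  }
  if (kind == "distinct_variants" && length(causalIndices) != 2L) {
    stop("distinct_variants needs two causal indices")
  }
  structure(list(kind = kind, gamma = gamma, eqtlPve = eqtlPve,
                 gwasPve = gwasPve, nEqtl = as.integer(nEqtl),
                 nGwas = as.integer(nGwas), mSnps = as.integer(mSnps),
                 ldRho = ldRho, causalIndices = as.integer(causalIndices),
                 mafRange = mafRange, seed = as.integer(seed)),
            class = "Scenario")
}

#' Construct an AR(1) LD reference with random allele frequencies
#'
#' The signed correlation between variants i and j is exactly
#' `ldRho^|i - j|` (built in closed form, not sampled), which is positive
#' definite for any `ldRho` in \[0, 1). Minor allele frequencies are drawn
#' uniformly from `mafRange`; positions are evenly spaced.
#'
#' @param mSnps Number of variants.
#' @param ldRho Adjacent-variant correlation in \[0, 1).
#' @param mafRange Uniform MAF range.
#' @param seed RNG seed (for the MAFs).
#' @param chrom,startBp,spacingBp Coordinate layout of the region.
#' @return List with `ld` ([LdReference-class]), `maf`, `pos`, `chrom`,
#'   `variant_ids`.
#' @export
simulateLd <- function(mSnps, ldRho = 0.9, mafRange = c(0.05, 0.5), seed = 1L,
                       chrom = "1", startBp = 1e6, spacingBp = 1e4) {
  stopifnot(mSnps >= 1)
  if (ldRho >= 1 || ldRho < 0) stop("ldRho must lie in [0, 1)")
  ids <- sprintf("rs%07d", seq_len(mSnps))
  r <- ldRho^abs(outer(seq_len(mSnps), seq_len(mSnps), "-"))
  set.seed(seed)
  maf <- stats::runif(mSnps, mafRange[1], mafRange[2])
  list(ld = LdReference(r, variantIds = ids),
       maf = maf,
       pos = startBp + spacingBp * (seq_len(mSnps) - 1L),
       chrom = chrom,
       variant_ids = ids)
}

#' @keywords internal
.drawSumstats <- function(lambda, n, region, trait, chol_R, geneId = NULL) {
  m <- length(region$maf)
  mu <- sqrt(n) * as.numeric(region$r %*% lambda)
  z <- mu + as.numeric(crossprod(chol_R, stats::rnorm(m)))
  se <- 1 / sqrt(2 * region$maf * (1 - region$maf) * n)
  out <- data.frame(variant_id = region$variant_ids, chrom = region$chrom,
                    pos = region$pos, effect_allele = "A", other_allele = "G",
                    eaf = region$maf, beta = z * se, se = se,
                    p = pmax(zToP(z), .Machine$double.xmin), n = n,
                    trait_id = trait, stringsAsFactors = FALSE)
  if (!is.null(geneId)) out$gene_id <- geneId
  out
}

#' Simulate one cis region under a causal scenario
#'
#' Draws marginal eQTL and GWAS z-scores from
#' `z ~ MVN(R lambda sqrt(n), R)` where `lambda` carries the per-SNP joint
#' standardized effects implied by the scenario, then back-fills betas and
#' standard errors on the per-allele scale via
#' `se = 1/sqrt(2 maf (1 - maf) n)`. The generated records satisfy all
#' summary-statistics invariants by construction.
#'
#' @param scenario A [makeScenario()] list.
#' @return List with `eqtl` and `gwas` canonical data frames, `ld`
#'   ([LdReference-class]), and `truth`: the scenario kind, the true Wald
#'   ratio (`gamma` under `shared_variant`, 0 where expression has no causal
#'   effect, `NA` where the single-SNP estimand is undefined), the causal
#'   variant ids, and the expected colocalization hypothesis.
#' @export
simulateRegion <- function(scenario) {
  stopifnot(inherits(scenario, "Scenario"))
  s <- scenario
  region <- simulateLd(s$mSnps, s$ldRho, s$mafRange, seed = s$seed)
  region$r <- ldMatrix(region$ld)

  lx <- numeric(s$mSnps)
  lg <- numeric(s$mSnps)
  bEqtl <- sqrt(s$eqtlPve)
  delta <- sqrt(s$gwasPve)
  c1 <- s$causalIndices[1]
  causal <- s$causalIndices
  switch(s$kind,
    null = NULL,
    eqtl_only = { lx[c1] <- bEqtl },
    gwas_only = { lg[c1] <- delta },
    shared_variant = { lx[c1] <- bEqtl; lg[c1] <- s$gamma * bEqtl },
    distinct_variants = { lx[causal[1]] <- bEqtl; lg[causal[2]] <- delta },
    reverse_causation = { lg[c1] <- delta; lx[c1] <- s$gamma * delta },
    horizontal_pleiotropy = { lx[c1] <- bEqtl; lg[c1] <- delta }
  )

  ## RNG state continues from the MAF draw inside simulateLd (seeded by
  ## scenario$seed), so one seed fixes the whole region deterministically.
  cholR <- chol(region$r)
  eqtl <- .drawSumstats(lx, s$nEqtl, region, "expression", cholR, geneId = "GENE1")
  gwas <- .drawSumstats(lg, s$nGwas, region, "disease", cholR)

  trueWald <- switch(s$kind,
    shared_variant = s$gamma,
    eqtl_only = 0, distinct_variants = 0,
    NA_real_)
  expectedColoc <- switch(s$kind,
    null = "H0", eqtl_only = "H1", gwas_only = "H2",
    distinct_variants = "H3", shared_variant = "H4",
    reverse_causation = "H4", horizontal_pleiotropy = "H4")

  list(eqtl = eqtl, gwas = gwas, ld = region$ld,
       truth = list(kind = s$kind, trueWald = trueWald,
                    causalVariantIds = region$variant_ids[causal],
                    expectedColoc = expectedColoc, gamma = s$gamma,
                    seed = s$seed))
}

#' Write a simulated region to disk
#'
#' Emits the eQTL and GWAS summary statistics in the package TSV dialect,
#' the LD matrix, and a one-row ground-truth TSV.
#'
#' @param sim A [simulateRegion()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
writeRegion <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(eqtl = file.path(dir, "eqtl.tsv"),
             gwas = file.path(dir, "gwas.tsv"),
             ld = file.path(dir, "ld.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeSumstats(sim$eqtl, paths["eqtl"])
  writeSumstats(sim$gwas, paths["gwas"])
  writeLdReference(sim$ld, paths["ld"])
  truth <- sim$truth
  utils::write.table(
    data.frame(kind = truth$kind, true_wald = truth$trueWald,
               causal_variants = paste(truth$causalVariantIds, collapse = ","),
               expected_coloc = truth$expectedColoc, seed = truth$seed),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate an MR-PheWAS matrix with planted effects
#'
#' Null cells draw their Wald z from a standard normal (so p-values are
#' uniform); planted cells receive the specified z. Traits are split into
#' brain-related and other categories.
#'
#' @param nInstruments,nTraits Matrix dimensions.
#' @param brainFraction Fraction of traits labelled brain-related
#'   (default 0.2).
#' @param plantedEffects Optional data frame with columns `instrument`,
#'   `trait` (integer indices) and `z`.
#' @param seed RNG seed.
#' @return List with `cells` (a [phewasScan()]-shaped data frame),
#'   `categories` (named vector) and `truth` (the planted effects).
#' @export
simulatePhewas <- function(nInstruments, nTraits, brainFraction = 0.2,
                           plantedEffects = NULL, seed = 1L) {
  stopifnot(nInstruments >= 1, nTraits >= 1)
  set.seed(seed)
  traitIds <- sprintf("trait%03d", seq_len(nTraits))
  nBrain <- round(brainFraction * nTraits)
  categories <- stats::setNames(
    rep(c("brain", "other"), c(nBrain, nTraits - nBrain)), traitIds)
  z <- matrix(stats::rnorm(nInstruments * nTraits), nInstruments, nTraits)
  if (!is.null(plantedEffects)) {
    z[cbind(plantedEffects$instrument, plantedEffects$trait)] <- plantedEffects$z
  }
  se <- 0.05
  cells <- data.frame(
    gene_id = rep(sprintf("GENE%03d", seq_len(nInstruments)), nTraits),
    variant_id = rep(sprintf("rs%07d", seq_len(nInstruments)), nTraits),
    trait_id = rep(traitIds, each = nInstruments),
    category = rep(unname(categories), each = nInstruments),
    wr = as.vector(z) * se, se = se, p = zToP(as.vector(z)),
    pp4 = NA_real_, coloc_pass = NA, stringsAsFactors = FALSE)
  list(cells = cells, categories = categories, truth = plantedEffects)
}
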