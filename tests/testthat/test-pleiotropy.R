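# Brute-force two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities of all tables with the same margins that are no more
# probable than the observed one.
bruteFisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

test_that("Fisher enrichment agrees with exhaustive hypergeometric enumeration", {
  expect_equal(enrichmentTest(matrix(c(3, 0, 0, 3), 2, 2))$p, 0.1,
               tolerance = 1e-10)
  expect_equal(enrichmentTest(matrix(c(5, 5, 5, 5), 2, 2))$p, 1)
  set.seed(15)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 8), 2, 2)
    expect_equal(enrichmentTest(tab)$p, bruteFisher(tab), tolerance = 1e-10)
  }
})

test_that("colocalization is enriched among brain traits in the published counts", {
  tab <- matrix(c(29, 35, 1549 - 29, 7892 - 35), 2, 2,
                dimnames = list(c("brain", "other"), c("coloc", "not")))
  res <- enrichmentTest(tab)
  expect_lt(res$p, 0.0001)
  expect_equal(res$p, bruteFisher(tab), tolerance = 1e-10)
})

test_that("the PheWAS scan computes one Wald cell per instrument x trait", {
  sim <- simulateRegion(makeScenario("shared_variant", seed = 61, mSnps = 10))
  inst <- standardizeEffects(sim$eqtl[5:6, ])
  traits <- list(t1 = sim$gwas, t2 = sim$gwas, t3 = sim$gwas)
  cats <- c(t1 = "brain", t2 = "other", t3 = "other")
  scan <- phewasScan(inst, traits, cats)
  expect_equal(nrow(scan), 6L)                       # 2 instruments x 3 traits
  expect_true(all(is.na(scan$coloc_pass)))           # no coloc config given
  expect_error(phewasScan(inst, traits, cats[-1]), "no category label")
})

test_that("coloc follow-up is gated on nominal MR evidence and finds the planted cell", {
  shared <- simulateRegion(makeScenario("shared_variant", seed = 62))
  nullsim <- simulateRegion(makeScenario("eqtl_only", seed = 63))
  anchor <- shared$truth$causalVariantIds
  instRow <- match(anchor, shared$eqtl$variant_id)
  inst <- standardizeEffects(shared$eqtl[instRow, ])
  traits <- list(linked = shared$gwas, unlinked = nullsim$gwas)
  cats <- c(linked = "brain", unlinked = "other")
  scan <- phewasScan(inst, traits, cats,
                     colocCfg = list(eqtl = shared$eqtl))
  linked <- scan[scan$trait_id == "linked", ]
  unlinked <- scan[scan$trait_id == "unlinked", ]
  expect_true(linked$coloc_pass)
  # null trait: coloc attempted only under p < 0.05, never passes
  if (!is.na(unlinked$coloc_pass)) expect_false(unlinked$coloc_pass)
  if (unlinked$p >= 0.05) expect_true(is.na(unlinked$coloc_pass))
})

test_that("permutation p matches exhaustive enumeration on a 5-trait pool", {
  sim <- simulatePhewas(12, 6, brainFraction = 1 / 6, seed = 16)
  pool <- sim$cells[sim$cells$category == "other", ]
  # exhaustive truth over all choose(5, 2) = 10 subsets
  traits <- unique(pool$trait_id)
  hits <- tapply(pool$p < 0.05, pool$trait_id, sum)[traits]
  tot <- tapply(pool$p, pool$trait_id, length)[traits]
  combos <- combn(traits, 2)
  exProps <- apply(combos, 2, function(tt) sum(hits[tt]) / sum(tot[tt]))
  obsCount <- 3; obsTotal <- 24
  exactP <- mean(exProps >= obsCount / obsTotal)

  perm <- sharingPermutation(sim$cells, obsCount, obsTotal, subsetSize = 2,
                             nIter = 4000, seed = 17)
  mcSe <- sqrt(exactP * (1 - exactP) / 4000)
  expect_lt(abs(perm@empiricalP - exactP), 4 * mcSe + 2 / 4000)
  expect_equal(perm@poolSize, 5L)
  # same seed: identical outcome object
  perm2 <- sharingPermutation(sim$cells, obsCount, obsTotal, subsetSize = 2,
                              nIter = 4000, seed = 17)
  expect_identical(perm@nullProps, perm2@nullProps)
  expect_identical(perm@empiricalP, perm2@empiricalP)
})

test_that("an observed proportion above the null maximum gets the minimum p", {
  sim <- simulatePhewas(10, 8, brainFraction = 0.25, seed = 18)
  perm <- sharingPermutation(sim$cells, observedCount = 99, observedTotal = 100,
                             subsetSize = 3, nIter = 500, seed = 19)
  expect_equal(perm@empiricalP, 1 / 501)
  expect_error(sharingPermutation(sim$cells, 1, 0, subsetSize = 3,
                                  nIter = 10, seed = 1),
               "positive")
})

test_that("permutation null mean converges to the pool-wide hit rate", {
  set.seed(20)
  sim <- simulatePhewas(40, 30, brainFraction = 0.2, seed = 20)
  pool <- sim$cells[sim$cells$category == "other", ]
  poolRate <- mean(pool$p < 0.05)
  perm <- sharingPermutation(sim$cells, 10, 100, subsetSize = 8,
                             nIter = 3000, seed = 21)
  # equal cells per trait, so the expected null proportion is the pool rate
  expect_equal(mean(perm@nullProps), poolRate, tolerance = 0.02)
})

test_that("molecular pleiotropy counts co-regulated genes and colocalizes them", {
  base <- simulateRegion(makeScenario("shared_variant", seed = 64, mSnps = 40))
  anchor <- base$truth$causalVariantIds
  # three co-regulated genes sharing the causal variant in one locus
  eqtlAll <- do.call(rbind, lapply(1:3, function(g) {
    sim <- simulateRegion(makeScenario("shared_variant", seed = 64 + g,
                                       mSnps = 40))
    sim$eqtl$gene_id <- sprintf("GENE%d", g)
    sim$eqtl
  }))
  res <- molecularPleiotropy(anchor, eqtlAll, base$gwas)
  expect_equal(nrow(res), 3L)
  expect_equal(res$bonferroni[1], 0.05 / 3)
  expect_true(all(res$passes))
  expect_true(all(res$coloc_pass))
  # Bonferroni over an arbitrary extraction count
  expect_equal(signif(bonferroniThreshold(0.05, 1482), 2), 3.4e-5)
  # absent variant: empty result with a notice
  expect_message(none <- molecularPleiotropy("rs_none", eqtlAll, base$gwas),
                 "absent")
  expect_equal(nrow(none), 0)
})
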