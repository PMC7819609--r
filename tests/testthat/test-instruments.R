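test_that("MHC mask removes chr6:24-36Mb inclusively and nothing else", {
  x <- rbind(makeRecord(variant_id = "in", chrom = "6", pos = 30000000),
             makeRecord(variant_id = "edge_out", chrom = "6", pos = 23999999),
             makeRecord(variant_id = "edge_in", chrom = "6", pos = 24000000),
             makeRecord(variant_id = "chr1", chrom = "1", pos = 30000000),
             makeRecord(variant_id = "prefixed", chrom = "chr6", pos = 25000000))
  kept <- maskMhc(x)
  expect_setequal(kept$variant_id, c("edge_out", "chr1"))
  expect_equal(nrow(maskMhc(x[0, ])), 0)
})

test_that("significance filter is strictly less-than", {
  x <- rbind(makeRecord(variant_id = "at", p = 5e-8),
             makeRecord(variant_id = "below", p = 4.9e-8),
             makeRecord(variant_id = "above", p = 6e-8))
  expect_equal(significanceFilter(x, 5e-8)$variant_id, "below")
  set.seed(3)
  y <- makeSumstats(50)
  y$p <- runif(50)
  expect_equal(nrow(significanceFilter(y, 0.3)), sum(y$p < 0.3))
})

test_that("greedy clumping matches the hand-executed oracle", {
  # A(p=1e-10), B(p=1e-9, r2AB=0.5), C(p=1e-8, r2AC=5e-4, r2BC=3e-4)
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- sqrt(0.5)
  r[1, 3] <- r[3, 1] <- sqrt(0.0005)
  r[2, 3] <- r[3, 2] <- sqrt(0.0003)
  ld <- makeLd(r, c("A", "B", "C"))
  x <- rbind(makeRecord(variant_id = "A", pos = 1e6, p = 1e-10),
             makeRecord(variant_id = "B", pos = 1.1e6, p = 1e-9),
             makeRecord(variant_id = "C", pos = 1.2e6, p = 1e-8))
  kept <- clumpVariants(x, ld, r2Threshold = 0.001, windowBp = 1e7)
  expect_setequal(kept$variant_id, c("A", "C"))
  # single variant is its own clump
  expect_equal(clumpVariants(x[1, ], ld)$variant_id, "A")
})

test_that("clumping respects the window and is order-invariant", {
  r <- matrix(c(1, 0.95, 0.95, 1), 2, 2)
  ld <- makeLd(r, c("A", "B"))
  far <- rbind(makeRecord(variant_id = "A", pos = 1e6, p = 1e-10),
               makeRecord(variant_id = "B", pos = 1e6 + 11e6, p = 1e-9))
  expect_equal(nrow(clumpVariants(far, ld, 0.001, windowBp = 1e7)), 2)
  near <- far
  near$pos[2] <- 1e6 + 4e6
  expect_equal(clumpVariants(near, ld, 0.001, 1e7)$variant_id, "A")

  set.seed(9)
  m <- 12
  rr <- 0.6^abs(outer(1:m, 1:m, "-"))
  ids <- sprintf("v%02d", 1:m)
  ld2 <- makeLd(rr, ids)
  x <- makeSumstats(m)
  x$variant_id <- ids
  x$p <- runif(m, 1e-12, 1e-6)
  a <- clumpVariants(x, ld2, 0.1, 1e7)
  b <- clumpVariants(x[sample(m), ], ld2, 0.1, 1e7)
  expect_equal(a$variant_id, b$variant_id)
})

test_that("variants missing from the LD panel are dropped with a warning", {
  ld <- makeLd(diag(1), "A")
  x <- rbind(makeRecord(variant_id = "A", p = 1e-9),
             makeRecord(variant_id = "ghost", p = 1e-10))
  expect_warning(kept <- clumpVariants(x, ld), "absent from the LD reference")
  expect_equal(kept$variant_id, "A")
})

test_that("standardization reproduces the closed-form per-SD scale", {
  # z = 5, maf = 0.5, n = 1286: beta_std = 5/sqrt(2*0.25*(1286+25))
  x <- makeRecord(eaf = 0.5, beta = 5, se = 1, p = zp(5), n = 1286)
  s <- standardizeEffects(x)
  expect_equal(s$beta_std, 0.19529164, tolerance = 1e-7)
  expect_equal(s$se_std, 0.03905833, tolerance = 1e-7)
  expect_equal(s$beta_std / s$se_std, s$z)     # exact by construction

  expect_equal(standardizeEffects(makeRecord(beta = 0))$beta_std, 0)
  # maf symmetry: eaf and 1 - eaf standardize identically
  a <- standardizeEffects(makeRecord(eaf = 0.3, beta = 0.15))
  b <- standardizeEffects(makeRecord(eaf = 0.7, beta = 0.15))
  expect_equal(a$beta_std, b$beta_std)
  expect_error(standardizeEffects(makeRecord(eaf = 1)), "degenerate")
})

test_that("PVE and Cragg-Donald F match the closed form and its limits", {
  s <- instrumentStrength(0.19529164, 0.03905833, 1286, 1)
  expect_equal(s$pve, 0.01907, tolerance = 1e-3)
  expect_equal(s$f_stat, 24.96, tolerance = 1e-3)
  expect_equal(instrumentStrength(0, 0.04, 1000)$pve, 0)
  expect_equal(instrumentStrength(0, 0.04, 1000)$f_stat, 0)
  # pve strictly decreases in n at fixed beta/se
  expect_lt(instrumentStrength(0.2, 0.04, 2000)$pve,
            instrumentStrength(0.2, 0.04, 1000)$pve)
  # k = 1, large n: F ~ z^2 within 2%
  for (z in c(5, 10, 20)) {
    s <- standardizeEffects(makeRecord(beta = z, se = 1, p = zp(z), n = 50000))
    f <- instrumentStrength(s$beta_std, s$se_std, 50000, 1)$f_stat
    expect_equal(f, z^2, tolerance = 0.02)
  }
})

test_that("selectInstruments recovers the planted causal eQTL per gene", {
  sim <- simulateRegion(makeScenario("shared_variant", seed = 21, mSnps = 41,
                                     ldRho = 0.9, eqtlPve = 0.1))
  inst <- selectInstruments(sim$eqtl, sim$ld)
  expect_gte(nrow(inst), 1)
  expect_true(all(c("beta_std", "se_std", "pve", "f_stat") %in% names(inst)))
  # pairwise r2 of retained instruments below the clump threshold
  if (nrow(inst) > 1) {
    r2 <- ldMatrix(sim$ld, squared = TRUE)[inst$variant_id, inst$variant_id]
    expect_true(all(r2[upper.tri(r2)] <= 0.001))
  }
  # the top instrument tags the causal variant tightly
  top <- inst$variant_id[which.min(inst$p)]
  r2c <- ldMatrix(sim$ld, squared = TRUE)[top, sim$truth$causalVariantIds]
  expect_gt(r2c, 0.5)
})

test_that("standardization plus strength recovers simulated per-SNP PVE", {
  pves <- vapply(1:200, function(i) {
    sim <- simulateRegion(makeScenario("eqtl_only", seed = 400 + i, mSnps = 3,
                                       ldRho = 0, eqtlPve = 0.04))
    ci <- match(sim$truth$causalVariantIds, sim$eqtl$variant_id)
    s <- standardizeEffects(sim$eqtl[ci, ])
    instrumentStrength(s$beta_std, s$se_std, s$n)$pve
  }, numeric(1))
  expect_equal(mean(pves), 0.04, tolerance = 0.15)
})
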