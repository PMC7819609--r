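test_that("matching, swapped and strand-complement alleles are resolved", {
  e <- makeRecord(effect_allele = "A", other_allele = "G", beta = 0.2, eaf = 0.3)

  same <- harmonizePair(e, makeRecord(effect_allele = "A", other_allele = "G",
                                      beta = 0.1))
  expect_equal(same$action, "unchanged")
  expect_equal(same$outcome$beta, 0.1)

  swap <- harmonizePair(e, makeRecord(effect_allele = "G", other_allele = "A",
                                      beta = 0.1, eaf = 0.7))
  expect_equal(swap$action, "sign_flipped")
  expect_equal(swap$outcome$beta, -0.1)
  expect_equal(swap$outcome$eaf, 0.3)

  strand <- harmonizePair(e, makeRecord(effect_allele = "T", other_allele = "C",
                                        beta = 0.1, eaf = 0.3))
  expect_equal(strand$action, "strand_flipped")
  expect_equal(strand$outcome$beta, 0.1)

  strandSwap <- harmonizePair(e, makeRecord(effect_allele = "C",
                                            other_allele = "T",
                                            beta = 0.1, eaf = 0.7))
  expect_equal(strandSwap$action, "sign_flipped")
  expect_equal(strandSwap$outcome$beta, -0.1)

  unmatched <- harmonizePair(e, makeRecord(effect_allele = "A",
                                           other_allele = "C"))
  expect_equal(unmatched$action, "dropped_unmatched")
})

test_that("palindromic variants near eaf 0.5 are dropped, others inferred by frequency", {
  pal <- makeRecord(effect_allele = "A", other_allele = "T", eaf = 0.50)
  expect_equal(harmonizePair(pal, makeRecord(effect_allele = "A",
                                             other_allele = "T",
                                             eaf = 0.50))$action,
               "dropped_palindromic")
  # band applies to either study
  palLow <- makeRecord(effect_allele = "A", other_allele = "T", eaf = 0.2)
  expect_equal(harmonizePair(palLow, makeRecord(effect_allele = "A",
                                                other_allele = "T",
                                                eaf = 0.45))$action,
               "dropped_palindromic")
  # concordant frequencies: kept as-is
  keep <- harmonizePair(palLow, makeRecord(effect_allele = "A",
                                           other_allele = "T",
                                           eaf = 0.25, beta = 0.1))
  expect_equal(keep$action, "unchanged")
  # discordant frequencies: effect allele inferred to be the other strand
  flip <- harmonizePair(palLow, makeRecord(effect_allele = "A",
                                           other_allele = "T",
                                           eaf = 0.8, beta = 0.1))
  expect_equal(flip$action, "sign_flipped")
  expect_equal(flip$outcome$beta, -0.1)
  expect_equal(flip$outcome$eaf, 0.2)
})

test_that("harmonization is idempotent and double sign-flip restores the record", {
  e <- makeRecord(effect_allele = "A", other_allele = "G", eaf = 0.3)
  cases <- list(
    makeRecord(effect_allele = "G", other_allele = "A", beta = 0.1, eaf = 0.7),
    makeRecord(effect_allele = "T", other_allele = "C", beta = 0.1, eaf = 0.3),
    makeRecord(effect_allele = "A", other_allele = "G", beta = -0.2, eaf = 0.4)
  )
  for (o in cases) {
    h1 <- harmonizePair(e, o)
    h2 <- harmonizePair(e, h1$outcome)
    expect_equal(h2$action, "unchanged")
    expect_equal(h2$outcome$beta, h1$outcome$beta)
  }
  # flipping twice is the identity on beta and eaf
  o <- makeRecord(effect_allele = "G", other_allele = "A", beta = 0.1, eaf = 0.7)
  once <- harmonizePair(e, o)$outcome
  eFlip <- makeRecord(effect_allele = "G", other_allele = "A", eaf = 0.7)
  twice <- harmonizePair(eFlip, once)$outcome
  expect_equal(twice$beta, o$beta)
  expect_equal(twice$eaf, o$eaf)
})

test_that("harmonizeSumstats joins on variant and drops unusable pairs", {
  exp <- rbind(makeRecord(variant_id = "rs1"),
               makeRecord(variant_id = "rs2", pos = 1001000),
               makeRecord(variant_id = "rs3", pos = 1002000,
                          effect_allele = "A", other_allele = "T", eaf = 0.5))
  out <- rbind(makeRecord(variant_id = "rs1", beta = 0.05),
               makeRecord(variant_id = "rs2", pos = 1001000,
                          effect_allele = "G", other_allele = "A",
                          beta = 0.05, eaf = 0.7),
               makeRecord(variant_id = "rs3", pos = 1002000,
                          effect_allele = "A", other_allele = "T", eaf = 0.5),
               makeRecord(variant_id = "rs4"))
  h <- harmonizeSumstats(exp, out)
  expect_equal(h$variant_id, c("rs1", "rs2"))   # rs3 palindromic, rs4 unshared
  expect_equal(h$beta_outcome, c(0.05, -0.05))
  expect_equal(h$action, c("unchanged", "sign_flipped"))
  hAll <- harmonizeSumstats(exp, out, dropRemoved = FALSE)
  expect_equal(hAll$action[3], "dropped_palindromic")
})
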