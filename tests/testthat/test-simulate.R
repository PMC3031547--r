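test_that("config validation enforces the declared invariants", {
  expect_error(familySimConfig(siteClassProps = c(0.5, 0.4)), "sum to 1")
  expect_error(familySimConfig(anchorPositions = c(5, 30, 40, 50, 60, 70),
                               signalLen = 10), "beyond the signal")
  expect_error(familySimConfig(nConserved = 2, nExpansion = 1), "at least 4")
  expect_error(familySimConfig(siteClassOmegas = c(-1, 1, 2)), ">= 0")
})

test_that("simulated tree has a monophyletic expansion clade and is deterministic", {
  cfg <- small_config(seed = 1, nConserved = 6, nExpansion = 7)
  tr <- simulateFamilyTree(cfg)
  expect_equal(ape::Ntip(tr), 13L)
  expect_true(ape::is.monophyletic(tr, grep("^exp", tr$tip.label,
                                            value = TRUE)))
  tr2 <- simulateFamilyTree(cfg)
  expect_identical(writeNewick(tr), writeNewick(tr2))
  fam1 <- evolveCodons(tr, cfg)
  fam2 <- evolveCodons(tr2, cfg)
  expect_identical(alignedSeqs(fam1@alignmentNt),
                   alignedSeqs(fam2@alignmentNt))
})

test_that("unattainable identity targets are rejected", {
  expect_error(simulateFamilyTree(small_config(1, targetIdentity = 0.97)),
               "targetIdentity")
  expect_error(simulateFamilyTree(small_config(1, targetIdentity = 0.05)),
               "unattainable")
})

test_that("deeper trees are less identical (depth-identity monotonicity)", {
  cfg <- small_config(seed = 4, indelRate = 0)
  tr <- simulateFamilyTree(cfg)
  ids <- vapply(c(1, 2), function(mult) {
    tr2 <- tr
    tr2$edge.length <- tr2$edge.length * mult
    mean(vapply(1:6, function(i) {
      cfg2 <- small_config(seed = 100 + i, indelRate = 0)
      percentIdentity(evolveCodons(tr2, cfg2)@alignmentAa)
    }, 0))
  }, 0)
  expect_lt(ids[2], ids[1])
})

test_that("evolved families respect the structural invariants", {
  fam <- simulateFamily(small_config(seed = 9))
  nt <- alignedSeqs(fam@alignmentNt)
  aa <- alignedSeqs(fam@alignmentAa)
  # translation commutes with alignment
  expect_equal(unname(vapply(nt, alnsens:::.translate_nt_row, "")),
               unname(aa))
  # gap runs divisible by 3
  gaps <- unlist(regmatches(nt, gregexpr("-+", nt)))
  expect_true(all(nchar(gaps) %% 3 == 0))
  # anchors carry C except in C-minus rows, which keep exactly 4
  census <- anchorCensus(fam@alignmentAa, fam@anchorColumns)
  expected <- ifelse(names(census) %in% fam@cminusLeaves, 4L, 6L)
  expect_equal(unname(census), expected)
  # ungapped nt length is 3x aa length
  expect_equal(unname(nchar(fam@unalignedNt)),
               unname(3L * nchar(fam@unalignedAa)))
  expect_equal(stripGaps(fam)$aa, fam@unalignedAa)
})

test_that("indelRate 0 gives a gapless true alignment", {
  fam <- simulateFamily(small_config(seed = 2, indelRate = 0))
  expect_false(any(grepl("-", alignedSeqs(fam@alignmentNt))))
  expect_equal(nCols(fam@alignmentNt), 90L * 3L)
})

test_that("omega 0 forbids amino-acid change outside C-minus edits", {
  # identity cannot decay when omega = 0, so skip calibration: reuse a tree
  # from a mixed-regime config and evolve under the purely synonymous one
  tr <- simulateFamilyTree(small_config(seed = 3, indelRate = 0))
  fam <- evolveCodons(tr, small_config(seed = 3, indelRate = 0,
                                       cminusFraction = 0,
                                       siteClassProps = 1,
                                       siteClassOmegas = 0))
  aa <- as.matrix(fam@alignmentAa)
  expect_true(all(apply(aa, 2, function(col) length(unique(col)) == 1L)))
  # but synonymous change did happen
  nt <- as.matrix(fam@alignmentNt)
  expect_gt(sum(apply(nt, 2, function(col) length(unique(col)) > 1L)), 0)
})

test_that("realized identity matches the target (calibration property)", {
  # default-style config at reduced size; +-0.05 band over seeds
  ids <- vapply(1:12, function(s) {
    percentIdentity(simulateFamily(small_config(seed = s,
                                                targetIdentity = 0.25,
                                                nCodons = 120L))@alignmentAa)
  }, 0)
  expect_lt(abs(mean(ids) - 0.25), 0.05)
  # the full-size default config, spot-checked at a few seeds
  ids18 <- vapply(c(7, 8, 9), function(s) {
    percentIdentity(simulateFamily(familySimConfig(seed = s))@alignmentAa)
  }, 0)
  expect_true(all(ids18 > 0.15 & ids18 < 0.25))
})

test_that("site classes are assigned at the declared proportions", {
  counts <- c(0, 0, 0)
  for (s in 1:8) {
    fam <- simulateFamily(small_config(seed = s))
    cls <- fam@siteClassOf
    counts <- counts + tabulate(cls[!is.na(cls)], 3)
  }
  p <- small_config(1)@siteClassProps
  test <- suppressWarnings(stats::chisq.test(counts, p = p))
  expect_gt(test$p.value, 0.001)
})

test_that("the expansion clade is recoverable from the true alignment", {
  hit <- vapply(1:10, function(s) {
    fam <- simulateFamily(familySimConfig(seed = s))
    tr <- bionjTree(proteinDistance(fam@alignmentAa, "poisson"))
    ape::is.monophyletic(tr, fam@expansionLeaves)
  }, NA)
  expect_gte(mean(hit), 0.9)
})
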