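test_that("core length spans the anchor columns", {
  expect_equal(coreLength(seqAlignment(c(a = "CAAC", b = "CAAC"), "aa")), 4L)
  expect_equal(coreLength(seqAlignment(c(a = "MKW", b = "MKW"), "aa")), 0L)
  # single anchor column is not a span
  expect_equal(coreLength(seqAlignment(c(a = "MCK", b = "MCK"), "aa")), 0L)
})

test_that("percent identity follows the shared non-gap convention", {
  expect_equal(percentIdentity(seqAlignment(c(a = "MKW", b = "MKW"), "aa")),
               1)
  expect_equal(percentIdentity(seqAlignment(c(a = "MK-", b = "M-K"), "aa")),
               1)  # only column 1 is shared, and it matches
  expect_equal(percentIdentity(seqAlignment(c(a = "M--", b = "-MM"), "aa")),
               0)  # no shared columns
})

test_that("table-2 metrics match brute-force rescans on random alignments", {
  set.seed(31)
  for (rep in 1:100) {
    aln <- rand_alignment(sample(3:10, 1), sample(5:60, 1),
                          gapProb = runif(1, 0, 0.4),
                          alpha = c("C", "M", "K", "W", "A"))
    expect_equal(coreLength(aln), oracle_core_length(aln))
    expect_equal(percentIdentity(aln), oracle_pct_identity(aln))
    expect_equal(parsimonyInformativeCount(aln),
                 oracle_pars_informative(aln))
  }
})

test_that("metrics are pure functions of the alignment", {
  aln <- rand_alignment(6, 30)
  expect_identical(percentIdentity(aln), percentIdentity(aln))
  expect_identical(coreLength(aln), coreLength(aln))
})

test_that("anchor census agrees with simulator truth", {
  fam <- simulateFamily(small_config(seed = 13, cminusFraction = 0.4))
  census <- anchorCensus(fam@alignmentAa, fam@anchorColumns)
  expect_equal(sort(names(census)[census == 4L]), sort(fam@cminusLeaves))
  expect_true(all(census[setdiff(names(census), fam@cminusLeaves)] == 6L))
  expect_error(anchorCensus(fam@alignmentAa, c(1, 1e6)), "out of range")
})

test_that("column congruence scores homology-pair agreement", {
  ref <- seqAlignment(c(a = "MK", b = "MK"), "aa")
  expect_equal(columnCongruence(ref, ref)$perColumnScore, c(1, 1))
  anti <- seqAlignment(c(a = "MK--", b = "--MK"), "aa")
  expect_equal(columnCongruence(ref, anti)$perColumnScore, c(0, 0))

  # 3-row toy with one shifted block, pair sets enumerated by hand:
  # ref col1 pairs {a1,b1},{a1,c1},{b1,c1}; alt co-aligns a1/b1 only.
  ref3 <- seqAlignment(c(a = "MKW", b = "MKW", c = "MKW"), "aa")
  alt3 <- seqAlignment(c(a = "MKW-", b = "MKW-", c = "-MKW"), "aa")
  sc <- columnCongruence(ref3, alt3)$perColumnScore
  expect_equal(sc, c(1 / 3, 1 / 3, 1 / 3))
  expect_error(columnCongruence(ref, seqAlignment(c(a = "MW", b = "MK"),
                                                  "aa")),
               "unaligned residues")
})

test_that("aggregate congruence is symmetric over the shared pair universe", {
  fam <- simulateFamily(small_config(seed = 14))
  a1 <- progressiveAlign(fam@unalignedAa, builtinPresets()[[1]])
  a2 <- progressiveAlign(fam@unalignedAa, builtinPresets()[[4]])
  pairs_of <- function(aln) {
    m <- as.matrix(aln)
    o <- alnsens:::.ordinal_matrix(m)
    out <- character()
    for (j in seq_len(ncol(m))) {
      rows <- which(!is.na(o[, j]))
      if (length(rows) < 2) next
      cmb <- combn(rows, 2)
      out <- c(out, paste(rownames(m)[cmb[1, ]], o[cbind(cmb[1, ], j)],
                          rownames(m)[cmb[2, ]], o[cbind(cmb[2, ], j)]))
    }
    out
  }
  p1 <- pairs_of(a1)
  p2 <- pairs_of(a2)
  expect_equal(length(intersect(p1, p2)) / length(p1),
               length(intersect(p2, p1)) / length(p1))
})

test_that("uncertainty profile is flat 1 for identical batteries", {
  aln <- rand_alignment(5, 25)
  prof <- uncertaintyProfile(list(aln, aln, aln))
  expect_equal(prof$perColumnScore, rep(1, nCols(aln)))
  expect_equal(prof$overall, 1)
  expect_length(uncertaintyProfile(list(aln, aln))$perColumnScore,
                nCols(aln))
})

test_that("signal region retains alignable blocks across the battery", {
  fam <- simulateFamily(familySimConfig(seed = 21))
  alns <- lapply(builtinPresets()[1:4], function(p) {
    progressiveAlign(fam@unalignedAa, p)
  })
  prof <- uncertaintyProfile(c(list(fam@alignmentAa), unname(alns)),
                             refIndex = 1)
  sig <- prof$perColumnScore[seq_len(fam@config@signalLen)]
  expect_gt(mean(sig), quantile(prof$perColumnScore, 0.05))
})

test_that("saturation index separates structure from saturation", {
  same <- seqAlignment(setNames(rep(paste(rep("ACDEFGHIKLMNPQRS", 2),
                                          collapse = ""), 5),
                                paste0("s", 1:5)), "aa")
  st <- saturationTest(same, nReps = 100, seed = 1)
  expect_equal(st$iss, 0)
  expect_false(st$saturated)
  expect_lt(st$pValue, 0.05)
  expect_equal(st$saturated, st$iss >= st$issC)

  # i.i.d. uniform columns: saturated in >= 90% of seeds
  set.seed(33)
  calls <- vapply(1:10, function(s) {
    aln <- rand_alignment(8, 50, gapProb = 0)
    saturationTest(aln, nReps = 150, seed = s)$saturated
  }, NA)
  expect_gte(mean(calls), 0.9)
})

test_that("saturation index grows with tree depth", {
  cfg <- small_config(seed = 17, indelRate = 0)
  tr <- simulateFamilyTree(cfg)
  iss <- vapply(c(0.5, 1, 2, 4), function(mult) {
    tr2 <- tr
    tr2$edge.length <- tr2$edge.length * mult
    mean(vapply(1:3, function(i) {
      fam <- evolveCodons(tr2, small_config(seed = 40 + i, indelRate = 0))
      saturationTest(fam@alignmentAa, nReps = 60, seed = i)$iss
    }, 0))
  }, 0)
  expect_true(all(diff(iss) > -0.01))  # non-decreasing on average
  expect_gt(iss[4], iss[1])
})

test_that("saturation test rejects unusable input", {
  expect_error(saturationTest(rand_alignment(3, 30), seed = 1),
               "at least 4 rows")
  tiny <- seqAlignment(setNames(rep("MKWC", 4), paste0("s", 1:4)), "aa")
  expect_error(saturationTest(tiny, seed = 1), "too few usable columns")
})
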