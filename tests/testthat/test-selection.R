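# Shared small fixture: one family with genuine positive selection, one
# nearly-neutral family, built once per test run.
fam_pos <- simulateFamily(small_config(seed = 101, indelRate = 0,
                                       nCodons = 150L,
                                       anchorPositions = c(15L, 40L, 60L,
                                                           90L, 110L, 130L),
                                       siteClassProps = c(0.5, 0.3, 0.2),
                                       siteClassOmegas = c(0.1, 1, 4),
                                       targetIdentity = 0.4))
fam_null <- simulateFamily(small_config(seed = 102, indelRate = 0,
                                        nCodons = 150L,
                                        anchorPositions = c(15L, 40L, 60L,
                                                            90L, 110L, 130L),
                                        siteClassProps = c(0.7, 0.3),
                                        siteClassOmegas = c(0.1, 1),
                                        targetIdentity = 0.4))

test_that("F3x4 frequencies follow the positional tallies", {
  # uniform nucleotide composition -> uniform sense-codon frequencies
  uni <- seqAlignment(c(a = "ACGT", b = "CAGT", c = "GTAC", d = "TGCA"),
                      "nt")
  expect_error(f3x4(uni), "frame")
  uni <- seqAlignment(c(a = "ACGTCANNN", b = "CATGTCNNN",
                        c = "GTACAGNNN", d = "TGCGTANNN"), "nt")
  pi <- f3x4(uni)
  expect_equal(sum(pi), 1)

  # hand-computable toy: tally the three positions literally
  toy <- seqAlignment(c(a = "ATGAAA", b = "ATGAAG"), "nt")
  pi <- f3x4(toy)
  f1 <- c(A = 1, C = 0, G = 0, T = 0)
  f2 <- c(A = 0.5, C = 0, G = 0, T = 0.5)
  f3 <- c(A = 0.25, G = 0.75, C = 0, T = 0)
  sense <- names(pi)
  manual <- vapply(sense, function(cod) {
    b <- strsplit(cod, "")[[1]]
    f1[b[1]] * f2[b[2]] * f3[b[3]]
  }, 0)
  manual <- manual / sum(manual)
  expect_equal(unname(pi), unname(manual))
})

test_that("codon rate matrix has the GY94 structure", {
  Q <- codonQ(2, 0, normalize = FALSE)
  tab <- alnsens:::.codon_tables()
  expect_true(all(Q[tab$nonsyn] == 0))
  Q <- codonQ(2.7, 0.37)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  pi <- rep(1 / 61, 61)
  expect_lt(max(abs(Q * pi - t(Q * pi))), 1e-12)   # detailed balance
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)  # unit rate
  set.seed(81)
  for (rep in 1:5) {
    Q <- codonQ(runif(1, 0.5, 8), runif(1, 0, 3), normalize = FALSE)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
  }
})

test_that("codon pruning equals exhaustive summation", {
  set.seed(83)
  tab <- alnsens:::.codon_tables()
  for (rep in 1:4) {
    tr <- ape::rtree(4, rooted = FALSE, br = function(k) runif(k, .05, .5))
    codons <- matrix(sample(tab$sense, 4 * 5, TRUE), 4,
                     dimnames = list(tr$tip.label, NULL))
    codons[2, 2] <- "---"
    aln <- seqAlignment(apply(codons, 1, paste, collapse = ""), "nt")
    pi <- rep(1 / 61, 61)
    pat <- alnsens:::.codon_patterns(aln, tr$tip.label)
    kappa <- runif(1, 1, 4); om <- runif(1, 0.05, 2)
    likf <- alnsens:::.codon_lik_factory(tr, pat, pi)
    ll <- likf(kappa, om, scale = 1)
    Q <- alnsens:::.codon_Q_raw(kappa, om, pi)
    po <- ape::reorder.phylo(tr, "postorder")
    Ps <- eigen_P_list(po, Q, pi)
    states <- pat$states
    states[states == 0L] <- NA_integer_
    oracle <- vapply(seq_len(ncol(states)), function(j) {
      oracle_site_lik(po, Q, pi, states[, j], Ps = Ps)
    }, 0)
    expect_lt(max(abs(ll - log(oracle))), 1e-8)
  }
})

test_that("LRT arithmetic and chi-square machinery are exact", {
  res <- lrt(-16240.8767, -16219.8, df = 2)
  expect_equal(res$statistic, 42.1534)
  expect_equal(lrt(-10, -10, 1)$statistic, 0)
  expect_equal(lrt(-10, -10, 1)$pChisq, 1)
  expect_equal(lrt(-10, -12, 2)$statistic, 0)  # floored at 0
  expect_equal(lrt(-10, -10 + 3.8415 / 2, 1)$pChisq, 0.05, tolerance = 1e-3)
  expect_error(lrt(-1, -1, 0), "df")
})

test_that("stop codons and all-gap sites are handled as declared", {
  bad <- seqAlignment(c(a = "ATGTAA", b = "ATGAAA"), "nt")
  tr <- NULL
  expect_error(alnsens:::.codon_patterns(bad, c("a", "b")),
               "stop codon in row 'a' at codon 2")
  gapped <- seqAlignment(c(a = "ATG---AAA", b = "ATG---AAA",
                           c = "ATG---AAG", d = "ATG---AAG"), "nt")
  expect_warning(alnsens:::.codon_patterns(gapped, c("a", "b", "c", "d")),
                 "all-gap codon site")
})

test_that("site models respect nesting dominance and recover parameters", {
  aln <- fam_pos@alignmentNt
  tr <- fam_pos@trueTree
  m0 <- fitSiteModel(aln, tr, "M0", nRestarts = 1)
  ini <- list(kappa = m0@kappa, scale = m0@extra$scale,
              w0 = min(m0@classOmegas[1], 0.9))
  m1 <- fitSiteModel(aln, tr, "M1a", nRestarts = 2, init = ini)
  m2 <- fitSiteModel(aln, tr, "M2a", nRestarts = 2,
                     init = c(ini, list(w2 = 2)))
  m7 <- fitSiteModel(aln, tr, "M7", nRestarts = 1, init = ini)
  m8 <- fitSiteModel(aln, tr, "M8", nRestarts = 1,
                     init = c(ini, list(ws = 2)))
  expect_gte(m1@lnL, m0@lnL - 1e-6)
  expect_gte(m2@lnL, m1@lnL - 1e-6)
  expect_gte(m8@lnL, m7@lnL - 1e-6)
  # strong true signal (20% of sites at omega 4) is detected
  expect_gt(lrt(m1@lnL, m2@lnL, 2)$statistic, 5.99)
  expect_gt(m2@classOmegas[3], 1.5)
  expect_s4_class(m2, "CodonModelFit")
  expect_true(m2@converged)
  # proportions live on the simplex
  expect_equal(sum(m2@classProps), 1, tolerance = 1e-9)
})

test_that("M0 recovers a known omega", {
  meds <- vapply(1:4, function(s) {
    fam <- simulateFamily(small_config(seed = 200 + s, indelRate = 0,
                                       nCodons = 200L,
                                       anchorPositions = c(15L, 40L, 60L,
                                                           90L, 110L, 130L),
                                       siteClassProps = 1,
                                       siteClassOmegas = 0.5,
                                       targetIdentity = 0.45))
    fitSiteModel(fam@alignmentNt, fam@trueTree, "M0",
                 nRestarts = 1)@classOmegas[1]
  }, 0)
  expect_gt(median(meds), 0.4)
  expect_lt(median(meds), 0.6)
})

test_that("empirical-Bayes site identification flags true targets", {
  aln <- fam_pos@alignmentNt
  tr <- fam_pos@trueTree
  m2 <- fitSiteModel(aln, tr, "M2a", nRestarts = 2, seed = 2)
  sp <- sitePosteriors(m2)
  expect_length(sp$pp, m2@nSites)
  expect_true(all(sp$pp >= 0 & sp$pp <= 1))
  expect_gt(length(sp$siteNumbers), 0)
  # flagged sites are mostly truly positive (class 3, omega = 4)
  truth <- fam_pos@siteClassOf[sp$siteNumbers]
  expect_gte(mean(truth == 3, na.rm = TRUE), 0.7)

  # beb-lite agrees on the strongest sites
  bl <- sitePosteriors(m2, method = "beb-lite", codonAln = aln, tree = tr)
  expect_equal(bl$method, "beb-lite")
  expect_gt(stats::cor(sp$pp, bl$pp), 0.8)

  expect_error(sitePosteriors(fitSiteModel(aln, tr, "M1a", nRestarts = 1)),
               "no positive-selection class")
})

test_that("posterior probabilities vanish when the positive class is empty", {
  aln <- fam_null@alignmentNt
  tr <- fam_null@trueTree
  m2 <- fitSiteModel(aln, tr, "M2a", nRestarts = 1, seed = 3)
  sp <- sitePosteriors(m2)
  if (m2@classProps[3] < 1e-4) {
    expect_true(all(sp$pp < 0.5))
  }
  expect_length(sp$pp, m2@nSites)
})

test_that("branch model separates foreground from background rates", {
  fam <- simulateFamily(small_config(seed = 103, indelRate = 0,
                                     nCodons = 150L,
                                     anchorPositions = c(15L, 40L, 60L, 90L,
                                                         110L, 130L),
                                     siteClassProps = 1,
                                     siteClassOmegas = 0.4,
                                     targetIdentity = 0.45))
  aln <- fam@alignmentNt
  tr <- fam@trueTree
  bm <- fitBranchModel(aln, tr, fam@expansionLeaves, nRestarts = 1)
  expect_gte(bm$ha@lnL, bm$h0@lnL - 1e-6)
  expect_equal(bm$lrt$df, 1L)
  expect_error(fitBranchModel(aln, tr, c("con01", "exp01"), nRestarts = 1),
               "available clades")
  # never reported as positive selection when foreground omega < 1
  if (bm$lrt$pChisq < 0.05 && bm$omegaFg < 1) {
    expect_match(bm$interpretation, "relaxed/purifying")
  }
})

test_that("branch-site model A nests properly and stays quiet under the null", {
  aln <- fam_null@alignmentNt
  tr <- fam_null@trueTree
  bs <- fitBranchSiteA(aln, tr, fam_null@expansionLeaves, nRestarts = 1)
  expect_gte(bs$ha@lnL, bs$h0@lnL - 1e-6)
  expect_lte(bs$lrt$statistic, 3.84)  # no foreground signal simulated
  expect_null(bs$sites)
})

test_that("the selection report compares alignments coherently", {
  aln <- fam_pos@alignmentNt
  tr <- fam_pos@trueTree
  rep2 <- selectionReport(list(aln, aln), list(tr, tr), nRestarts = 1,
                          seed = 5)
  expect_equal(nrow(rep2), 2L)
  expect_equal(rep2$lnL_M2a[1], rep2$lnL_M2a[2])
  needed <- c("lnL_M1a", "lnL_M2a", "LRT_M1a_M2a", "p_df2", "p_df1",
              "lnL_M7", "lnL_M8", "LRT_M7_M8", "flagged_sites")
  expect_true(all(needed %in% names(rep2)))
  ov <- attr(rep2, "siteOverlap")
  if (rep2$n_flagged[1] > 0) {
    expect_equal(ov[1, 2], 1)
  }
})
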