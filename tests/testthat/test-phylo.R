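test_that("protein distances follow their closed forms", {
  aln <- seqAlignment(c(a = "MMKK", b = "MMRR"), "aa")  # p = 0.5
  expect_equal(proteinDistance(aln, "p")["a", "b"], 0.5)
  expect_equal(proteinDistance(aln, "poisson")["a", "b"], -log(0.5))
  expect_equal(proteinDistance(aln, "gamma", alpha = 2)["a", "b"],
               2 * ((1 - 0.5)^(-1 / 2) - 1))
  # gamma -> poisson as alpha -> Inf
  expect_lt(abs(proteinDistance(aln, "gamma", alpha = 1e6)["a", "b"] -
                  proteinDistance(aln, "poisson")["a", "b"]), 1e-4)
  same <- seqAlignment(c(a = "MMKK", b = "MMKK"), "aa")
  expect_equal(proteinDistance(same, "gamma")["a", "b"], 0)
  expect_error(proteinDistance(seqAlignment(c(a = "M-", b = "-M"), "aa")),
               "share no non-gap")
})

test_that("BioNJ recovers additive distances exactly", {
  tru <- readNewick("((a:1,b:2):1,(c:3,d:4):0.5);")
  D <- ape::cophenetic.phylo(tru)
  tr <- bionjTree(D)
  expect_equal(rfDistance(tr, tru)$rf, 0L)
  expect_equal(sort(tr$edge.length), sort(ape::unroot(tru)$edge.length),
               tolerance = 1e-8)

  # 3 taxa: closed-form pair equations
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- bionjTree(D3)
  expect_equal(sort(t3$edge.length), c(1, 2, 3))

  # permutation invariance
  perm <- sample(rownames(D))
  t2 <- bionjTree(D[perm, perm])
  expect_equal(rfDistance(t2, tr)$rf, 0L)
  expect_error(bionjTree(matrix(c(0, 1, 2, 0), 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
  Dns <- D; Dns[1, 2] <- 99
  expect_error(bionjTree(Dns), "not symmetric")
})

test_that("tree likelihood matches the 2-taxon closed form", {
  mod <- proteinModel(alpha = 1, pInv = 0, nRateCats = 1L)
  Q <- alnsens:::.lg_Q(mod$freqs)
  P <- as.matrix(Matrix::expm(Q * 0.7))
  tr <- readNewick("(a:0.3,b:0.4);")
  aln <- seqAlignment(c(a = "M", b = "K"), "aa")
  i <- match("M", AA); j <- match("K", AA)
  expect_equal(treeLogLik(tr, aln, mod), log(mod$freqs[[i]] * P[i, j]),
               tolerance = 1e-8)
})

test_that("pruning equals exhaustive summation on small instances", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(4:5, 1)
    tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, .05, .9))
    aln <- rand_alignment(n, sample(4:10, 1), gapProb = 0.1)
    names(aln@seqs) <- tr$tip.label
    mod <- proteinModel(alpha = runif(1, 0.3, 2), pInv = runif(1, 0, 0.4),
                        nRateCats = sample(c(1L, 4L), 1))
    expect_equal(treeLogLik(tr, aln, mod), oracle_protein_lnl(tr, aln, mod),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to rerooting and leaf order", {
  fam <- simulateFamily(small_config(seed = 19, indelRate = 0))
  aln <- fam@alignmentAa
  mod <- proteinModel(alpha = 0.8, pInv = 0.1,
                      freqs = empiricalFreqs(aln))
  tr <- ape::unroot(fam@trueTree)
  l0 <- treeLogLik(tr, aln, mod)
  for (tip in tr$tip.label[1:3]) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = FALSE)
    expect_equal(treeLogLik(rr, aln, mod), l0, tolerance = 1e-7)
  }
})

test_that("branch-length optimization improves monotonically to a fixed point", {
  fam <- simulateFamily(small_config(seed = 23, indelRate = 0,
                                     nCodons = 160L,
                                     anchorPositions = c(15L, 40L, 60L, 90L,
                                                         110L, 130L)))
  aln <- fam@alignmentAa
  tr <- fam@trueTree
  l0 <- treeLogLik(tr, aln)
  fit <- optimizeBranchLengths(tr, aln, maxCycles = 10L)
  expect_gte(fit$lnL, l0 - 1e-9)
  fit2 <- optimizeBranchLengths(fit$tree, aln, fit$model, maxCycles = 10L)
  expect_lt(fit2$lnL - fit$lnL, 1e-2)
})

test_that("perturbed branch lengths are recovered", {
  set.seed(29)
  tru <- ape::rtree(6, rooted = FALSE, br = function(n) runif(n, 0.2, 0.8))
  aln <- simulate_lg_alignment(tru, 500L, seed = 29)
  pert <- tru
  pert$edge.length <- pert$edge.length * 2
  fit <- optimizeBranchLengths(pert, aln, proteinModel(nRateCats = 1L),
                               maxCycles = 25L)
  expect_lt(abs(treeSize(fit$tree) - treeSize(tru)) / treeSize(tru), 0.2)
  expect_gt(stats::cor(fit$tree$edge.length, tru$edge.length), 0.8)
})

test_that("NNI search finds the exhaustive 4-taxon optimum", {
  fam <- simulateFamily(small_config(seed = 31, nConserved = 2L,
                                     nExpansion = 2L, indelRate = 0,
                                     targetIdentity = 0.5))
  aln <- fam@alignmentAa
  res <- nniSearch(aln, nStarts = 2L, seed = 1)
  # exhaustive: all 3 unrooted topologies
  tips <- names(alignedSeqs(aln))
  best <- -Inf
  for (top in list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))) {
    nwk <- sprintf("((%s:0.3,%s:0.3):0.3,(%s:0.3,%s:0.3):0.3);",
                   tips[top[1]], tips[top[2]], tips[top[3]], tips[top[4]])
    fit <- optimizeBranchLengths(readNewick(nwk), aln, maxCycles = 10L)
    best <- max(best, fit$lnL)
  }
  expect_equal(res$lnL, best, tolerance = 1e-4)

  # hill-climbing contract and determinism
  bt <- bionjTree(proteinDistance(aln, "poisson"))
  expect_gte(res$lnL, treeLogLik(bt, aln) - 1e-9)
  res2 <- nniSearch(aln, nStarts = 2L, seed = 1)
  expect_identical(writeNewick(res$tree), writeNewick(res2$tree))
})

test_that("bootstrap supports behave at the contract level", {
  # clean, long-branch instance: balanced tree, generous internal branches
  tr <- readNewick(paste0("(((a:0.5,b:0.5):0.4,(c:0.5,d:0.5):0.4):0.2,",
                          "(e:0.5,f:0.5):0.4);"))
  tr <- ape::unroot(tr)
  aln <- simulate_lg_alignment(tr, 300L, seed = 37)
  bs <- bootstrapSupport(tr, aln, nReps = 40L, seed = 2)
  sup <- bs$support[-1]
  expect_length(bs$support, tr$Nnode)
  expect_true(all(sup >= 0 & sup <= 1))
  # clean, long-branch data: high support everywhere
  expect_true(all(sup >= 0.9))
  # no-op contract
  expect_identical(bootstrapSupport(tr, aln, nReps = 0L)$tree, tr)
})

test_that("Fitch parsimony matches exhaustive labelings", {
  cst <- seqAlignment(c(a = "MM", b = "MM", c = "MM", d = "MM"), "aa")
  tr4 <- readNewick("((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(fitchParsimony(tr4, cst), 0L)
  ab <- seqAlignment(c(a = "M", b = "M", c = "K", d = "K"), "aa")
  expect_equal(fitchParsimony(tr4, ab), 1L)

  set.seed(51)
  for (rep in 1:10) {
    tr <- ape::rtree(6, rooted = FALSE)
    aln <- rand_alignment(6, 8, gapProb = 0.15,
                          alpha = c("M", "K", "W", "C"))
    names(aln@seqs) <- tr$tip.label
    expect_equal(fitchParsimony(tr, aln), oracle_fitch(tr, aln))
  }
})

test_that("midpoint rooting balances the longest leaf path", {
  mt <- midpointRoot(readNewick("(a:1,b:3);"))
  d <- ape::cophenetic.phylo(mt)
  expect_equal(unname(d["a", "b"]), 4)
  dr <- ape::dist.nodes(mt)[, ape::Ntip(mt) + 1]
  expect_equal(unname(dr[1:2]), c(2, 2))

  set.seed(61)
  for (rep in 1:30) {
    tr <- ape::rtree(sample(4:10, 1))
    mt <- midpointRoot(tr)
    dd <- ape::cophenetic.phylo(mt)
    far <- which(dd == max(dd), arr.ind = TRUE)[1, ]
    droot <- ape::dist.nodes(mt)[, ape::Ntip(mt) + 1]
    expect_equal(unname(droot[far[1]]), unname(droot[far[2]]),
                 tolerance = 1e-9)
    expect_equal(treeSize(mt), treeSize(tr), tolerance = 1e-9)
  }
  expect_warning(midpointRoot(readNewick("(a:0,b:0);")), "zero length")
})

test_that("tree size sums branch lengths", {
  expect_equal(treeSize(readNewick("((a:1,b:1):1,c:2);")), 5)
})

test_that("ML search keeps the expansion clade monophyletic at study scale", {
  hit <- vapply(1:3, function(s) {
    fam <- simulateFamily(familySimConfig(seed = 70 + s))
    fit <- nniSearch(fam@alignmentAa, nStarts = 1L, seed = s, blCycles = 3L)
    ape::is.monophyletic(fit$tree, fam@expansionLeaves)
  }, NA)
  expect_gte(mean(hit), 2 / 3)
})
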