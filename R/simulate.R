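# Synthetic divergent gene families with known truth: birth-death-style gene
# tree with a rapid lineage-specific expansion clade, codon-level evolution
# under site-class dN/dS regimes, frozen cysteine anchors and signal-start
# methionine, whole-codon indels, and occasional loss of one cysteine pair.

#' Build a family simulation configuration
#'
#' Defaults emulate the study family: 18 lineages (11 conserved orthologs
#' plus a 7-gene expansion), ~150 codons, ~20\% target mean pairwise
#' amino-acid identity, a 19-codon signal region, six cysteine anchors with
#' realistic spacing, whole-codon indels at 0.01 events per substitution,
#' and a purifying-dominated site-class mixture with a small positively
#' selected fraction.
#'
#' @param nConserved,nExpansion Lineage counts (total >= 4).
#' @param nCodons Root sequence length in codons.
#' @param anchorPositions Six strictly increasing 1-based codon positions,
#'   all beyond the signal region.
#' @param signalLen Signal-peptide length in codons.
#' @param targetIdentity Target mean pairwise aa identity in (0, 1).
#' @param indelRate Whole-codon indel events per substitution.
#' @param kappa Transition/transversion ratio.
#' @param siteClassProps,siteClassOmegas Site-class mixture (proportions sum
#'   to 1; omegas >= 0).
#' @param cminusFraction Per-lineage probability of losing the C2/C5 pair.
#' @param seed Master seed.
#' @return A [FamilySimConfig-class].
#' @export
familySimConfig <- function(nConserved = 11L, nExpansion = 7L,
                            nCodons = 150L,
                            anchorPositions = c(30L, 58L, 62L, 100L, 112L,
                                                121L),
                            signalLen = 19L, targetIdentity = 0.20,
                            indelRate = 0.01, kappa = 2,
                            siteClassProps = c(0.60, 0.30, 0.10),
                            siteClassOmegas = c(0.08, 0.60, 2.50),
                            cminusFraction = 0.10, seed = 1L) {
  new("FamilySimConfig", nConserved = as.integer(nConserved),
      nExpansion = as.integer(nExpansion), nCodons = as.integer(nCodons),
      anchorPositions = as.integer(anchorPositions),
      signalLen = as.integer(signalLen),
      targetIdentity = as.numeric(targetIdentity),
      indelRate = as.numeric(indelRate), kappa = as.numeric(kappa),
      siteClassProps = as.numeric(siteClassProps),
      siteClassOmegas = as.numeric(siteClassOmegas),
      cminusFraction = as.numeric(cminusFraction), seed = as.integer(seed))
}

# Mixture-normalized class rate matrices for a config (uniform codon
# frequencies on the simulation side).
.sim_class_Qs <- function(config) {
  pi <- rep(1 / 61, 61)
  Qs <- lapply(config@siteClassOmegas, function(om) {
    .codon_Q_raw(config@kappa, om, pi)
  })
  rates <- vapply(Qs, .codon_rate, 0, pi = pi)
  R <- sum(config@siteClassProps * rates)
  list(Qs = lapply(Qs, function(Q) Q / R), pi = pi)
}

# Analytic expected aa identity between two sequences at codon-path
# distance d (expected substitutions/codon at the mixture mean), frozen
# anchor/M columns accounted for. Match probability per class is expanded in
# the eigenbasis, m_c(d) = sum_l coef_l exp(lambda_l d), so evaluation per
# distance is O(61).
.expected_identity <- function(config, dvec) {
  cq <- .sim_class_Qs(config)
  tab <- .codon_tables()
  sameAA <- outer(tab$aa, tab$aa, "==") * 1
  systems <- lapply(cq$Qs, function(Q) .rev_eigen_cpp(Q, cq$pi))
  coefs <- lapply(systems, function(sys) {
    vapply(seq_len(61L), function(l) {
      sum((cq$pi * sys$U[, l]) * (sameAA %*% sys$Uinv[l, ]))
    }, 0)
  })
  lams <- lapply(systems, function(sys) sys$lambda)
  nFrozen <- 7L
  L <- config@nCodons
  vapply(dvec, function(d) {
    m <- sum(vapply(seq_along(coefs), function(c) {
      config@siteClassProps[c] * sum(coefs[[c]] * exp(lams[[c]] * d))
    }, 0))
    m <- min(max(m, 0), 1)
    (nFrozen + (L - nFrozen) * m) / L
  }, 0)
}

# identity floor: two independent stationary sequences
.identity_floor <- function(config) {
  tab <- .codon_tables()
  aaFreq <- table(tab$aa) / 61
  m <- sum(aaFreq^2)
  (7 + (config@nCodons - 7) * m) / config@nCodons
}

#' Simulate the family gene tree
#'
#' A random gene tree with \code{nConserved} conserved-ortholog lineages and
#' a monophyletic expansion clade of \code{nExpansion} lineages: the clade
#' sits on a long stem (an old duplication) and all its internal divergences
#' are shortened by a radiation factor (a recent, rapid radiation).
#' The whole tree is then depth-scaled, by bisection on the analytic
#' expected pairwise amino-acid identity of the codon process along the
#' tree's path lengths, so that the realized mean identity matches
#' \code{targetIdentity}. Deterministic for a fixed config.
#'
#' @param config A [FamilySimConfig-class].
#' @param radiationFactor Multiplier (< 1) on expansion-clade internal
#'   branches.
#' @return An \code{ape::phylo} with leaf names \code{con01..} and
#'   \code{exp01..}.
#' @export
simulateFamilyTree <- function(config, radiationFactor = 0.35) {
  validObject(config)
  floor_id <- .identity_floor(config)
  if (config@targetIdentity > 0.95 ||
      config@targetIdentity < floor_id + 0.01) {
    stop("unattainable targetIdentity ", config@targetIdentity,
         " (attainable range ~[", round(floor_id + 0.01, 3), ", 0.95])")
  }
  tree <- .with_stream(config@seed, "tree", {
    nc <- config@nConserved
    ne <- config@nExpansion
    backbone <- ape::rtree(nc + 1L, rooted = TRUE,
                           tip.label = c(sprintf("con%02d", seq_len(nc)),
                                         "EXPSTEM"),
                           br = function(n) rexp(n, 2))
    expclade <- ape::rtree(ne, rooted = TRUE,
                           tip.label = sprintf("exp%02d", seq_len(ne)),
                           br = function(n) rexp(n, 2))
    # a recent radiation: every divergence inside the clade is young, the
    # stem that separates it from the orthologs is old
    expclade$edge.length <- expclade$edge.length * radiationFactor
    expclade$root.edge <- 1.0
    ape::bind.tree(backbone, expclade, where = match("EXPSTEM",
                                                     backbone$tip.label))
  })
  # calibrate the depth multiplier: bisection on the analytic expected
  # pairwise identity, then up to two pilot simulations to absorb what the
  # analytic curve does not model (indel columns are younger than the root,
  # so they pull the realized identity up)
  d <- cophenetic(tree)
  pd <- d[upper.tri(d)]
  solve_mult <- function(target) {
    f <- function(mult) {
      mean(.expected_identity(config, pd * mult)) - target
    }
    lo <- 1e-3
    hi <- 1
    while (f(hi) > 0 && hi < 2000) hi <- hi * 2
    tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-4)$root,
             error = function(e) {
               stop("identity calibration failed: ", conditionMessage(e))
             })
  }
  floor_adj <- floor_id + 0.015
  target <- config@targetIdentity
  mult <- solve_mult(target)
  if (config@indelRate > 0) {
    for (iter in 1:2) {
      tr2 <- tree
      tr2$edge.length <- tr2$edge.length * mult
      pilot <- evolveCodons(tr2, config)
      realized <- percentIdentity(pilot@alignmentAa)
      if (abs(realized - config@targetIdentity) < 0.015) break
      analytic <- mean(.expected_identity(config, pd * mult))
      target <- max(config@targetIdentity - (realized - analytic),
                    floor_adj)
      mult <- solve_mult(target)
    }
  }
  tree$edge.length <- tree$edge.length * mult
  tree
}

# sample child codon indices given parent indices, grouped by parent state
.sample_codons <- function(P, parents) {
  out <- integer(length(parents))
  for (i in unique(parents)) {
    sel <- which(parents == i)
    out[sel] <- sample.int(61L, length(sel), replace = TRUE, prob = P[i, ])
  }
  out
}

#' Evolve codon sequences along a tree
#'
#' Each codon column is assigned a site class by the configured proportions
#' and evolves under a Goldman-Yang process with that class's dN/dS and the
#' global kappa (class matrices jointly scaled so branch lengths are
#' expected substitutions per codon at the mixture mean). The six anchor
#' columns (cysteine) and the initial methionine are frozen. Whole-codon
#' indel events occur at \code{indelRate} per substitution with geometric
#' lengths (mean 2 codons) and never touch frozen columns; insertions enter
#' the alignment bookkeeping so the emitted true alignment is the exact
#' homology map. Lineages lose the C2/C5 cysteine pair with probability
#' \code{cminusFraction}.
#'
#' @param tree Tree from [simulateFamilyTree()] (leaf count must match the
#'   config).
#' @param config The [FamilySimConfig-class].
#' @return A [SimulatedFamily-class].
#' @export
evolveCodons <- function(tree, config) {
  validObject(config)
  nTip <- ape::Ntip(tree)
  if (nTip != config@nConserved + config@nExpansion) {
    stop("tree has ", nTip, " leaves but config declares ",
         config@nConserved + config@nExpansion)
  }
  tab <- .codon_tables()
  cq <- .sim_class_Qs(config)
  nclass <- length(config@siteClassProps)
  sys <- lapply(cq$Qs, function(Q) .rev_eigen_cpp(Q, cq$pi))
  cysIdx <- which(tab$aa == "C")
  metIdx <- which(tab$aa == "M")
  nonCys <- which(tab$aa != "C")

  .with_stream(config@seed, "evolve", {
    L <- config@nCodons
    colIds <- paste0("r", seq_len(L))          # root columns
    colOrder <- colIds                         # master column order
    colClass <- setNames(sample.int(nclass, L, replace = TRUE,
                                    prob = config@siteClassProps), colIds)
    frozen <- setNames(rep(FALSE, L), colIds)
    frozen[c(1L, config@anchorPositions)] <- TRUE
    colClass[frozen[colIds]] <- NA_integer_

    root <- setNames(sample.int(61L, L, replace = TRUE), colIds)
    root[1L] <- metIdx
    root[config@anchorPositions] <- sample(cysIdx, 6L, replace = TRUE)

    nextId <- L + 1L
    po <- ape::reorder.phylo(tree, "postorder")
    # preorder: parents before children
    pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
    lens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
    seqs <- vector("list", nTip + tree$Nnode)
    seqs[[nTip + 1L]] <- root

    for (e in seq_len(nrow(pre))) {
      par <- pre[e, 1L]; chi <- pre[e, 2L]; t <- lens[e]
      s <- seqs[[par]]
      ids <- names(s)
      # substitutions per class
      Ps <- lapply(sys, function(y) .pmat_cpp(y$U, y$lambda, y$Uinv, t))
      out <- s
      for (cl in seq_len(nclass)) {
        sel <- which(!is.na(colClass[ids]) & colClass[ids] == cl)
        if (length(sel)) out[sel] <- .sample_codons(Ps[[cl]], s[sel])
      }
      # indels: whole-codon, never on frozen columns
      nSub <- rpois(1L, t * length(out))
      nEvents <- rpois(1L, config@indelRate * nSub)
      for (ev in seq_len(nEvents)) {
        len <- 1L + rgeom(1L, 0.5)
        if (runif(1) < 0.5 && length(out) > len + 7L) {     # deletion
          ok <- FALSE
          for (try in 1:20) {
            at <- sample.int(max(length(out) - len, 1L), 1L)
            span <- at:(at + len - 1L)
            if (!any(frozen[names(out)[span]])) { ok <- TRUE; break }
          }
          if (ok) out <- out[-span]
        } else {                                            # insertion
          at <- sample.int(length(out), 1L)
          anchorCol <- names(out)[at]
          newIds <- paste0("i", nextId:(nextId + len - 1L))
          nextId <- nextId + len
          newClass <- sample.int(nclass, len, replace = TRUE,
                                 prob = config@siteClassProps)
          colClass[newIds] <- newClass
          frozen[newIds] <- FALSE
          newCod <- setNames(sample.int(61L, len, replace = TRUE), newIds)
          out <- append(out, newCod, after = at)
          # splice into the master column order after the anchoring column
          pos <- match(anchorCol, colOrder)
          if (is.na(pos)) pos <- length(colOrder)
          colOrder <- append(colOrder, newIds, after = pos)
        }
      }
      seqs[[chi]] <- out
    }

    # C-minus lineages: lose anchors C2 and C5
    cminus <- tree$tip.label[runif(nTip) < config@cminusFraction]
    a25 <- colIds[config@anchorPositions[c(2L, 5L)]]
    for (leaf in cminus) {
      i <- match(leaf, tree$tip.label)
      s <- seqs[[i]]
      hit <- intersect(a25, names(s))
      s[hit] <- sample(nonCys, length(hit), replace = TRUE)
      seqs[[i]] <- s
    }

    # assemble alignment over the master column order
    aligned <- vapply(seq_len(nTip), function(i) {
      s <- seqs[[i]]
      cods <- setNames(rep("---", length(colOrder)), colOrder)
      cods[names(s)] <- tab$sense[s]
      paste(cods, collapse = "")
    }, "")
    names(aligned) <- tree$tip.label
    # drop columns absent from every leaf (events on internal paths only)
    occupied <- rep(FALSE, length(colOrder))
    for (i in seq_len(nTip)) {
      occupied[match(names(seqs[[i]]), colOrder)] <- TRUE
    }
    keepCols <- which(occupied)
    ntRows <- vapply(aligned, function(s) {
      cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      paste(cods[keepCols], collapse = "")
    }, "")
    colOrder <- colOrder[keepCols]

    alnNt <- seqAlignment(ntRows, "nt", "truth")
    aaRows <- vapply(ntRows, .translate_nt_row, "")
    names(aaRows) <- names(ntRows)
    alnAa <- seqAlignment(aaRows, "aa", "truth")

    new("SimulatedFamily",
        trueTree = tree,
        alignmentNt = alnNt,
        alignmentAa = alnAa,
        unalignedNt = gsub("-", "", ntRows, fixed = TRUE),
        unalignedAa = gsub("-", "", aaRows, fixed = TRUE),
        siteClassOf = unname(colClass[colOrder]),
        anchorColumns = match(colIds[config@anchorPositions], colOrder),
        expansionLeaves = grep("^exp", tree$tip.label, value = TRUE),
        cminusLeaves = cminus,
        config = config)
  })
}

#' Simulate a complete family
#'
#' Convenience wrapper: [simulateFamilyTree()] then [evolveCodons()].
#'
#' @inheritParams simulateFamilyTree
#' @return A [SimulatedFamily-class].
#' @examples
#' fam <- simulateFamily(familySimConfig(nConserved = 4, nExpansion = 4,
#'                                       nCodons = 60, seed = 3,
#'                                       anchorPositions = c(12, 20, 24, 38,
#'                                                           45, 52),
#'                                       signalLen = 8))
#' fam
#' @export
simulateFamily <- function(config, radiationFactor = 0.35) {
  tree <- simulateFamilyTree(config, radiationFactor)
  evolveCodons(tree, config)
}
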