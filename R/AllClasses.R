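#' Multiple sequence alignment container
#'
#' A rectangular, gap-padded residue matrix stored as one string per row,
#' together with the molecule type and a label identifying the alignment
#' method that produced it. Gaps are always \code{"-"} (a \code{"."} in
#' input is normalized on read). Columns are indexed 0-based internally and
#' reported 1-based in report tables.
#'
#' @slot seqs Named character vector, one gapped sequence per row; all rows
#'   have equal width and names are unique, non-empty, whitespace-free ids.
#' @slot moltype Either \code{"aa"} or \code{"nt"}.
#' @slot methodLabel Free-text label of the producing method (e.g. a preset
#'   name or \code{"PRANK"} for an ingested external alignment).
#'
#' @seealso [seqAlignment()], [readAlignment()], [alignedSeqs()]
#' @export
setClass("SeqAlignment",
  representation(seqs = "character", moltype = "character",
                 methodLabel = "character"),
  validity = function(object) {
    s <- object@seqs
    msg <- character()
    if (length(s) < 2L) msg <- c(msg, "alignment needs at least 2 rows")
    if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == "")) {
      msg <- c(msg, "every row needs a non-empty id")
    } else {
      if (anyDuplicated(names(s))) msg <- c(msg, "duplicate row ids")
      if (any(grepl("[[:space:]]", names(s)))) {
        msg <- c(msg, "row ids must not contain whitespace")
      }
    }
    if (length(unique(nchar(s))) > 1L) {
      msg <- c(msg, "rows have unequal lengths")
    }
    if (!object@moltype %in% c("aa", "nt")) {
      msg <- c(msg, "moltype must be 'aa' or 'nt'")
    } else {
      alpha <- c(if (object@moltype == "aa") .aa_alphabet else .nt_alphabet,
                 "-")
      bad <- grepl(paste0("[^", paste(alpha, collapse = ""), "]"),
                   s)
      if (any(bad)) {
        msg <- c(msg, paste0("illegal character in row '",
                             names(s)[bad][1], "'"))
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SeqAlignment
#'
#' @param seqs Named character vector of equal-width gapped sequences
#'   (uppercased; \code{"."} normalized to \code{"-"}).
#' @param moltype \code{"aa"} or \code{"nt"}.
#' @param methodLabel Method label stored verbatim.
#' @return A [SeqAlignment-class] object.
#' @examples
#' seqAlignment(c(a = "M-K", b = "MLK"), "aa", "toy")
#' @export
seqAlignment <- function(seqs, moltype = c("aa", "nt"), methodLabel = "") {
  moltype <- match.arg(moltype)
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  new("SeqAlignment", seqs = seqs, moltype = moltype,
      methodLabel = as.character(methodLabel))
}

#' @describeIn SeqAlignment-class Named character vector of gapped rows.
#' @param x,object A \code{SeqAlignment}.
#' @export
alignedSeqs <- function(x) x@seqs

#' @describeIn SeqAlignment-class Molecule type (\code{"aa"}/\code{"nt"}).
#' @export
molType <- function(x) x@moltype

#' @describeIn SeqAlignment-class Method label.
#' @export
methodLabel <- function(x) x@methodLabel

#' @describeIn SeqAlignment-class Number of rows.
#' @export
nRows <- function(x) length(x@seqs)

#' @describeIn SeqAlignment-class Number of columns.
#' @export
nCols <- function(x) nchar(x@seqs[[1]])

#' @describeIn SeqAlignment-class Character matrix (rows x columns).
#' @param ... Unused.
#' @export
setMethod("as.matrix", "SeqAlignment", function(x, ...) .chr_mat(x@seqs))

setMethod("show", "SeqAlignment", function(object) {
  cat(sprintf("SeqAlignment: %d x %d (%s)%s\n", nRows(object),
              nCols(object), object@moltype,
              if (nzchar(object@methodLabel)) {
                paste0(" [", object@methodLabel, "]")
              } else ""))
  ids <- names(object@seqs)
  k <- min(5L, length(ids))
  w <- min(60L, nCols(object))
  for (i in seq_len(k)) {
    cat(sprintf("  %-12s %s%s\n", ids[i], substr(object@seqs[i], 1, w),
                if (nCols(object) > w) "..." else ""))
  }
  if (length(ids) > k) cat("  ...\n")
})

#' Gene-family simulation configuration
#'
#' Parameters of the synthetic divergent-family generator. Defaults emulate
#' an odorant-binding-protein-like family: 18 lineages of ~150 codons at
#' ~20\% mean pairwise amino-acid identity, an N-terminal signal-peptide
#' region, six conserved cysteine anchors with occasional loss of one pair,
#' a rapid lineage-specific expansion clade of seven genes, whole-codon
#' indels, and a mixture of per-site selective regimes (site classes with
#' distinct dN/dS).
#'
#' @slot nConserved Number of conserved-ortholog lineages.
#' @slot nExpansion Number of expansion-clade lineages.
#' @slot nCodons Family length in codons (root sequence).
#' @slot anchorPositions Six strictly increasing 1-based codon positions that
#'   carry the conserved cysteines C1..C6; all at or beyond the signal region.
#' @slot signalLen Signal-peptide length in codons (position 1 is a frozen M).
#' @slot targetIdentity Target mean pairwise amino-acid identity.
#' @slot indelRate Whole-codon indel events per substitution.
#' @slot kappa Transition/transversion rate ratio.
#' @slot siteClassProps Site-class proportions (sum to 1).
#' @slot siteClassOmegas Site-class dN/dS values (same length, all >= 0).
#' @slot cminusFraction Probability that a lineage loses the C2/C5 pair.
#' @slot seed Master seed; named child streams derive from it per operation.
#' @seealso [familySimConfig()], [simulateFamily()]
#' @export
setClass("FamilySimConfig",
  representation(nConserved = "integer", nExpansion = "integer",
                 nCodons = "integer", anchorPositions = "integer",
                 signalLen = "integer", targetIdentity = "numeric",
                 indelRate = "numeric", kappa = "numeric",
                 siteClassProps = "numeric", siteClassOmegas = "numeric",
                 cminusFraction = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nConserved + object@nExpansion < 4L) {
      msg <- c(msg, "need at least 4 lineages in total")
    }
    if (length(object@anchorPositions) != 6L ||
        is.unsorted(object@anchorPositions, strictly = TRUE)) {
      msg <- c(msg, "anchorPositions must be 6 strictly increasing values")
    }
    if (any(object@anchorPositions <= object@signalLen)) {
      msg <- c(msg, "anchors must lie beyond the signal region")
    }
    if (max(object@anchorPositions) > object@nCodons) {
      msg <- c(msg, "anchors must lie within the sequence")
    }
    if (abs(sum(object@siteClassProps) - 1) > 1e-9) {
      msg <- c(msg, "site-class proportions must sum to 1")
    }
    if (length(object@siteClassProps) != length(object@siteClassOmegas)) {
      msg <- c(msg, "one omega per site class required")
    }
    if (any(object@siteClassOmegas < 0)) msg <- c(msg, "omegas must be >= 0")
    if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
    if (object@indelRate < 0) msg <- c(msg, "indelRate must be >= 0")
    if (object@cminusFraction < 0 || object@cminusFraction > 1) {
      msg <- c(msg, "cminusFraction must be in [0,1]")
    }
    if (object@targetIdentity <= 0 || object@targetIdentity >= 1) {
      msg <- c(msg, "targetIdentity must be in (0,1)")
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "FamilySimConfig", function(object) {
  cat(sprintf(
    "FamilySimConfig: %d conserved + %d expansion lineages, %d codons\n",
    object@nConserved, object@nExpansion, object@nCodons))
  cat(sprintf("  target identity %.2f, kappa %.2f, indel rate %.3f, seed %d\n",
              object@targetIdentity, object@kappa, object@indelRate,
              object@seed))
  cat(sprintf("  site classes: %s\n",
              paste(sprintf("%.2f@omega=%.2f", object@siteClassProps,
                            object@siteClassOmegas), collapse = ", ")))
})

#' Simulated gene family with known truth
#'
#' The output of [evolveCodons()]: true tree, true codon-aware nucleotide and
#' amino-acid alignments, the unaligned sequences, per-column site-class
#' truth, anchor-column coordinates, and the identities of expansion-clade
#' and C-minus lineages.
#'
#' @slot trueTree \code{ape::phylo} gene tree the sequences evolved on.
#' @slot alignmentNt True codon alignment ([SeqAlignment-class], nt).
#' @slot alignmentAa True amino-acid alignment.
#' @slot unalignedNt,unalignedAa Named character vectors of gap-stripped rows.
#' @slot siteClassOf Integer true class index per codon column (NA for
#'   frozen anchor/M columns).
#' @slot anchorColumns Six 1-based codon-column indices of C1..C6.
#' @slot expansionLeaves,cminusLeaves Character vectors of leaf ids.
#' @slot config The generating [FamilySimConfig-class].
#' @export
setClass("SimulatedFamily",
  representation(trueTree = "ANY", alignmentNt = "SeqAlignment",
                 alignmentAa = "SeqAlignment", unalignedNt = "character",
                 unalignedAa = "character", siteClassOf = "integer",
                 anchorColumns = "integer", expansionLeaves = "character",
                 cminusLeaves = "character", config = "FamilySimConfig"))

setMethod("show", "SimulatedFamily", function(object) {
  cat(sprintf("SimulatedFamily: %d lineages, %d codon columns\n",
              nRows(object@alignmentNt), nCols(object@alignmentNt) %/% 3L))
  cat(sprintf("  expansion clade: %s\n",
              paste(object@expansionLeaves, collapse = ", ")))
  cat(sprintf("  C-minus lineages: %s\n",
              if (length(object@cminusLeaves)) {
                paste(object@cminusLeaves, collapse = ", ")
              } else "none"))
})

#' Progressive aligner preset
#'
#' A named parameterization of the in-package progressive aligner:
#' substitution matrix, affine gap costs, and guide-tree strategy. The six
#' built-in presets (see [builtinPresets()]) span strict/loose gap costs,
#' two substitution matrices and two guide strategies, standing in for the
#' spread of behaviors among common external MSA programs; externally
#' computed alignments can be ingested with [readAlignment()].
#'
#' @slot name Preset name (stored as the alignment's method label).
#' @slot substMatrix Symmetric 20x20 (or larger) integer score matrix.
#' @slot matrixName Name of the score matrix.
#' @slot gapOpen,gapExtend Affine gap costs, \code{gapOpen <= gapExtend < 0};
#'   a gap run of length k costs \code{gapOpen + k * gapExtend}.
#' @slot guide Guide-tree strategy: \code{"identity-kmer"} (k-mer distance +
#'   UPGMA) or \code{"distance-NJ"} (pairwise alignment distances + NJ).
#' @export
setClass("AlignerPreset",
  representation(name = "character", substMatrix = "matrix",
                 matrixName = "character", gapOpen = "numeric",
                 gapExtend = "numeric", guide = "character"),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@substMatrix, t(object@substMatrix)))) {
      msg <- c(msg, "substitution matrix must be symmetric")
    }
    if (!(object@gapOpen <= object@gapExtend && object@gapExtend < 0)) {
      msg <- c(msg, "need gapOpen <= gapExtend < 0")
    }
    if (!object@guide %in% c("identity-kmer", "distance-NJ")) {
      msg <- c(msg, "guide must be 'identity-kmer' or 'distance-NJ'")
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "AlignerPreset", function(object) {
  cat(sprintf("AlignerPreset '%s': %s, gap %g/%g, guide %s\n", object@name,
              object@matrixName, object@gapOpen, object@gapExtend,
              object@guide))
})

#' Fitted codon model
#'
#' Result of [fitSiteModel()], [fitBranchModel()] or [fitBranchSiteA()]:
#' maximum-likelihood estimates of a Goldman-Yang style codon model on a
#' fixed topology.
#'
#' @slot modelTag One of \code{"M0","M1a","M2a","M7","M8","branch2",
#'   "branchsiteA","branchsiteA0"}.
#' @slot kappa Estimated transition/transversion ratio.
#' @slot pi F3x4 sense-codon frequencies used.
#' @slot classProps Estimated site-class proportions.
#' @slot classOmegas Estimated site-class dN/dS values (for beta models the
#'   discretized category values).
#' @slot extra Named list of model-specific estimates (beta shapes, scale,
#'   foreground/background omegas, ...).
#' @slot lnL Maximized natural-log likelihood.
#' @slot converged TRUE when the best two restarts agree within 0.01 lnL
#'   (always TRUE for a single restart).
#' @slot nRestartsAgreeing Number of restarts within 0.01 of the best lnL.
#' @slot siteLik Per-class conditional site likelihood matrix at the MLE
#'   (classes x sites), the input to [sitePosteriors()].
#' @slot nSites Number of codon sites retained.
#' @export
setClass("CodonModelFit",
  representation(modelTag = "character", kappa = "numeric", pi = "numeric",
                 classProps = "numeric", classOmegas = "numeric",
                 extra = "list", lnL = "numeric", converged = "logical",
                 nRestartsAgreeing = "integer", siteLik = "matrix",
                 nSites = "integer"))

setMethod("show", "CodonModelFit", function(object) {
  cat(sprintf("CodonModelFit %s: lnL = %.4f (kappa = %.3f)%s\n",
              object@modelTag, object@lnL, object@kappa,
              if (object@converged) "" else "  [not converged]"))
  if (length(object@classProps)) {
    cat(sprintf("  classes: %s\n",
                paste(sprintf("p=%.3f omega=%.3f", object@classProps,
                              object@classOmegas), collapse = "; ")))
  }
})
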