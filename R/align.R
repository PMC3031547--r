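# Progressive multiple alignment with affine gaps: preset battery standing
# in for a spread of external MSA programs, so the sensitivity analysis can
# run self-contained. External alignments are ingested via readAlignment().

.get_submatrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e2) FALSE)
  if (!ok || !exists(name, envir = e)) {
    stop("unknown substitution matrix '", name, "'")
  }
  m <- get(name, envir = e)
  m[.AA20, .AA20]
}

#' Create an aligner preset
#'
#' @param name Preset name; recorded as the method label on alignments.
#' @param matrixName A Biostrings substitution matrix name (e.g.
#'   \code{"BLOSUM62"}, \code{"BLOSUM45"}, \code{"PAM250"}).
#' @param gapOpen,gapExtend Affine gap costs; \code{gapOpen <= gapExtend < 0}.
#'   A gap run of length k costs \code{gapOpen + k * gapExtend}.
#' @param guide Guide-tree strategy, \code{"distance-NJ"} (pairwise alignment
#'   distances, neighbor joining) or \code{"identity-kmer"} (shared 3-mer
#'   distance, UPGMA).
#' @return An [AlignerPreset-class].
#' @examples
#' alignerPreset("strict62-nj")
#' @export
alignerPreset <- function(name, matrixName = "BLOSUM62", gapOpen = -10,
                          gapExtend = -1,
                          guide = c("distance-NJ", "identity-kmer")) {
  guide <- match.arg(guide)
  new("AlignerPreset", name = name, substMatrix = .get_submatrix(matrixName),
      matrixName = matrixName, gapOpen = gapOpen, gapExtend = gapExtend,
      guide = guide)
}

#' The built-in preset battery
#'
#' Six presets spanning strict/loose gap costs, two substitution matrices
#' and two guide-tree strategies. On divergent families they disagree in
#' alignment length and column homology, which is the raw material of the
#' sensitivity analysis.
#'
#' @return Named list of [AlignerPreset-class] objects.
#' @export
builtinPresets <- function() {
  ps <- list(
    alignerPreset("strict62-nj", "BLOSUM62", -12, -2, "distance-NJ"),
    alignerPreset("loose62-nj", "BLOSUM62", -4, -0.5, "distance-NJ"),
    alignerPreset("strict45-nj", "BLOSUM45", -12, -2, "distance-NJ"),
    alignerPreset("loose45-kmer", "BLOSUM45", -4, -0.5, "identity-kmer"),
    alignerPreset("strict62-kmer", "BLOSUM62", -12, -2, "identity-kmer"),
    alignerPreset("medium45-kmer", "BLOSUM45", -8, -1, "identity-kmer")
  )
  setNames(ps, vapply(ps, function(p) p@name, ""))
}

# 21-row profile (20 aa frequencies + gap fraction) of an alignment block.
.profile_of <- function(rows) {
  m <- .chr_mat(rows)
  L <- ncol(m)
  f <- matrix(0, nrow = 20L, ncol = L, dimnames = list(.AA20, NULL))
  for (a in .AA20) f[a, ] <- colSums(m == a)
  f / nrow(m)
}

# Merge two alignment blocks with the preset's scores; returns named rows.
.merge_blocks <- function(ra, rb, preset) {
  S <- preset@substMatrix
  fa <- .profile_of(ra)
  fb <- .profile_of(rb)
  colScore <- t(fa) %*% S %*% fb
  res <- .gotoh_align_cpp(colScore, preset@gapOpen, preset@gapExtend)
  na <- length(res$a)
  expand <- function(rows, idx) {
    m <- .chr_mat(rows)
    out <- matrix("-", nrow = nrow(m), ncol = na,
                  dimnames = list(rownames(m), NULL))
    out[, idx > 0] <- m[, idx[idx > 0], drop = FALSE]
    apply(out, 1, paste, collapse = "")
  }
  c(expand(ra, res$a), expand(rb, res$b))
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment of two amino-acid sequences under
#' a preset's substitution matrix and affine gap costs. Tie-breaking during
#' traceback is deterministic: aligned column, then gap in the first
#' sequence, then gap in the second.
#'
#' @param a,b Single named character elements (or length-1 named vectors).
#' @param preset An [AlignerPreset-class].
#' @return List with \code{alignment} (a 2-row [SeqAlignment-class]) and
#'   \code{score} (the optimal global score).
#' @examples
#' p <- alignerPreset("toy")
#' pairwiseAlign(c(a = "MKC"), c(b = "MC"), p)$score
#' @export
pairwiseAlign <- function(a, b, preset) {
  av <- .as_seqvec(a, "aa")
  bv <- .as_seqvec(b, "aa")
  if (length(av) != 1L || length(bv) != 1L) {
    stop("pairwiseAlign expects exactly one sequence on each side")
  }
  merged <- .merge_blocks(av, bv, preset)
  S <- preset@substMatrix
  fa <- .profile_of(av); fb <- .profile_of(bv)
  score <- .gotoh_align_cpp(t(fa) %*% S %*% fb, preset@gapOpen,
                            preset@gapExtend)$score
  list(alignment = seqAlignment(merged, "aa", preset@name), score = score)
}

.kmer_sets <- function(seqs, k = 3L) {
  lapply(seqs, function(s) {
    if (nchar(s) < k) return(s)
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
}

# Guide 'tree' as a merge schedule: list of integer pairs referring to
# cluster indices (negative = original sequence, positive = earlier merge),
# hclust convention.
.guide_merges <- function(seqs, preset) {
  n <- length(seqs)
  if (preset@guide == "identity-kmer") {
    ks <- .kmer_sets(seqs)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shared <- length(intersect(ks[[i]], ks[[j]]))
        d[i, j] <- d[j, i] <- 1 - shared / min(length(ks[[i]]),
                                               length(ks[[j]]))
      }
    }
    hc <- hclust(as.dist(d), method = "average")
    return(hc$merge)
  }
  # distance-NJ: p-distances from pairwise alignments
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rows <- .merge_blocks(seqs[i], seqs[j], preset)
      m <- .chr_mat(rows)
      both <- m[1, ] != "-" & m[2, ] != "-"
      p <- if (any(both)) mean(m[1, both] != m[2, both]) else 1
      d[i, j] <- d[j, i] <- p
    }
  }
  if (n == 2L) return(matrix(c(-1L, -2L), 1, 2))
  if (n == 3L) {
    # NJ is degenerate at 3 taxa: merge closest pair first
    pr <- which(d == min(d[upper.tri(d)]), arr.ind = TRUE)
    pr <- pr[pr[, 1] < pr[, 2], , drop = FALSE][1, ]
    rest <- setdiff(1:3, pr)
    return(matrix(c(-pr[1], -pr[2], -rest, 1L), 2, 2, byrow = TRUE))
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr <- phangorn::midpoint(tr)
  # postorder merge schedule from the rooted guide tree
  merges <- list()
  cluster_of <- integer(ape::Ntip(tr) + tr$Nnode)
  cluster_of[seq_len(ape::Ntip(tr))] <- -match(tr$tip.label, names(seqs))
  po <- ape::reorder.phylo(tr, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (node in unique(po$edge[, 1])) {
    ch <- kids[[as.character(node)]]
    acc <- cluster_of[ch[1]]
    for (k in ch[-1]) {
      merges[[length(merges) + 1L]] <- c(acc, cluster_of[k])
      acc <- length(merges)
    }
    cluster_of[node] <- acc
  }
  do.call(rbind, merges)
}

#' Progressive multiple sequence alignment
#'
#' Aligns sequences progressively along a guide tree, merging profiles
#' leaf-to-root with sum-of-pairs profile scoring and affine gap costs.
#' Input order is canonicalized (rows sorted by id) before guide-tree
#' construction, so the result is a deterministic function of the sequence
#' set and the preset.
#'
#' @param seqs Named character vector or XStringSet of amino-acid sequences
#'   (at least 2).
#' @param preset An [AlignerPreset-class].
#' @return A [SeqAlignment-class] labeled with the preset name.
#' @examples
#' p <- alignerPreset("toy")
#' progressiveAlign(c(a = "MKCW", b = "MCW", c = "MKW"), p)
#' @export
progressiveAlign <- function(seqs, preset) {
  seqs <- .as_seqvec(seqs, "aa")
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  seqs <- seqs[order(names(seqs))]
  merges <- .guide_merges(seqs, preset)
  blocks <- vector("list", nrow(merges))
  getb <- function(i) if (i < 0) seqs[-i] else blocks[[i]]
  for (r in seq_len(nrow(merges))) {
    blocks[[r]] <- .merge_blocks(getb(merges[r, 1]), getb(merges[r, 2]),
                                 preset)
  }
  rows <- blocks[[nrow(merges)]]
  rows <- rows[order(match(names(rows), names(seqs)))]
  seqAlignment(rows, "aa", preset@name)
}

#' Back-translate an amino-acid alignment to a codon alignment
#'
#' Expands every amino-acid column to one codon column of the corresponding
#' in-frame nucleotide record; an amino-acid gap becomes \code{"---"}.
#' Requires that the gap-stripped translation of each row equals the
#' translation of its nucleotide record.
#'
#' @param aaAln A [SeqAlignment-class] with \code{moltype "aa"}.
#' @param ntRecords Named character vector or DNAStringSet of in-frame coding
#'   sequences covering every alignment row.
#' @return A [SeqAlignment-class] with \code{moltype "nt"} and the same
#'   method label.
#' @export
codonBackmap <- function(aaAln, ntRecords) {
  stopifnot(methods::is(aaAln, "SeqAlignment"), molType(aaAln) == "aa")
  nt <- .as_seqvec(ntRecords, "nt")
  rows <- alignedSeqs(aaAln)
  missing <- setdiff(names(rows), names(nt))
  if (length(missing)) {
    stop("no nucleotide record for row '", missing[1], "'")
  }
  out <- vapply(names(rows), function(id) {
    aa <- strsplit(rows[[id]], "")[[1]]
    cds <- nt[[id]]
    if (nchar(cds) %% 3 != 0) {
      stop("row '", id, "': coding sequence length not a multiple of 3")
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    trans <- .translate_codon(codons)
    res <- aa[aa != "-"]
    if (length(res) != length(codons)) {
      stop("row '", id, "': alignment has ", length(res),
           " residues but coding sequence has ", length(codons), " codons")
    }
    bad <- which(trans != res & res != "X" & trans != "X")
    if (length(bad)) {
      stop("row '", id, "': translation mismatch at codon ", bad[1],
           " (", trans[bad[1]], " vs ", res[bad[1]], ")")
    }
    outc <- character(length(aa))
    outc[aa == "-"] <- "---"
    outc[aa != "-"] <- codons
    paste(outc, collapse = "")
  }, "")
  seqAlignment(out, "nt", methodLabel(aaAln))
}

#' Strip gaps from alignment rows
#'
#' @param x A [SeqAlignment-class] or [SimulatedFamily-class].
#' @return For an alignment, the named character vector of ungapped rows;
#'   for a simulated family, \code{list(nt = ..., aa = ...)}.
#' @export
setGeneric("stripGaps", function(x) standardGeneric("stripGaps"))

#' @rdname stripGaps
#' @export
setMethod("stripGaps", "SeqAlignment", function(x) {
  gsub("-", "", alignedSeqs(x), fixed = TRUE)
})

#' @rdname stripGaps
#' @export
setMethod("stripGaps", "SimulatedFamily", function(x) {
  list(nt = x@unalignedNt, aa = x@unalignedAa)
})
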