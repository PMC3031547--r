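# Per-alignment statistics: core length, percent identity, parsimony
# informative sites, anchor census, column congruence between alternative
# alignments, and an entropy-based substitution-saturation index.

#' Core length between the first and last anchor column
#'
#' Anchor columns are columns in which at least a \code{majority} fraction of
#' the non-gap cells carry the anchor residue (cysteine by default). The core
#' length is the inclusive column span from the first to the last anchor
#' column, 0 when fewer than two anchor columns exist.
#'
#' @param aln An amino-acid [SeqAlignment-class].
#' @param anchor Anchor residue.
#' @param majority Fraction of non-gap cells required.
#' @return Integer column count.
#' @examples
#' coreLength(seqAlignment(c(a = "CAAC", b = "CAAC"), "aa"))
#' @export
coreLength <- function(aln, anchor = "C", majority = 0.5) {
  m <- as.matrix(aln)
  hit <- which(apply(m, 2, function(col) {
    ng <- col != "-"
    sum(ng) > 0 && sum(col[ng] == anchor) >= majority * sum(ng)
  }))
  if (length(hit) < 2L) return(0L)
  as.integer(max(hit) - min(hit) + 1L)
}

#' Detect anchor columns
#'
#' The column indices found by the majority scan used by [coreLength()].
#'
#' @inheritParams coreLength
#' @return Integer vector of 1-based column indices.
#' @export
anchorColumnScan <- function(aln, anchor = "C", majority = 0.5) {
  m <- as.matrix(aln)
  which(apply(m, 2, function(col) {
    ng <- col != "-"
    sum(ng) > 0 && sum(col[ng] == anchor) >= majority * sum(ng)
  }))
}

#' Mean pairwise percent identity of an alignment
#'
#' For every unordered row pair: the fraction of columns in which both rows
#' are non-gap and equal, out of columns in which both are non-gap; a pair
#' sharing no non-gap column contributes 0. The mean over pairs is returned.
#'
#' @param aln A [SeqAlignment-class].
#' @return Fraction in [0, 1].
#' @export
percentIdentity <- function(aln) {
  m <- as.matrix(aln)
  n <- nrow(m)
  stopifnot(n >= 2L)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      tot <- tot + if (any(both)) mean(m[i, both] == m[j, both]) else 0
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Count parsimony-informative columns
#'
#' A column is parsimony-informative when at least two distinct non-gap
#' states are each present in at least two rows.
#'
#' @param aln A [SeqAlignment-class].
#' @return Integer count.
#' @export
parsimonyInformativeCount <- function(aln) {
  m <- as.matrix(aln)
  sum(apply(m, 2, function(col) {
    tab <- table(col[col != "-"])
    sum(tab >= 2L) >= 2L
  }))
}

#' Per-row census of anchor-position cysteines
#'
#' Counts, per row, how many of the supplied anchor columns hold a 'C'.
#' Intact lineages of a six-cysteine family score 6, C-minus lineages 4.
#'
#' @param aln An amino-acid [SeqAlignment-class].
#' @param anchorColumns 1-based column indices of the anchors (simulator
#'   truth, or detected via [anchorColumnScan()]).
#' @return Named integer vector, one count per row.
#' @export
anchorCensus <- function(aln, anchorColumns) {
  m <- as.matrix(aln)
  anchorColumns <- as.integer(anchorColumns)
  if (any(anchorColumns < 1L | anchorColumns > ncol(m))) {
    stop("anchor column index out of range 1..", ncol(m))
  }
  counts <- apply(m[, anchorColumns, drop = FALSE] == "C", 1, sum)
  setNames(as.integer(counts), rownames(m))
}

# residue-ordinal matrix: cell = cumulative non-gap count, NA at gaps
.ordinal_matrix <- function(m) {
  t(apply(m, 1, function(r) {
    ng <- r != "-"
    o <- rep(NA_integer_, length(r))
    o[ng] <- seq_len(sum(ng))
    o
  }))
}

#' Column congruence between two alignments of the same sequences
#'
#' For each column of the reference alignment, the set of residue pairs it
#' co-aligns (pairs of (row, residue ordinal)) is computed; the column score
#' is the fraction of those pairs that some column of the alternative
#' alignment also co-aligns. Columns with fewer than two non-gap cells score
#' 1 by convention. This is the standard homology-pair currency of
#' developer-versus-test alignment comparison, used here as the congruence
#' analog of alignment-uncertainty heat maps.
#'
#' @param ref,alt [SeqAlignment-class] objects over identical ids and
#'   identical underlying unaligned residues.
#' @return List with \code{perColumnScore} (length \code{nCols(ref)}) and
#'   \code{overall} (its mean).
#' @export
columnCongruence <- function(ref, alt) {
  mr <- as.matrix(ref)
  ma <- as.matrix(alt)
  if (!setequal(rownames(mr), rownames(ma))) {
    stop("alignments cover different sequence ids")
  }
  ma <- ma[rownames(mr), , drop = FALSE]
  ur <- gsub("-", "", alignedSeqs(ref), fixed = TRUE)
  ua <- gsub("-", "", alignedSeqs(alt), fixed = TRUE)
  if (!identical(ur[rownames(mr)], ua[rownames(mr)])) {
    stop("alignments disagree on the underlying unaligned residues")
  }
  ordR <- .ordinal_matrix(mr)
  ordA <- .ordinal_matrix(ma)
  # posA[r, o]: column of alt holding residue ordinal o of row r
  posA <- matrix(NA_integer_, nrow(ma), max(nchar(ua)))
  for (r in seq_len(nrow(ma))) {
    ng <- which(!is.na(ordA[r, ]))
    posA[r, ordA[r, ng]] <- ng
  }
  score <- vapply(seq_len(ncol(mr)), function(j) {
    rows <- which(!is.na(ordR[, j]))
    if (length(rows) < 2L) return(1)
    cols <- posA[cbind(rows, ordR[rows, j])]
    pairs <- combn(seq_along(rows), 2)
    mean(cols[pairs[1, ]] == cols[pairs[2, ]])
  }, 0)
  list(perColumnScore = score, overall = mean(score))
}

#' Alignment-uncertainty profile across a battery of alignments
#'
#' The mean of [columnCongruence()] of a reference alignment against every
#' other alignment of the same sequences: a per-column score in [0, 1] whose
#' low values mark regions where methods disagree (the heat-map analog of
#' alignment-uncertainty plots).
#'
#' @param alignments List of [SeqAlignment-class] objects (>= 2) over the
#'   same sequences.
#' @param refIndex Index of the reference alignment.
#' @return List with \code{perColumnScore} (length \code{nCols} of the
#'   reference) and \code{overall}.
#' @export
uncertaintyProfile <- function(alignments, refIndex = 1L) {
  stopifnot(length(alignments) >= 2L)
  ref <- alignments[[refIndex]]
  profs <- lapply(alignments[-refIndex], function(alt) {
    columnCongruence(ref, alt)$perColumnScore
  })
  score <- Reduce(`+`, profs) / length(profs)
  list(perColumnScore = score, overall = mean(score))
}

#' Entropy-based substitution-saturation test
#'
#' Computes a saturation index Iss as the mean per-column Shannon entropy of
#' the non-gap cells (log base = alphabet size, so the index lies in [0, 1]),
#' over columns with at least 4 non-gap cells. The critical value Iss.c is
#' the 5th percentile of the same statistic over \code{nReps} alignments
#' whose columns are filled i.i.d. from the empirical residue frequencies
#' (the full-saturation null). The p-value is the fraction of null
#' replicates at or below the observed index; a small p-value means the
#' alignment is significantly more structured than saturated data. The data
#' are called saturated when \code{iss >= issC} (equivalently p >= 0.05):
#' saturation is the failure to reject the full-saturation null.
#'
#' @param aln A [SeqAlignment-class] with at least 4 rows.
#' @param nReps Monte-Carlo replicates for the null.
#' @param seed Integer seed for the Monte-Carlo draw.
#' @return List with \code{iss}, \code{issC}, \code{pValue},
#'   \code{saturated}, \code{nColsUsed}, \code{alphabetSize}.
#' @export
saturationTest <- function(aln, nReps = 500L, seed = 1L) {
  m <- as.matrix(aln)
  if (nrow(m) < 4L) stop("need at least 4 rows")
  alpha <- if (molType(aln) == "aa") .AA20 else .NT4
  S <- length(alpha)
  usable <- which(colSums(m != "-" & m != "X" & m != "N") >= 4L)
  if (length(usable) < 10L) {
    stop("too few usable columns (", length(usable), " < 10)")
  }
  col_entropy <- function(col) {
    col <- col[col %in% alpha]
    p <- table(col) / length(col)
    -sum(p * log(p)) / log(S)
  }
  iss <- mean(apply(m[, usable, drop = FALSE], 2, col_entropy))
  mu <- m[, usable, drop = FALSE]
  cells <- mu[mu %in% alpha]
  freqs <- table(factor(cells, levels = alpha)) / length(cells)
  ncells <- colSums(matrix(mu %in% alpha, nrow(mu)))
  null <- .with_stream(seed, "saturation-null", {
    vapply(seq_len(nReps), function(r) {
      sim <- lapply(ncells, function(k) {
        sample(alpha, k, replace = TRUE, prob = freqs)
      })
      mean(vapply(sim, col_entropy, 0))
    }, 0)
  })
  issC <- unname(quantile(null, 0.05, type = 7))
  p <- mean(null <= iss)
  list(iss = iss, issC = issC, pValue = p, saturated = iss >= issC,
       nColsUsed = length(usable), alphabetSize = S)
}
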