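# Goldman-Yang style codon process: F3x4 frequencies, rate matrix, site
# pattern compression, and a cached per-class site-likelihood evaluator
# shared by all selection models.

#' F3x4 codon frequencies
#'
#' Empirical nucleotide frequencies at each of the three codon positions,
#' multiplied per codon and renormalized over the 61 sense codons of the
#' universal code (stops excluded). Gap codons and ambiguous bases are
#' ignored in the tallies.
#'
#' @param codonAln An in-frame nucleotide [SeqAlignment-class] (width a
#'   multiple of 3).
#' @return Named 61-vector of sense-codon frequencies summing to 1.
#' @export
f3x4 <- function(codonAln) {
  stopifnot(methods::is(codonAln, "SeqAlignment"), molType(codonAln) == "nt")
  w <- nCols(codonAln)
  if (w %% 3L != 0L) stop("frame violation: alignment width ", w,
                          " is not a multiple of 3")
  m <- as.matrix(codonAln)
  pos <- rep(1:3, length.out = w)
  f <- matrix(0, 3, 4, dimnames = list(NULL, .NT4))
  for (k in 1:3) {
    cells <- m[, pos == k, drop = FALSE]
    for (b in .NT4) f[k, b] <- sum(cells == b)
    f[k, ] <- f[k, ] / sum(f[k, ])
  }
  tab <- .codon_tables()
  cm <- do.call(rbind, strsplit(tab$sense, ""))
  pi <- f[1, cm[, 1]] * f[2, cm[, 2]] * f[3, cm[, 3]]
  pi <- pi / sum(pi)
  setNames(pi, tab$sense)
}

# Unnormalized GY94 generator: q_ij = pi_j * kappa^[transition] *
# omega^[nonsynonymous] for single-nucleotide changes.
.codon_Q_raw <- function(kappa, omega, pi) {
  tab <- .codon_tables()
  Q <- matrix(0, 61, 61, dimnames = list(tab$sense, tab$sense))
  Q[tab$single] <- rep(pi, each = 61)[tab$single]
  Q[tab$is_ts] <- Q[tab$is_ts] * kappa
  Q[tab$nonsyn] <- Q[tab$nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  Q
}

.codon_rate <- function(Q, pi) -sum(pi * diag(Q))

#' Codon substitution rate matrix
#'
#' Goldman-Yang style 61x61 generator: zero for multi-nucleotide changes,
#' proportional to the target codon frequency, multiplied by kappa for
#' transitions and by omega for nonsynonymous changes. By default the matrix
#' is scaled so the expected number of substitutions per codon per unit time
#' is 1 at stationarity; for site-class mixtures pass
#' \code{normalize = FALSE} and scale the class matrices jointly by the
#' mixture-mean rate.
#'
#' @param kappa Transition/transversion ratio (> 0).
#' @param omega dN/dS (>= 0).
#' @param pi 61-vector of sense-codon frequencies (lexicographic codon
#'   order); default uniform.
#' @param normalize Scale to unit expected rate.
#' @return 61x61 rate matrix with zero row sums.
#' @export
codonQ <- function(kappa, omega, pi = NULL, normalize = TRUE) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  if (length(pi) != 61L || abs(sum(pi) - 1) > 1e-6) {
    stop("pi must be a 61-vector summing to 1")
  }
  Q <- .codon_Q_raw(kappa, omega, pi)
  if (normalize) {
    r <- .codon_rate(Q, pi)
    if (r > 0) Q <- Q / r
  }
  Q
}

# Codon site patterns from an in-frame nt alignment.
# Returns states (nTip x npat, 1..61, 0 = missing), weights, siteOfPattern
# mapping (pattern index per retained site), retainedSites (1-based codon
# column indices kept), after dropping all-gap codon columns with a warning.
.codon_patterns <- function(codonAln, tipOrder) {
  tab <- .codon_tables()
  gc <- .genetic_code()
  stops <- names(gc)[gc == "*"]
  seqs <- alignedSeqs(codonAln)[tipOrder]
  w <- nchar(seqs[[1]])
  if (w %% 3L != 0L) stop("frame violation: width not a multiple of 3")
  nsite <- w %/% 3L
  codons <- vapply(seqs, function(s) {
    substring(s, seq(1, w, 3), seq(3, w, 3))
  }, character(nsite))
  codons <- t(codons)  # nTip x nsite
  bad <- which(matrix(codons %in% stops, nrow(codons)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("stop codon in row '", tipOrder[bad[1, 1]], "' at codon ",
         bad[1, 2])
  }
  st <- matrix(match(codons, tab$sense, nomatch = 0L), nrow(codons))
  allgap <- colSums(st > 0L) == 0L
  if (any(allgap)) {
    warning(sum(allgap), " all-gap codon site(s) dropped")
  }
  retained <- which(!allgap)
  st <- st[, retained, drop = FALSE]
  key <- apply(st, 2, paste, collapse = ",")
  u <- which(!duplicated(key))
  states <- st[, u, drop = FALSE]
  weights <- as.numeric(table(key)[key[u]])
  siteOfPattern <- match(key, key[u])
  list(states = states, weights = weights, siteOfPattern = siteOfPattern,
       retainedSites = retained)
}

# Locate the edge subtending exactly the given leaf set; error listing the
# clades actually available.
.find_clade_edge <- function(tree, leaves) {
  leaves <- sort(leaves)
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing)) {
    stop("foreground leaves not in tree: ", paste(missing, collapse = ", "))
  }
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  ntip <- ape::Ntip(tree)
  # tip edges
  if (length(leaves) == 1L) {
    tip <- match(leaves, tree$tip.label)
    return(which(tree$edge[, 2] == tip))
  }
  for (node in (ntip + 2L):(ntip + tree$Nnode)) {
    below <- sort(labs[parts[[node - ntip]]])
    if (identical(below, leaves)) {
      return(which(tree$edge[, 2] == node))
    }
  }
  avail <- vapply((ntip + 2L):(ntip + tree$Nnode), function(node) {
    paste(sort(labs[parts[[node - ntip]]]), collapse = ",")
  }, "")
  stop("no edge subtends clade {", paste(leaves, collapse = ","),
       "}; available clades:\n  ", paste(avail, collapse = "\n  "))
}

# Factory for cached per-class site log-likelihood evaluation.
# fgEdge: optional edge index (row of tree$edge) carrying the foreground
# omega; class omega is then c(background, foreground).
.codon_lik_factory <- function(tree, pat, pi, fgEdge = NULL) {
  po <- ape::reorder.phylo(tree, "postorder")
  # map postorder edges back to original edge rows to mark the foreground
  fgMask <- rep(FALSE, nrow(po$edge))
  if (!is.null(fgEdge)) {
    key <- paste(tree$edge[fgEdge, 1], tree$edge[fgEdge, 2])
    pokey <- paste(po$edge[, 1], po$edge[, 2])
    fgMask <- pokey %in% key
  }
  ntip <- ape::Ntip(po)
  pi <- pmax(pi, 1e-10)
  pi <- pi / sum(pi)
  cache <- new.env(parent = emptyenv())
  # omegaBg, omegaFg: foreground ignored unless fgEdge was given
  function(kappa, omegaBg, omegaFg = omegaBg, scale = 1) {
    key <- sprintf("%.13g|%.13g|%.13g|%.13g", kappa, omegaBg, omegaFg, scale)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    sysBg <- .rev_eigen_cpp(.codon_Q_raw(kappa, omegaBg, pi), pi)
    if (any(fgMask) && omegaFg != omegaBg) {
      sysFg <- .rev_eigen_cpp(.codon_Q_raw(kappa, omegaFg, pi), pi)
      U <- list(sysBg$U, sysFg$U)
      lam <- list(sysBg$lambda, sysFg$lambda)
      Ui <- list(sysBg$Uinv, sysFg$Uinv)
      esys <- ifelse(fgMask, 2L, 1L)
    } else {
      U <- list(sysBg$U); lam <- list(sysBg$lambda); Ui <- list(sysBg$Uinv)
      esys <- rep(1L, nrow(po$edge))
    }
    ll <- .prune_siteloglik_cpp(po$edge, po$edge.length, ntip, U, lam, Ui,
                                as.integer(esys), pat$states, pi, scale)
    cache[[key]] <- ll
    ll
  }
}

# Small Latin-hypercube sampler for optimizer restarts (values in (0,1)).
.latin_hypercube <- function(n, k) {
  m <- vapply(seq_len(k), function(j) (sample.int(n) - runif(n)) / n,
              numeric(n))
  matrix(m, nrow = n, ncol = k)
}
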