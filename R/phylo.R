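# Tree inference and scoring: protein distances, BioNJ, LG+I+Gamma pruning
# likelihood, branch-length optimization, NNI search, bootstrap support,
# Fitch parsimony, midpoint rooting.

#' Protein substitution model (LG family)
#'
#' LG exchangeabilities with either the canonical LG frequencies or
#' alignment-derived (+F) frequencies, a discrete-gamma rate mixture and a
#' proportion of invariable sites. Rate categories are the means of the
#' equal-probability gamma bins; the invariant-plus-gamma site likelihood is
#' \code{pInv * I[column constant] * pi(state) + (1 - pInv) * mean_k L_k}.
#'
#' @param alpha Gamma shape (> 0).
#' @param pInv Proportion of invariable sites in [0, 1).
#' @param nRateCats Number of discrete-gamma categories.
#' @param freqs Optional 20-vector of equilibrium frequencies in the order
#'   ARNDCQEGHILKMFPSTWYV; defaults to the published LG frequencies. Use
#'   [empiricalFreqs()] for the +F variant.
#' @return A list of class \code{"ProteinSubstModel"}.
#' @export
proteinModel <- function(alpha = 1, pInv = 0, nRateCats = 4L, freqs = NULL) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (pInv < 0 || pInv >= 1) stop("pInv must be in [0, 1)")
  if (is.null(freqs)) freqs <- .lg_freqs
  freqs <- as.numeric(freqs)
  if (length(freqs) != 20L || abs(sum(freqs) - 1) > 1e-6) {
    stop("freqs must be a 20-vector summing to 1")
  }
  freqs <- freqs / sum(freqs)
  structure(list(alpha = alpha, pInv = pInv, nRateCats = as.integer(nRateCats),
                 freqs = setNames(freqs, .AA20)),
            class = "ProteinSubstModel")
}

#' Empirical amino-acid frequencies of an alignment
#'
#' @param aln An amino-acid [SeqAlignment-class].
#' @param pseudocount Added per residue to avoid zero frequencies.
#' @return Named 20-vector summing to 1.
#' @export
empiricalFreqs <- function(aln, pseudocount = 0.5) {
  m <- as.matrix(aln)
  counts <- vapply(.AA20, function(a) sum(m == a), 0) + pseudocount
  counts / sum(counts)
}

# LG rate matrix for given frequencies, normalized to mean rate 1.
.lg_Q <- function(freqs) {
  R <- matrix(0, 20, 20, dimnames = list(.AA20, .AA20))
  R[lower.tri(R)] <- .lg_exch_lower
  R <- R + t(R)
  Q <- R * rep(freqs, each = 20)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  Q / rate
}

.protein_system <- function(model) {
  key <- paste0("lgsys:", paste(signif(model$freqs, 10), collapse = ","))
  if (!is.null(.alnsens_cache[[key]])) return(.alnsens_cache[[key]])
  sys <- .rev_eigen_cpp(.lg_Q(model$freqs), model$freqs)
  .alnsens_cache[[key]] <- sys
  sys
}

# Site-pattern compression for an aa alignment, rows ordered by tip labels.
.aa_patterns <- function(aln, tipOrder) {
  m <- as.matrix(aln)[tipOrder, , drop = FALSE]
  st <- matrix(match(m, .AA20, nomatch = 0L), nrow(m), ncol(m))
  key <- apply(st, 2, paste, collapse = ",")
  u <- !duplicated(key)
  states <- st[, u, drop = FALSE]
  w <- as.numeric(table(key)[key[u]])
  const <- apply(states, 2, function(col) {
    obs <- unique(col[col != 0L])
    if (length(obs) == 0L) 0L else if (length(obs) == 1L) obs else NA_integer_
  })
  list(states = states, weights = w, constState = const)
}

.gamma_rates <- function(alpha, k) {
  if (k <= 1L) return(1)
  phangorn::discrete.gamma(alpha, k)
}

# Core protein log-likelihood on compressed patterns.
.protein_loglik_pat <- function(tree, pat, model) {
  po <- ape::reorder.phylo(tree, "postorder")
  sys <- .protein_system(model)
  rates <- .gamma_rates(model$alpha, model$nRateCats)
  npat <- ncol(pat$states)
  lik <- matrix(0, length(rates), npat)
  for (k in seq_along(rates)) {
    lik[k, ] <- exp(.prune_siteloglik_cpp(
      po$edge, po$edge.length, ape::Ntip(po), list(sys$U), list(sys$lambda),
      list(sys$Uinv), rep(1L, nrow(po$edge)), pat$states, model$freqs,
      rates[k]))
  }
  gpart <- colMeans(lik)
  if (model$pInv > 0) {
    inv <- ifelse(is.na(pat$constState), 0,
                  ifelse(pat$constState == 0L, 1,
                         model$freqs[pmax(pat$constState, 1L)]))
    site <- model$pInv * inv + (1 - model$pInv) * gpart
  } else {
    site <- gpart
  }
  sum(pat$weights * log(site))
}

.check_tree_aln <- function(tree, aln) {
  ids <- names(alignedSeqs(aln))
  if (!setequal(tree$tip.label, ids)) {
    stop("tree tips and alignment rows differ: ",
         paste(c(setdiff(tree$tip.label, ids), setdiff(ids, tree$tip.label)),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
}

#' Log-likelihood of a tree under LG+I+Gamma
#'
#' Felsenstein pruning over alignment columns; gaps and 'X' are missing data
#' (all-ones partials). The per-column likelihood is
#' \code{pInv * I[constant] * pi(state) + (1 - pInv) * mean_k L(rate_k)}.
#'
#' @param tree \code{ape::phylo} whose tips match the alignment rows.
#' @param aln An amino-acid [SeqAlignment-class].
#' @param model A [proteinModel()]; default LG+F with alpha 1, no invariant
#'   sites.
#' @return Natural-log likelihood.
#' @export
treeLogLik <- function(tree, aln, model = NULL) {
  .check_tree_aln(tree, aln)
  if (is.null(model)) model <- proteinModel(freqs = empiricalFreqs(aln))
  pat <- .aa_patterns(aln, tree$tip.label)
  .protein_loglik_pat(tree, pat, model)
}

#' Optimize branch lengths (and optionally alpha, pInv)
#'
#' Coordinate-wise bounded scalar optimization: each branch in turn by
#' Brent's method on [1e-8, 20], optionally interleaved with 1-D searches
#' for the gamma shape and the proportion of invariable sites, cycling until
#' the log-likelihood improves by less than \code{tol} or \code{maxCycles}
#' cycles. Improvement is monotone (moves are only accepted when better).
#'
#' @inheritParams treeLogLik
#' @param optAlpha,optPInv Also optimize the gamma shape / invariant
#'   proportion.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param maxCycles Maximum optimization cycles.
#' @return List with \code{tree} (optimized lengths), \code{lnL},
#'   \code{model} (possibly updated alpha/pInv).
#' @export
optimizeBranchLengths <- function(tree, aln, model = NULL, optAlpha = FALSE,
                                  optPInv = FALSE, tol = 1e-6,
                                  maxCycles = 50L) {
  .check_tree_aln(tree, aln)
  if (is.null(model)) model <- proteinModel(freqs = empiricalFreqs(aln))
  pat <- .aa_patterns(aln, tree$tip.label)
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  cur <- .protein_loglik_pat(tree, pat, model)
  for (cycle in seq_len(maxCycles)) {
    prev <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tr2 <- tree
        tr2$edge.length[e] <- x
        .protein_loglik_pat(tr2, pat, model)
      }
      # local bracket around the current value; the cycle loop lets the
      # optimum walk across brackets when needed
      x <- tree$edge.length[e]
      lo <- max(1e-8, x / 10)
      hi <- min(20, x * 10 + 0.1)
      op <- optimize(f, c(lo, hi), maximum = TRUE,
                     tol = max(1e-6, 0.01 * x))
      if (op$objective > cur) {
        tree$edge.length[e] <- op$maximum
        cur <- op$objective
      }
    }
    if (optAlpha) {
      op <- optimize(function(a) {
        m2 <- model; m2$alpha <- a
        .protein_loglik_pat(tree, pat, m2)
      }, c(0.05, 50), maximum = TRUE, tol = 1e-4)
      if (op$objective > cur) {
        model$alpha <- op$maximum
        cur <- op$objective
      }
    }
    if (optPInv) {
      op <- optimize(function(p) {
        m2 <- model; m2$pInv <- p
        .protein_loglik_pat(tree, pat, m2)
      }, c(0, 0.9), maximum = TRUE, tol = 1e-4)
      if (op$objective > cur) {
        model$pInv <- op$maximum
        cur <- op$objective
      }
    }
    if (cur - prev < tol) break
  }
  list(tree = tree, lnL = cur, model = model)
}

#' Pairwise protein distances from an alignment
#'
#' p-distance (mismatch fraction over shared non-gap columns), Poisson
#' correction \code{-ln(1 - p)}, or gamma correction
#' \code{alpha * ((1 - p)^(-1/alpha) - 1)}. Saturated pairs (p within 1e-9
#' of 1) yield \code{Inf}; [bionjTree()] caps these.
#'
#' @param aln An amino-acid [SeqAlignment-class].
#' @param correction One of \code{"p"}, \code{"poisson"}, \code{"gamma"}.
#' @param alpha Gamma shape for \code{correction = "gamma"}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
proteinDistance <- function(aln, correction = c("poisson", "p", "gamma"),
                            alpha = 1) {
  correction <- match.arg(correction)
  m <- as.matrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != "-" & m[j, ] != "-" & m[i, ] != "X" & m[j, ] != "X"
      if (!any(both)) {
        stop("rows '", rownames(m)[i], "' and '", rownames(m)[j],
             "' share no non-gap columns")
      }
      p <- mean(m[i, both] != m[j, both])
      d <- switch(correction,
        p = p,
        poisson = if (p >= 1 - 1e-9) Inf else -log(1 - p),
        gamma = if (p >= 1 - 1e-9) Inf else alpha * ((1 - p)^(-1 / alpha) - 1)
      )
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' BioNJ tree from a distance matrix
#'
#' Neighbor joining with BioNJ variance weighting (via \code{ape::bionj}).
#' Taxa are put in canonical (sorted) order first so the result is invariant
#' to input permutation; infinite (saturated) distances are capped at 1.5x
#' the largest finite distance, and negative branch-length estimates are
#' clamped to zero.
#'
#' @param D Symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return Unrooted \code{ape::phylo}.
#' @export
bionjTree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must have taxon names")
  if (max(abs(D - t(D)), na.rm = TRUE) > 1e-8) {
    stop("distance matrix is not symmetric")
  }
  ord <- order(rownames(D))
  D <- D[ord, ord]
  if (any(!is.finite(D))) {
    cap <- 1.5 * max(D[is.finite(D)])
    D[!is.finite(D)] <- cap
  }
  tr <- ape::bionj(D)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

# All NNI neighbors of an unrooted binary tree, edge lengths inherited.
.nni_neighbors <- function(tree) {
  phangorn::nni(tree)
}

#' Maximum-likelihood topology search by NNI hill climbing
#'
#' From each start (a BioNJ tree plus \code{nStarts - 1} seeded random
#' resolutions), branch lengths are optimized, then all
#' nearest-neighbor-interchange moves are scored and the best improving move
#' accepted (lengths re-optimized after each accept) until a local optimum.
#' The best tree over starts is returned.
#'
#' @inheritParams treeLogLik
#' @param nStarts Number of starting trees (>= 1).
#' @param seed Integer seed for the random starts.
#' @param optAlpha,optPInv Passed to [optimizeBranchLengths()].
#' @param blCycles Branch-length optimization cycles per start (accepted
#'   moves re-optimize with half as many).
#' @return List with \code{tree}, \code{lnL}, \code{model},
#'   \code{startLnL} (vector of per-start final log-likelihoods).
#' @export
nniSearch <- function(aln, model = NULL, nStarts = 5L, seed = 1L,
                      optAlpha = FALSE, optPInv = FALSE, blCycles = 5L) {
  if (is.null(model)) model <- proteinModel(freqs = empiricalFreqs(aln))
  ids <- names(alignedSeqs(aln))
  if (length(ids) < 4L) stop("need at least 4 taxa")
  starts <- list(bionjTree(proteinDistance(aln, "poisson")))
  if (nStarts > 1L) {
    starts <- c(starts, .with_stream(seed, "nni-starts", {
      lapply(seq_len(nStarts - 1L), function(i) {
        tr <- ape::rtopology(length(ids), rooted = FALSE, tip.label = ids)
        tr$edge.length <- rep(0.3, nrow(tr$edge))
        tr
      })
    }))
  }
  best <- NULL
  startLnL <- numeric(length(starts))
  for (s in seq_along(starts)) {
    fit <- optimizeBranchLengths(starts[[s]], aln, model, optAlpha = optAlpha,
                                 optPInv = optPInv, maxCycles = blCycles)
    pat <- .aa_patterns(aln, fit$tree$tip.label)
    repeat {
      nbs <- .nni_neighbors(fit$tree)
      sc <- vapply(nbs, function(tr) {
        tr$edge.length <- pmax(tr$edge.length, 1e-8)
        pat2 <- .aa_patterns(aln, tr$tip.label)
        .protein_loglik_pat(tr, pat2, fit$model)
      }, 0)
      if (max(sc) <= fit$lnL + 1e-8) break
      cand <- nbs[[which.max(sc)]]
      cand$edge.length <- pmax(cand$edge.length, 1e-8)
      fit <- optimizeBranchLengths(cand, aln, fit$model, optAlpha = optAlpha,
                                   optPInv = optPInv,
                                   maxCycles = max(2L, blCycles %/% 2L))
    }
    startLnL[s] <- fit$lnL
    if (is.null(best) || fit$lnL > best$lnL) best <- fit
  }
  list(tree = best$tree, lnL = best$lnL, model = best$model,
       startLnL = startLnL)
}

#' Nonparametric bootstrap support
#'
#' Columns are resampled with replacement; each replicate is analyzed by
#' Poisson-distance BioNJ (fast mode), and bipartition frequencies are
#' mapped onto the internal edges of the input tree. Supports are fractions
#' in [0, 1], stored in \code{node.label}. With \code{nReps = 0} the tree is
#' returned unchanged.
#'
#' @param tree Tree to annotate.
#' @param aln The amino-acid alignment.
#' @param nReps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return List with \code{tree} (node labels = supports) and
#'   \code{support} (numeric vector over internal nodes, NA at the root).
#' @export
bootstrapSupport <- function(tree, aln, nReps = 100L, seed = 1L) {
  .check_tree_aln(tree, aln)
  if (nReps == 0L) {
    return(list(tree = tree, support = NULL))
  }
  seqs <- alignedSeqs(aln)
  m <- .chr_mat(seqs)
  reps <- .with_stream(seed, "bootstrap", {
    lapply(seq_len(nReps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      b <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
      D <- tryCatch(proteinDistance(seqAlignment(b, molType(aln)), "poisson"),
                    error = function(e) NULL)
      if (is.null(D)) return(NULL)
      bionjTree(D)
    })
  })
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- counts / length(reps)
  # root 'bipartition' of an unrooted tree is trivial
  supp[1] <- NA_real_
  tree$node.label <- ifelse(is.na(supp), "", format(supp, digits = 3))
  list(tree = tree, support = supp)
}

#' Fitch parsimony score
#'
#' Minimum number of state changes over all columns, gaps and ambiguity
#' codes treated as missing (compatible with any state).
#'
#' @inheritParams treeLogLik
#' @return Integer parsimony steps.
#' @export
fitchParsimony <- function(tree, aln) {
  ids <- names(alignedSeqs(aln))
  if (!setequal(tree$tip.label, ids)) {
    stop("tree tips and alignment rows differ")
  }
  m <- as.matrix(aln)
  type <- if (molType(aln) == "aa") "AA" else "DNA"
  pd <- phangorn::phyDat(m, type = type)
  as.integer(phangorn::fitch(tree, pd))
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. When
#' the tree has zero total length the tree is rooted arbitrarily at the
#' first tip, with a warning.
#'
#' @param tree \code{ape::phylo} with >= 2 leaves and finite lengths.
#' @return Rooted \code{ape::phylo}.
#' @export
midpointRoot <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0) {
    warning("tree has zero length; rooting arbitrarily")
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Total tree size
#'
#' Sum of branch lengths; invariant under rerooting.
#'
#' @param tree \code{ape::phylo}.
#' @return Numeric.
#' @export
treeSize <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}
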