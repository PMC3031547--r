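# Independent brute-force oracles. These deliberately re-derive each
# quantity by literal enumeration or rescanning, sharing no code with the
# package implementations they check.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_aa_string <- function(n) paste(sample(AA, n, replace = TRUE),
                                    collapse = "")

rand_alignment <- function(nrow, ncol, gapProb = 0.15, alpha = AA) {
  rows <- vapply(seq_len(nrow), function(i) {
    chars <- sample(alpha, ncol, replace = TRUE)
    chars[runif(ncol) < gapProb] <- "-"
    paste(chars, collapse = "")
  }, "")
  names(rows) <- paste0("s", seq_len(nrow))
  seqAlignment(rows, "aa")
}

# ---- pairwise alignment: exhaustive enumeration over monotone alignments
# with affine gap runs costing gapOpen + k * gapExtend
oracle_pairwise_score <- function(a, b, S, gapOpen, gapExtend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, lastState) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      recurse(i + 1, j + 1, score + S[av[i], bv[j]], "M")
    }
    if (i <= length(av)) {
      add <- if (lastState == "X") gapExtend else gapOpen + gapExtend
      recurse(i + 1, j, score + add, "X")
    }
    if (j <= length(bv)) {
      add <- if (lastState == "Y") gapExtend else gapOpen + gapExtend
      recurse(i, j + 1, score + add, "Y")
    }
  }
  recurse(1, 1, 0, "start")
  best
}

# ---- metric rescans (literal loops, no apply tricks shared with package)
oracle_core_length <- function(aln, anchor = "C", majority = 0.5) {
  m <- as.matrix(aln)
  anchors <- c()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    ng <- 0; hit <- 0
    for (i in seq_len(nrow(m))) {
      if (col[i] != "-") {
        ng <- ng + 1
        if (col[i] == anchor) hit <- hit + 1
      }
    }
    if (ng > 0 && hit >= majority * ng) anchors <- c(anchors, j)
  }
  if (length(anchors) < 2) return(0L)
  as.integer(anchors[length(anchors)] - anchors[1] + 1)
}

oracle_pct_identity <- function(aln) {
  m <- as.matrix(aln)
  vals <- c()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      shared <- 0; same <- 0
      for (k in seq_len(ncol(m))) {
        if (m[i, k] != "-" && m[j, k] != "-") {
          shared <- shared + 1
          if (m[i, k] == m[j, k]) same <- same + 1
        }
      }
      vals <- c(vals, if (shared == 0) 0 else same / shared)
    }
  }
  mean(vals)
}

oracle_pars_informative <- function(aln) {
  m <- as.matrix(aln)
  count <- 0
  for (j in seq_len(ncol(m))) {
    states <- m[, j][m[, j] != "-"]
    good <- 0
    for (s in unique(states)) if (sum(states == s) >= 2) good <- good + 1
    if (good >= 2) count <- count + 1
  }
  count
}

# ---- RF: independent bipartition builder by edge traversal
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  out <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    side <- sort(desc_tips(child))
    other <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (min(tree$tip.label) %in% side) {
      paste(other, collapse = "|")
    } else {
      paste(side, collapse = "|")
    }
    out <- c(out, key)
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# ---- Fitch: exhaustive minimum over internal labelings restricted to the
# observed states of the column (valid for Fitch parsimony)
oracle_fitch_column <- function(tree, states) {
  ntip <- length(tree$tip.label)
  obs <- unique(states[!is.na(states)])
  if (length(obs) <= 1) return(0L)
  nint <- tree$Nnode
  grid <- expand.grid(rep(list(obs), nint), stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- unlist(grid[g, ], use.names = FALSE)
    stateof <- function(node) {
      if (node <= ntip) states[node] else lab[node - ntip]
    }
    steps <- 0
    for (e in seq_len(nrow(tree$edge))) {
      pa <- stateof(tree$edge[e, 1])
      ch <- stateof(tree$edge[e, 2])
      if (!is.na(ch) && !is.na(pa) && pa != ch) steps <- steps + 1
    }
    best <- min(best, steps)
  }
  as.integer(best)
}

oracle_fitch <- function(tree, aln) {
  m <- as.matrix(aln)[tree$tip.label, , drop = FALSE]
  m[m == "-" | m == "X"] <- NA
  sum(vapply(seq_len(ncol(m)), function(j) {
    oracle_fitch_column(tree, m[, j])
  }, 0L))
}

# ---- exhaustive-state pruning oracles (semi-vectorized over the internal
# state grid; transition matrices via Matrix::expm, an independent code path)
oracle_site_lik <- function(tree, Q, freqs, states, scale = 1, Ps = NULL) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  S <- length(freqs)
  if (is.null(Ps)) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
      as.matrix(Matrix::expm(Q * tree$edge.length[e] * scale))
    })
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), nint)))
  stateof <- function(node, grid) {
    if (node <= ntip) rep(states[node], nrow(grid)) else grid[, node - ntip]
  }
  pr <- freqs[grid[, 1]]   # root = ntip + 1 is the first internal node
  for (e in seq_len(nrow(tree$edge))) {
    pa <- stateof(tree$edge[e, 1], grid)
    ch <- stateof(tree$edge[e, 2], grid)
    if (is.na(states[tree$edge[e, 2]]) && tree$edge[e, 2] <= ntip) next
    pr <- pr * Ps[[e]][cbind(pa, ch)]
  }
  sum(pr)
}

oracle_protein_lnl <- function(tree, aln, model) {
  Q <- alnsens:::.lg_Q(model$freqs)
  rates <- phangorn::discrete.gamma(model$alpha, model$nRateCats)
  m <- as.matrix(aln)[tree$tip.label, , drop = FALSE]
  states <- matrix(match(m, AA), nrow(m))
  tot <- 0
  for (j in seq_len(ncol(states))) {
    Ls <- vapply(rates, function(r) {
      oracle_site_lik(tree, Q, model$freqs, states[, j], scale = r)
    }, 0)
    obs <- unique(states[, j][!is.na(states[, j])])
    inv <- if (length(obs) == 0) 1 else if (length(obs) == 1) {
      model$freqs[obs]
    } else 0
    tot <- tot + log(unname(model$pInv * inv + (1 - model$pInv) * mean(Ls)))
  }
  tot
}

# small simulated families reused across tests
small_config <- function(seed, ...) {
  defaults <- list(nConserved = 4L, nExpansion = 4L, nCodons = 90L,
                   anchorPositions = c(15L, 25L, 35L, 50L, 60L, 70L),
                   signalLen = 10L, targetIdentity = 0.35, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(familySimConfig, args)
}

# transition matrices from the package eigen system (shared P: the oracle
# then differs from the implementation only in the summation algorithm)
eigen_P_list <- function(tree, Q, freqs, scale = 1) {
  sys <- alnsens:::.rev_eigen_cpp(Q, freqs)
  lapply(seq_len(nrow(tree$edge)), function(e) {
    alnsens:::.pmat_cpp(sys$U, sys$lambda, sys$Uinv,
                        tree$edge.length[e] * scale)
  })
}

# amino-acid data simulated directly under the LG model (unit-consistent
# with the fitted model, unlike codon-simulated families)
simulate_lg_alignment <- function(tree, ncols, seed = 1) {
  set.seed(seed)
  freqs <- alnsens:::.lg_freqs
  Q <- alnsens:::.lg_Q(freqs)
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  lens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  ntip <- ape::Ntip(tree)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1]] <- sample.int(20, ncols, TRUE, prob = freqs)
  for (e in seq_len(nrow(pre))) {
    P <- as.matrix(Matrix::expm(Q * lens[e]))
    par <- states[[pre[e, 1]]]
    states[[pre[e, 2]]] <- vapply(par, function(i) {
      sample.int(20, 1, prob = P[i, ])
    }, 0L)
  }
  rows <- vapply(seq_len(ntip), function(i) {
    paste(AA[states[[i]]], collapse = "")
  }, "")
  names(rows) <- tree$tip.label
  seqAlignment(rows, "aa")
}
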