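# Codon-model positive-selection machinery: site models M0/M1a/M2a/M7/M8,
# branch and branch-site tests, likelihood-ratio tests, empirical-Bayes site
# identification, and the cross-alignment selection report.

# mixture log-likelihood from a class x site log-lik matrix
.mix_lnl <- function(llmat, props, weights) {
  m <- apply(llmat, 2, max)
  L <- exp(sweep(llmat, 2, m))
  sum(weights * (log(colSums(L * props)) + m))
}

# EM for mixture proportions given fixed class log-likelihoods
.em_props <- function(llmat, weights, init, maxIter = 200L, tol = 1e-9) {
  m <- apply(llmat, 2, max)
  L <- exp(sweep(llmat, 2, m))
  p <- init
  lnl <- -Inf
  for (it in seq_len(maxIter)) {
    num <- L * p
    den <- colSums(num)
    new_lnl <- sum(weights * (log(den) + m))
    gam <- sweep(num, 2, den, "/")
    p <- as.numeric(gam %*% weights)
    p <- p / sum(p)
    if (new_lnl - lnl < tol && it > 2L) { lnl <- new_lnl; break }
    lnl <- new_lnl
  }
  list(props = p, lnl = lnl)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Shared scaffolding: run nlminb from a set of starts, return the best.
.run_restarts <- function(objective, starts, lower, upper) {
  fits <- lapply(starts, function(s) {
    tryCatch(
      nlminb(s, objective, lower = lower, upper = upper,
             control = list(iter.max = 150L, eval.max = 500L)),
      error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$objective), fits)
  if (!length(fits)) stop("codon model optimization failed for every restart")
  lnls <- -vapply(fits, `[[`, 0, "objective")
  best <- which.max(lnls)
  list(par = fits[[best]]$par, lnL = lnls[best], all = lnls)
}

.restart_starts <- function(base, box, nRestarts, seed, tag) {
  starts <- list(base)
  if (nRestarts > 1L) {
    extra <- .with_stream(seed, paste0("restarts-", tag), {
      u <- .latin_hypercube(nRestarts - 1L, nrow(box))
      lapply(seq_len(nRestarts - 1L), function(i) {
        box[, 1] + u[i, ] * (box[, 2] - box[, 1])
      })
    })
    starts <- c(starts, extra)
  }
  starts
}

.convergence_flags <- function(lnls) {
  lnls <- sort(lnls, decreasing = TRUE)
  agree <- sum(lnls >= lnls[1] - 0.01)
  list(converged = length(lnls) == 1L || agree >= 2L,
       nAgree = as.integer(agree))
}

#' Fit a codon site model
#'
#' Maximum-likelihood fit of one of the standard Goldman-Yang site-class
#' models on a fixed topology: M0 (one ratio), M1a (nearly neutral), M2a
#' (positive selection), M7 (beta) and M8 (beta plus omega >= 1). The input
#' tree's branch lengths are held proportional; every model re-optimizes
#' kappa and a single rate-scale factor. Beta models use 10 equal-probability
#' categories at the category medians. Mixture proportions are profiled out
#' by expectation-maximization at every objective evaluation; the remaining
#' parameters are optimized by bounded quasi-Newton from \code{nRestarts}
#' starts (the default start plus seeded Latin-hypercube draws), and the
#' best restart is returned.
#'
#' @param codonAln In-frame nucleotide [SeqAlignment-class]. Stop codons are
#'   an error; all-gap codon sites are dropped with a warning.
#' @param tree \code{ape::phylo} with branch lengths, tips matching rows.
#' @param modelTag One of \code{"M0"}, \code{"M1a"}, \code{"M2a"},
#'   \code{"M7"}, \code{"M8"}.
#' @param nRestarts Number of optimizer starts (>= 1).
#' @param seed Integer seed for the restart draws.
#' @param init Optional named list of starting values (\code{kappa},
#'   \code{scale}, \code{w0}, \code{w2}, \code{p}, \code{q}, \code{ws}) used
#'   to warm-start, e.g. from a simpler nested model.
#' @param pi Optional 61-vector of codon frequencies; default [f3x4()] of the
#'   alignment.
#' @return A [CodonModelFit-class].
#' @export
fitSiteModel <- function(codonAln, tree, modelTag = c("M0", "M1a", "M2a",
                                                      "M7", "M8"),
                         nRestarts = 3L, seed = 1L, init = NULL, pi = NULL) {
  modelTag <- match.arg(modelTag)
  .check_tree_aln(tree, codonAln)
  if (is.null(pi)) pi <- f3x4(codonAln)
  pat <- .codon_patterns(codonAln, tree$tip.label)
  likf <- .codon_lik_factory(tree, pat, pi)
  w <- pat$weights
  s0 <- 1 / .codon_rate(.codon_Q_raw(2, 0.5, pmax(pi, 1e-10) /
                                       sum(pmax(pi, 1e-10))), pi)
  g <- function(x, d) if (!is.null(init[[x]])) init[[x]] else d

  if (modelTag == "M0") {
    base <- c(log(g("kappa", 2)), log(g("scale", s0)), log(g("w0", 0.3)))
    lower <- c(log(0.1), log(s0) - 7, log(1e-4))
    upper <- c(log(20), log(s0) + 7, log(50))
    box <- cbind(c(log(0.5), log(s0) - 2, log(0.02)),
                 c(log(8), log(s0) + 2, log(3)))
    obj <- function(th) {
      ll <- likf(exp(th[1]), exp(th[3]), scale = exp(th[2]))
      v <- sum(w * ll)
      if (!is.finite(v)) 1e10 else -v
    }
    decode <- function(th) {
      ll <- likf(exp(th[1]), exp(th[3]), scale = exp(th[2]))
      list(kappa = exp(th[1]), scale = exp(th[2]), props = 1,
           omegas = exp(th[3]), llmat = matrix(ll, 1),
           extra = list())
    }
  } else if (modelTag %in% c("M1a", "M2a")) {
    m2 <- modelTag == "M2a"
    base <- c(log(g("kappa", 2)), log(g("scale", s0)),
              stats::qlogis(min(max(g("w0", 0.15), 1e-4), 0.999)))
    lower <- c(log(0.1), log(s0) - 7, stats::qlogis(1e-4))
    upper <- c(log(20), log(s0) + 7, stats::qlogis(1 - 1e-6))
    box <- cbind(c(log(0.5), log(s0) - 2, -4), c(log(8), log(s0) + 2, 1))
    if (m2) {
      base <- c(base, log(max(g("w2", 2) - 1, 1e-5)))
      lower <- c(lower, -12)
      upper <- c(upper, log(49))
      box <- rbind(box, c(-2, 2.5))
    }
    pinit <- if (m2) c(0.6, 0.3, 0.1) else c(0.7, 0.3)
    decode <- function(th) {
      kappa <- exp(th[1]); scale <- exp(th[2]); w0 <- .sigmoid(th[3])
      lls <- rbind(likf(kappa, w0, scale = scale),
                   likf(kappa, 1, scale = scale))
      if (m2) lls <- rbind(lls, likf(kappa, 1 + exp(th[4]), scale = scale))
      em <- .em_props(lls, w, pinit)
      list(kappa = kappa, scale = scale, props = em$props,
           omegas = c(w0, 1, if (m2) 1 + exp(th[4])), llmat = lls,
           lnl = em$lnl, extra = list())
    }
    obj <- function(th) {
      d <- decode(th)
      if (!is.finite(d$lnl)) 1e10 else -d$lnl
    }
  } else {  # M7 / M8
    m8 <- modelTag == "M8"
    base <- c(log(g("kappa", 2)), log(g("scale", s0)),
              log(g("p", 0.5)), log(g("q", 1.5)))
    lower <- c(log(0.1), log(s0) - 7, log(0.005), log(0.005))
    upper <- c(log(20), log(s0) + 7, log(99), log(99))
    box <- cbind(c(log(0.5), log(s0) - 2, log(0.1), log(0.1)),
                 c(log(8), log(s0) + 2, log(4), log(4)))
    if (m8) {
      base <- c(base, log(max(g("ws", 2) - 1, 1e-5)))
      lower <- c(lower, -12)
      upper <- c(upper, log(49))
      box <- rbind(box, c(-2, 2.5))
    }
    ncat <- 10L
    decode <- function(th) {
      kappa <- exp(th[1]); scale <- exp(th[2])
      bp <- exp(th[3]); bq <- exp(th[4])
      wk <- stats::qbeta((seq_len(ncat) - 0.5) / ncat, bp, bq)
      wk <- pmin(pmax(wk, 1e-6), 1 - 1e-9)
      lls <- t(vapply(wk, function(om) likf(kappa, om, scale = scale),
                      numeric(length(w))))
      if (m8) {
        ws <- 1 + exp(th[5])
        llS <- likf(kappa, ws, scale = scale)
        # collapse beta part to one group for the 2-group EM
        m <- pmax(apply(lls, 2, max), llS)
        gBeta <- log(colMeans(exp(sweep(lls, 2, m)))) + m
        em <- .em_props(rbind(gBeta, llS), w, c(0.9, 0.1))
        props <- c(rep(em$props[1] / ncat, ncat), em$props[2])
        list(kappa = kappa, scale = scale, props = props,
             omegas = c(wk, ws), llmat = rbind(lls, llS), lnl = em$lnl,
             extra = list(betaP = bp, betaQ = bq, ws = ws,
                          p0 = em$props[1]))
      } else {
        props <- rep(1 / ncat, ncat)
        list(kappa = kappa, scale = scale, props = props, omegas = wk,
             llmat = lls, lnl = .mix_lnl(lls, props, w),
             extra = list(betaP = bp, betaQ = bq))
      }
    }
    obj <- function(th) {
      d <- decode(th)
      if (!is.finite(d$lnl)) 1e10 else -d$lnl
    }
  }

  starts <- .restart_starts(base, box, nRestarts, seed, modelTag)
  if (modelTag %in% c("M2a", "M8")) {
    # boundary start at the nested null (omega2/omegaS -> 1) so the fit
    # dominates the null by construction
    bd <- base
    bd[length(bd)] <- -12
    starts <- c(starts, list(bd))
  }
  res <- .run_restarts(obj, starts, lower, upper)
  d <- decode(res$par)
  fl <- .convergence_flags(res$all)
  siteLik <- d$llmat[, pat$siteOfPattern, drop = FALSE]
  new("CodonModelFit", modelTag = modelTag, kappa = d$kappa, pi = pi,
      classProps = as.numeric(d$props), classOmegas = as.numeric(d$omegas),
      extra = c(d$extra, list(scale = d$scale,
                              retainedSites = pat$retainedSites)),
      lnL = res$lnL, converged = fl$converged,
      nRestartsAgreeing = fl$nAgree, siteLik = siteLik,
      nSites = length(pat$retainedSites))
}

#' Likelihood-ratio test
#'
#' Statistic \code{max(0, 2 * (lnl1 - lnl0))} with the chi-square p-value at
#' the stated degrees of freedom and, following common practice for the site
#' model comparisons, a conservative p-value at df = 1.
#'
#' @param lnl0,lnl1 Log-likelihoods of the null and the more general model.
#' @param df Degrees of freedom (>= 1).
#' @return List with \code{statistic}, \code{df}, \code{pChisq},
#'   \code{pConservative}, \code{lnl0}, \code{lnl1}.
#' @examples
#' lrt(-16240.8767, -16219.8, df = 2)$statistic  # 42.1534
#' @export
lrt <- function(lnl0, lnl1, df) {
  if (df < 1) stop("df must be >= 1")
  stat <- max(0, 2 * (lnl1 - lnl0))
  list(statistic = stat, df = as.integer(df),
       pChisq = pchisq(stat, df, lower.tail = FALSE),
       pConservative = pchisq(stat, 1, lower.tail = FALSE),
       lnl0 = lnl0, lnl1 = lnl1)
}

#' Empirical-Bayes identification of positively selected sites
#'
#' Per-site posterior probability of membership in the positive-selection
#' class(es) (omega > 1). The default \code{"neb"} computes naive empirical
#' Bayes posteriors at the maximum-likelihood estimates; \code{"beb-lite"}
#' (M2a only) additionally averages the posteriors over a coarse grid of the
#' mixture parameters (5 points for each of omega0 and omega2, proportions
#' re-profiled per grid point), a lightweight approximation to full Bayes
#' empirical Bayes. Sites are flagged at posterior probability >= threshold
#' and numbered 1-based over the retained codon (amino-acid) columns.
#'
#' @param fit A [CodonModelFit-class] from a model containing an omega > 1
#'   class (M2a, M8, branch-site A alternative).
#' @param threshold Flagging threshold.
#' @param method \code{"neb"} or \code{"beb-lite"}.
#' @param codonAln,tree Required for \code{"beb-lite"} (to re-evaluate the
#'   grid); ignored for \code{"neb"}.
#' @return List with \code{pp} (posterior per retained site),
#'   \code{flaggedSites} (1-based retained-site indices with pp >=
#'   threshold), \code{siteNumbers} (their original codon-column numbers),
#'   \code{method}.
#' @export
sitePosteriors <- function(fit, threshold = 0.95,
                           method = c("neb", "beb-lite"), codonAln = NULL,
                           tree = NULL) {
  method <- match.arg(method)
  posClasses <- which(fit@classOmegas > 1)
  if (fit@modelTag %in% c("M0", "M1a", "M7", "branch2")) {
    stop("model ", fit@modelTag, " has no positive-selection class")
  }
  if (!length(posClasses)) {
    pp <- rep(0, fit@nSites)
  } else if (method == "neb") {
    pp <- .neb_pp(fit@siteLik, fit@classProps, posClasses)
  } else {
    if (fit@modelTag != "M2a") stop("beb-lite is implemented for M2a")
    if (is.null(codonAln) || is.null(tree)) {
      stop("beb-lite needs codonAln and tree")
    }
    pp <- .beb_lite_m2a(fit, codonAln, tree)
  }
  flagged <- which(pp >= threshold)
  list(pp = pp, flaggedSites = flagged,
       siteNumbers = fit@extra$retainedSites[flagged], method = method)
}

.neb_pp <- function(llmat, props, posClasses) {
  m <- apply(llmat, 2, max)
  L <- exp(sweep(llmat, 2, m)) * props
  colSums(L[posClasses, , drop = FALSE]) / colSums(L)
}

.beb_lite_m2a <- function(fit, codonAln, tree) {
  pat <- .codon_patterns(codonAln, tree$tip.label)
  likf <- .codon_lik_factory(tree, pat, fit@pi)
  w0g <- seq(0.05, 0.85, length.out = 5)
  w2g <- seq(1.2, 8, length.out = 5)
  kap <- fit@kappa
  sc <- fit@extra$scale
  ll1 <- likf(kap, 1, scale = sc)
  ppAcc <- 0
  wAcc <- numeric()
  pps <- list()
  for (a in w0g) for (b in w2g) {
    lls <- rbind(likf(kap, a, scale = sc), ll1, likf(kap, b, scale = sc))
    em <- .em_props(lls, pat$weights, c(0.6, 0.3, 0.1))
    wAcc <- c(wAcc, em$lnl)
    pps[[length(pps) + 1L]] <-
      .neb_pp(lls[, pat$siteOfPattern, drop = FALSE], em$props, 3L)
  }
  wAcc <- exp(wAcc - max(wAcc))
  wAcc <- wAcc / sum(wAcc)
  Reduce(`+`, Map(`*`, pps, wAcc))
}

#' Branch-specific test of selection (two-ratio model)
#'
#' Null: one omega for the whole tree (M0). Alternative: a separate omega on
#' the foreground branch, the edge subtending the named clade. The LRT has
#' 1 degree of freedom. A significant test with a foreground omega below 1
#' is reported as relaxed/purifying selection on the foreground, never as
#' positive selection.
#'
#' @inheritParams fitSiteModel
#' @param foregroundLeaves Character vector of leaf ids; the foreground is
#'   the branch subtending exactly this clade (error listing available
#'   clades otherwise).
#' @return List with \code{h0}, \code{ha} ([CodonModelFit-class]),
#'   \code{lrt}, \code{omegaFg}, \code{omegaBg}, \code{interpretation}.
#' @export
fitBranchModel <- function(codonAln, tree, foregroundLeaves, nRestarts = 2L,
                           seed = 1L, pi = NULL) {
  .check_tree_aln(tree, codonAln)
  if (is.null(pi)) pi <- f3x4(codonAln)
  fgEdge <- .find_clade_edge(tree, foregroundLeaves)
  h0 <- fitSiteModel(codonAln, tree, "M0", nRestarts = nRestarts,
                     seed = seed, pi = pi)
  pat <- .codon_patterns(codonAln, tree$tip.label)
  likf <- .codon_lik_factory(tree, pat, pi, fgEdge = fgEdge)
  w <- pat$weights
  base <- c(log(h0@kappa), log(h0@extra$scale), log(h0@classOmegas[1]),
            log(h0@classOmegas[1]))
  lower <- c(log(0.1), base[2] - 7, log(1e-4), log(1e-4))
  upper <- c(log(20), base[2] + 7, log(50), log(50))
  box <- cbind(base - 1.5, base + 1.5)
  obj <- function(th) {
    v <- sum(w * likf(exp(th[1]), exp(th[3]), exp(th[4]),
                      scale = exp(th[2])))
    if (!is.finite(v)) 1e10 else -v
  }
  starts <- .restart_starts(base, box, nRestarts, seed, "branch2")
  res <- .run_restarts(obj, starts, lower, upper)
  fl <- .convergence_flags(res$all)
  th <- res$par
  llha <- likf(exp(th[1]), exp(th[3]), exp(th[4]), scale = exp(th[2]))
  ha <- new("CodonModelFit", modelTag = "branch2", kappa = exp(th[1]),
            pi = pi, classProps = 1,
            classOmegas = exp(th[3]),
            extra = list(scale = exp(th[2]), omegaFg = exp(th[4]),
                         omegaBg = exp(th[3]),
                         retainedSites = pat$retainedSites),
            lnL = res$lnL, converged = fl$converged,
            nRestartsAgreeing = fl$nAgree,
            siteLik = matrix(llha[pat$siteOfPattern], 1),
            nSites = length(pat$retainedSites))
  test <- lrt(h0@lnL, ha@lnL, df = 1)
  wFg <- ha@extra$omegaFg
  wBg <- ha@extra$omegaBg
  interpretation <- if (test$pChisq >= 0.05) {
    "no significant branch-specific rate shift"
  } else if (wFg > 1 && wFg > wBg) {
    "positive selection on foreground branch"
  } else {
    "relaxed/purifying selection on foreground (foreground omega < 1)"
  }
  list(h0 = h0, ha = ha, lrt = test, omegaFg = wFg, omegaBg = wBg,
       interpretation = interpretation)
}

#' Branch-site test of selection (model A)
#'
#' Four site classes on a designated foreground branch: class 0 (omega0 on
#' all branches), class 1 (neutral everywhere), and classes 2a/2b in which
#' background sites at omega0 or 1 switch to omega2 on the foreground. The
#' null fixes omega2 = 1; the alternative frees omega2 >= 1; the LRT has 1
#' degree of freedom. When the alternative wins, foreground sites are
#' flagged by empirical-Bayes posteriors of the 2a/2b classes.
#'
#' @inheritParams fitBranchModel
#' @return List with \code{h0}, \code{ha}, \code{lrt}, \code{omega2},
#'   \code{sites} (posterior flags from [sitePosteriors()], NULL when the
#'   test is not significant at 0.05).
#' @export
fitBranchSiteA <- function(codonAln, tree, foregroundLeaves, nRestarts = 2L,
                           seed = 1L, pi = NULL) {
  .check_tree_aln(tree, codonAln)
  if (is.null(pi)) pi <- f3x4(codonAln)
  fgEdge <- .find_clade_edge(tree, foregroundLeaves)
  pat <- .codon_patterns(codonAln, tree$tip.label)
  likf <- .codon_lik_factory(tree, pat, pi, fgEdge = fgEdge)
  w <- pat$weights
  s0 <- 1 / .codon_rate(.codon_Q_raw(2, 0.5, pmax(pi, 1e-10) /
                                       sum(pmax(pi, 1e-10))), pi)

  fitA <- function(freeW2) {
    # theta: logk, logs, logit w0, logit t, logit u, [log(w2-1)]
    base <- c(log(2), log(s0), stats::qlogis(0.15), stats::qlogis(0.85),
              stats::qlogis(0.7), if (freeW2) log(1) else NULL)
    k <- length(base)
    lower <- c(log(0.1), log(s0) - 7, stats::qlogis(1e-4), -12, -12,
               if (freeW2) -12 else NULL)
    upper <- c(log(20), log(s0) + 7, stats::qlogis(1 - 1e-6), 12, 12,
               if (freeW2) log(49) else NULL)
    box <- cbind(base - 1.5, base + 1.5)
    decode <- function(th) {
      kap <- exp(th[1]); sc <- exp(th[2]); w0 <- .sigmoid(th[3])
      tt <- .sigmoid(th[4]); uu <- .sigmoid(th[5])
      w2 <- if (freeW2) 1 + exp(th[6]) else 1
      props <- c(tt * uu, tt * (1 - uu), (1 - tt) * uu, (1 - tt) * (1 - uu))
      lls <- rbind(likf(kap, w0, w0, scale = sc),
                   likf(kap, 1, 1, scale = sc),
                   likf(kap, w0, w2, scale = sc),
                   likf(kap, 1, w2, scale = sc))
      list(kappa = kap, scale = sc, w0 = w0, w2 = w2, props = props,
           llmat = lls, lnl = .mix_lnl(lls, props, w))
    }
    obj <- function(th) {
      d <- decode(th)
      if (!is.finite(d$lnl)) 1e10 else -d$lnl
    }
    starts <- .restart_starts(base, box, nRestarts, seed,
                              paste0("bsA", freeW2))
    res <- .run_restarts(obj, starts, lower, upper)
    d <- decode(res$par)
    fl <- .convergence_flags(res$all)
    new("CodonModelFit",
        modelTag = if (freeW2) "branchsiteA" else "branchsiteA0",
        kappa = d$kappa, pi = pi, classProps = d$props,
        classOmegas = c(d$w0, 1, d$w2, d$w2),
        extra = list(scale = d$scale, w0 = d$w0, w2 = d$w2,
                     retainedSites = pat$retainedSites),
        lnL = res$lnL, converged = fl$converged,
        nRestartsAgreeing = fl$nAgree,
        siteLik = d$llmat[, pat$siteOfPattern, drop = FALSE],
        nSites = length(pat$retainedSites))
  }

  h0 <- fitA(FALSE)
  ha <- fitA(TRUE)
  test <- lrt(h0@lnL, ha@lnL, df = 1)
  sites <- NULL
  if (test$pChisq < 0.05 && ha@extra$w2 > 1) {
    sites <- sitePosteriors(ha)
  }
  list(h0 = h0, ha = ha, lrt = test, omega2 = ha@extra$w2, sites = sites)
}

# map flagged codon columns to alignment-independent homology tokens
# (row id + residue ordinal), the currency for cross-alignment overlap
.flag_tokens <- function(codonAln, siteNumbers) {
  if (!length(siteNumbers)) return(character())
  seqs <- alignedSeqs(codonAln)
  toks <- character()
  for (id in names(seqs)) {
    cods <- substring(seqs[[id]], seq(1, nchar(seqs[[id]]), 3),
                      seq(3, nchar(seqs[[id]]), 3))
    ng <- cods != "---"
    ord <- cumsum(ng)
    keep <- siteNumbers[ng[siteNumbers]]
    toks <- c(toks, paste0(id, ":", ord[keep]))
  }
  toks
}

#' Cross-alignment selection report
#'
#' Runs the M1a/M2a and M7/M8 comparisons on each alignment/tree pair and
#' assembles the per-alignment table: log-likelihoods, LRT statistics,
#' chi-square p-values (stated df and conservative df = 1), significance
#' stars at the conventional 3.84 (5\%) and 6.63 (1\%) thresholds, and the
#' M2a empirical-Bayes flagged sites. A cross-alignment summary of flagged
#' sites is attached as \code{attr(x, "siteOverlap")}: the Jaccard index of
#' the flagged-site sets after mapping each alignment's columns to
#' alignment-independent (sequence, residue-ordinal) tokens.
#'
#' @param alignments List of in-frame codon [SeqAlignment-class] objects.
#' @param trees Parallel list of trees with branch lengths.
#' @param nRestarts,seed Passed to [fitSiteModel()].
#' @param ppThreshold Posterior threshold for flagging sites.
#' @return A data.frame, one row per alignment.
#' @export
selectionReport <- function(alignments, trees, nRestarts = 3L, seed = 1L,
                            ppThreshold = 0.95) {
  stopifnot(length(alignments) == length(trees))
  stars <- function(stat) {
    if (stat >= 6.63) "**" else if (stat >= 3.84) "*" else ""
  }
  rows <- list()
  tokens <- list()
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    tr <- trees[[i]]
    pi <- f3x4(aln)
    m0 <- fitSiteModel(aln, tr, "M0", nRestarts = 1L, seed = seed, pi = pi)
    ini <- list(kappa = m0@kappa, scale = m0@extra$scale,
                w0 = min(m0@classOmegas[1], 0.9))
    m1a <- fitSiteModel(aln, tr, "M1a", nRestarts = nRestarts, seed = seed,
                        init = ini, pi = pi)
    m2a <- fitSiteModel(aln, tr, "M2a", nRestarts = nRestarts, seed = seed,
                        init = c(ini, list(w0 = m1a@classOmegas[1],
                                           w2 = 2)), pi = pi)
    m7 <- fitSiteModel(aln, tr, "M7", nRestarts = nRestarts, seed = seed,
                       init = ini, pi = pi)
    m8 <- fitSiteModel(aln, tr, "M8", nRestarts = nRestarts, seed = seed,
                       init = c(ini, list(ws = 2)), pi = pi)
    t12 <- lrt(m1a@lnL, m2a@lnL, df = 2)
    t78 <- lrt(m7@lnL, m8@lnL, df = 2)
    sp <- sitePosteriors(m2a, threshold = ppThreshold)
    lbl <- methodLabel(aln)
    if (!nzchar(lbl)) lbl <- paste0("alignment", i)
    rows[[i]] <- data.frame(
      method = lbl,
      lnL_M1a = m1a@lnL, lnL_M2a = m2a@lnL,
      LRT_M1a_M2a = t12$statistic, p_df2 = t12$pChisq,
      p_df1 = t12$pConservative, sig_M1a_M2a = stars(t12$statistic),
      omega2 = m2a@classOmegas[3], p2 = m2a@classProps[3],
      lnL_M7 = m7@lnL, lnL_M8 = m8@lnL,
      LRT_M7_M8 = t78$statistic, p78_df2 = t78$pChisq,
      p78_df1 = t78$pConservative, sig_M7_M8 = stars(t78$statistic),
      n_flagged = length(sp$siteNumbers),
      flagged_sites = paste(sp$siteNumbers, collapse = ","),
      stringsAsFactors = FALSE)
    tokens[[i]] <- .flag_tokens(aln, sp$siteNumbers)
  }
  out <- do.call(rbind, rows)
  n <- length(alignments)
  ov <- matrix(NA_real_, n, n, dimnames = list(out$method, out$method))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- union(tokens[[i]], tokens[[j]])
    ov[i, j] <- if (!length(u)) NA_real_ else
      length(intersect(tokens[[i]], tokens[[j]])) / length(u)
  }
  attr(out, "siteOverlap") <- ov
  out
}
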