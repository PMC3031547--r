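# Tree concordance (Robinson-Foulds) and the alignment-method ranking table.

# canonical non-trivial bipartitions of an unrooted tree, as strings
.bipartitions <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 4L) return(character())
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  all_sorted <- sort(labs)
  out <- vapply(parts[-1], function(p) {       # parts[1] is the root clade
    side <- sort(labs[p])
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    if (all_sorted[1] %in% side) {
      side <- setdiff(all_sorted, side)
    }
    paste(side, collapse = "|")
  }, "")
  unique(out[!is.na(out)])
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartition sets of two unrooted
#' leaf-labeled trees (branch lengths ignored, multifurcations allowed). The
#' trees must cover the same leaf set unless \code{prune = TRUE}, in which
#' case both trees are first restricted to the shared leaves.
#'
#' @param t1,t2 \code{ape::phylo} trees.
#' @param prune Restrict to the common leaf set instead of erroring on a
#'   mismatch.
#' @return List with \code{rf} (even integer), \code{normalizedRf}
#'   (fraction of \code{2 (n - 3)}), \code{sharedBipartitions}, and \code{n}
#'   (leaf count compared).
#' @examples
#' a <- readNewick("((a:1,b:1):1,(c:1,d:1):1);")
#' b <- readNewick("((a:1,c:1):1,(b:1,d:1):1);")
#' rfDistance(a, b)$rf
#' @export
rfDistance <- function(t1, t2, prune = FALSE) {
  l1 <- t1$tip.label
  l2 <- t2$tip.label
  if (!setequal(l1, l2)) {
    if (!prune) {
      stop("leaf sets differ: only in first {",
           paste(setdiff(l1, l2), collapse = ","), "}; only in second {",
           paste(setdiff(l2, l1), collapse = ","), "}")
    }
    common <- intersect(l1, l2)
    if (length(common) < 3L) stop("fewer than 3 shared leaves")
    t1 <- ape::keep.tip(t1, common)
    t2 <- ape::keep.tip(t2, common)
  }
  b1 <- .bipartitions(t1)
  b2 <- .bipartitions(t2)
  shared <- length(intersect(b1, b2))
  rf <- (length(b1) - shared) + (length(b2) - shared)
  n <- ape::Ntip(t1)
  maxrf <- 2 * (n - 3)
  list(rf = as.integer(rf),
       normalizedRf = if (maxrf > 0) rf / maxrf else 0,
       sharedBipartitions = as.integer(shared), n = as.integer(n))
}

#' Rank alignment methods by tree concordance
#'
#' Sorts the per-alignment metric battery by Robinson-Foulds distance to the
#' reference tree (ascending), breaking ties by log-likelihood (descending)
#' and then mean branch support (descending). Ties on the full sort key are
#' reported in a \code{tied} column, not hidden.
#'
#' @param battery A data.frame with one row per alignment containing at
#'   least \code{method}, \code{rf}, \code{lnL} and \code{meanSupport}
#'   columns (any further metric columns are carried through).
#' @return The battery with \code{rank} and \code{tied} columns, sorted.
#' @export
rankAlignments <- function(battery) {
  need <- c("method", "rf", "lnL", "meanSupport")
  miss <- setdiff(need, names(battery))
  if (length(miss)) {
    stop("missing metric column(s): ", paste(miss, collapse = ", "))
  }
  ord <- order(battery$rf, -battery$lnL, -battery$meanSupport)
  out <- battery[ord, , drop = FALSE]
  key <- paste(out$rf, out$lnL, out$meanSupport)
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(key) | duplicated(key, fromLast = TRUE)
  rownames(out) <- NULL
  out
}
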