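## The taxa-partition (TP) summary tree.
##
## A single-stage construction: order the taxa so that clades of the
## posterior tend to occupy contiguous blocks, collect from every
## posterior tree the ages of clades compatible with the ordering (one
## age per inter-taxon boundary), take a point estimate per boundary and
## rebuild a tree recursively from the boundary ages, highest first.

#' Mean MRCA-size distance matrix between taxa
#'
#' d(a,b) is the mean, over the sampled trees, of the number of taxa in
#' the smallest clade containing both a and b.
#'
#' @param sample a \code{treeSample}.
#' @return symmetric numeric matrix with zero diagonal, labelled by taxa.
#' @export
pairDistanceMatrix <- function(sample) {
  taxa <- sample$taxa
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (t in sample$trees) {
    ## size of MRCA clade for every pair: for each internal clade, the
    ## pairs splitting at it get its size
    for (i in which(t$size > 1L)) {
      kids <- t$children[[i]]
      if (length(kids) < 2L) next
      for (a in seq_len(length(kids) - 1L)) for (b in (a + 1L):length(kids)) {
        ma <- t$members[[kids[a]]]; mb <- t$members[[kids[b]]]
        d[ma, mb] <- d[ma, mb] + t$size[i]
        d[mb, ma] <- d[mb, ma] + t$size[i]
      }
    }
  }
  d / length(sample$trees)
}

## lexicographic comparison of two label sequences; TRUE if a < b
lexLess <- function(a, b) {
  cmp <- which(a != b)
  if (length(cmp) == 0L) return(FALSE)
  a[cmp[1L]] < b[cmp[1L]]
}

#' Linear taxa ordering by agglomerative clustering
#'
#' Starts with each taxon in its own ordered group and progressively
#' joins the two closest groups (group distance = mean of cross-pair
#' distances). The joined group concatenates the two in whichever of the
#' four end-to-end orientations minimizes the distance between the two
#' boundary taxa; all ties resolve to the lexicographically smallest
#' resulting label sequence.
#'
#' @param d symmetric distance matrix from \code{pairDistanceMatrix}.
#' @return object of class \code{taxaOrder}: list with \code{order}
#'   (integer permutation) and \code{labels}.
#' @export
taxaOrder <- function(d) {
  taxa <- rownames(d)
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  while (length(groups) > 1L) {
    ng <- length(groups)
    bestPair <- NULL; bestD <- Inf
    for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
      dd <- mean(d[groups[[i]], groups[[j]]])
      if (dd < bestD - 1e-12) { bestD <- dd; bestPair <- c(i, j) }
    }
    i <- bestPair[1L]; j <- bestPair[2L]
    A <- groups[[i]]; B <- groups[[j]]
    variants <- list(c(A, B), c(A, rev(B)), c(rev(A), B), c(rev(A), rev(B)))
    bd <- vapply(variants, function(v) {
      left <- v[length(A)]; right <- v[length(A) + 1L]
      d[left, right]
    }, 0)
    cand <- variants[bd <= min(bd) + 1e-12]
    ## ties: lexicographically smallest label sequence
    best <- cand[[1L]]
    for (v in cand[-1L]) if (lexLess(taxa[v], taxa[best])) best <- v
    groups[[i]] <- best
    groups[[j]] <- NULL
  }
  structure(list(order = groups[[1L]], labels = taxa[groups[[1L]]]),
            class = "taxaOrder")
}

#' @export
print.taxaOrder <- function(x, ...) {
  cat("taxaOrder:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Collect split ages along a taxa ordering
#'
#' A clade of a sampled tree contributes its age to boundary k (between
#' order positions k and k+1) iff its members occupy a contiguous block
#' of positions, its two children occupy disjoint contiguous sub-blocks,
#' and k is exactly the boundary between those sub-blocks. For each
#' boundary a fallback estimate (the MRCA age of the two adjacent taxa,
#' defined in every tree) is also recorded for boundaries no clade
#' contributes to.
#'
#' @param order a \code{taxaOrder}.
#' @param sample a \code{treeSample}.
#' @return object of class \code{splitAges}: \code{ages} (list of n-1
#'   numeric vectors), \code{fallback} (numeric n-1 matrix of per-tree
#'   adjacent-pair MRCA ages).
#' @export
splitAges <- function(order, sample) {
  n <- length(order$order)
  pos <- integer(n)
  pos[order$order] <- seq_len(n)   # taxon index -> order position
  ages <- vector("list", n - 1L)
  for (t in sample$trees) {
    for (i in which(t$size > 1L)) {
      p <- pos[t$members[[i]]]
      if (max(p) - min(p) + 1L != length(p)) next  # not contiguous
      kids <- t$children[[i]]
      if (length(kids) != 2L) next
      p1 <- pos[t$members[[kids[1L]]]]
      p2 <- pos[t$members[[kids[2L]]]]
      if (max(p1) - min(p1) + 1L != length(p1)) next
      if (max(p2) - min(p2) + 1L != length(p2)) next
      k <- if (max(p1) < min(p2)) max(p1) else max(p2)
      ages[[k]] <- c(ages[[k]], t$age[i])
    }
  }
  fallback <- matrix(0, n - 1L, length(sample$trees))
  for (k in seq_len(n - 1L)) {
    pair <- c(order$order[k], order$order[k + 1L])
    fallback[k, ] <- vapply(sample$trees, mrcaAge, 0, subset = pair)
  }
  structure(list(ages = ages, fallback = fallback, order = order),
            class = "splitAges")
}

#' Reconstruct the taxa-partition tree from split ages
#'
#' Each boundary gets a point age (mean or median of its collected ages;
#' boundaries with no contribution fall back to the same statistic of the
#' adjacent-pair MRCA ages over all trees, and are flagged). The tree is
#' rebuilt recursively: the root sits at the highest boundary age
#' (leftmost on ties), and the construction recurses left and right.
#' Since boundary estimates are independent, a sub-interval's maximum can
#' exceed its parent's chosen age; such children are clamped to the
#' parent age and counted.
#'
#' @param order a \code{taxaOrder}.
#' @param splits a \code{splitAges} built on the same order.
#' @param sample the \code{treeSample} (for taxon labels).
#' @param stat "median" or "mean".
#' @return a \code{timeTree} with attributes \code{"clamped"} (count of
#'   clamped nodes) and \code{"fallback_used"} (boundary indices that had
#'   no direct contribution).
#' @export
tpTree <- function(order, splits, sample, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") median else mean
  n <- length(order$order)
  if (n == 1L)
    return(timeTree(sample$taxa, list(), numeric(0)))
  est <- numeric(n - 1L)
  fallbackUsed <- integer(0)
  for (k in seq_len(n - 1L)) {
    if (length(splits$ages[[k]]) > 0L) {
      est[k] <- f(splits$ages[[k]])
    } else {
      est[k] <- f(splits$fallback[k, ])
      fallbackUsed <- c(fallbackUsed, k)
    }
  }
  clamped <- 0L
  cladeList <- list(); ageList <- numeric(0)
  rec <- function(lo, hi, cap) {
    ## builds the subtree over order positions lo..hi; returns nothing,
    ## appends clades via <<-
    if (lo == hi) return(invisible())
    ks <- lo:(hi - 1L)
    k <- ks[which.max(est[ks])]
    a <- est[k]
    if (a > cap) { a <- cap; clamped <<- clamped + 1L }
    cladeList[[length(cladeList) + 1L]] <<- order$order[lo:hi]
    ageList[length(ageList) + 1L] <<- a
    rec(lo, k, a)
    rec(k + 1L, hi, a)
  }
  rec(1L, n, Inf)
  out <- timeTree(sample$taxa, cladeList, ageList, validate = FALSE)
  attr(out, "clamped") <- clamped
  attr(out, "fallback_used") <- fallbackUsed
  out
}

#' Taxa-partition summary tree (one call)
#'
#' @param sample a \code{treeSample}.
#' @param stat "median" or "mean".
#' @return a \code{timeTree} (see \code{\link{tpTree}} for attributes).
#' @export
taxaPartitionTree <- function(sample, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  ord <- taxaOrder(pairDistanceMatrix(sample))
  tpTree(ord, splitAges(ord, sample), sample, stat)
}
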