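## Selecting a summary topology from the sampled topologies.
##
## All selectors return an index into the sample: the chosen topology is
## always one that was actually sampled. Ties break to the lowest index
## for reproducibility.

#' Posterior clade frequencies
#'
#' For every clade observed in the sample, the fraction of trees
#' containing it (exact fractions with denominator = sample size).
#'
#' @param sample a \code{treeSample}.
#' @return object of class \code{cladeFrequencies}: list with \code{freq}
#'   (named vector, clade key -> fraction) and \code{k} (sample size).
#' @export
cladeFrequencies <- function(sample) {
  k <- length(sample$trees)
  counts <- table(unlist(lapply(sample$trees, function(t) t$keys)))
  structure(list(freq = as.numeric(counts) / k,
                 keys = names(counts), k = k,
                 lookup = stats::setNames(as.numeric(counts) / k,
                                          names(counts))),
            class = "cladeFrequencies")
}

#' @export
print.cladeFrequencies <- function(x, ...) {
  cat(sprintf("cladeFrequencies: %d clades over %d trees\n",
              length(x$keys), x$k))
  invisible(x)
}

#' Log clade credibility of a tree
#'
#' The log of the product of posterior frequencies of the tree's clades.
#' A clade never observed in the sample contributes \code{-Inf} (the
#' sentinel for an impossible tree under the empirical clade
#' distribution), not an error.
#'
#' @param tree a \code{timeTree}.
#' @param freqs a \code{cladeFrequencies}.
#' @return log score (0 for a tree whose clades all have frequency 1).
#' @export
cladeCredibility <- function(tree, freqs) {
  f <- freqs$lookup[tree$keys]
  f[is.na(f)] <- 0
  sum(log(f))
}

#' Select the maximum clade credibility (MCC) tree
#'
#' @param sample a \code{treeSample}.
#' @return index of the sampled tree maximizing \code{cladeCredibility};
#'   ties go to the lowest index.
#' @export
selectMCC <- function(sample) {
  freqs <- cladeFrequencies(sample)
  scores <- vapply(sample$trees, cladeCredibility, 0, freqs = freqs)
  which.max(scores)
}

#' Tally of conditional clade splits
#'
#' For every internal clade observed in the sample, counts how often each
#' child bipartition (split) of that clade occurs, along with the clade's
#' own occurrence count. This is the sufficient statistic of the
#' conditional clade distribution (CCD): the probability of a topology is
#' the product over its internal clades of (split count / clade count).
#'
#' @param sample a \code{treeSample}.
#' @return object of class \code{splitTally}.
#' @export
ccdTally <- function(sample) {
  cladeCount <- new.env(parent = emptyenv())
  splitCount <- new.env(parent = emptyenv())
  for (t in sample$trees) {
    for (i in which(t$size > 1L)) {
      key <- t$keys[i]
      cladeCount[[key]] <- (cladeCount[[key]] %||% 0L) + 1L
      kids <- t$children[[i]]
      skey <- paste(sort(t$keys[kids]), collapse = "|")
      full <- paste0(key, "=", skey)
      splitCount[[full]] <- (splitCount[[full]] %||% 0L) + 1L
    }
  }
  structure(list(clades = cladeCount, splits = splitCount,
                 k = length(sample$trees)), class = "splitTally")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.splitTally <- function(x, ...) {
  cat(sprintf("splitTally: %d clades, %d distinct splits over %d trees\n",
              length(ls(x$clades)), length(ls(x$splits)), x$k))
  invisible(x)
}

#' Log CCD probability of a tree's topology
#'
#' @param tree a \code{timeTree}.
#' @param tally a \code{splitTally}.
#' @return sum over internal clades of log(split count / clade count);
#'   \code{-Inf} if any split was never observed.
#' @export
ccdLogProb <- function(tree, tally) {
  total <- 0
  for (i in which(tree$size > 1L)) {
    key <- tree$keys[i]
    f <- tally$clades[[key]]
    if (is.null(f)) return(-Inf)
    kids <- tree$children[[i]]
    skey <- paste(sort(tree$keys[kids]), collapse = "|")
    s <- tally$splits[[paste0(key, "=", skey)]]
    if (is.null(s)) return(-Inf)
    total <- total + log(s / f)
  }
  total
}

#' Select the topology maximizing the conditional clade probability
#' @param sample a \code{treeSample}.
#' @return index of the sampled tree with the highest \code{ccdLogProb};
#'   ties go to the lowest index.
#' @export
selectCCD <- function(sample) {
  tally <- ccdTally(sample)
  scores <- vapply(sample$trees, ccdLogProb, 0, tally = tally)
  which.max(scores)
}

#' Total clade branch (TCB) scores
#'
#' Each clade's score is the total length of its matched branches across
#' the sample, combining frequency (how many trees contain the clade)
#' with confidence (longer branches being more likely real).
#'
#' @param sample a \code{treeSample}.
#' @return named numeric vector, clade key -> summed branch length.
#' @export
tcbScores <- function(sample) {
  keys <- character(0); bs <- numeric(0)
  for (t in sample$trees) {
    keys <- c(keys, t$keys)
    bs <- c(bs, branchLengths(t))
  }
  sums <- vapply(split(bs, keys), sum, 0)
  sums
}

#' Select the topology with the highest total clade branch score
#'
#' A tree's score combines the TCB scores of its clades, by sum (default)
#' or product.
#'
#' @param sample a \code{treeSample}.
#' @param combine "sum" (default) or "product" (log-sum of positive clade
#'   scores).
#' @return index of the best sampled tree; ties go to the lowest index.
#' @export
selectTCB <- function(sample, combine = c("sum", "product")) {
  combine <- match.arg(combine)
  tcb <- tcbScores(sample)
  scores <- vapply(sample$trees, function(t) {
    v <- tcb[t$keys]
    if (combine == "sum") sum(v) else sum(log(pmax(v, .Machine$double.xmin)))
  }, 0)
  which.max(scores)
}

#' Select the highest posterior frequency (HPF) topology
#'
#' Picks a tree of the most frequent topology in the sample. Among
#' frequency-tied topologies, the winner is the topology containing the
#' sampled tree whose root height is closest to the overall mean root
#' height; remaining ties go to the lowest index.
#'
#' @param sample a \code{treeSample}.
#' @return index of a sampled tree of the selected topology (the first
#'   tree of that topology in the sample).
#' @export
selectHPF <- function(sample) {
  topo <- vapply(sample$trees, topologyKey, "")
  counts <- table(topo)
  best <- names(counts)[counts == max(counts)]
  if (length(best) > 1L) {
    meanRoot <- mean(rootAges(sample))
    cand <- which(topo %in% best)
    dist <- abs(rootAges(sample)[cand] - meanRoot)
    best <- topo[cand[which.min(dist)]]
  }
  which(topo == best)[1L]
}
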