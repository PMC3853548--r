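## Pairwise tree scores and the preprocessed mean distance to a sample.
##
## All four scores operate on the clade decomposition of a pair of trees
## on the same taxa. Clade matching is exact (bitset/key equality). The
## branch length of a clade absent from a tree is 0 by convention, so a
## clade private to one tree contributes its full branch length.

METRICS <- c("rbs", "srbs", "hs", "ras", "hs_matched")

matchMetric <- function(metric) {
  match.arg(metric, METRICS)
}

#' Measure of the symmetric difference of two intervals
#'
#' \code{len(i1) + len(i2) - 2 * overlap(i1, i2)}.
#'
#' @param i1,i2 numeric length-2 vectors (low, high), low <= high.
#' @return the measure of the symmetric difference.
#' @export
intervalSymDiff <- function(i1, i2) {
  if (i1[2L] < i1[1L] || i2[2L] < i2[1L]) stop("malformed interval")
  (i1[2L] - i1[1L]) + (i2[2L] - i2[1L]) -
    2 * max(min(i1[2L], i2[2L]) - max(i1[1L], i2[1L]), 0)
}

#' Distance between two rooted time trees
#'
#' Four scores over the union (or intersection) of the two trees' clades:
#' \describe{
#'   \item{rbs}{rooted branch score: sum over the clade union of absolute
#'     branch-length differences (absent clade = branch 0). A metric.}
#'   \item{srbs}{squared rooted branch score: squared differences instead
#'     of absolute values. Not a metric.}
#'   \item{hs}{heights score: absolute age differences over shared clades,
#'     plus the full branch length of every private clade. Not a metric.}
#'   \item{ras}{rooted agreement score: the measure of the symmetric
#'     difference of the branch intervals [age, age + branch] over shared
#'     clades, plus private branch lengths. A metric.}
#'   \item{hs_matched}{the shared-clades heights term of hs only, with no
#'     private-branch penalty (the "heights only" objective).}
#' }
#'
#' @param t1,t2 \code{timeTree} objects on the same taxa.
#' @param metric one of \code{"rbs"}, \code{"srbs"}, \code{"hs"},
#'   \code{"ras"}, \code{"hs_matched"}.
#' @return a non-negative score.
#' @examples
#' ta <- timeTree(letters[1:3], list(c(1, 2), 1:3), c(1, 2))
#' tb <- timeTree(letters[1:3], list(c(1, 2), 1:3), c(0.5, 3))
#' treeDistance(ta, tb, "rbs")   # 3.5
#' treeDistance(ta, tb, "hs")    # 1.5
#' @export
treeDistance <- function(t1, t2, metric = c("rbs", "srbs", "hs", "ras",
                                            "hs_matched")) {
  metric <- match.arg(metric)
  if (!identical(t1$taxa, t2$taxa)) stop("trees are on different taxa")
  b1 <- branchLengths(t1); b2 <- branchLengths(t2)
  m12 <- match(t1$keys, t2$keys)
  shared1 <- which(!is.na(m12))
  shared2 <- m12[shared1]
  priv1 <- which(is.na(m12))
  priv2 <- setdiff(seq_along(t2$keys), shared2)
  switch(metric,
    rbs = sum(abs(b1[shared1] - b2[shared2])) + sum(b1[priv1]) + sum(b2[priv2]),
    srbs = sum((b1[shared1] - b2[shared2])^2) +
      sum(b1[priv1]^2) + sum(b2[priv2]^2),
    hs = sum(abs(t1$age[shared1] - t2$age[shared2])) +
      sum(b1[priv1]) + sum(b2[priv2]),
    hs_matched = sum(abs(t1$age[shared1] - t2$age[shared2])),
    ras = {
      l1 <- t1$age[shared1]; u1 <- l1 + b1[shared1]
      l2 <- t2$age[shared2]; u2 <- l2 + b2[shared2]
      ov <- pmax(pmin(u1, u2) - pmax(l1, l2), 0)
      sum(u1 - l1) + sum(u2 - l2) - 2 * sum(ov) +
        sum(b1[priv1]) + sum(b2[priv2])
    })
}

#' Preprocess a tree sample for fast mean-distance evaluation
#'
#' Collects, for every clade observed anywhere in the sample, its matched
#' branch lengths, ages and branch-interval endpoints, sorted and with
#' prefix sums, plus the sample-wide totals. With this index the mean
#' distance of a candidate tree to the whole sample is evaluated in
#' O(|clades| log |sample|) instead of O(|clades| * |sample|).
#'
#' @param sample a \code{treeSample}.
#' @param metric metric the index is intended for (all statistics are
#'   stored regardless, so one index serves every metric).
#' @return an object of class \code{cladeIndex}.
#' @export
cladeIndex <- function(sample, metric = "rbs") {
  metric <- matchMetric(metric)
  k <- length(sample$trees)
  keys <- character(0); bs <- numeric(0); hs <- numeric(0)
  for (t in sample$trees) {
    b <- branchLengths(t)
    keys <- c(keys, t$keys)
    bs <- c(bs, b)
    hs <- c(hs, t$age)
  }
  us <- hs + bs
  grp <- split(seq_along(keys), keys)
  clades <- lapply(grp, function(ii) {
    b <- sort(bs[ii]); h <- sort(hs[ii]); u <- sort(us[ii])
    list(n = length(ii),
         b = b, bcum = cumsum(b), bsum = sum(b), bsq = sum(b^2),
         h = h, hcum = cumsum(h), hsum = sum(h),
         l = h, lcum = cumsum(h),
         u = u, ucum = cumsum(u))
  })
  structure(list(metric = metric, k = k, taxa = sample$taxa,
                 clades = clades,
                 totalB = sum(bs), totalBsq = sum(bs^2)),
            class = "cladeIndex")
}

#' @export
print.cladeIndex <- function(x, ...) {
  cat(sprintf("cladeIndex: %d trees, %d distinct clades (metric %s)\n",
              x$k, length(x$clades), x$metric))
  invisible(x)
}

## sum of |x - v| over sorted v with prefix sums
absDevSum <- function(x, v, vcum, vsum) {
  cnt <- findInterval(x, v)
  le <- if (cnt == 0L) 0 else vcum[cnt]
  x * cnt - le + (vsum - le) - x * (length(v) - cnt)
}

## F(x) = sum_i max(0, min(u_i, x) - l_i) for intervals (l_i, u_i):
## cumulative covered length below x
coverBelow <- function(x, l, lcum, u, ucum) {
  cl <- findInterval(x, l)
  cu <- findInterval(x, u)
  a <- x * cl - (if (cl == 0L) 0 else lcum[cl])
  b <- x * cu - (if (cu == 0L) 0 else ucum[cu])
  a - b
}

## per-clade contribution of a (branch, age) pair under a metric;
## cl = NULL for a clade never observed in the sample
cladeTerm <- function(metric, cl, b, h, k) {
  if (is.null(cl)) {
    return(switch(metric,
                  rbs = b * k, srbs = b^2 * k, hs = b * k,
                  hs_matched = 0, ras = b * k))
  }
  n <- cl$n
  switch(metric,
    rbs = absDevSum(b, cl$b, cl$bcum, cl$bsum) + b * (k - n),
    srbs = k * b^2 - 2 * b * cl$bsum + cl$bsq,
    hs = absDevSum(h, cl$h, cl$hcum, cl$hsum) + b * (k - n),
    hs_matched = absDevSum(h, cl$h, cl$hcum, cl$hsum),
    ras = {
      u <- h + b
      k * b + cl$bsum -
        2 * (coverBelow(u, cl$l, cl$lcum, cl$u, cl$ucum) -
             coverBelow(h, cl$l, cl$lcum, cl$u, cl$ucum))
    })
}

## core evaluation shared by setDistance and the optimizer objective:
## takes per-clade (key, b, h) triplets of the candidate tree
setDistanceCore <- function(keys, b, h, index, metric) {
  k <- index$k
  total <- 0
  matchedBsum <- 0
  matchedBsq <- 0
  for (i in seq_along(keys)) {
    cl <- index$clades[[keys[i]]]
    total <- total + cladeTerm(metric, cl, b[i], h[i], k)
    if (!is.null(cl)) {
      matchedBsum <- matchedBsum + cl$bsum
      matchedBsq <- matchedBsq + cl$bsq
    }
  }
  total <- total + switch(metric,
    rbs = index$totalB - matchedBsum,
    hs = index$totalB - matchedBsum,
    ras = index$totalB - matchedBsum,
    srbs = index$totalBsq - matchedBsq,
    hs_matched = 0)
  total / k
}

#' Mean distance of a tree to a whole sample
#'
#' Equals the naive mean of pairwise \code{treeDistance} over all trees in
#' the indexed sample (to within floating-point error), but evaluated via
#' the preprocessed per-clade statistics.
#'
#' @param tree a \code{timeTree} on the index's taxa.
#' @param index a \code{cladeIndex}.
#' @param metric metric to evaluate under (defaults to the index's).
#' @return mean distance.
#' @export
setDistance <- function(tree, index, metric = index$metric) {
  metric <- matchMetric(metric)
  if (!identical(tree$taxa, index$taxa)) stop("taxa mismatch with index")
  setDistanceCore(tree$keys, branchLengths(tree), tree$age, index, metric)
}
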