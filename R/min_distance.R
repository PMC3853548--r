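## Minimum-distance summary trees.
##
## A candidate tree on a fixed topology is represented as a point
## z = (root_height, ratios) with one ratio per non-root internal clade
## (its age divided by its parent's age), listed in a fixed pre-order.
## Every component has a simple bound (root >= 0, ratios in [0,1]) and
## any point within bounds decodes to a valid tree, which makes the mean
## distance to the sample a suitable target for bounded quasi-Newton
## (L-BFGS-B) descent. The objective and its analytic gradient are
## evaluated against a preprocessed cladeIndex.

## pre-order listing of internal clade indices (root first)
preorderInternal <- function(topo) {
  out <- integer(0)
  stack <- topo$root
  while (length(stack)) {
    i <- stack[1L]; stack <- stack[-1L]
    out <- c(out, i)
    kids <- topo$children[[i]]
    kids <- kids[topo$size[kids] > 1L]
    if (length(kids))
      stack <- c(kids[order(vapply(kids, function(k) topo$members[[k]][1L], 0L))],
                 stack)
  }
  out
}

#' Encode a time tree as a bounded parameter vector
#'
#' @param tree a \code{timeTree}.
#' @return object of class \code{paramVector}: list with \code{topology},
#'   \code{root_height}, \code{ratios} (pre-order over non-root internal
#'   clades) and \code{order} (the clade indices).
#' @export
encodeTree <- function(tree) {
  ord <- preorderInternal(tree)
  nonroot <- ord[-1L]
  ratios <- vapply(nonroot, function(i) {
    pa <- tree$age[tree$parent[i]]
    if (pa <= 0) 0 else tree$age[i] / pa
  }, 0)
  structure(list(topology = tree, root_height = tree$age[tree$root],
                 ratios = pmin(pmax(ratios, 0), 1), order = ord),
            class = "paramVector")
}

## ages for all clades of pv$topology from (root_height, ratios)
decodeAges <- function(topo, ord, rootHeight, ratios) {
  age <- numeric(length(topo$age))
  age[ord[1L]] <- rootHeight
  if (length(ord) > 1L) {
    for (j in 2L:length(ord)) {
      i <- ord[j]
      age[i] <- age[topo$parent[i]] * ratios[j - 1L]
    }
  }
  age
}

#' Decode a parameter vector into a time tree
#'
#' @param pv a \code{paramVector} (ratios in [0,1], root height >= 0;
#'   out-of-bound values are an error).
#' @return a \code{timeTree} on \code{pv$topology}'s clade set.
#' @export
decodeTree <- function(pv) {
  if (pv$root_height < 0) stop("negative root height")
  if (any(pv$ratios < 0 | pv$ratios > 1)) stop("ratio out of [0,1]")
  topo <- pv$topology
  age <- decodeAges(topo, pv$order, pv$root_height, pv$ratios)
  idx <- which(topo$size > 1L)
  timeTree(topo$taxa, topo$members[idx], age[idx], validate = FALSE)
}

## left (one-sided from below) derivative helpers -----------------------

## d/dx sum_i |x - v_i| evaluated from below
absDevLeftDeriv <- function(x, v) {
  cntLt <- findInterval(x, v, left.open = TRUE)  # strictly below x
  2L * cntLt - length(v)
}

## F'(x-) where F is cumulative covered length of intervals (l, u)
coverLeftDeriv <- function(x, l, u) {
  findInterval(x, l, left.open = TRUE) - findInterval(x, u, left.open = TRUE)
}

## value and gradient (w.r.t. z) of the mean distance at z
objectiveCore <- function(rootHeight, ratios, topo, ord, index, metric) {
  age <- decodeAges(topo, ord, rootHeight, ratios)
  b <- numeric(length(age))
  ok <- !is.na(topo$parent)
  b[ok] <- age[topo$parent[ok]] - age[ok]
  value <- setDistanceCore(topo$keys, b, age, index, metric)
  k <- index$k
  ## g[i] = d(value)/d(age_i) for internal clades
  g <- numeric(length(age))
  for (i in seq_along(topo$keys)) {
    cl <- index$clades[[topo$keys[i]]]
    p <- topo$parent[i]
    isTip <- topo$size[i] == 1L
    n <- if (is.null(cl)) 0L else cl$n
    if (metric %in% c("rbs", "srbs")) {
      if (is.na(p)) next  # root has no branch
      db <- if (metric == "srbs") {
        2 * k * b[i] - 2 * (if (is.null(cl)) 0 else cl$bsum)
      } else {
        ## padded multiset: matched values plus (k - n) zeros
        cntLt <- if (is.null(cl)) 0L else
          findInterval(b[i], cl$b, left.open = TRUE)
        if (b[i] > 0) cntLt <- cntLt + (k - n)
        2 * cntLt - k
      }
      g[p] <- g[p] + db / k
      if (!isTip) g[i] <- g[i] - db / k
    } else if (metric %in% c("hs", "hs_matched")) {
      if (!isTip && !is.null(cl)) {
        dh <- absDevLeftDeriv(age[i], cl$h)
        g[i] <- g[i] + dh / k
      }
      if (metric == "hs" && !is.na(p)) {
        dpriv <- (k - n)  # d/db of b*(k-n)
        g[p] <- g[p] + dpriv / k
        if (!isTip) g[i] <- g[i] - dpriv / k
      }
    } else if (metric == "ras") {
      if (is.na(p)) next  # root: l = u, gradient cancels
      l <- age[i]; u <- age[p]
      if (is.null(cl)) {
        g[p] <- g[p] + 1      # k/k
        if (!isTip) g[i] <- g[i] - 1
      } else {
        du <- (k - 2 * coverLeftDeriv(u, cl$l, cl$u)) / k
        dl <- (-k + 2 * coverLeftDeriv(l, cl$l, cl$u)) / k
        g[p] <- g[p] + du
        if (!isTip) g[i] <- g[i] + dl
      }
    }
  }
  ## chain rule through the ratio parametrization: accumulate subtree
  ## sums A_j = g_j + sum over internal children of ratio_c * A_c,
  ## in reverse pre-order so children precede parents
  A <- numeric(length(age))
  ratioOf <- numeric(length(age))
  if (length(ord) > 1L) ratioOf[ord[-1L]] <- ratios
  for (j in rev(seq_along(ord))) {
    i <- ord[j]
    A[i] <- g[i]
    kids <- topo$children[[i]]
    kids <- kids[topo$size[kids] > 1L]
    for (c in kids) A[i] <- A[i] + ratioOf[c] * A[c]
  }
  gradRoot <- A[ord[1L]]
  gradRatios <- if (length(ord) > 1L)
    vapply(2L:length(ord), function(j) {
      i <- ord[j]
      age[topo$parent[i]] * A[i]
    }, 0) else numeric(0)
  list(value = value, gradient = c(gradRoot, gradRatios))
}

#' Mean-distance objective and analytic gradient at a parameter vector
#'
#' The value equals \code{setDistance(decodeTree(pv), index)}; the
#' gradient is exact where the objective is differentiable, with the
#' one-sided (from below) derivative at the kinks of the L1-type metrics.
#'
#' @param pv a \code{paramVector}.
#' @param index a \code{cladeIndex} over the sample.
#' @param metric metric to evaluate (defaults to the index's).
#' @return list with \code{value} and \code{gradient} (root height first,
#'   then ratios in pre-order).
#' @export
paramObjective <- function(pv, index, metric = index$metric) {
  metric <- matchMetric(metric)
  objectiveCore(pv$root_height, pv$ratios, pv$topology, pv$order,
                index, metric)
}

## median of matched values padded with zeros for absent trees,
## without materializing the zeros
paddedMedian <- function(v, k) {
  nz <- k - length(v)
  q <- function(pos) {  # pos in 1..k over the padded sorted multiset
    if (pos <= nz) 0 else sort(v)[pos - nz]
  }
  if (k %% 2L == 1L) q((k + 1L) %/% 2L)
  else (q(k %/% 2L) + q(k %/% 2L + 1L)) / 2
}

#' Initial tree for the fixed-topology search
#'
#' Each branch of the topology first gets its own isolated optimum: the
#' minimizer of its per-clade term of the mean distance, which is the
#' median (rbs/hs/ras) or mean (srbs) of its matched posterior branch
#' lengths padded with zeros for the trees lacking the clade. Ages are
#' then built in post-order, each clade's age being the average over its
#' children of (child age + child optimal branch), clamped from below by
#' the oldest child so the start point is always a valid tree.
#'
#' @param topology a \code{timeTree} supplying the clade set.
#' @param index a \code{cladeIndex}.
#' @param metric the target metric.
#' @return a \code{timeTree}.
#' @export
initTree <- function(topology, index, metric = index$metric) {
  metric <- matchMetric(metric)
  k <- index$k
  bstar <- numeric(length(topology$keys))
  for (i in seq_along(topology$keys)) {
    if (is.na(topology$parent[i])) next
    cl <- index$clades[[topology$keys[i]]]
    v <- if (is.null(cl)) numeric(0) else cl$b
    bstar[i] <- if (metric == "srbs") sum(v) / k else paddedMedian(v, k)
  }
  age <- numeric(length(topology$keys))
  ord <- preorderInternal(topology)
  for (i in rev(ord)) {
    kids <- topology$children[[i]]
    est <- mean(age[kids] + bstar[kids])
    age[i] <- max(est, max(age[kids]))
  }
  idx <- which(topology$size > 1L)
  timeTree(topology$taxa, topology$members[idx], age[idx], validate = FALSE)
}

defaultOptimizerOptions <- function(opts = list()) {
  defaults <- list(maxit = 500L, restarts = 3L, seed = NULL,
                   factr = 1e7, polish = TRUE)
  defaults[names(opts)] <- opts
  defaults
}

## one L-BFGS-B run (plus optional Nelder-Mead polish) from a start point
runDescent <- function(par, topo, ord, index, metric, opts) {
  np <- length(par)
  fn <- function(p) objectiveCore(p[1L], if (np > 1L) p[-1L] else numeric(0),
                                  topo, ord, index, metric)$value
  gr <- function(p) objectiveCore(p[1L], if (np > 1L) p[-1L] else numeric(0),
                                  topo, ord, index, metric)$gradient
  lower <- c(0, rep(0, np - 1L))
  upper <- c(Inf, rep(1, np - 1L))
  best <- par
  bestVal <- fn(par)
  res <- tryCatch(
    optim(par, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = opts$maxit, factr = opts$factr)),
    error = function(e) NULL)
  if (!is.null(res) && res$value < bestVal) {
    best <- res$par; bestVal <- res$value
  }
  if (isTRUE(opts$polish) && np <= 12L) {
    clamped <- function(p) fn(pmin(pmax(p, lower), upper))
    res2 <- tryCatch(
      optim(best, clamped, method = "Nelder-Mead",
            control = list(maxit = 400L)),
      error = function(e) NULL)
    if (!is.null(res2)) {
      p2 <- pmin(pmax(res2$par, lower), upper)
      v2 <- fn(p2)
      if (v2 < bestVal) { best <- p2; bestVal <- v2 }
    }
  }
  list(par = best, value = bestVal)
}

#' Optimize branch assignment for a fixed topology
#'
#' Bounded quasi-Newton (L-BFGS-B) descent of the mean distance to the
#' sample over the ratio parametrization, started from \code{initTree}
#' plus seeded random restarts, with a derivative-free polish to cope
#' with the kinks of the L1-type metrics. Sampled trees of the same
#' topology are always included as candidates, so the result is never
#' worse than any of them; ties go to the earliest candidate.
#'
#' @param topology a \code{timeTree} giving the clade set to optimize.
#' @param sample a \code{treeSample} (ignored if \code{index} given,
#'   except for locating same-topology candidates).
#' @param metric target metric.
#' @param opts list of optimizer options: \code{maxit}, \code{restarts},
#'   \code{seed}, \code{factr}, \code{polish}.
#' @param index optional precomputed \code{cladeIndex}.
#' @return the best \code{timeTree} found, with attribute
#'   \code{"distance"} holding its mean distance.
#' @export
optimizeTopology <- function(topology, sample, metric = "rbs",
                             opts = list(), index = NULL) {
  metric <- matchMetric(metric)
  opts <- defaultOptimizerOptions(opts)
  if (!is.null(opts$seed)) set.seed(opts$seed)
  if (is.null(index)) index <- cladeIndex(sample, metric)
  topoKey <- topologyKey(topology)

  candidates <- list()
  if (!is.null(sample)) {
    for (t in sample$trees)
      if (topologyKey(t) == topoKey) candidates <- c(candidates, list(t))
  }

  maxRoot <- if (!is.null(sample)) max(rootAges(sample)) else
    max(vapply(index$clades, function(cl) max(cl$u), 0))
  if (maxRoot <= 0) {
    ## degenerate sample: all heights zero
    idx <- which(topology$size > 1L)
    zero <- timeTree(topology$taxa, topology$members[idx],
                     rep(0, length(idx)), validate = FALSE)
    attr(zero, "distance") <- setDistance(zero, index, metric)
    return(zero)
  }

  init <- initTree(topology, index, metric)
  candidates <- c(candidates, list(init))
  pvInit <- encodeTree(init)
  ord <- pvInit$order
  topo <- pvInit$topology
  starts <- list(c(pvInit$root_height, pvInit$ratios))
  ## descend from a few sampled trees of this topology as well: local
  ## minima of the L1-type objectives often sit near sampled trees
  for (t in candidates[seq_len(min(4L, length(candidates)))]) {
    tAge <- t$age[match(topo$keys[ord], t$keys)]
    rr <- if (length(ord) > 1L) vapply(2L:length(ord), function(j) {
      pa <- tAge[match(topo$parent[ord[j]], ord)]
      if (pa <= 0) 0 else tAge[j] / pa
    }, 0) else numeric(0)
    starts[[length(starts) + 1L]] <- c(tAge[1L], pmin(pmax(rr, 0), 1))
  }
  nr <- max(0L, as.integer(opts$restarts))
  for (r in seq_len(nr)) {
    starts[[length(starts) + 1L]] <- c(runif(1, 0.2, 1.5) * maxRoot,
                                       runif(length(ord) - 1L))
  }
  for (s in starts) {
    res <- runDescent(s, topo, ord, index, metric, opts)
    dec <- decodeAges(topo, ord, res$par[1L],
                      if (length(res$par) > 1L) res$par[-1L] else numeric(0))
    idx <- which(topo$size > 1L)
    candidates <- c(candidates,
                    list(timeTree(topo$taxa, topo$members[idx], dec[idx],
                                  validate = FALSE)))
  }
  dists <- vapply(candidates, setDistance, 0, index = index, metric = metric)
  ## first candidate within numerical noise of the minimum wins, so a
  ## sampled tree is preferred over an optimizer output that "beats" it
  ## only by floating-point cancellation
  minD <- min(dists)
  best <- which(dists <= minD + 1e-9 * (1 + abs(minD)))[1L]
  out <- candidates[[best]]
  attr(out, "distance") <- dists[best]
  out
}

#' Minimum-distance summary tree
#'
#' Finds the tree minimizing the mean distance to the sample under the
#' chosen metric. The topology search is restricted to topologies present
#' in the sample: either all of them (the "m" methods mRBS, mSRBS, mRAS,
#' mHS), or the single topology chosen by the MCC or TCB selector, or an
#' explicitly supplied topology. Every sampled tree is also evaluated
#' as-is, so the result is never worse than the best sampled tree.
#'
#' @param sample a \code{treeSample}.
#' @param metric target metric.
#' @param topology "all" (search every sampled topology), "mcc", "tcb",
#'   or a \code{timeTree} giving the topology.
#' @param opts optimizer options (see \code{\link{optimizeTopology}}).
#' @param maxTopologies cap on the number of distinct topologies searched
#'   (most frequent first); a warning reports truncation.
#' @return the best \code{timeTree}, with attribute \code{"distance"}.
#' @export
minDistanceTree <- function(sample, metric = "rbs", topology = "all",
                            opts = list(), maxTopologies = 1024L) {
  metric <- matchMetric(metric)
  index <- cladeIndex(sample, metric)
  if (inherits(topology, "timeTree"))
    return(optimizeTopology(topology, sample, metric, opts, index))
  if (topology == "mcc")
    return(optimizeTopology(sample$trees[[selectMCC(sample)]], sample,
                            metric, opts, index))
  if (topology == "tcb")
    return(optimizeTopology(sample$trees[[selectTCB(sample)]], sample,
                            metric, opts, index))
  if (topology != "all") stop("unknown topology source: ", topology)

  keys <- vapply(sample$trees, topologyKey, "")
  counts <- table(keys)
  ## most frequent first; ties by first occurrence in the sample
  firstSeen <- vapply(names(counts), function(k) which(keys == k)[1L], 0L)
  ordT <- names(counts)[order(-as.numeric(counts), firstSeen)]
  if (length(ordT) > maxTopologies) {
    warning(sprintf("topology search truncated to the %d most frequent of %d",
                    maxTopologies, length(ordT)))
    ordT <- ordT[seq_len(maxTopologies)]
  }
  best <- NULL
  bestDist <- Inf
  for (key in ordT) {
    rep1 <- sample$trees[[which(keys == key)[1L]]]
    sub <- structure(list(taxa = sample$taxa,
                          trees = sample$trees[keys == key]),
                     class = "treeSample")
    cand <- optimizeTopology(rep1, sub, metric, opts, index)
    d <- attr(cand, "distance")
    if (d < bestDist - 1e-9 * (1 + abs(d))) { best <- cand; bestDist <- d }
  }
  attr(best, "distance") <- bestDist
  best
}
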