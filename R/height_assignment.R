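## Fixed-topology height assignment.
##
## A heightAssignment records a topology (clade set), one age per clade,
## and whether the ages actually form a tree: independent per-clade
## estimation (mean/median of matched posterior ages) can produce
## "negative branches", where a clade is assigned an older age than its
## parent. Such assignments are flagged, not silently repaired.

newHeightAssignment <- function(taxa, cladeMembers, heights) {
  ## detect parent-child inversions against the raw heights: build the
  ## hierarchy at age zero (structure only), then compare along parent
  ## links, since constructing a tree directly would clamp them away
  skel <- timeTree(taxa, cladeMembers, rep(0, length(cladeMembers)),
                   validate = FALSE)
  h <- numeric(length(skel$keys))
  h[match(vapply(cladeMembers, cladeKey, ""), skel$keys)] <- heights
  neg <- list()
  for (i in seq_along(skel$keys)) {
    p <- skel$parent[i]
    if (!is.na(p) && h[i] > h[p] + 1e-9)
      neg[[length(neg) + 1L]] <- list(clade = skel$keys[i],
                                      magnitude = h[i] - h[p])
  }
  structure(list(taxa = taxa, clades = cladeMembers, heights = heights,
                 valid = length(neg) == 0L, negative_branches = neg),
            class = "heightAssignment")
}

#' @export
print.heightAssignment <- function(x, ...) {
  cat(sprintf("heightAssignment: %d clades, %s\n", length(x$clades),
              if (x$valid) "valid" else
                sprintf("%d negative branch(es)", length(x$negative_branches))))
  invisible(x)
}

#' Convert a height assignment to a time tree
#'
#' @param ha a \code{heightAssignment}.
#' @param repair "none" (error if the assignment has negative branches)
#'   or "clamp" (clamp each child age to its parent's, producing
#'   zero-length branches where estimates conflicted).
#' @return a \code{timeTree}.
#' @export
assignmentTree <- function(ha, repair = c("none", "clamp")) {
  repair <- match.arg(repair)
  if (!ha$valid && repair == "none")
    stop("assignment has negative branches; use repair = \"clamp\"")
  ## timeTree() clamps parents-first internally when validate = FALSE
  t <- timeTree(ha$taxa, ha$clades, pmax(ha$heights, 0), validate = FALSE)
  t
}

## clade member lists (size > 1) of a topology given as a timeTree
topologyClades <- function(topology) {
  idx <- which(topology$size > 1L)
  stats::setNames(topology$members[idx], topology$keys[idx])
}

#' Per-clade pointwise heights (TreeAnnotator-style AVG/MED)
#'
#' Each clade of the topology gets the mean or median of its ages in the
#' sampled trees that contain it. Because every clade uses a different
#' subset of trees, the result can have negative branches; validity is
#' flagged, not repaired.
#'
#' @param topology a \code{timeTree} supplying the clade set (its ages
#'   are ignored).
#' @param sample a \code{treeSample}.
#' @param stat "mean" or "median" (median of an even count = midpoint of
#'   the two central values).
#' @return a \code{heightAssignment}.
#' @export
pointwiseHeights <- function(topology, sample, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else median
  clades <- topologyClades(topology)
  heights <- vapply(names(clades), function(key) {
    ages <- unlist(lapply(sample$trees, function(t) {
      i <- match(key, t$keys)
      if (is.na(i)) NULL else t$age[i]
    }))
    if (length(ages) == 0L)
      stop("clade never observed in the sample: ", key)
    f(ages)
  }, 0)
  newHeightAssignment(topology$taxa, clades, heights)
}

#' Common-ancestor heights (CAT)
#'
#' Each clade of the topology gets the mean, over \emph{all} sampled
#' trees, of the age of its MRCA in that tree. Since nesting of clades
#' implies nesting of MRCAs in every tree, the resulting ages always form
#' a valid tree.
#'
#' @inheritParams pointwiseHeights
#' @param stat "mean" (the standard construction) or "median".
#' @return a \code{heightAssignment} (always valid).
#' @export
catHeights <- function(topology, sample, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else median
  clades <- topologyClades(topology)
  heights <- vapply(clades, function(members) {
    f(vapply(sample$trees, mrcaAge, 0, subset = members))
  }, 0)
  newHeightAssignment(topology$taxa, clades, heights)
}

#' Majority-rule consensus tree with heights
#'
#' The topology consists of the clades present in more than
#' \code{threshold} of the sampled trees (majority rule at 0.5; such
#' clades are mutually compatible by construction). Heights are, by
#' default, CAT-style MRCA-age statistics over all trees, which
#' guarantees a valid tree; \code{heights = "matched"} instead uses only
#' the trees containing each clade (the result may then need clamping).
#'
#' @param sample a \code{treeSample}.
#' @param threshold frequency cutoff in [0.5, 1); a clade is kept iff its
#'   frequency is strictly greater.
#' @param stat "median" or "mean".
#' @param heights "mrca" (default) or "matched".
#' @return a \code{timeTree}.
#' @export
consensusTree <- function(sample, threshold = 0.5,
                          stat = c("median", "mean"),
                          heights = c("mrca", "matched")) {
  stat <- match.arg(stat)
  heights <- match.arg(heights)
  if (threshold < 0.5 || threshold >= 1) stop("threshold must be in [0.5, 1)")
  freqs <- cladeFrequencies(sample)
  keep <- freqs$keys[freqs$freq > threshold]
  members <- lapply(keep, keyMembers)
  sizes <- lengths(members)
  topoMembers <- members[sizes > 1L]
  ## the root is always at frequency 1, so it is always kept
  topo <- timeTree(sample$taxa, topoMembers, rep(0, length(topoMembers)),
                   validate = FALSE)
  ha <- if (heights == "mrca") catHeights(topo, sample, stat)
        else pointwiseHeights(topo, sample,
                              if (stat == "median") "median" else "mean")
  assignmentTree(ha, repair = "clamp")
}
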