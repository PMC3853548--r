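## Summary-versus-truth error measures.
##
## "Non-trivial" clades are internal non-root clades: singletons and the
## root are present in every rooted tree on the same taxa, and only this
## convention makes the clades-missed count equal half the
## Robinson-Foulds distance for fully resolved trees.

checkSameTaxa <- function(t, ref) {
  if (!identical(t$taxa, ref$taxa)) stop("trees are on different taxa")
}

#' Heights error of a tree against a reference
#'
#' Sum over every clade of \code{t} of the absolute difference between its
#' age and the age of its MRCA in the reference tree. A clade absent from
#' the reference is scored against the (larger) clade spanned by its taxa
#' there. Not symmetric.
#'
#' @param t the tree being scored.
#' @param ref the reference (true) tree.
#' @return non-negative error (age units).
#' @export
heightsError <- function(t, ref) {
  checkSameTaxa(t, ref)
  idx <- which(t$size > 1L)
  sum(vapply(idx, function(i)
    abs(t$age[i] - mrcaAge(ref, t$members[[i]])), 0))
}

#' Divergence-times error of a tree against a reference
#'
#' Sum over every clade of \code{t} of the absolute difference between its
#' age and its mean divergence time in the reference (the mean reference
#' MRCA age of the taxon pairs splitting at the clade). Coincides with
#' \code{heightsError} when the two trees share a topology.
#'
#' @inheritParams heightsError
#' @return non-negative error (age units).
#' @export
divergenceError <- function(t, ref) {
  checkSameTaxa(t, ref)
  idx <- which(t$size > 1L)
  sum(vapply(idx, function(i)
    abs(t$age[i] - divergenceTime(t$members[[i]], t, ref)), 0))
}

## internal non-root clade keys with strictly positive branch length
positiveCladeKeys <- function(tree) {
  b <- branchLengths(tree)
  tree$keys[tree$size > 1L & tree$size < tree$n & b > 0]
}

#' Count of reference clades missed by a tree
#'
#' The number of non-trivial (internal, non-root) clades of \code{ref}
#' that are not present in \code{t} with a strictly positive branch
#' length: a zero-length branch does not count as a match. For fully
#' resolved trees with all-positive branches this equals half the
#' Robinson-Foulds distance.
#'
#' @inheritParams heightsError
#' @return non-negative integer count.
#' @export
cladesMissed <- function(t, ref) {
  checkSameTaxa(t, ref)
  bref <- branchLengths(ref)
  refKeys <- ref$keys[ref$size > 1L & ref$size < ref$n & bref > 0]
  sum(!(refKeys %in% positiveCladeKeys(t)))
}

#' Clades-called score of a tree against a reference
#'
#' Wrongly called clades minus correctly called clades, over the
#' non-trivial positive-branch clades of \code{t}: lower is better, and a
#' tree that calls nothing (a star) scores 0.
#'
#' @inheritParams heightsError
#' @return integer score (can be negative).
#' @export
cladesCalled <- function(t, ref) {
  checkSameTaxa(t, ref)
  tk <- positiveCladeKeys(t)
  refKeys <- ref$keys[ref$size > 1L & ref$size < ref$n]
  sum(!(tk %in% refKeys)) - sum(tk %in% refKeys)
}

#' Absolute root-height error
#' @inheritParams heightsError
#' @return |root age of t - root age of ref|.
#' @export
rootHeightError <- function(t, ref) {
  checkSameTaxa(t, ref)
  abs(rootAge(t) - rootAge(ref))
}

#' Normalized error variants for reporting
#'
#' Heights error per internal clade as a percentage of the true root
#' height, and clades missed as a percentage of the reference's
#' non-trivial clades.
#'
#' @inheritParams heightsError
#' @return named numeric vector \code{c(heights_pct, missed_pct)}.
#' @export
normalizedErrors <- function(t, ref) {
  nInternal <- sum(t$size > 1L)
  nNontrivial <- sum(ref$size > 1L & ref$size < ref$n &
                     branchLengths(ref) > 0)
  c(heights_pct = 100 * heightsError(t, ref) / nInternal / rootAge(ref),
    missed_pct = if (nNontrivial == 0L) 0 else
      100 * cladesMissed(t, ref) / nNontrivial)
}

#' Write a table of error vectors to TSV
#' @param rows data.frame with one row per (case, method).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeErrorTable <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
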