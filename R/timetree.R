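#' @importFrom stats median optim rexp rpois rlnorm rnorm runif setNames
#' @importFrom utils write.table
#' @importFrom ape as.phylo
NULL

## Canonical key for a clade: taxon indices (sorted) joined by ".".
## Keys are the unit of clade matching throughout the package; two clades
## match iff their keys are equal.
cladeKey <- function(members) {
  paste(members, collapse = ".")
}

keyMembers <- function(key) {
  as.integer(strsplit(key, ".", fixed = TRUE)[[1L]])
}

#' Construct a rooted time tree from aged clades
#'
#' A time tree is a set of clades over a fixed taxon set, each with a
#' non-negative age. The clade set must form a strict hierarchy (any two
#' clades are nested or disjoint), contain every singleton and the full
#' taxon set (the root), and ages must respect nesting: a clade can never
#' be older than a clade containing it. Tips are contemporaneous at age 0;
#' trees with dated (non-zero age) tips are rejected.
#'
#' @param taxa character vector of unique taxon labels; their order fixes
#'   the bit/index layout used for clade matching.
#' @param clades list of clades, each either an integer vector of taxon
#'   indices or a character vector of taxon labels. Singletons may be
#'   omitted; they are implied at age 0. The root (all taxa) must be
#'   present unless \code{ages} is empty and \code{length(taxa) == 1}.
#' @param ages numeric vector of ages, parallel to \code{clades}.
#' @param validate logical; skip validation only for internally generated
#'   trees known to be valid.
#' @return an object of class \code{timeTree}.
#' @examples
#' ta <- timeTree(c("a", "b", "c"),
#'                list(c("a", "b"), c("a", "b", "c")), c(1, 2))
#' mrcaAge(ta, c("a", "b"))
#' @export
timeTree <- function(taxa, clades, ages, validate = TRUE) {
  n <- length(taxa)
  if (n < 1L || anyDuplicated(taxa))
    stop("taxa must be a non-empty set of unique labels")
  clades <- lapply(clades, function(cl) {
    if (is.character(cl)) {
      idx <- match(cl, taxa)
      if (anyNA(idx)) stop("clade member not in taxon set: ",
                           paste(cl[is.na(idx)], collapse = ", "))
      cl <- idx
    }
    sort(unique(as.integer(cl)))
  })
  if (length(clades) != length(ages))
    stop("clades and ages must have the same length")
  sizes <- lengths(clades)
  if (any(sizes == 0L)) stop("empty clade")
  if (validate && any(ages < -1e-9)) stop("negative clade age")
  ages <- pmax(ages, 0)

  ## drop caller-supplied singletons, re-add canonically at age 0
  if (validate && any(sizes == 1L & ages > 1e-9))
    stop("dated tips are not supported: singleton clades must have age 0")
  keep <- sizes > 1L
  clades <- clades[keep]
  ages <- ages[keep]
  keys <- vapply(clades, cladeKey, "")
  if (anyDuplicated(keys)) stop("duplicate clade")

  allc <- c(as.list(seq_len(n)), clades)
  allages <- c(rep(0, n), ages)
  allkeys <- c(as.character(seq_len(n)), keys)
  m <- length(allc)

  rootKey <- cladeKey(seq_len(n))
  rootIdx <- match(rootKey, allkeys)
  if (is.na(rootIdx)) {
    if (n == 1L) {
      rootIdx <- 1L
    } else stop("missing root clade (all taxa)")
  }

  ## membership matrix: rows = clades, cols = taxa
  M <- matrix(FALSE, m, n)
  for (i in seq_len(m)) M[i, allc[[i]]] <- TRUE
  sz <- lengths(allc)

  if (validate && m > 1L) {
    inter <- tcrossprod(M)
    minsz <- outer(sz, sz, pmin)
    bad <- inter > 0 & inter < minsz
    if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("clades overlap without nesting: {%s} and {%s}",
                   paste(taxa[allc[[ij[1L]]]], collapse = ","),
                   paste(taxa[allc[[ij[2L]]]], collapse = ",")))
    }
  } else inter <- NULL

  ## parent = minimal proper superset
  parent <- rep(NA_integer_, m)
  if (m > 1L) {
    if (is.null(inter)) inter <- tcrossprod(M)
    ord <- order(sz)
    for (i in seq_len(m)) {
      if (i == rootIdx) next
      sup <- which(inter[i, ] == sz[i] & sz > sz[i])
      parent[i] <- sup[which.min(sz[sup])]
    }
  }

  ## age order along parent links (condition iv), with 1e-9 clamp
  if (validate) {
    for (i in seq_len(m)) {
      p <- parent[i]
      if (is.na(p)) next
      if (allages[i] > allages[p] + 1e-9)
        stop(sprintf("clade {%s} (age %g) older than its parent (age %g)",
                     paste(taxa[allc[[i]]], collapse = ","),
                     allages[i], allages[p]))
    }
  }
  ## clamp tiny inversions introduced by I/O round-trips (parents first)
  ord <- order(sz, decreasing = TRUE)
  for (i in ord) {
    p <- parent[i]
    if (!is.na(p) && allages[i] > allages[p]) allages[i] <- allages[p]
  }

  children <- vector("list", m)
  for (i in seq_len(m)) {
    p <- parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }

  structure(list(taxa = taxa, n = n, members = unname(allc),
                 keys = unname(allkeys), size = unname(sz),
                 age = unname(allages), parent = parent,
                 children = children, root = rootIdx),
            class = "timeTree")
}

#' @export
print.timeTree <- function(x, ...) {
  cat(sprintf("timeTree: %d taxa, %d internal clades, root age %g\n",
              x$n, sum(x$size > 1L & x$size < x$n), x$age[x$root]))
  invisible(x)
}

#' Number of taxa of a tree or sample
#' @param x a \code{timeTree} or \code{treeSample}.
#' @return integer count of taxa.
#' @export
nTaxa <- function(x) length(x$taxa)

#' Taxon labels of a tree or sample
#' @param x a \code{timeTree} or \code{treeSample}.
#' @return character vector of labels.
#' @export
taxaLabels <- function(x) x$taxa

#' Clade ages of a tree
#'
#' @param tree a \code{timeTree}.
#' @param internal if TRUE, restrict to internal clades (size > 1,
#'   including the root).
#' @return named numeric vector of ages, names are clade keys.
#' @export
cladeAges <- function(tree, internal = FALSE) {
  idx <- if (internal) which(tree$size > 1L) else seq_along(tree$keys)
  stats::setNames(tree$age[idx], tree$keys[idx])
}

#' Root age of a time tree
#' @param tree a \code{timeTree}.
#' @return the age of the root clade.
#' @export
rootAge <- function(tree) tree$age[tree$root]

resolveSubset <- function(tree, subset) {
  if (is.character(subset)) {
    idx <- match(subset, tree$taxa)
    if (anyNA(idx)) stop("unknown taxon: ",
                         paste(subset[is.na(idx)], collapse = ", "))
    subset <- idx
  }
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L) stop("empty taxon subset")
  subset
}

## index of the minimal clade containing subset (the MRCA clade)
mrcaIndex <- function(tree, subset) {
  subset <- resolveSubset(tree, subset)
  if (length(subset) == 1L) return(subset)
  ## walk up from the first member until all are contained
  i <- subset[1L]
  repeat {
    i <- tree$parent[i]
    if (is.na(i)) return(tree$root)
    if (all(subset %in% tree$members[[i]])) return(i)
  }
}

#' Age of the most recent common ancestor of a taxon subset
#'
#' The age of the minimal clade of \code{tree} containing every member of
#' \code{subset}; for a singleton this is the tip age, 0.
#'
#' @param tree a \code{timeTree}.
#' @param subset taxon labels or indices (non-empty).
#' @return the MRCA age.
#' @export
mrcaAge <- function(tree, subset) {
  tree$age[mrcaIndex(tree, subset)]
}

#' Branch length above a taxon subset
#'
#' For a clade of the tree, the age of its parent minus its own age. The
#' root has no parent and gets 0; a subset that is not a clade of the tree
#' also gets 0 (the convention that makes clade-union sums well defined).
#'
#' @param tree a \code{timeTree}.
#' @param subset taxon labels or indices.
#' @return branch length (>= 0).
#' @export
branchLength <- function(tree, subset) {
  subset <- resolveSubset(tree, subset)
  i <- match(cladeKey(subset), tree$keys)
  if (is.na(i)) return(0)
  p <- tree$parent[i]
  if (is.na(p)) 0 else tree$age[p] - tree$age[i]
}

## all branch lengths, indexed like tree$keys (root gets 0)
branchLengths <- function(tree) {
  b <- numeric(length(tree$age))
  ok <- !is.na(tree$parent)
  b[ok] <- tree$age[tree$parent[ok]] - tree$age[ok]
  b
}

#' Total branch length of a tree
#' @param tree a \code{timeTree}.
#' @return sum of all branch lengths (the root contributes 0).
#' @export
totalTreeLength <- function(tree) sum(branchLengths(tree))

#' Taxon pairs whose MRCA is a given clade
#'
#' All unordered taxon pairs within \code{clade} whose most recent common
#' ancestor in \code{tree} is exactly that clade: the cross pairs between
#' its child clades. Singletons contain no pairs.
#'
#' @param tree a \code{timeTree}.
#' @param clade taxon labels or indices; must be a clade of \code{tree}.
#' @return a 2-column matrix of taxon indices (possibly 0 rows).
#' @export
pairsSplittingAt <- function(tree, clade) {
  clade <- resolveSubset(tree, clade)
  i <- match(cladeKey(clade), tree$keys)
  if (is.na(i)) stop("not a clade of the tree")
  kids <- tree$children[[i]]
  out <- matrix(integer(0), 0, 2)
  if (length(kids) < 2L) return(out)
  for (a in seq_len(length(kids) - 1L)) {
    for (b in (a + 1L):length(kids)) {
      ma <- tree$members[[kids[a]]]
      mb <- tree$members[[kids[b]]]
      out <- rbind(out, cbind(rep(ma, each = length(mb)), rep(mb, length(ma))))
    }
  }
  out
}

#' Mean divergence time of a clade against a reference tree
#'
#' The pairs of taxa splitting exactly at \code{clade} in \code{source}
#' are looked up in \code{reference}, and their MRCA ages averaged. For
#' trees of identical topology this equals the clade's age in the
#' reference; where topologies disagree the two quantities diverge. (The
#' pairs are taken from the tree being scored and the split ages from the
#' reference; this is the reading under which the heights and divergence
#' errors coincide on shared topologies.)
#'
#' @param clade taxon labels or indices, a clade of \code{source}.
#' @param source the tree supplying the splitting pairs.
#' @param reference the tree supplying the split ages.
#' @return mean split age; 0 for singletons.
#' @export
divergenceTime <- function(clade, source, reference) {
  prs <- pairsSplittingAt(source, clade)
  if (nrow(prs) == 0L) return(0)
  mean(vapply(seq_len(nrow(prs)),
              function(r) mrcaAge(reference, prs[r, ]), 0))
}

## canonical topology identifier: sorted internal clade keys
topologyKey <- function(tree) {
  k <- tree$keys[tree$size > 1L]
  paste(sort(k), collapse = ";")
}

## internal non-root clade indices
internalIdx <- function(tree, root = FALSE) {
  which(tree$size > 1L & (root | tree$size < tree$n))
}

#' Test two time trees for equality
#'
#' Trees on the same taxon set compare equal iff their clade sets match
#' and every clade age agrees within \code{tol}; a different ordering of
#' the same taxa is reconciled before comparing.
#'
#' @param t1,t2 \code{timeTree} objects.
#' @param tol absolute age tolerance.
#' @return TRUE or FALSE.
#' @export
sameTree <- function(t1, t2, tol = 1e-9) {
  if (!identical(t1$taxa, t2$taxa)) {
    if (!setequal(t1$taxa, t2$taxa)) return(FALSE)
    t2 <- remapTree(t2, t1$taxa)
  }
  o1 <- order(t1$keys); o2 <- order(t2$keys)
  if (!identical(t1$keys[o1], t2$keys[o2])) return(FALSE)
  all(abs(t1$age[o1] - t2$age[o2]) <= tol)
}

#' Convert a timeTree to an ape "phylo" object
#'
#' Polytomies (clades with more than two children) carry over as
#' multifurcations. Zero-length branches are preserved.
#'
#' @param x a \code{timeTree}.
#' @param ... unused.
#' @return an object of class \code{phylo}.
#' @export
as.phylo.timeTree <- function(x, ...) {
  ape::read.tree(text = writeNewickString(x, digits = 15))
}

#' Convert an ape "phylo" object to a timeTree
#'
#' Node ages are recovered by placing every tip at age 0 and setting each
#' internal node's age to the longest path to any descendant tip. Trees
#' whose tip depths drift by more than \code{tol} times the root height
#' are rejected as non-ultrametric.
#'
#' @param phy a rooted \code{phylo} with branch lengths.
#' @param taxa optional taxon ordering to key clades against (defaults to
#'   the tree's own tip labels, sorted).
#' @param tol relative tolerance for tip-age drift.
#' @return a \code{timeTree}.
#' @export
asTimeTree <- function(phy, taxa = NULL, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (is.null(taxa)) taxa <- sort(phy$tip.label)
  tipIdx <- match(phy$tip.label, taxa)
  if (anyNA(tipIdx)) stop("tip labels not covered by taxon set")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  ## depth from root for every node
  depth <- numeric(ntip + nnode)
  eo <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(eo$edge))) {
    depth[eo$edge[e, 2L]] <- depth[eo$edge[e, 1L]] + eo$edge.length[e]
  }
  tipDepth <- depth[seq_len(ntip)]
  span <- max(tipDepth) - min(tipDepth)
  if (span > tol * max(tipDepth))
    stop(sprintf("non-ultrametric tree: tip depth spread %g exceeds tolerance", span))
  ## age = longest path to a descendant tip, built tip-to-root
  age <- numeric(ntip + nnode)
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    age[par] <- max(age[par], age[ch] + po$edge.length[e])
  }
  ## clade membership per internal node
  memb <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) memb[[i]] <- tipIdx[i]
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    memb[[par]] <- c(memb[[par]], memb[[ch]])
  }
  ints <- (ntip + 1L):(ntip + nnode)
  timeTree(taxa, memb[ints], age[ints])
}
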