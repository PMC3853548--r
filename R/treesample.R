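#' Construct a tree sample
#'
#' An ordered collection of time trees on one shared taxon set, typically
#' a posterior sample from a Bayesian phylogenetic analysis. All trees are
#' re-keyed against the first tree's taxon ordering so clade keys are
#' comparable across the whole sample.
#'
#' @param trees non-empty list of \code{timeTree} objects.
#' @return an object of class \code{treeSample}.
#' @export
treeSample <- function(trees) {
  if (length(trees) == 0L) stop("empty tree sample")
  taxa <- trees[[1L]]$taxa
  trees <- lapply(trees, function(t) {
    if (!inherits(t, "timeTree")) stop("not a timeTree")
    if (identical(t$taxa, taxa)) return(t)
    if (!setequal(t$taxa, taxa))
      stop("trees do not share a common taxon set")
    remapTree(t, taxa)
  })
  structure(list(taxa = taxa, trees = trees), class = "treeSample")
}

## re-express a tree's clades in a different taxon ordering
remapTree <- function(tree, taxa) {
  map <- match(tree$taxa, taxa)
  idx <- which(tree$size > 1L)
  timeTree(taxa, lapply(tree$members[idx], function(m) map[m]),
           tree$age[idx], validate = FALSE)
}

#' @export
print.treeSample <- function(x, ...) {
  cat(sprintf("treeSample: %d trees on %d taxa\n",
              length(x$trees), length(x$taxa)))
  invisible(x)
}

#' @export
length.treeSample <- function(x) length(x$trees)

#' Extract trees from a sample
#' @param x a \code{treeSample}.
#' @param i tree index or indices.
#' @return a \code{timeTree} (for \code{[[}) or a \code{treeSample}.
#' @rdname treeSample-extract
#' @export
`[[.treeSample` <- function(x, i) x$trees[[i]]

#' @rdname treeSample-extract
#' @export
`[.treeSample` <- function(x, i) {
  structure(list(taxa = x$taxa, trees = x$trees[i]), class = "treeSample")
}

#' Root ages of every tree in a sample
#' @param sample a \code{treeSample}.
#' @return numeric vector of root ages.
#' @export
rootAges <- function(sample) {
  vapply(sample$trees, rootAge, 0)
}
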