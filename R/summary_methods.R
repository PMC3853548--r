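## One front door for every summary-tree method, addressed by the method
## ids used throughout the package: a height rule, optionally combined
## with a topology selector.

topoSelectors <- c(mcc = "selectMCC", tcb = "selectTCB",
                   ccd = "selectCCD", hpf = "selectHPF")

#' List the available summary-method identifiers
#'
#' Method ids combine a height rule with a topology selector:
#' \itemize{
#'   \item \code{cat-<sel>}, \code{med-<sel>}, \code{avg-<sel>}: common
#'     ancestor / median / mean heights on the topology chosen by
#'     \code{<sel>} in mcc, tcb, ccd, hpf.
#'   \item \code{rbs-<sel>}, \code{srbs-<sel>}, \code{ras-<sel>},
#'     \code{hs-<sel>}, \code{hso-<sel>}: minimum-distance branch
#'     assignment under the named metric on a selected topology (hso =
#'     matched-heights-only objective).
#'   \item \code{mrbs}, \code{msrbs}, \code{mras}, \code{mhs}:
#'     minimum-distance trees searched over all sampled topologies.
#'   \item \code{tp-median}, \code{tp-mean}: taxa-partition trees.
#'   \item \code{cons-median}, \code{cons-mean}: majority-rule consensus
#'     with CAT-style heights.
#'   \item \code{ccd}, \code{hpf}: shorthand for \code{cat-ccd} /
#'     \code{cat-hpf}.
#' }
#'
#' @return character vector of method ids.
#' @export
summaryMethods <- function() {
  sels <- names(topoSelectors)
  c(paste0(rep(c("cat", "med", "avg", "rbs", "srbs", "ras", "hs", "hso"),
               each = length(sels)), "-", sels),
    "mrbs", "msrbs", "mras", "mhs",
    "tp-median", "tp-mean", "cons-median", "cons-mean", "ccd", "hpf")
}

#' Build a summary tree by method id
#'
#' @param sample a \code{treeSample}.
#' @param method a method id (see \code{\link{summaryMethods}}).
#' @param opts optimizer options for the minimum-distance methods.
#' @param repair how to handle negative branches from the pointwise
#'   (med/avg) height rules: "clamp" (default; clamps child ages to the
#'   parent and warns) or "none" (error).
#' @return a \code{timeTree}; if the underlying height assignment had
#'   negative branches, attribute \code{"negative_branches"} lists them.
#' @export
summaryTree <- function(sample, method, opts = list(),
                        repair = c("clamp", "none")) {
  repair <- match.arg(repair)
  method <- tolower(method)
  if (method == "ccd") method <- "cat-ccd"
  if (method == "hpf") method <- "cat-hpf"
  if (method %in% c("mrbs", "msrbs", "mras", "mhs")) {
    metric <- substring(method, 2L)
    return(minDistanceTree(sample, metric, "all", opts))
  }
  if (method %in% c("tp-median", "tp-mean"))
    return(taxaPartitionTree(sample, sub("tp-", "", method)))
  if (method %in% c("cons-median", "cons-mean"))
    return(consensusTree(sample, stat = sub("cons-", "", method)))
  parts <- strsplit(method, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !(parts[2L] %in% names(topoSelectors)))
    stop("unknown method: ", method,
         " (see summaryMethods() for valid ids)")
  selector <- get(topoSelectors[[parts[2L]]])
  topo <- sample$trees[[selector(sample)]]
  rule <- parts[1L]
  if (rule == "cat") {
    ha <- catHeights(topo, sample)
    return(assignmentTree(ha))
  }
  if (rule %in% c("med", "avg")) {
    ha <- pointwiseHeights(topo, sample,
                           if (rule == "med") "median" else "mean")
    if (!ha$valid) {
      if (repair == "none")
        stop("pointwise heights produced negative branches")
      warning(sprintf("%d negative branch(es) clamped to zero length",
                      length(ha$negative_branches)))
    }
    out <- assignmentTree(ha, repair = "clamp")
    if (!ha$valid) attr(out, "negative_branches") <- ha$negative_branches
    return(out)
  }
  if (rule %in% c("rbs", "srbs", "ras", "hs", "hso")) {
    metric <- if (rule == "hso") "hs_matched" else rule
    return(minDistanceTree(sample, metric, topo, opts))
  }
  stop("unknown method: ", method)
}

#' Posterior annotations for a summary tree
#'
#' For every clade of the tree: its posterior frequency in the sample
#' and the HPD interval plus point estimate of its MRCA age.
#'
#' @param tree a \code{timeTree}.
#' @param sample a \code{treeSample}.
#' @param level HPD coverage level.
#' @return named list (clade key -> annotation list) suitable for
#'   \code{\link{writeTrees}}.
#' @export
summaryAnnotations <- function(tree, sample, level = 0.95) {
  freqs <- cladeFrequencies(sample)
  idx <- which(tree$size > 1L)
  anns <- lapply(idx, function(i) {
    f <- freqs$lookup[tree$keys[i]]
    ages <- vapply(sample$trees, mrcaAge, 0, subset = tree$members[[i]])
    list(posterior = if (is.na(f)) 0 else f,
         height_interval = heightHPD(ages, level),
         height_point = tree$age[i])
  })
  names(anns) <- tree$keys[idx]
  anns
}
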