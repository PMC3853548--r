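## Reading and writing tree sets.
##
## Parsing of standard formats (plain Newick, NEXUS trees block with
## translate table, BEAST dialect) is delegated to ape after stripping
## BEAST-style [&...] comment blocks, which ape's parsers do not accept.
## The annotated writer emits the BEAST node-comment dialect directly.

stripNexusComments <- function(txt) {
  ## remove [&...] metadata blocks (BEAST annotations); non-greedy, no
  ## nesting occurs in practice
  gsub("\\[&[^]]*\\]", "", txt)
}

#' Read a set of time trees
#'
#' Accepts plain Newick (one or more trees, one per statement) or a NEXUS
#' trees block with an optional translate table (BEAST output included;
#' node annotations are ignored). Branch lengths are converted to clade
#' ages by placing every tip at age 0; trees whose tip depths drift by
#' more than \code{tol} times the root height are rejected as
#' non-ultrametric.
#'
#' @param path file path.
#' @param format "auto" (sniff for a #NEXUS header), "nexus" or "newick".
#' @param burnin fraction (in [0,1)) or count (>= 1) of leading trees to
#'   discard.
#' @param tol relative tolerance for tip-age drift.
#' @return a \code{treeSample}.
#' @export
readTrees <- function(path, format = c("auto", "nexus", "newick"),
                      burnin = 0, tol = 1e-6) {
  format <- match.arg(format)
  txt <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^\\s*#NEXUS", txt[1L], ignore.case = TRUE)))
      "nexus" else "newick"
  }
  txt <- stripNexusComments(txt)
  tf <- tempfile(fileext = if (format == "nexus") ".nex" else ".nwk")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  phys <- if (format == "nexus") ape::read.nexus(tf) else ape::read.tree(tf)
  if (is.null(phys)) stop("no trees could be parsed from ", path)
  if (inherits(phys, "phylo")) phys <- list(phys)
  tl <- attr(phys, "TipLabel")  # multiPhylo with a shared translate table
  phys <- unclass(phys)
  if (!is.null(tl))
    phys <- lapply(phys, function(p) { p$tip.label <- tl; p })
  k <- length(phys)
  if (burnin < 0 || (burnin >= 1 && burnin >= k) ||
      (burnin < 1 && burnin > 0 && burnin * k >= k))
    stop("invalid burn-in")
  drop <- if (burnin >= 1) as.integer(burnin) else floor(burnin * k)
  if (drop > 0L) phys <- phys[-seq_len(drop)]
  taxa <- sort(phys[[1L]]$tip.label)
  treeSample(lapply(phys, asTimeTree, taxa = taxa, tol = tol))
}

fmtAge <- function(x, digits = 12) {
  trimws(formatC(x, digits = digits, format = "g"))
}

## Newick string for a timeTree, with optional per-clade annotation
## strings (named by clade key) inserted as [&...] node comments.
writeNewickString <- function(tree, annotations = NULL, digits = 12) {
  rec <- function(i) {
    key <- tree$keys[i]
    ann <- if (!is.null(annotations) && !is.na(annotations[key]))
      annotations[[key]] else ""
    p <- tree$parent[i]
    blen <- if (is.na(p)) NULL else tree$age[p] - tree$age[i]
    core <- if (tree$size[i] == 1L) {
      tree$taxa[tree$members[[i]]]
    } else {
      kids <- tree$children[[i]]
      ## order children by smallest member index for a stable layout
      kids <- kids[order(vapply(kids, function(k) tree$members[[k]][1L], 0L))]
      paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")")
    }
    paste0(core, ann,
           if (is.null(blen)) "" else paste0(":", fmtAge(blen, digits)))
  }
  paste0(rec(tree$root), ";")
}

annotationString <- function(ann) {
  parts <- character(0)
  if (!is.null(ann$posterior))
    parts <- c(parts, paste0("posterior=", fmtAge(ann$posterior)))
  if (!is.null(ann$height_interval))
    parts <- c(parts, sprintf("height_95%%_HPD={%s,%s}",
                              fmtAge(ann$height_interval[1L]),
                              fmtAge(ann$height_interval[2L])))
  if (!is.null(ann$height_point))
    parts <- c(parts, paste0("height=", fmtAge(ann$height_point)))
  if (length(parts) == 0L) return("")
  paste0("[&", paste(parts, collapse = ","), "]")
}

#' Write trees to Newick or NEXUS
#'
#' Branch lengths are parent age minus clade age, written with 12
#' significant digits so that read/write round-trips preserve ages to
#' well below 1e-9. Optional per-clade annotations (posterior support,
#' height HPD intervals, height point estimates) are written as
#' BEAST-style \code{[&...]} node comments.
#'
#' @param trees a \code{timeTree} or \code{treeSample}.
#' @param path output file.
#' @param format "newick" (one tree per line) or "nexus" (trees block with
#'   translate table).
#' @param annotations optional named list: clade key -> list with any of
#'   \code{posterior}, \code{height_interval} (length-2), \code{height_point}.
#'   Applied to a single tree only.
#' @param digits significant digits for ages.
#' @return \code{path}, invisibly.
#' @export
writeTrees <- function(trees, path, format = c("newick", "nexus"),
                       annotations = NULL, digits = 12) {
  format <- match.arg(format)
  if (inherits(trees, "timeTree")) trees <- treeSample(list(trees))
  annStrings <- NULL
  if (!is.null(annotations)) {
    if (length(trees$trees) != 1L)
      stop("annotations are supported for a single tree only")
    bad <- setdiff(names(annotations), trees$trees[[1L]]$keys)
    if (length(bad)) stop("annotation for unknown clade: ", bad[1L])
    annStrings <- vapply(annotations, annotationString, "")
  }
  lines <- vapply(trees$trees, writeNewickString,
                  "", annotations = annStrings, digits = digits)
  if (format == "nexus") {
    taxa <- trees$taxa
    trans <- paste0("\t\t", seq_along(taxa), " ", taxa,
                    c(rep(",", length(taxa) - 1L), ";"))
    ## relabel tips by translate indices
    numbered <- lines
    for (i in order(nchar(taxa), decreasing = TRUE)) {
      numbered <- gsub(paste0("([(,])", taxa[i], "(?=[:,)\\[])"),
                       paste0("\\1", i), numbered, perl = TRUE)
    }
    lines <- c("#NEXUS", "Begin trees;", "\tTranslate", trans,
               paste0("tree STATE_", seq_along(numbered) - 1L,
                      " = ", numbered),
               "End;")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Shortest (highest-density) interval of a set of age samples
#'
#' The shortest contiguous window of the sorted samples containing at
#' least \code{ceiling(level * k)} of the k samples; ties are broken by
#' the lowest starting point.
#'
#' @param samples non-empty numeric vector.
#' @param level coverage fraction in (0,1).
#' @return numeric length-2 vector (low, high).
#' @export
heightHPD <- function(samples, level = 0.95) {
  k <- length(samples)
  if (k == 0L) stop("no samples")
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  s <- sort(samples)
  need <- ceiling(level * k)
  if (need >= k) return(c(s[1L], s[k]))
  starts <- seq_len(k - need + 1L)
  widths <- s[starts + need - 1L] - s[starts]
  i <- which.min(widths)  # which.min takes the first (lowest start) on ties
  c(s[i], s[i + need - 1L])
}
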