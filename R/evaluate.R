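## Model-fit likelihoods, per-case error reports and the ranking
## protocol used to compare summary-tree methods across many test cases.

#' Jukes-Cantor log-likelihood of an alignment on a time tree
#'
#' Felsenstein pruning with the JC transition probability
#' p_same(d) = 1/4 + 3/4 exp(-4 d / 3), where d is the branch duration
#' times the mutation rate, uniform root frequencies and independent
#' sites. Site patterns are compressed before the traversal.
#'
#' @param tree a \code{timeTree}.
#' @param aln character matrix (taxa x sites) over A/C/G/T.
#' @param rate mutation rate (substitutions per site per time unit).
#' @return total log-likelihood.
#' @export
jcLogLik <- function(tree, aln, rate = 0.005) {
  if (is.null(rownames(aln)) || !setequal(rownames(aln), tree$taxa))
    stop("alignment taxa do not match the tree")
  if (ncol(aln) == 0L) stop("empty alignment")
  aln <- aln[tree$taxa, , drop = FALSE]
  code <- matrix(match(aln, c("A", "C", "G", "T")), nrow(aln), ncol(aln))
  if (anyNA(code)) stop("non-ACGT character in alignment")
  ## compress site patterns
  pat <- apply(code, 2L, paste, collapse = ",")
  upat <- unique(pat)
  w <- as.numeric(table(factor(pat, levels = upat)))
  cols <- match(upat, pat)
  code <- code[, cols, drop = FALSE]
  np <- length(upat)

  ## partials: per node, 4 x np matrix; log-scaled per node
  partial <- function(i) {
    if (tree$size[i] == 1L) {
      tip <- tree$members[[i]]
      m <- matrix(0, 4L, np)
      m[cbind(code[tip, ], seq_len(np))] <- 1
      return(list(m = m, logscale = 0))
    }
    m <- matrix(1, 4L, np)
    logscale <- 0
    for (ch in tree$children[[i]]) {
      sub <- partial(ch)
      d <- (tree$age[i] - tree$age[ch]) * rate
      psame <- 0.25 + 0.75 * exp(-4 * d / 3)
      pdiff <- (1 - psame) / 3
      ## transition: P %*% sub$m with P = pdiff + (psame-pdiff) I
      trans <- pdiff * matrix(colSums(sub$m), 4L, np, byrow = TRUE) +
        (psame - pdiff) * sub$m
      m <- m * trans
      logscale <- logscale + sub$logscale
    }
    mx <- max(m)
    if (mx > 0 && mx < 1e-100) { m <- m / mx; logscale <- logscale + log(mx) }
    list(m = m, logscale = logscale)
  }
  rootP <- partial(tree$root)
  siteL <- colSums(rootP$m) * 0.25
  sum(w * (log(siteL) + rootP$logscale))
}

#' Log-density of a time tree under the constant-size coalescent
#'
#' Sum over inter-event intervals of -k(k-1)/2 * dt / Ne, minus log(Ne)
#' per coalescent event. Multifurcations are treated as simultaneous
#' binary coalescences (each merge of c children contributes c-1
#' events).
#'
#' @param tree a \code{timeTree} with contemporaneous tips.
#' @param Ne population size (> 0).
#' @return log-density.
#' @export
coalescentLogLik <- function(tree, Ne = 1) {
  if (Ne <= 0) stop("Ne must be positive")
  idx <- which(tree$size > 1L)
  ev <- data.frame(age = tree$age[idx],
                   merges = lengths(tree$children[idx]) - 1L)
  ev <- ev[order(ev$age), , drop = FALSE]
  k <- tree$n
  tPrev <- 0
  ll <- 0
  for (r in seq_len(nrow(ev))) {
    dt <- ev$age[r] - tPrev
    ll <- ll - k * (k - 1) / 2 * dt / Ne
    for (m in seq_len(ev$merges[r])) {
      ll <- ll - log(Ne)
      k <- k - 1L
    }
    tPrev <- ev$age[r]
  }
  ll
}

#' Model-fit percentile of a summary tree within its sample
#'
#' The fraction of sampled trees whose combined (tree + coalescent)
#' log-likelihood is less than or equal to the summary tree's.
#'
#' @param summary a \code{timeTree}.
#' @param sample a \code{treeSample}.
#' @param aln alignment (taxa x sites character matrix).
#' @param rate mutation rate.
#' @param Ne coalescent population size.
#' @return fraction in [0, 1].
#' @export
modelFitPercentile <- function(summary, sample, aln, rate = 0.005, Ne = 1) {
  fit <- function(t) jcLogLik(t, aln, rate) + coalescentLogLik(t, Ne)
  fs <- fit(summary)
  mean(vapply(sample$trees, fit, 0) <= fs)
}

#' Full error report of a summary tree against the truth
#'
#' Combines the four tree-error measures, the root-height error and the
#' two model-fit likelihoods (their sum is the overall model fit).
#'
#' @param summary a \code{timeTree}.
#' @param truth the true \code{timeTree}.
#' @param aln alignment used to score the tree likelihood (NULL to skip
#'   the likelihood fields).
#' @param rate mutation rate.
#' @param Ne coalescent population size.
#' @return named list (an error vector).
#' @export
errorReport <- function(summary, truth, aln = NULL, rate = 0.005, Ne = 1) {
  out <- list(root_height_error = rootHeightError(summary, truth),
              heights_error = heightsError(summary, truth),
              divergence_error = divergenceError(summary, truth),
              clades_missed = cladesMissed(summary, truth),
              clades_called = cladesCalled(summary, truth))
  if (!is.null(aln)) {
    out$tree_loglik <- jcLogLik(summary, aln, rate)
    out$coalescent_loglik <- coalescentLogLik(summary, Ne)
    out$model_fit <- out$tree_loglik + out$coalescent_loglik
  }
  out
}

#' Dense ranks (the 1-2-2-3 rule)
#'
#' Equal values share a rank; the next distinct value gets the next
#' integer. Lower values rank first.
#'
#' @param values numeric vector.
#' @return integer ranks starting at 1.
#' @export
denseRank <- function(values) {
  match(values, sort(unique(values)))
}

#' Normalize an error matrix per case
#'
#' Each row (one test case across methods) is shifted and scaled to mean
#' 0 and variance 1, using the population (1/N) standard deviation; rows
#' with no variation map to all zeros.
#'
#' @param mat numeric matrix, cases x methods.
#' @return matrix of the same shape.
#' @export
normalizeErrors <- function(mat) {
  t(apply(mat, 1L, function(row) {
    s <- sqrt(mean((row - mean(row))^2))
    if (s == 0) rep(0, length(row)) else (row - mean(row)) / s
  }))
}

#' Bootstrap dominance scores for a set of methods
#'
#' Per bootstrap replicate, test cases are resampled with replacement
#' and each method's mean per-case dense rank (or mean normalized error)
#' recomputed. Method A dominates B iff A's mean beats B's (strictly
#' smaller) in at least \code{threshold} of the replicates. The final
#' score is 0 for an undominated method, otherwise 1 + the maximum score
#' among its dominators. Cyclic domination is impossible for thresholds
#' above 0.5; it is asserted and an error raised if floating ties ever
#' break the assumption.
#'
#' @param mat error matrix, cases x methods (lower = better; negate
#'   likelihood-type columns before calling).
#' @param reps number of bootstrap replicates.
#' @param threshold dominance fraction in (0.5, 1].
#' @param statistic "rank" (dense ranks per case) or "normalized".
#' @return integer scores, one per method (named from columns).
#' @export
bootstrapScores <- function(mat, reps = 4000L, threshold = 0.9,
                            statistic = c("rank", "normalized")) {
  statistic <- match.arg(statistic)
  if (reps < 1L) stop("reps must be >= 1")
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  nc <- nrow(mat); nm <- ncol(mat)
  if (nm < 2L) stop("need at least two methods")
  base <- if (statistic == "rank") {
    t(apply(mat, 1L, denseRank))
  } else normalizeErrors(mat)
  wins <- matrix(0L, nm, nm)
  for (r in seq_len(reps)) {
    rows <- sample.int(nc, nc, replace = TRUE)
    means <- colMeans(base[rows, , drop = FALSE])
    wins <- wins + outer(means, means, "<")
  }
  dominates <- wins >= threshold * reps
  diag(dominates) <- FALSE
  if (any(dominates & t(dominates)))
    stop("cyclic domination detected; threshold assumption violated")
  score <- rep(NA_integer_, nm)
  repeat {
    progressed <- FALSE
    for (j in seq_len(nm)) {
      if (!is.na(score[j])) next
      dom <- which(dominates[, j])
      if (length(dom) == 0L) { score[j] <- 0L; progressed <- TRUE }
      else if (all(!is.na(score[dom]))) {
        score[j] <- 1L + max(score[dom]); progressed <- TRUE
      }
    }
    if (all(!is.na(score))) break
    if (!progressed) stop("cyclic domination detected")
  }
  names(score) <- colnames(mat)
  score
}

#' Rank a set of methods over a matrix of per-case errors
#'
#' For each error measure, computes mean dense ranks and mean normalized
#' errors across cases, and the two bootstrap dominance scores
#' (comparison-based and magnitude-based).
#'
#' @param errors named list of cases x methods matrices, one per error
#'   measure (lower = better in every matrix).
#' @param reps bootstrap replicates.
#' @param threshold dominance threshold.
#' @return object of class \code{rankTable}: per measure, a data.frame
#'   with method, mean_rank, mean_normalized, comparison_score,
#'   magnitude_score.
#' @export
rankMethods <- function(errors, reps = 4000L, threshold = 0.9) {
  tabs <- lapply(names(errors), function(measure) {
    mat <- errors[[measure]]
    ranks <- t(apply(mat, 1L, denseRank))
    norm <- normalizeErrors(mat)
    data.frame(method = colnames(mat),
               mean_rank = colMeans(ranks),
               mean_normalized = colMeans(norm),
               comparison_score = bootstrapScores(mat, reps, threshold,
                                                  "rank"),
               magnitude_score = bootstrapScores(mat, reps, threshold,
                                                 "normalized"),
               row.names = NULL)
  })
  names(tabs) <- names(errors)
  structure(tabs, class = "rankTable")
}

#' @export
print.rankTable <- function(x, ...) {
  for (m in names(x)) {
    cat("==", m, "==\n")
    print.data.frame(x[[m]], digits = 4)
  }
  invisible(x)
}

#' Write a rank table to TSV files
#' @param rt a \code{rankTable}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeRankTable <- function(rt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(rt)) {
    write.table(rt[[m]], file.path(dir, paste0("rank_", m, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
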