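## User-facing drivers: summarize one tree file, or run a scaled
## simulation experiment comparing methods. These back the command-line
## script in inst/scripts/treesum.R.

#' Summarize a posterior tree file
#'
#' Reads a tree set, removes burn-in, builds the requested summary tree
#' and writes it with posterior supports and height HPD annotations.
#'
#' @param input tree file (Newick or NEXUS).
#' @param output output file for the annotated summary tree.
#' @param method a method id (see \code{\link{summaryMethods}}).
#' @param burnin fraction or count of leading trees to discard.
#' @param seed RNG seed (the minimum-distance methods use random
#'   restarts).
#' @param format output format, "nexus" or "newick".
#' @param opts optimizer options.
#' @return the summary \code{timeTree}, invisibly.
#' @export
runSummarize <- function(input, output, method = "cat-mcc", burnin = 0.1,
                         seed = 42L, format = c("nexus", "newick"),
                         opts = list()) {
  format <- match.arg(format)
  set.seed(seed)
  sample <- readTrees(input, burnin = burnin)
  message(sprintf("read %d trees on %d taxa (burn-in %s); method %s, seed %d",
                  length(sample$trees), length(sample$taxa),
                  format(burnin), method, seed))
  tree <- summaryTree(sample, method, opts = opts)
  neg <- attr(tree, "negative_branches")
  if (!is.null(neg))
    message(sprintf("warning: %d negative branch(es) were clamped", length(neg)))
  cl <- attr(tree, "clamped")
  if (!is.null(cl) && cl > 0L)
    message(sprintf("warning: %d split age(s) clamped during reconstruction", cl))
  writeTrees(tree, output, format = format,
             annotations = summaryAnnotations(tree, sample))
  invisible(tree)
}

#' Run a simulation experiment comparing summary methods
#'
#' For each replicate: draw a Kingman coalescent tree, generate a
#' Jukes-Cantor alignment, build a pseudo-posterior around the true
#' tree, run every requested method and score it against the truth.
#' Emits per-case error tables and bootstrap rank tables.
#'
#' @param n_tips,Ne vectors defining the simulation grid.
#' @param cases replicates per grid cell.
#' @param posterior_size trees per pseudo-posterior.
#' @param methods method ids to compare.
#' @param seq_length,rate alignment length and mutation rate.
#' @param topo_moves_mean,height_cv pseudo-posterior noise parameters.
#' @param seed RNG seed; the whole run is reproducible from it.
#' @param out optional output directory for TSV tables and a JSON
#'   manifest.
#' @param reps,threshold bootstrap ranking parameters.
#' @param likelihoods include the model-fit measures (slower).
#' @return list with \code{errors} (long data.frame), \code{ranks} (a
#'   \code{rankTable}) and \code{config}.
#' @export
runExperiment <- function(n_tips = 8, Ne = 1, cases = 5,
                          posterior_size = 50,
                          methods = c("cat-mcc", "med-mcc", "tp-median",
                                      "cons-median", "mrbs"),
                          seq_length = 800, rate = 0.005,
                          topo_moves_mean = 1, height_cv = 0.1,
                          seed = 1L, out = NULL,
                          reps = 1000L, threshold = 0.9,
                          likelihoods = TRUE) {
  if (cases < 1L) stop("need at least one test case")
  bad <- setdiff(methods, summaryMethods())
  if (length(bad)) stop("unknown method id(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  grid <- expand.grid(n = n_tips, Ne = Ne)
  rows <- list()
  caseId <- 0L
  for (g in seq_len(nrow(grid))) {
    for (rep_ in seq_len(cases)) {
      caseId <- caseId + 1L
      ## coalescent time units; heights in substitution units are
      ## age * rate
      truth <- rCoalescentTree(grid$n[g], grid$Ne[g])
      aln <- if (likelihoods) simulateJC(truth, seq_length, rate) else NULL
      post <- pseudoPosterior(truth, posterior_size,
                              topo_moves_mean, height_cv)
      for (m in methods) {
        stree <- suppressWarnings(summaryTree(post, m))
        ev <- errorReport(stree, truth, aln, rate, grid$Ne[g])
        rows[[length(rows) + 1L]] <-
          c(list(case = caseId, n = grid$n[g], Ne = grid$Ne[g], method = m),
            ev)
      }
    }
  }
  errors <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  measures <- c("root_height_error", "heights_error", "divergence_error",
                "clades_missed", "clades_called")
  if (likelihoods)
    measures <- c(measures, "tree_loglik", "coalescent_loglik", "model_fit")
  mats <- lapply(measures, function(ms) {
    m <- matrix(errors[[ms]], ncol = length(methods), byrow = TRUE,
                dimnames = list(NULL, methods))
    ## likelihoods: larger is better, negate before ranking
    if (ms %in% c("tree_loglik", "coalescent_loglik", "model_fit")) -m else m
  })
  names(mats) <- measures
  ranks <- rankMethods(mats, reps = reps, threshold = threshold)

  config <- list(n_tips = n_tips, Ne = Ne, cases = cases,
                 posterior_size = posterior_size, methods = methods,
                 seq_length = seq_length, rate = rate,
                 topo_moves_mean = topo_moves_mean, height_cv = height_cv,
                 seed = seed, reps = reps, threshold = threshold)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    writeErrorTable(errors, file.path(out, "errors.tsv"))
    writeRankTable(ranks, out)
    jsonlite::write_json(config, file.path(out, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(errors = errors, ranks = ranks, config = config)
}
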