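## Test-case generation: Kingman coalescent genealogies, Jukes-Cantor
## sequence evolution, and a pseudo-posterior generator that emulates the
## spread of an MCMC sample around a reference tree (topology jitter via
## NNI moves plus height noise in the ratio parametrization).
##
## All randomness flows from R's global RNG; callers seed with set.seed.

#' Simulate a Kingman coalescent tree
#'
#' While k lineages remain, a waiting time is drawn from an exponential
#' with rate k(k-1)/(2 Ne) and a uniformly random pair of lineages is
#' merged. Ages are in population-size time units; multiply by a
#' mutation rate to express heights in expected substitutions per site.
#'
#' @param n number of tips (>= 2).
#' @param Ne constant (effective) population size.
#' @param labels optional tip labels, default t1..tn.
#' @return an ultrametric \code{timeTree}.
#' @export
rCoalescentTree <- function(n, Ne = 1, labels = NULL) {
  if (n < 2L) stop("need at least two tips")
  if (Ne <= 0) stop("Ne must be positive")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  lineages <- as.list(seq_len(n))
  time <- 0
  clades <- vector("list", n - 1L)
  ages <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(lineages)
    time <- time + rexp(1L, rate = k * (k - 1) / (2 * Ne))
    pair <- sample.int(k, 2L)
    merged <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
    lineages[[pair[1L]]] <- merged
    lineages[[pair[2L]]] <- NULL
    clades[[step]] <- merged
    ages[step] <- time
  }
  timeTree(labels, clades, ages, validate = FALSE)
}

jcMutate <- function(seq, duration, rate) {
  p <- 0.75 * (1 - exp(-4 * duration * rate / 3))
  hit <- runif(length(seq)) < p
  if (any(hit)) {
    ## uniform over the three other states
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    seq[hit] <- (seq[hit] + shift) %% 4L
  }
  seq
}

#' Simulate a Jukes-Cantor alignment on a time tree
#'
#' The root sequence is uniform over {A,C,G,T}; along each branch of
#' duration t, each site changes with probability
#' 3/4 (1 - exp(-4 t mu / 3)) to a uniformly chosen different state.
#'
#' @param tree a \code{timeTree}.
#' @param length alignment length in sites.
#' @param rate mutation rate in substitutions per site per time unit.
#' @return a character matrix (taxa x sites) with rownames = taxon
#'   labels, entries in A/C/G/T.
#' @export
simulateJC <- function(tree, length = 800L, rate = 0.005) {
  if (length < 1L || rate < 0) stop("invalid length or rate")
  bases <- c("A", "C", "G", "T")
  n <- tree$n
  seqs <- matrix(NA_integer_, n, length)
  rootSeq <- sample.int(4L, length, replace = TRUE) - 1L
  ## walk the clade hierarchy from the root, evolving along branches
  rec <- function(i, seqIn) {
    if (tree$size[i] == 1L) {
      seqs[tree$members[[i]], ] <<- seqIn
      return(invisible())
    }
    for (ch in tree$children[[i]]) {
      dur <- tree$age[i] - tree$age[ch]
      rec(ch, jcMutate(seqIn, dur, rate))
    }
  }
  rec(tree$root, rootSeq)
  out <- matrix(bases[seqs + 1L], n, length)
  rownames(out) <- tree$taxa
  out
}

#' Write an alignment to FASTA
#' @param aln character matrix from \code{simulateJC}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  dna <- ape::as.DNAbin(aln)
  ape::write.dna(dna, path, format = "fasta", colsep = "")
  invisible(path)
}

#' Read a FASTA alignment
#' @param path FASTA file.
#' @return character matrix (taxa x sites), uppercase.
#' @export
readAlignment <- function(path) {
  dna <- ape::read.FASTA(path)
  toupper(as.character(as.matrix(dna)))
}

## ---- pseudo-posterior -------------------------------------------------

## one age-preserving NNI move on the clade hierarchy; returns the new
## tree or NULL if the drawn move is invalid
tryNNI <- function(tree) {
  ## eligible edges: internal non-root clade C with internal parent P
  eligible <- which(tree$size > 1L & tree$size < tree$n &
                    !is.na(tree$parent))
  eligible <- eligible[vapply(eligible, function(i)
    length(tree$children[[i]]) == 2L &&
      length(tree$children[[tree$parent[i]]]) == 2L, TRUE)]
  if (length(eligible) == 0L) return(NULL)
  C <- eligible[sample.int(length(eligible), 1L)]
  P <- tree$parent[C]
  sibs <- setdiff(tree$children[[P]], C)
  S <- sibs[1L]
  X <- tree$children[[C]][sample.int(2L, 1L)]
  ## swap S and X: S becomes a child of C, X a child of P.
  ## ages are preserved; the move is valid iff age(S) <= age(C).
  if (tree$age[S] > tree$age[C]) return(NULL)
  ## rebuild clade member lists: C's members become (C \ X) + S
  newMembers <- tree$members
  newMembers[[C]] <- sort(c(setdiff(tree$members[[C]], tree$members[[X]]),
                            tree$members[[S]]))
  ## ancestors of C below P keep their members (only C changes: X and S
  ## swap places directly under P and C)
  idx <- which(tree$size > 1L)
  timeTree(tree$taxa, newMembers[idx], tree$age[idx], validate = FALSE)
}

logit <- function(p) log(p / (1 - p))
invLogit <- function(x) 1 / (1 + exp(-x))

#' Generate a pseudo-posterior sample around a reference tree
#'
#' Emulates the spread of a Bayesian posterior without running MCMC: each
#' replicate is a copy of \code{true_tree} with (a) a Poisson-distributed
#' number of age-preserving NNI moves applied to random internal edges
#' and (b) height noise applied in the ratio parametrization — the root
#' height is multiplied by a lognormal factor (meanlog 0, sdlog =
#' \code{height_cv}) and each clade ratio is perturbed on the logit scale
#' with the same spread — so every replicate is a valid time tree. With
#' both parameters 0 the replicates are exact copies.
#'
#' @param true_tree the reference \code{timeTree}.
#' @param size number of replicates.
#' @param topo_moves_mean mean number of NNI moves per replicate.
#' @param height_cv spread of the height noise (0 = none).
#' @return a \code{treeSample}.
#' @export
pseudoPosterior <- function(true_tree, size, topo_moves_mean = 1,
                            height_cv = 0.1) {
  if (size < 1L) stop("size must be >= 1")
  trees <- vector("list", size)
  for (r in seq_len(size)) {
    t <- true_tree
    nmoves <- rpois(1L, topo_moves_mean)
    tries <- 0L
    while (nmoves > 0L && tries < 20L * (nmoves + 1L)) {
      cand <- tryNNI(t)
      tries <- tries + 1L
      if (!is.null(cand)) {
        t <- cand
        nmoves <- nmoves - 1L
      }
    }
    if (height_cv > 0) {
      pv <- encodeTree(t)
      pv$root_height <- pv$root_height * rlnorm(1L, 0, height_cv)
      if (length(pv$ratios)) {
        a <- pv$ratios
        interior <- a > 0 & a < 1
        a[interior] <- invLogit(logit(a[interior]) +
                                rnorm(sum(interior), 0, height_cv))
        pv$ratios <- a
      }
      t <- decodeTree(pv)
    }
    trees[[r]] <- t
  }
  treeSample(trees)
}
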