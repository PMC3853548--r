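# Shared fixtures and independent oracles.

# three-taxon fixtures used throughout: TA = ((a,b),c), TB same topology
# with different ages, TC = (a,(b,c))
fixTA <- function() timeTree(c("a", "b", "c"),
                             list(c("a", "b"), c("a", "b", "c")), c(1, 2))
fixTB <- function() timeTree(c("a", "b", "c"),
                             list(c("a", "b"), c("a", "b", "c")), c(0.5, 3))
fixTC <- function() timeTree(c("a", "b", "c"),
                             list(c("b", "c"), c("a", "b", "c")), c(1, 2))

randTree <- function(n = 6, Ne = 1) rCoalescentTree(n, Ne)

randSample <- function(k = 10, n = 6, Ne = 1, moves = 1, cv = 0.15) {
  pseudoPosterior(rCoalescentTree(n, Ne), k, moves, cv)
}

# naive mean pairwise distance (the oracle setDistance must reproduce)
naiveSetDistance <- function(tree, sample, metric) {
  mean(vapply(sample$trees, treeDistance, 0, t1 = tree, metric = metric))
}

# independent total-length oracle: recursive traversal over raw member
# sets, never touching the parent/children arrays of the object
oracleTotalLength <- function(tree) {
  sets <- tree$members[tree$size > 1L]
  ages <- tree$age[tree$size > 1L]
  sets <- c(sets, as.list(seq_len(tree$n)))
  ages <- c(ages, rep(0, tree$n))
  total <- 0
  rec <- function(si) {
    s <- sets[[si]]
    # maximal proper subsets of s among all sets
    sub <- which(vapply(sets, function(x)
      length(x) < length(s) && all(x %in% s), TRUE))
    taken <- rep(FALSE, length(s))
    for (ci in sub[order(-lengths(sets[sub]))]) {
      if (any(taken[match(sets[[ci]], s)])) next
      taken[match(sets[[ci]], s)] <- TRUE
      total <<- total + ages[si] - ages[ci]
      rec(ci)
    }
  }
  rootIdx <- which(lengths(sets) == tree$n)[1L]
  rec(rootIdx)
  total
}

# vectorized closed-form grid oracle for the mean distance of a 3-taxon
# candidate topology ((x,y),z) with internal age H and root R, against a
# sample of 3-taxon trees; independent of cladeIndex/setDistance
grid3Oracle <- function(sample, intKey, R, H, metric) {
  stopifnot(length(R) == length(H))
  acc <- numeric(length(R))
  xy <- keyMembers3(intKey)
  z <- setdiff(1:3, xy)
  for (t in sample$trees) {
    r_i <- rootAge(t)
    internal <- which(t$size == 2L)
    if (length(internal) == 1L) {
      ikey <- t$keys[internal]
      h_i <- t$age[internal]
      bint <- r_i - h_i
      inTi <- t$members[[internal]]
    } else {
      ikey <- ""; h_i <- NA; bint <- 0; inTi <- integer(0)
    }
    tipB <- vapply(1:3, function(tx)
      if (tx %in% inTi) h_i else r_i, 0)
    bx <- tipB[xy[1L]]; by <- tipB[xy[2L]]; bz <- tipB[z]
    match_ <- identical(ikey, intKey)
    d <- switch(metric,
      rbs = abs(H - bx) + abs(H - by) + abs(R - bz) +
        (if (match_) abs((R - H) - bint) else (R - H) + bint),
      srbs = (H - bx)^2 + (H - by)^2 + (R - bz)^2 +
        (if (match_) ((R - H) - bint)^2 else (R - H)^2 + bint^2),
      hs = abs(R - r_i) +
        (if (match_) abs(H - h_i) else (R - H) + bint),
      hs_matched = abs(R - r_i) + (if (match_) abs(H - h_i) else 0),
      ras = abs(H - bx) + abs(H - by) + abs(R - bz) +
        (if (match_) {
          (R - H) + bint - 2 * pmax(pmin(R, r_i) - pmax(H, h_i), 0)
        } else (R - H) + bint))
    acc <- acc + d
  }
  acc / length(sample$trees)
}

keyMembers3 <- function(key) as.integer(strsplit(key, ".", fixed = TRUE)[[1L]])

# best value of the 3-taxon grid oracle over a two-stage grid
grid3Best <- function(sample, intKey, metric, coarse = 150L, fine = 60L) {
  maxR <- 2 * max(vapply(sample$trees, rootAge, 0))
  Rg <- seq(1e-6, maxR, length.out = coarse)
  Ag <- seq(0, 1, length.out = coarse)
  G <- expand.grid(R = Rg, A = Ag)
  v <- grid3Oracle(sample, intKey, G$R, G$R * G$A, metric)
  i <- which.min(v)
  # refine around the coarse optimum
  dr <- maxR / coarse; da <- 1 / coarse
  Rg2 <- seq(max(G$R[i] - dr, 0), G$R[i] + dr, length.out = fine)
  Ag2 <- seq(max(G$A[i] - da, 0), min(G$A[i] + da, 1), length.out = fine)
  G2 <- expand.grid(R = Rg2, A = Ag2)
  v2 <- grid3Oracle(sample, intKey, G2$R, G2$R * G2$A, metric)
  min(min(v), min(v2))
}

# brute-force JC likelihood by enumerating internal-node states (<= 4
# taxa); works directly on the clade structure
enumJCLogLik <- function(tree, aln, rate) {
  aln <- aln[tree$taxa, , drop = FALSE]
  code <- matrix(match(aln, c("A", "C", "G", "T")), nrow(aln), ncol(aln))
  ints <- which(tree$size > 1L)
  ni <- length(ints)
  psame <- function(d) 0.25 + 0.75 * exp(-4 * d / 3)
  ll <- 0
  for (site in seq_len(ncol(code))) {
    p <- 0
    for (combo in seq_len(4L^ni) - 1L) {
      states <- integer(length(tree$keys))
      cc <- combo
      for (j in seq_len(ni)) {
        states[ints[j]] <- cc %% 4L + 1L
        cc <- cc %/% 4L
      }
      for (tip in seq_len(tree$n)) states[tip] <- code[tip, site]
      pr <- 0.25
      for (i in seq_along(tree$keys)) {
        pa <- tree$parent[i]
        if (is.na(pa)) next
        d <- (tree$age[pa] - tree$age[i]) * rate
        ps <- psame(d)
        pr <- pr * if (states[i] == states[pa]) ps else (1 - ps) / 3
      }
      p <- p + pr
    }
    ll <- ll + log(p)
  }
  ll
}

# rooted Robinson-Foulds via phangorn on outgroup-augmented unrooted
# trees: clades of the rooted tree <-> splits of the augmented tree
rootedRFOracle <- function(t1, t2) {
  aug <- function(t) {
    txt <- ape::write.tree(ape::as.phylo(t))
    ape::read.tree(text = paste0("(", sub(";$", "", txt), ":1,OUTGRP__:1);"))
  }
  as.numeric(phangorn::RF.dist(aug(t1), aug(t2)))
}

# shortest HPD window by brute force over all contiguous windows
bruteHPD <- function(samples, level) {
  s <- sort(samples)
  k <- length(s)
  need <- min(ceiling(level * k), k)
  best <- NULL
  for (i in seq_len(k - need + 1L)) {
    w <- s[i + need - 1L] - s[i]
    if (is.null(best) || w < best$w - 1e-12) best <- list(w = w, lo = s[i],
                                                         hi = s[i + need - 1L])
  }
  c(best$lo, best$hi)
}

# canonical topology identifier used in the tests
topologyKeyOf <- function(t) paste(sort(t$keys[t$size > 1L]), collapse = ";")
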