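# Topology selectors: clade frequencies, MCC, CCD, TCB, HPF.

test_that("clade frequencies are exact fractions and match ape's bipartition counts", {
  s <- treeSample(list(fixTA(), fixTB(), fixTC()))
  fr <- cladeFrequencies(s)
  expect_equal(fr$lookup[["1.2"]], 2 / 3)
  expect_equal(fr$lookup[["2.3"]], 1 / 3)
  expect_equal(fr$lookup[["1.2.3"]], 1)

  set.seed(501)
  samp <- randSample(k = 30, n = 6, moves = 2)
  fr <- cladeFrequencies(samp)
  pp <- ape::prop.part(lapply(samp$trees, ape::as.phylo))
  labs <- attr(pp, "labels")
  for (i in seq_along(pp)) {
    key <- paste(sort(match(labs[pp[[i]]], samp$taxa)), collapse = ".")
    expect_equal(fr$lookup[[key]], attr(pp, "number")[i] / 30)
  }
})

test_that("clade credibility is the log product of clade frequencies", {
  s <- treeSample(list(fixTA(), fixTB(), fixTC()))
  fr <- cladeFrequencies(s)
  expect_equal(cladeCredibility(fixTA(), fr), log(2 / 3))
  expect_equal(cladeCredibility(fixTC(), fr), log(1 / 3))
  one <- treeSample(list(fixTA()))
  expect_equal(cladeCredibility(fixTA(), cladeFrequencies(one)), 0)
  # unobserved clade yields the -Inf sentinel
  other <- timeTree(c("a", "b", "c"), list(c("a", "c"), c("a", "b", "c")),
                    c(1, 2))
  expect_equal(cladeCredibility(other, fr), -Inf)
})

test_that("MCC selection maximizes clade credibility, lowest index on ties", {
  s <- treeSample(list(fixTA(), fixTB(), fixTC()))
  expect_equal(selectMCC(s), 1)
  expect_equal(selectMCC(treeSample(list(fixTC()))), 1)

  set.seed(502)
  samp <- randSample(k = 40, n = 7, moves = 2)
  i <- selectMCC(samp)
  fr <- cladeFrequencies(samp)
  scores <- vapply(samp$trees, cladeCredibility, 0, freqs = fr)
  expect_true(all(is.finite(scores)))
  expect_equal(scores[i], max(scores))
  # agrees with phangorn's maximum clade credibility score
  mp <- phangorn::maxCladeCred(lapply(samp$trees, ape::as.phylo),
                               rooted = TRUE)
  expect_equal(scores[i],
               cladeCredibility(asTimeTree(mp, taxa = samp$taxa), fr),
               tolerance = 1e-9)
})

test_that("CCD probabilities multiply split counts conditional on clades", {
  s <- treeSample(list(fixTA(), fixTB(), fixTC()))
  tally <- ccdTally(s)
  expect_equal(ccdLogProb(fixTA(), tally), log(2 / 3))
  expect_equal(ccdLogProb(fixTC(), tally), log(1 / 3))
  expect_equal(selectCCD(s), 1)
  one <- treeSample(list(fixTB()))
  expect_equal(ccdLogProb(fixTB(), ccdTally(one)), 0)

  # normalized over sampled topologies, total probability <= 1
  set.seed(503)
  samp <- randSample(k = 25, n = 5, moves = 2)
  tally <- ccdTally(samp)
  keys <- vapply(samp$trees, function(t) topologyKeyOf(t), "")
  probs <- exp(vapply(samp$trees, ccdLogProb, 0, tally = tally))
  expect_lte(sum(probs[!duplicated(keys)]), 1 + 1e-9)
})

test_that("TCB scores sum matched branch lengths", {
  expect_equal(tcbScores(treeSample(list(fixTA(), fixTB())))[["1.2"]], 3.5)
  tcb2 <- tcbScores(treeSample(list(fixTA(), fixTC())))
  expect_equal(tcb2[["1.2"]], 1)
  expect_equal(tcb2[["2.3"]], 1)
  expect_equal(selectTCB(treeSample(list(fixTB()))), 1)
})

test_that("HPF picks the most frequent topology, root-height tie-break", {
  s <- treeSample(list(fixTA(), fixTB(), fixTC()))
  i <- selectHPF(s)
  expect_true(i %in% c(1, 2))  # the ((a,b),c) topology

  # frequency tie broken by root height closest to the posterior mean
  taxa <- c("a", "b", "c")
  ta2 <- timeTree(taxa, list(c("a", "b"), taxa), c(1, 2))
  ta4 <- timeTree(taxa, list(c("a", "b"), taxa), c(1, 4))
  tc3 <- timeTree(taxa, list(c("b", "c"), taxa), c(1, 3))
  tc31 <- timeTree(taxa, list(c("b", "c"), taxa), c(1, 3.1))
  s2 <- treeSample(list(ta2, ta4, tc3, tc31))
  expect_equal(selectHPF(s2), 3)  # first tree of the (a,(b,c)) topology

  expect_equal(selectHPF(treeSample(list(fixTA()))), 1)
})

test_that("a single-topology sample makes all selectors agree", {
  set.seed(504)
  samp <- pseudoPosterior(randTree(6), 15, 0, 0.2)
  keys <- vapply(samp$trees, function(t) topologyKeyOf(t), "")
  for (sel in list(selectMCC, selectCCD, selectTCB, selectHPF)) {
    expect_equal(keys[sel(samp)], keys[1])
  }
})
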