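# Taxa-partition summary tree: ordering, split-age collection,
# reconstruction.

test_that("pair distances average the MRCA clade sizes", {
  one <- treeSample(list(fixTA()))
  d <- pairDistanceMatrix(one)
  expect_equal(d["a", "b"], 2)
  expect_equal(d["a", "c"], 3)
  expect_equal(d["b", "c"], 3)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  two <- treeSample(list(fixTA(), fixTC()))
  expect_equal(pairDistanceMatrix(two)["a", "b"], 2.5)

  star <- timeTree(letters[1:4], list(letters[1:4]), 1)
  dStar <- pairDistanceMatrix(treeSample(list(star)))
  expect_true(all(dStar[upper.tri(dStar)] == 4))
})

test_that("taxa ordering keeps close taxa adjacent", {
  ordA <- taxaOrder(pairDistanceMatrix(treeSample(list(fixTA()))))
  pos <- match(c("a", "b"), ordA$labels)
  expect_equal(abs(diff(pos)), 1)  # a and b adjacent

  cat4 <- timeTree(letters[1:4],
                   list(c("a", "b"), c("a", "b", "c"), letters[1:4]),
                   c(1, 2, 3))
  ordC <- taxaOrder(pairDistanceMatrix(treeSample(list(cat4))))
  expect_equal(ordC$labels, c("a", "b", "c", "d"))

  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(taxaOrder(d2)$labels, c("a", "b"))
})

test_that("split-age collection follows the boundary rule", {
  taxa <- letters[1:4]
  ord <- structure(list(order = 1:4, labels = taxa), class = "taxaOrder")
  mk <- function(clades, ages) treeSample(list(timeTree(taxa, clades, ages)))

  # caterpillar (((a,b),c),d): each nested clade feeds its boundary
  s1 <- mk(list(c("a", "b"), c("a", "b", "c"), taxa), c(1, 2, 3))
  v1 <- splitAges(ord, s1)
  expect_equal(v1$ages[[1]], 1)
  expect_equal(v1$ages[[2]], 2)
  expect_equal(v1$ages[[3]], 3)

  # ((a,d),(b,c)): only (b,c) occupies a contiguous block
  s2 <- mk(list(c("a", "d"), c("b", "c"), taxa), c(1, 1, 2))
  v2 <- splitAges(ord, s2)
  expect_null(v2$ages[[1]])
  expect_equal(v2$ages[[2]], 1)
  expect_null(v2$ages[[3]])

  # (a,((d,b),c)): only the root is compatible, at the first boundary
  s3 <- mk(list(c("b", "d"), c("b", "c", "d"), taxa), c(0.5, 1, 2))
  v3 <- splitAges(ord, s3)
  expect_equal(v3$ages[[1]], 2)
  expect_null(v3$ages[[2]])
  expect_null(v3$ages[[3]])
})

test_that("reconstruction resolves the worked three-tree mixture", {
  taxa <- c("a", "b", "c")
  ta <- fixTA()
  tcp <- timeTree(taxa, list(c("b", "c"), taxa), c(0.8, 2))
  s <- treeSample(list(ta, ta, tcp))
  tp <- taxaPartitionTree(s, "median")
  # boundary estimates: [a|bc] median {1,1,2} = 1, [ab|c] median {2,2,0.8} = 2
  # the root goes to the higher boundary, giving ((a,b),c)
  expect_true("1.2" %in% tp$keys)
  expect_equal(mrcaAge(tp, c("a", "b")), 1)
  expect_equal(rootAge(tp), 2)
  expect_equal(attr(tp, "clamped"), 0)
})

test_that("identical samples are recovered exactly, and 2-taxon trees average roots", {
  set.seed(801)
  for (rep_ in 1:10) {
    tr <- randTree(sample(3:8, 1))
    s <- pseudoPosterior(tr, 6, 0, 0)
    for (stat in c("median", "mean")) {
      expect_true(sameTree(taxaPartitionTree(s, stat), tr, tol = 1e-9))
    }
  }
  t2a <- timeTree(c("a", "b"), list(c("a", "b")), 1)
  t2b <- timeTree(c("a", "b"), list(c("a", "b")), 3)
  s2 <- treeSample(list(t2a, t2b))
  expect_equal(rootAge(taxaPartitionTree(s2, "mean")), 2)
})

test_that("reconstruction always yields a valid tree with the root at the maximal split", {
  set.seed(802)
  for (rep_ in 1:25) {
    samp <- randSample(k = 8, n = 7, moves = 3, cv = 0.4)
    ord <- taxaOrder(pairDistanceMatrix(samp))
    sp <- splitAges(ord, samp)
    for (stat in c("median", "mean")) {
      tp <- tpTree(ord, sp, samp, stat)
      idx <- which(tp$size > 1L)
      rebuilt <- timeTree(tp$taxa, tp$members[idx], tp$age[idx])
      expect_s3_class(rebuilt, "timeTree")
      f <- if (stat == "median") median else mean
      est <- vapply(seq_len(6), function(k)
        if (length(sp$ages[[k]])) f(sp$ages[[k]]) else f(sp$fallback[k, ]), 0)
      expect_equal(rootAge(tp), max(est), tolerance = 1e-12)
    }
  }
})
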