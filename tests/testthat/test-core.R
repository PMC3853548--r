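# Tree data model: construction, validation, clade primitives.

test_that("construction validates the hierarchy and age conditions", {
  ta <- fixTA()
  expect_s3_class(ta, "timeTree")
  expect_equal(sort(ta$age), c(0, 0, 0, 1, 2))

  # overlapping, non-nested clades
  expect_error(timeTree(c("a", "b", "c"),
                        list(c("a", "b"), c("b", "c"), c("a", "b", "c")),
                        c(1, 1, 2)),
               "overlap")
  # child older than parent
  expect_error(timeTree(c("a", "b", "c"),
                        list(c("a", "b"), c("a", "b", "c")), c(3, 2)),
               "older")
  expect_error(timeTree(c("a", "b", "c"),
                        list(c("a", "b"), c("a", "b", "c")), c(-1, 2)),
               "negative")
  expect_error(timeTree(c("a", "b", "c"), list(c("a", "b")), 1), "root")
  # dated tips rejected
  expect_error(timeTree(c("a", "b"), list("a", c("a", "b")), c(0.5, 1)),
               "dated tips")
})

test_that("accessors round-trip the constructed clades and ages", {
  set.seed(101)
  for (rep_ in 1:20) {
    tr <- randTree(sample(3:10, 1))
    idx <- which(tr$size > 1L)
    rebuilt <- timeTree(tr$taxa, tr$members[idx], tr$age[idx])
    expect_true(sameTree(tr, rebuilt, tol = 0))
    for (i in idx) {
      expect_identical(mrcaAge(rebuilt, tr$members[[i]]), tr$age[i])
    }
  }
})

test_that("MRCA age is the age of the minimal containing clade", {
  ta <- fixTA(); tc <- fixTC()
  expect_equal(mrcaAge(ta, c("a", "b")), 1)
  expect_equal(mrcaAge(tc, c("a", "b")), 2)  # minimal container is the root
  expect_equal(mrcaAge(ta, "a"), 0)
  expect_error(mrcaAge(ta, character(0)), "empty")

  # monotone in the subset
  set.seed(102)
  for (rep_ in 1:20) {
    tr <- randTree(8)
    x <- sample(8, sample(2:4, 1))
    y <- union(x, sample(8, 2))
    expect_lte(mrcaAge(tr, x), mrcaAge(tr, y))
  }
})

test_that("branch lengths follow the parent-minus-child convention", {
  ta <- fixTA()
  expect_equal(branchLength(ta, c("a", "b")), 1)
  expect_equal(branchLength(ta, c("a", "b", "c")), 0)  # root
  expect_equal(branchLength(ta, c("b", "c")), 0)       # not a clade

  # branch sum equals an independent traversal oracle
  set.seed(103)
  for (rep_ in 1:15) {
    tr <- randTree(sample(3:9, 1))
    expect_equal(totalTreeLength(tr), oracleTotalLength(tr), tolerance = 1e-12)
  }
})

test_that("splitting pairs partition all taxon pairs across internal clades", {
  ta <- fixTA()
  p <- pairsSplittingAt(ta, c("a", "b", "c"))
  expect_setequal(apply(p, 1, function(r) paste(sort(r), collapse = "-")),
                  c("1-3", "2-3"))
  expect_equal(nrow(pairsSplittingAt(ta, c("a", "b"))), 1)
  expect_equal(nrow(pairsSplittingAt(ta, "a")), 0)
  expect_error(pairsSplittingAt(ta, c("b", "c")), "not a clade")

  set.seed(104)
  for (rep_ in 1:10) {
    n <- sample(4:9, 1)
    tr <- randTree(n)
    seen <- character(0)
    for (i in which(tr$size > 1L)) {
      p <- pairsSplittingAt(tr, tr$members[[i]])
      seen <- c(seen, apply(p, 1, function(r) paste(sort(r), collapse = "-")))
    }
    expect_equal(sort(seen),
                 sort(apply(t(combn(n, 2)), 1, paste, collapse = "-")))
  }
})

test_that("divergence time averages reference split ages of the source pairs", {
  ta <- fixTA(); tc <- fixTC()
  expect_equal(divergenceTime(c("a", "b", "c"), ta, ta), 2)
  expect_equal(divergenceTime(c("a", "b", "c"), ta, tc), 1.5)
  expect_equal(divergenceTime(c("a", "b"), ta, tc), 2)

  # against the same tree, divergence time equals the clade age
  set.seed(105)
  for (rep_ in 1:10) {
    tr <- randTree(7)
    for (i in which(tr$size > 1L)) {
      expect_equal(divergenceTime(tr$members[[i]], tr, tr), tr$age[i],
                   tolerance = 1e-12)
    }
  }
})
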