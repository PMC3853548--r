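# Likelihoods, error reports and the ranking protocol.

test_that("JC pruning matches the cherry closed form and the enumeration oracle", {
  t2 <- timeTree(c("a", "b"), list(c("a", "b")), 1)
  mu <- 0.005
  alnSame <- matrix(c("A", "A"), 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(jcLogLik(t2, alnSame, mu),
               log(0.25 * (0.25 + 0.75 * exp(-8 * mu / 3))))
  alnL <- matrix("G", 2, 7, dimnames = list(c("a", "b"), NULL))
  t0 <- timeTree(c("a", "b"), list(c("a", "b")), 0)
  expect_equal(jcLogLik(t0, alnL, mu), 7 * log(0.25))

  set.seed(1001)
  for (rep_ in 1:12) {
    n <- sample(3:4, 1)
    tr <- rCoalescentTree(n, 1)
    aln <- simulateJC(tr, 8, 0.3)
    expect_equal(jcLogLik(tr, aln, 0.3), enumJCLogLik(tr, aln, 0.3),
                 tolerance = 1e-10)
  }
})

test_that("JC pruning agrees with phangorn's likelihood engine", {
  set.seed(1002)
  tr <- rCoalescentTree(6, 1)
  aln <- simulateJC(tr, 100, 0.05)
  dat <- phangorn::phyDat(aln)
  fit <- phangorn::pml(ape::as.phylo(tr), dat, rate = 0.05)
  expect_equal(jcLogLik(tr, aln, 0.05), as.numeric(fit$logLik),
               tolerance = 1e-6)
})

test_that("coalescent density matches closed forms and the scaling identity", {
  t2 <- timeTree(c("a", "b"), list(c("a", "b")), 0.7)
  Ne <- 1.3
  expect_equal(coalescentLogLik(t2, Ne), -log(Ne) - 0.7 / Ne)
  expect_equal(coalescentLogLik(fixTA(), 1), -4)

  set.seed(1003)
  for (rep_ in 1:10) {
    tr <- rCoalescentTree(sample(3:10, 1), 1)
    s <- runif(1, 0.5, 3)
    idx <- which(tr$size > 1L)
    scaled <- timeTree(tr$taxa, tr$members[idx], tr$age[idx] * s)
    expect_equal(coalescentLogLik(scaled, s),
                 coalescentLogLik(tr, 1) - (tr$n - 1) * log(s),
                 tolerance = 1e-9)
  }
  expect_error(coalescentLogLik(t2, 0), "positive")
})

test_that("model-fit percentile ranks the summary within the sample", {
  set.seed(1004)
  tr <- rCoalescentTree(5, 1)
  aln <- simulateJC(tr, 50, 0.05)
  samp <- pseudoPosterior(tr, 12, 1, 0.2)
  fits <- vapply(samp$trees, function(t)
    jcLogLik(t, aln, 0.05) + coalescentLogLik(t, 1), 0)
  best <- samp[[which.max(fits)]]
  expect_gte(modelFitPercentile(best, samp, aln, 0.05, 1), 11 / 12)
  conc <- pseudoPosterior(tr, 8, 0, 0)
  expect_equal(modelFitPercentile(tr, conc, aln, 0.05, 1), 1)
})

test_that("the error report composes the individual measures", {
  set.seed(1005)
  tr <- rCoalescentTree(4, 1)
  aln <- simulateJC(tr, 30, 0.05)
  ev <- errorReport(tr, tr, aln, 0.05, 1)
  expect_equal(ev$heights_error, 0)
  expect_equal(ev$divergence_error, 0)
  expect_equal(ev$clades_missed, 0)
  expect_equal(ev$root_height_error, 0)
  expect_equal(ev$model_fit, ev$tree_loglik + ev$coalescent_loglik)

  ev2 <- errorReport(fixTA(), fixTC())
  expect_equal(ev2$heights_error, 1)
  expect_equal(ev2$divergence_error, 1.5)
  expect_equal(ev2$clades_missed, 1)
  expect_equal(ev2$clades_called, 1)
})

test_that("dense ranking follows the 1-2-2-3 rule", {
  expect_equal(denseRank(c(0.1, 0.3, 0.3, 0.5)), c(1, 2, 2, 3))
  expect_equal(denseRank(rep(2, 5)), rep(1, 5))
  expect_equal(denseRank(c(5, 1, 3)), c(3, 1, 2))
  expect_equal(denseRank(sort(runif(7))), 1:7)
})

test_that("per-case normalization standardizes rows, constants to zero", {
  expect_equal(normalizeErrors(matrix(c(1, 3), 1)), matrix(c(-1, 1), 1))
  expect_equal(normalizeErrors(matrix(2, 1, 4)), matrix(0, 1, 4))
  set.seed(1006)
  m <- matrix(rnorm(40), 8, 5)
  z <- normalizeErrors(m)
  expect_equal(rowMeans(z), rep(0, 8), tolerance = 1e-12)
  expect_equal(apply(z, 1, function(r) mean(r^2)), rep(1, 8),
               tolerance = 1e-12)
})

test_that("bootstrap dominance scores order methods and respect ties", {
  set.seed(1007)
  m <- matrix(c(1, 2, 3,
                1.1, 2.2, 3.3,
                0.9, 2.1, 3.2,
                1.0, 2.0, 3.0), 4, 3, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(unname(bootstrapScores(m, 4000, 0.9)), c(0, 1, 2))
  expect_equal(unname(bootstrapScores(m, 4000, 0.9, "normalized")), c(0, 1, 2))

  # duplicated method: neither dominates its twin
  m2 <- cbind(m, A2 = m[, "A"])
  sc <- bootstrapScores(m2, 2000, 0.9)
  expect_equal(unname(sc[c("A", "A2")]), c(0, 0))

  # permutation of columns permutes scores identically
  set.seed(1)
  s1 <- bootstrapScores(m, 1000, 0.9)
  set.seed(1)
  s2 <- bootstrapScores(m[, c(3, 1, 2)], 1000, 0.9)
  expect_equal(unname(s2[names(s1)]), unname(s1))
})

test_that("rankMethods assembles complete tables without NaNs", {
  set.seed(1008)
  errs <- list(height = matrix(runif(30), 10, 3,
                               dimnames = list(NULL, c("x", "y", "z"))),
               missed = matrix(rpois(30, 2), 10, 3,
                               dimnames = list(NULL, c("x", "y", "z"))))
  rt <- rankMethods(errs, reps = 300)
  expect_s3_class(rt, "rankTable")
  for (tab in rt) {
    expect_false(any(is.na(as.matrix(tab[, -1]))))
    expect_true(all(tab$mean_rank >= 1))
  }
  d <- tempfile()
  writeRankTable(rt, d)
  expect_true(file.exists(file.path(d, "rank_height.tsv")))
})
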