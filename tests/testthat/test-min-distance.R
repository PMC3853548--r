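# Ratio parametrization, objective/gradient, initialization, and the
# fixed-topology / all-topology minimum-distance searches.

test_that("encode and decode are mutual inverses within bounds", {
  pv <- encodeTree(fixTA())
  expect_equal(pv$root_height, 2)
  expect_equal(pv$ratios, 0.5)
  expect_true(sameTree(decodeTree(pv), fixTA(), tol = 1e-12))

  bad <- pv; bad$ratios <- 1.2
  expect_error(decodeTree(bad), "ratio")
  bad2 <- pv; bad2$root_height <- -1
  expect_error(decodeTree(bad2), "negative")

  set.seed(701)
  for (rep_ in 1:30) {
    tr <- randTree(sample(3:10, 1))
    expect_true(sameTree(decodeTree(encodeTree(tr)), tr, tol = 1e-12))
  }
})

test_that("objective value equals the naive mean pairwise distance", {
  one <- treeSample(list(fixTB()))
  ix1 <- cladeIndex(one, "srbs")
  o <- paramObjective(encodeTree(fixTB()), ix1)
  expect_equal(o$value, 0)
  expect_equal(o$gradient, c(0, 0))

  set.seed(702)
  for (rep_ in 1:12) {
    samp <- randSample(k = 8, n = 6, moves = 2, cv = 0.3)
    ix <- cladeIndex(samp)
    pv <- encodeTree(pseudoPosterior(samp[[1]], 1, 1, 0.3)[[1]])
    for (m in c("rbs", "srbs", "hs", "ras", "hs_matched")) {
      expect_equal(paramObjective(pv, ix, m)$value,
                   naiveSetDistance(decodeTree(pv), samp, m),
                   tolerance = 1e-9)
    }
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(703)
  checked <- 0
  for (rep_ in 1:20) {
    samp <- randSample(k = 6, n = 5, moves = 1, cv = 0.3)
    ix <- cladeIndex(samp)
    pv <- encodeTree(samp[[1]])
    # random interior point, away from bound edges
    pv$root_height <- runif(1, 0.3, 1.7) * pv$root_height + 0.013
    pv$ratios <- runif(length(pv$ratios), 0.05, 0.95)
    eps <- 1e-6
    for (m in c("rbs", "srbs", "hs", "ras", "hs_matched")) {
      ana <- paramObjective(pv, ix, m)$gradient
      np <- 1L + length(pv$ratios)
      num <- vapply(seq_len(np), function(j) {
        shift <- function(s) {
          p <- pv
          if (j == 1L) p$root_height <- p$root_height + s
          else p$ratios[j - 1L] <- p$ratios[j - 1L] + s
          paramObjective(p, ix, m)$value
        }
        (shift(eps) - shift(-eps)) / (2 * eps)
      }, 0)
      # skip comparisons straddling a kink of the L1 objectives: there
      # the two-sided difference sits between the one-sided derivatives
      kink <- abs(num - ana) > 1e-4 * (1 + abs(num)) &
        m %in% c("rbs", "hs", "ras", "hs_matched")
      if (m == "srbs") expect_equal(ana, num, tolerance = 1e-5)
      else checked <- checked + sum(!kink &
        abs(num - ana) <= 1e-4 * (1 + abs(num)))
    }
  }
  expect_gt(checked, 100)  # the L1 gradients agree away from kinks
})

test_that("initialization reproduces the worked per-branch optima", {
  s <- treeSample(list(fixTA(), fixTB()))
  ixS <- cladeIndex(s, "srbs")
  it <- initTree(fixTA(), ixS, "srbs")
  expect_equal(mrcaAge(it, c("a", "b")), 0.75)
  expect_equal(rootAge(it), 2.5)

  # rbs uses the padded median, even counts resolved to the midpoint
  ixR <- cladeIndex(s, "rbs")
  itR <- initTree(fixTA(), ixR, "rbs")
  expect_equal(mrcaAge(itR, c("a", "b")), 0.75)  # midpoint of 0.5 and 1

  one <- treeSample(list(fixTC()))
  expect_true(sameTree(initTree(fixTC(), cladeIndex(one, "srbs"), "srbs"),
                       fixTC(), tol = 1e-12))
})

test_that("fixed-topology optimization reaches the grid-search optimum", {
  s <- treeSample(list(fixTA(), fixTB()))
  opt <- optimizeTopology(fixTA(), s, "srbs", opts = list(seed = 1))
  expect_equal(mrcaAge(opt, c("a", "b")), 0.75, tolerance = 1e-4)
  expect_equal(rootAge(opt), 2.5, tolerance = 1e-4)
  expect_equal(attr(opt, "distance"), 0.9375, tolerance = 1e-6)

  one <- treeSample(list(fixTB()))
  optOne <- optimizeTopology(fixTB(), one, "rbs", opts = list(seed = 1))
  expect_true(sameTree(optOne, fixTB()))
  expect_equal(attr(optOne, "distance"), 0)
})

test_that("the optimum improves monotonically over the initialization", {
  set.seed(704)
  for (rep_ in 1:10) {
    samp <- randSample(k = 8, n = 6, moves = 1, cv = 0.3)
    topo <- samp[[1]]
    for (m in c("rbs", "srbs")) {
      ix <- cladeIndex(samp, m)
      opt <- optimizeTopology(topo, samp, m,
                              opts = list(restarts = 1, seed = rep_))
      expect_lte(attr(opt, "distance"),
                 setDistance(initTree(topo, ix, m), ix, m) + 1e-9)
    }
  }
})

test_that("all-topology search never loses to a sampled tree", {
  one <- pseudoPosterior(fixTB(), 5, 0, 0)
  m1 <- minDistanceTree(one, "srbs", "all", opts = list(seed = 1))
  expect_true(sameTree(m1, fixTB()))

  set.seed(705)
  for (rep_ in 1:10) {
    samp <- randSample(k = 8, n = 5, moves = 2, cv = 0.3)
    for (m in c("rbs", "hs")) {
      ix <- cladeIndex(samp, m)
      best <- minDistanceTree(samp, m, "all",
                              opts = list(restarts = 0, polish = FALSE))
      sampledMin <- min(vapply(samp$trees, setDistance, 0, index = ix,
                               metric = m))
      expect_lte(attr(best, "distance"), sampledMin + 1e-9)
    }
  }

  s3 <- treeSample(list(fixTA(), fixTB(), fixTC()))
  mAll <- minDistanceTree(s3, "rbs", "all", opts = list(seed = 2))
  ix <- cladeIndex(s3, "rbs")
  expect_lte(attr(mAll, "distance"),
             min(vapply(s3$trees, setDistance, 0, index = ix)) + 1e-9)
})

test_that("decoded parameter vectors never contain negative branches", {
  set.seed(706)
  for (rep_ in 1:20) {
    tr <- randTree(6)
    pv <- encodeTree(tr)
    pv$root_height <- runif(1, 0, 3)
    pv$ratios <- runif(length(pv$ratios))
    dec <- decodeTree(pv)
    expect_true(all(branchLength(dec, 1) >= 0))
    b <- vapply(which(dec$size > 1L), function(i)
      min(dec$age[i] - dec$age[dec$children[[i]]]), 0)
    expect_true(all(b >= 0))
  }
})
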