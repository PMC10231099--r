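test_that("polarization keeps only fixed-outgroup sites and flips at 1", {
  m <- matrix(c(0.2, 0.9, 0.4, 0.1,
                0.3, 0.8, 0.5, 0.6), ncol = 2)
  fm <- tinyFreq(m, sampleIds = c("a", "b"))
  og <- c(1, 0.3, 0, 1)
  out <- polarizeFrequencies(fm, og)
  expect_equal(nrow(out), 3L)  # the 0.3 site is excluded
  f <- alleleFreq(out)
  expect_equal(unname(f[, "a"]), c(0.8, 0.4, 0.9))  # sites 1 and 4 flipped
  expect_equal(unname(f[, "b"]), c(0.7, 0.5, 0.4))
  expect_error(polarizeFrequencies(fm, c(0.5, 0.5, 0.5, 0.5)), "fixed")
})

test_that("a mixed panel restricts to its outgroup-fixed subset", {
  m <- matrix(runif(10), ncol = 1)
  og <- c(0, 0.3, 1, 0.4, 0.7, 1, 0.2, 0.9, 0, 0.5)
  out <- polarizeFrequencies(tinyFreq(m, "a"), og)
  expect_equal(nrow(out), 4L)
})

test_that("pattern sums match pure configurations and the enumeration oracle", {
  pure <- function(p1, p2, p3)
    sitePatternSums(makeTrio(cbind(a = rep(p1, 2), b = p2, c = p3),
                             "a", "b", "c", nBlocks = 2))
  expect_equal(pure(0, 1, 1), c(abba = 2, baba = 0))  # 2 identical ABBA sites
  expect_equal(pure(1, 0, 1), c(abba = 0, baba = 2))
  withr::with_seed(51, {
    p1 <- runif(100); p2 <- runif(100); p3 <- runif(100)
  })
  trio <- makeTrio(cbind(a = p1, b = p2, c = p3), "a", "b", "c",
                   nBlocks = 5)
  expect_equal(sitePatternSums(trio), enumeratePatternSums(p1, p2, p3),
               tolerance = 1e-12)
})

test_that("Patterson's D covers its symmetry and boundary cases", {
  allAbba <- makeTrio(cbind(a = rep(0, 4), b = 1, c = 1), "a", "b", "c",
                      nBlocks = 2)
  expect_equal(pattersonD(allAbba), 1)
  withr::with_seed(52, p <- runif(200))
  same <- makeTrio(cbind(a = p, b = p, c = runif(200)), "a", "b", "c")
  expect_equal(pattersonD(same), 0)
  # swapping P1 and P2 negates D exactly
  withr::with_seed(53, m <- cbind(a = runif(300), b = runif(300),
                                  c = runif(300)))
  expect_equal(pattersonD(makeTrio(m, "a", "b", "c")),
               -pattersonD(makeTrio(m, "b", "a", "c")))
  zero <- makeTrio(cbind(a = c(0, 0), b = c(0, 0), c = c(1, 1)),
                   "a", "b", "c", nBlocks = 2)
  expect_error(pattersonD(zero), "undefined")
})

test_that("jackknife blocks have near-equal SNP counts", {
  big <- makeTrio(cbind(a = runif(10500), b = runif(10500),
                        c = runif(10500)), "a", "b", "c", nBlocks = 20)
  expect_true(all(table(big@blockId) == 525))
  odd <- makeTrio(cbind(a = runif(103), b = runif(103), c = runif(103)),
                  "a", "b", "c", nBlocks = 20)
  sizes <- table(odd@blockId)
  expect_lte(diff(range(sizes)), 1)
  expect_true(!is.unsorted(odd@blockId))  # contiguous assignment
  expect_error(makeTrio(cbind(a = runif(10), b = runif(10), c = runif(10)),
                        "a", "b", "c", nBlocks = 20), "fewer sites")
})

test_that("block jackknife reproduces hand-computed delete-one values", {
  # 6 sites in 3 blocks of 2; expected values computed independently by
  # explicit leave-one-block-out arithmetic and frozen here
  m <- cbind(a = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
             b = c(0.8, 0.7, 0.6, 0.5, 0.4, 0.9),
             c = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  trio <- makeTrio(m, "a", "b", "c", nBlocks = 3)
  s <- sitePatternSums(trio)
  expect_equal(unname(s["abba"]), 1.814, tolerance = 1e-12)
  expect_equal(unname(s["baba"]), 0.444, tolerance = 1e-12)
  jk <- blockJackknife(trio, "D")
  expect_equal(jk$theta, 0.6067316209, tolerance = 1e-9)
  expect_equal(jk$se, 0.2608301568, tolerance = 1e-9)
  expect_equal(jk$z, 2.3261559493, tolerance = 1e-8)
})

test_that("identical per-block sums give zero jackknife SE", {
  # the same two sites repeated in every block
  m <- cbind(a = rep(c(0.1, 0.3), 4), b = rep(c(0.7, 0.5), 4),
             c = rep(c(0.9, 0.6), 4))
  trio <- makeTrio(m, "a", "b", "c", nBlocks = 4)
  expect_equal(blockJackknife(trio, "D")$se, 0)
})

test_that("jackknife SE is invariant to block relabelling", {
  withr::with_seed(54, m <- cbind(a = runif(400), b = runif(400),
                                  c = runif(400)))
  trio <- makeTrio(m, "a", "b", "c", nBlocks = 8)
  shuffled <- trio
  shuffled@blockId <- as.integer(9 - trio@blockId)  # reverse labels
  expect_equal(blockJackknife(trio, "D")$se,
               blockJackknife(shuffled, "D")$se)
})

test_that("Z to p-value conversion is two-sided normal", {
  expect_equal(zToPValue(0), 1)
  expect_equal(zToPValue(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(zToPValue(-2), zToPValue(2))
  expect_error(zToPValue(Inf), "finite")
})

test_that("a no-gene-flow trio is not declared significant", {
  panel <- simulateLineagePanel(10000, seed = 55, outgroupFixedFraction = 1)
  p1 <- poolFreqColumn(ColonySpec(0, rep(0, 8)), panel, 551)
  p2 <- poolFreqColumn(ColonySpec(0, rep(0, 8)), panel, 552)
  p3 <- poolFreqColumn(ColonySpec(1, rep(1, 8)), panel, 553)
  res <- dstatTest(makeTrio(cbind(p1 = p1, p2 = p2, p3 = p3),
                            "p1", "p2", "p3", nBlocks = 20))
  expect_lt(abs(res@D), 3 * res@jackknifeSE)
})

test_that("f is 1 under complete admixture and 0 for an unadmixed P2", {
  # realistic topology: P1 from the recipient lineage, P3 and the second
  # donor representative correlated draws from the donor lineage
  withr::with_seed(56, {
    pAnc <- runif(500, 0.05, 0.95)
    fM <- driftFrequencies(pAnc, 0.3)
    fC <- driftFrequencies(pAnc, 0.3)
    p1 <- driftFrequencies(fM, 0.02)
    p3 <- driftFrequencies(fC, 0.02)
    p3a <- driftFrequencies(fC, 0.02)
  })
  complete <- makeTrio(cbind(a = p1, b = p3a, c = p3, d = p3a),
                       "a", "b", "c", p3a = "d")
  expect_equal(admixtureF(complete), 1)
  none <- makeTrio(cbind(a = p1, b = p1, c = p3, d = p3a),
                   "a", "b", "c", p3a = "d")
  expect_equal(admixtureF(none), 0)
})

test_that("f recovers a simulated admixture proportion", {
  withr::with_seed(57, {
    pAnc <- runif(20000, 0.05, 0.95)
    fM <- driftFrequencies(pAnc, 0.3)
    fC <- driftFrequencies(pAnc, 0.3)
    p1 <- driftFrequencies(fM, 0.02)
    p3 <- driftFrequencies(fC, 0.02)
    p3a <- driftFrequencies(fC, 0.02)
    p2 <- 0.7 * driftFrequencies(fM, 0.02) + 0.3 * driftFrequencies(fC, 0.02)
  })
  trio <- makeTrio(cbind(a = p1, b = p2, c = p3, d = p3a),
                   "a", "b", "c", p3a = "d", nBlocks = 20)
  expect_lt(abs(admixtureF(trio) - 0.3), 0.05)
  # f and its jackknife agree on the point estimate
  expect_equal(blockJackknife(trio, "f")$theta, admixtureF(trio))
})

test_that("undefined f denominators raise rather than clamp", {
  trio <- makeTrio(cbind(a = c(0.5, 0.5), b = c(0.6, 0.4),
                         c = c(0.5, 0.5), d = c(0.5, 0.5)),
                   "a", "b", "c", p3a = "d", nBlocks = 2)
  expect_error(admixtureF(trio), "undefined")
})

test_that("the f4-ratio recovers orientation and admixture fraction", {
  withr::with_seed(58, {
    pAnc <- runif(20000, 0.05, 0.95)
    fM <- driftFrequencies(pAnc, 0.3)
    fC <- driftFrequencies(pAnc, 0.3)
    donorA <- driftFrequencies(fC, 0.02)
    donorB <- driftFrequencies(fC, 0.02)
    recip <- driftFrequencies(fM, 0.02)
    mixed <- 0.66 * driftFrequencies(fM, 0.02) +
      0.34 * driftFrequencies(fC, 0.02)
  })
  expect_equal(unname(f4Ratio(donorA, donorB, donorB, recip)["alpha"]), 1)
  expect_lt(abs(f4Ratio(donorA, donorB, driftFrequencies(fM, 0.02),
                        recip)["alpha"]), 0.05)
  a <- f4Ratio(donorA, donorB, mixed, recip)
  expect_lt(abs(a[["alpha"]] - 0.34), 0.05)
  expect_equal(a[["alpha"]] + a[["oneMinusAlpha"]], 1)
  # the f estimator on the same scenario agrees within 0.05
  trioF <- makeTrio(cbind(a = recip, b = mixed, c = donorB, d = donorA),
                    "a", "b", "c", p3a = "d", nBlocks = 20)
  expect_lt(abs(admixtureF(trioF) - a[["alpha"]]), 0.05)
  expect_error(f4Ratio(donorA, donorA, mixed, donorA), "undefined")
})

test_that("missing frequencies are dropped listwise with a count", {
  m <- cbind(a = c(0.1, NA, 0.3, 0.4), b = c(0.5, 0.6, NA, 0.8),
             c = c(0.9, 0.8, 0.7, 0.6))
  trio <- makeTrio(m, "a", "b", "c", nBlocks = 2)
  expect_equal(length(trio@p1), 2L)
  expect_equal(trio@nDropped, 2L)
})
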