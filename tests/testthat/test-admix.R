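test_that("extreme cluster frequencies give a degenerate assignment", {
  fExt <- rep(c(0.999, 0.001), 100)
  withr::with_seed(71, {
    refs <- t(sapply(1:5, function(i) rbinom(200, 2, fExt)))
    alts <- t(sapply(1:5, function(i) rbinom(200, 2, 1 - fExt)))
    target <- rbinom(200, 2, fExt)
  })
  G <- rbind(refs, alts, target)
  rownames(G) <- c(paste0("a", 1:5), paste0("b", 1:5), "x")
  sup <- setNames(rep(c("one", "two"), each = 5), rownames(G)[1:10])
  fit <- fitAdmixture(G, K = 2, supervised = sup, seed = 71)
  expect_gt(qMatrix(fit)["x", "one"], 0.99)
})

test_that("supervised admixture recovers individual ancestry fractions", {
  panel <- simulateLineagePanel(10000, seed = 72)
  f <- alleleFreq(panel)
  truth <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  withr::with_seed(72, {
    G <- rbind(
      t(sapply(1:10, function(i) rbinom(10000, 2, f[, "M"]))),
      t(sapply(1:10, function(i) rbinom(10000, 2, f[, "C1"]))),
      t(sapply(truth, function(q)
        rbinom(10000, 2, (1 - q) * f[, "M"] + q * f[, "C1"]))))
  })
  rownames(G) <- c(paste0("m", 1:10), paste0("c", 1:10), paste0("x", 1:5))
  sup <- setNames(rep(c("M", "C"), each = 10), rownames(G)[1:20])
  fit <- fitAdmixture(G, K = 2, supervised = sup, seed = 73)
  est <- qMatrix(fit)[paste0("x", 1:5), "C"]
  expect_true(all(abs(est - truth) < 0.05))
  expect_true(fit@converged)
})

test_that("the EM log-likelihood is non-decreasing from random starts", {
  panel <- simulateLineagePanel(200, seed = 74)
  f <- alleleFreq(panel)
  withr::with_seed(74, {
    G <- rbind(t(sapply(1:10, function(i) rbinom(200, 2, f[, "M"]))),
               t(sapply(1:10, function(i) rbinom(200, 2, f[, "C1"]))))
  })
  G[sample(length(G), 50)] <- NA  # missing entries are skipped, not fatal
  for (s in 1:50) {
    fit <- fitAdmixture(G, K = 2, seed = s, maxIter = 150)
    expect_true(all(diff(fit@logLik) > -1e-8))
    expect_true(all(abs(rowSums(qMatrix(fit)) - 1) <= 1e-8))
  }
})

test_that("permuting the initialization permutes clusters, not the fit", {
  panel <- simulateLineagePanel(300, seed = 75)
  f <- alleleFreq(panel)
  withr::with_seed(75, {
    G <- rbind(t(sapply(1:8, function(i) rbinom(300, 2, f[, "M"]))),
               t(sapply(1:8, function(i) rbinom(300, 2, f[, "C1"]))))
    Q0 <- matrix(rgamma(16 * 2, 1), 16, 2)
    Q0 <- Q0 / rowSums(Q0)
    F0 <- matrix(runif(2 * 300, 0.05, 0.95), 2, 300)
  })
  fit1 <- fitAdmixture(G, K = 2, initQ = Q0, initF = F0)
  fit2 <- fitAdmixture(G, K = 2, initQ = Q0[, 2:1], initF = F0[2:1, ])
  ll1 <- fit1@logLik[length(fit1@logLik)]
  ll2 <- fit2@logLik[length(fit2@logLik)]
  expect_lt(abs(ll1 - ll2), 1e-6)
  expect_equal(unname(qMatrix(fit1)), unname(qMatrix(fit2)[, 2:1]),
               tolerance = 1e-4)
})

test_that("fits are deterministic given a seed and restarts keep the best", {
  panel <- simulateLineagePanel(150, seed = 78)
  f <- alleleFreq(panel)
  G <- withr::with_seed(78, rbind(
    t(sapply(1:6, function(i) rbinom(150, 2, f[, "M"]))),
    t(sapply(1:6, function(i) rbinom(150, 2, f[, "C1"])))))
  f1 <- fitAdmixture(G, K = 2, seed = 5, maxIter = 200)
  f2 <- fitAdmixture(G, K = 2, seed = 5, maxIter = 200)
  expect_identical(qMatrix(f1), qMatrix(f2))
  multi <- fitAdmixture(G, K = 2, seed = 5, nStarts = 5, maxIter = 200)
  expect_gte(multi@logLik[length(multi@logLik)] + 1e-9,
             f1@logLik[length(f1@logLik)])
})

test_that("input validation catches impossible designs", {
  G <- matrix(rbinom(40, 2, 0.5), 4, 10)
  expect_error(fitAdmixture(G, K = 5), "exceed")
  expect_error(fitAdmixture(G, K = 0), "at least 1")
  expect_error(fitAdmixture(G, K = 2,
                            supervised = c(nope = "M")), "absent")
})

test_that("cross-validation selects the generating number of clusters", {
  panel <- simulateLineagePanel(300, seed = 76,
                                divergence = c(MC = 0.4, C12 = 0.05,
                                               outgroup = 0.5))
  f <- alleleFreq(panel)
  hits <- 0L
  for (s in 1:20) {
    G <- withr::with_seed(s, rbind(
      t(sapply(1:20, function(i) rbinom(300, 2, f[, "M"]))),
      t(sapply(1:20, function(i) rbinom(300, 2, f[, "C1"])))))
    cv <- suppressWarnings(crossValidation(G, Krange = 1:3, nFolds = 3,
                                           seed = s, maxIter = 300))
    hits <- hits + (cv@chosenK == 2L)
  }
  expect_gte(hits, 18L)  # >= 90% of 20 seeds
})

test_that("homogeneous data prefers a single cluster", {
  panel <- simulateLineagePanel(300, seed = 77)
  f <- alleleFreq(panel)
  G <- withr::with_seed(77,
    t(sapply(1:30, function(i) rbinom(300, 2, f[, "M"]))))
  cv <- suppressWarnings(crossValidation(G, Krange = 1:3, nFolds = 3,
                                         seed = 77, maxIter = 300))
  expect_equal(cv@chosenK, 1L)
  expect_error(crossValidation(G, Krange = 1:2, maskFraction = 0),
               "degenerate")
})

test_that("pooled frequencies convert to pseudo-genotypes under both rules", {
  fm <- tinyFreq(matrix(c(0, 0.2, 1 / 3, 0.5, 0.6, 0.75, 1)), "p1")
  round_ <- dosage(poolToPseudogenotypes(fm, "round-dosage"))[, 1]
  thr <- dosage(poolToPseudogenotypes(fm, "threshold"))[, 1]
  expect_equal(unname(round_), c(0L, 0L, 1L, 1L, 1L, 2L, 2L))
  expect_equal(unname(thr), c(0L, 0L, 1L, 1L, 1L, 2L, 2L))
  expect_identical(
    S4Vectors::metadata(poolToPseudogenotypes(fm, "threshold"))$pseudogenotypeRule,
    "threshold")
})

test_that("C-lineage membership resolves cluster identity from references", {
  Q <- rbind(c(0.98, 0.02), c(0.95, 0.05), c(0.62, 0.38), c(0.05, 0.95))
  rownames(Q) <- c("cRef1", "cRef2", "sw1", "mRef")
  colnames(Q) <- c("cluster1", "cluster2")
  fit <- new("AdmixtureFit", Q = Q, F = matrix(0.5, 2, 3),
             logLik = -1, K = 2L, converged = TRUE,
             supervised = character(0))
  cq <- cLineageQ(fit, c("cRef1", "cRef2"))
  expect_equal(unname(cq["sw1"]), 0.62)
  expect_gt(cq[["cRef1"]], 0.9)
  # references loading half-and-half make cluster identity ambiguous
  expect_error(cLineageQ(fit, c("cRef1", "mRef")), "ambiguous")
  expect_error(cLineageQ(fit, "missing"), "absent")
})
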