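test_that("zero drift between C1 and C2 collapses them to one population", {
  panel <- simulateLineagePanel(500, divergence = c(MC = 0.3, C12 = 0,
                                                    outgroup = 0.5),
                                seed = 1)
  f <- alleleFreq(panel)
  expect_identical(f[, "C1"], f[, "C2"])
})

test_that("outgroupFixedFraction = 1 fixes the outgroup ancestral everywhere", {
  panel <- simulateLineagePanel(200, outgroupFixedFraction = 1, seed = 2)
  expect_true(all(outgroupFixed(panel)))
  expect_true(all(alleleFreq(panel)[, "outgroup"] == 0))
})

test_that("generator rejects invalid inputs", {
  expect_error(simulateLineagePanel(0), "positive")
  expect_error(simulateLineagePanel(10, divergence = c(MC = -1, C12 = 0.1,
                                                       outgroup = 0.5)))
  expect_error(driftFrequencies(0.5, 1.2), "fst")
})

test_that("Hudson FST between M and C matches the drift parameterization", {
  # Monte-Carlo oracle: with each branch drifting F from the shared
  # ancestor, the ratio-of-averages Hudson FST converges to F.
  # C12 = 0 keeps C1 at the C-branch ancestor, so FST(M, C1) targets MC
  fsts <- vapply(1:5, function(s) {
    panel <- simulateLineagePanel(10000, divergence = c(MC = 0.30, C12 = 0,
                                                        outgroup = 0.5),
                                  seed = s)
    f <- alleleFreq(panel)
    hudsonFst(f[, "M"], f[, "C1"])
  }, 0)
  expect_lt(abs(mean(fsts) - 0.30), 0.02)
})

test_that("M vs C differentiation exceeds C1 vs C2 differentiation", {
  panel <- simulateLineagePanel(5000, seed = 3)
  f <- alleleFreq(panel)
  expect_gt(hudsonFst(f[, "M"], f[, "C1"]), hudsonFst(f[, "C1"], f[, "C2"]))
})

test_that("workers obey haplodiploid construction invariants", {
  panel <- simulateLineagePanel(300, seed = 4)
  spec <- ColonySpec(0.5, c(0, 1, 0.5), patrilineWeights = c(0.5, 0.3, 0.2))
  ws <- simulateColony(spec, panel, seed = 5)
  expect_equal(ncol(ws), 30L)  # default pool size
  expect_true(all(dosage(ws) ==
                    assay(ws, "maternal") + assay(ws, "paternal")))
  expect_true(all(colData(ws)$patriline %in% 1:3))
  expect_error(ColonySpec(0.5, numeric(0)), "drone")
})

test_that("a pure-M colony's pool frequency is centred on the M panel", {
  panel <- simulateLineagePanel(4000, seed = 6)
  ws <- simulateColony(ColonySpec(0, rep(0, 6)), panel, seed = 7)
  diff <- poolTrueFrequency(ws) - alleleFreq(panel)[, "M"]
  # per-site binomial noise averages out across sites
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(length(diff)))
})

test_that("colony-mean C fraction matches its closed-form expectation", {
  # queen ancestry 0.5 and a single fully-C drone give expected colony
  # C fraction 0.5*0.5 + 1.0*0.5 = 0.75, so the expected pool frequency is
  # 0.75*fC + 0.25*fM; checked over 1000 replicate colonies.
  spec <- ColonySpec(0.5, 1.0)
  expect_equal(expectedColonyAncestry(spec), 0.75)
  panel <- simulateLineagePanel(50, seed = 8)
  f <- alleleFreq(panel)
  target <- mean(0.75 * f[, "C1"] + 0.25 * f[, "M"])
  means <- vapply(1:1000, function(i) {
    mean(poolTrueFrequency(simulateColony(spec, panel, seed = 100 + i)))
  }, 0)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - target), 3 * se)
})

test_that("pool sequencing reflects depth and binomial sampling", {
  panel <- simulateLineagePanel(10000, seed = 9)
  ws <- simulateColony(ColonySpec(0.5, c(0, 1)), panel, seed = 10)
  pc <- sequencePool(ws, meanDepth = 40, seed = 11)
  expect_lt(abs(mean(poolDepth(pc)) - 40), 1)
  # zero-frequency sites never yield alternate reads
  zero <- poolTrueFrequency(ws) == 0
  if (any(zero))
    expect_true(all(alleleDepth(pc)$alt[zero, ] == 0))
  expect_error(sequencePool(ws, meanDepth = 0), "positive")
})

test_that("read frequencies at half-frequency sites show binomial moments", {
  # workers all heterozygous -> pool frequency exactly 0.5 at every site;
  # across sites mean(alt/dp) ~ 0.5 and var ~ E[0.25/dp] ~ 0.25/40
  panel <- simulateLineagePanel(8000, seed = 12)
  ws <- simulateColony(ColonySpec(0, rep(0, 4)), panel, seed = 13)
  het <- ws
  assay(het, "maternal")[] <- 0L
  assay(het, "paternal")[] <- 1L
  assay(het, "dosage")[] <- 1L
  pc <- sequencePool(het, meanDepth = 40, seed = 14)
  est <- alleleDepth(pc)$alt / poolDepth(pc)
  est <- est[is.finite(est)]
  expect_lt(abs(mean(est) - 0.5), 0.005)
  expect_lt(abs(var(est) - 0.25 / 40), 0.002)
})

test_that("sampleIndividual draws workers uniformly and reproducibly", {
  panel <- simulateLineagePanel(5, seed = 15)
  ws <- simulateColony(ColonySpec(0.3, c(0, 1, 0.5)), panel, seed = 16)
  one <- ws[, 7]
  single <- sampleIndividual(ws[, 7], seed = 1)
  expect_identical(unname(dosage(single)[, 1]), unname(dosage(one)[, 1]))
  expect_identical(dosage(sampleIndividual(ws, seed = 42)),
                   dosage(sampleIndividual(ws, seed = 42)))
  idx <- vapply(1:10000, function(i)
    S4Vectors::metadata(sampleIndividual(ws, seed = i))$workerIndex, 0L)
  freq <- tabulate(idx, 30) / 10000
  expect_true(all(abs(freq - 1 / 30) <= 0.01))
})

test_that("identical seeds reproduce panels, colonies and counts exactly", {
  p1 <- simulateLineagePanel(100, seed = 20)
  p2 <- simulateLineagePanel(100, seed = 20)
  expect_identical(alleleFreq(p1), alleleFreq(p2))
  expect_identical(siteIds(p1), siteIds(p2))
  w1 <- simulateColony(ColonySpec(0.4, c(0, 1)), p1, seed = 21)
  w2 <- simulateColony(ColonySpec(0.4, c(0, 1)), p2, seed = 21)
  expect_identical(dosage(w1), dosage(w2))
  s1 <- sequencePool(w1, 40, seed = 22)
  s2 <- sequencePool(w2, 40, seed = 22)
  expect_identical(alleleDepth(s1), alleleDepth(s2))
})

test_that("deep sequencing recovers the colony's true pool frequencies", {
  # at depth 10,000 the read-count estimate converges on the realized pool
  # frequency per site, and on the panel frequency in the across-site mean
  panel <- simulateLineagePanel(500, seed = 23)
  ws <- simulateColony(ColonySpec(0, rep(0, 10)), panel, seed = 24)
  pc <- sequencePool(ws, meanDepth = 10000, seed = 25)
  est <- as.vector(alleleFreq(estimatePoolFrequencies(pc)))
  expect_lt(mean(abs(est - poolTrueFrequency(ws))), 0.01)
  expect_lt(abs(mean(est) - mean(alleleFreq(panel)[, "M"])), 0.02)
})
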