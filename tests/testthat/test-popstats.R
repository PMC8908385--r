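test_that("gene diversity and effective alleles satisfy the closed forms", {
  expect_equal(geneDiversity(1.0), 0)
  expect_equal(geneDiversity(c(0.5, 0.5)), 0.5)
  expect_equal(geneDiversity(rep(0.25, 4)), 0.75)
  expect_equal(effectiveAlleles(0), 1)
  expect_equal(effectiveAlleles(0.5), 2)
  expect_equal(effectiveAlleles(0.75), 4)  # k equifrequent alleles -> EN = k
  expect_error(effectiveAlleles(1), "\\[0, 1\\)")
  expect_error(geneDiversity(c(0.5, 0.4)), "sum to 1")
})

test_that("diversity table: monomorphic pops, EN/Hs bijection, ploidy invariance", {
  mono <- toyDataset(list(P1 = list(list(L1 = 100L, L2 = 103L),
                                    list(L1 = 100L, L2 = 103L))),
                     loci = c("L1", "L2"))
  for (m in c(2, 4, 8)) {
    dt <- diversityTable(recodeDataset(mono, m))
    expect_equal(dt$Hs, 0)
    expect_equal(dt$EN, 1)
  }

  # mixoploid blades at study-like diversity levels (population Hs ~ 0.2-0.5)
  cfg <- simConfig(nSpecies = 1, clustersPerSpecies = 2, popsPerCluster = 2,
                   indsPerPop = 40, nLoci = 6, fscSim = 0.05, fctSim = 0.5,
                   speciesDivergence = 0, hybridFraction = 0, seed = 13)
  sim <- simulateDataset(cfg)
  ds <- simGenotypes(sim)
  hsByPloidy <- sapply(c(2, 4, 8), function(m) {
    dt <- diversityTable(recodeDataset(ds, m))
    expect_equal(dt$EN, 1 / (1 - dt$Hs), tolerance = 1e-9)
    dt$Hs
  })
  # raising the assumed ploidy shrinks Hs mildly and systematically (the
  # random-mating dosage EM attributes excess single-allele phenotypes to
  # skewed frequencies), but never reorders the populations: the diversity
  # ranking the biogeographic conclusions rest on is ploidy-robust
  expect_true(all(hsByPloidy[, 1] >= hsByPloidy[, 2] - 0.02))
  expect_true(all(hsByPloidy[, 2] >= hsByPloidy[, 3] - 0.02))
  expect_equal(order(hsByPloidy[, 1]), order(hsByPloidy[, 2]))
  expect_equal(order(hsByPloidy[, 1]), order(hsByPloidy[, 3]))
})

test_that("high-diversity populations keep their EN ranking at every ploidy", {
  mkpop <- function(hsHigh, seed) {
    cfg <- simConfig(nSpecies = 1, clustersPerSpecies = 1, popsPerCluster = 1,
                     indsPerPop = 50, nLoci = 5,
                     allelesPerLocus = if (hsHigh) 8 else 2,
                     fctSim = 0, fscSim = 0, speciesDivergence = 0,
                     dropoutProb = 0, hybridFraction = 0, seed = seed)
    simGenotypes(simulateDataset(cfg))
  }
  rich <- mkpop(TRUE, 101); poor <- mkpop(FALSE, 102)
  for (m in c(2, 4, 8)) {
    enRich <- diversityTable(recodeDataset(rich, m))$EN
    enPoor <- diversityTable(recodeDataset(poor, m))$EN
    expect_gt(enRich, enPoor)
  }
})

test_that("pairwise Gst and Jost's D hit their endpoints", {
  # identical frequency vectors -> 0
  same <- toyDataset(list(
    P1 = list(list(L1 = 100L), list(L1 = 103L)),
    P2 = list(list(L1 = 100L), list(L1 = 103L))), "L1")
  frS <- estimateAlleleFrequencies(recodeDataset(same, 2))
  frS$P2 <- frS$P1  # exactly equal vectors
  expect_equal(pairwiseDifferentiation(frS, "Gst")$values["P1", "P2"], 0)
  expect_equal(pairwiseDifferentiation(frS, "JostD")$values["P1", "P2"], 0)

  # fixed for different alleles -> 1 (Hs_bar = 0, Ht = 0.5)
  fixed <- toyDataset(list(
    P1 = list(list(L1 = 100L), list(L1 = 100L)),
    P2 = list(list(L1 = 103L), list(L1 = 103L))), "L1")
  frF <- estimateAlleleFrequencies(recodeDataset(fixed, 2))
  expect_equal(pairwiseDifferentiation(frF, "Gst")$values["P1", "P2"], 1)
  expect_equal(pairwiseDifferentiation(frF, "JostD")$values["P1", "P2"], 1)

  # both monomorphic for the same allele: Ht = 0 -> statistic defined as 0
  monoSame <- toyDataset(list(
    P1 = list(list(L1 = 100L)), P2 = list(list(L1 = 100L))), "L1")
  frM <- estimateAlleleFrequencies(recodeDataset(monoSame, 2))
  expect_equal(pairwiseDifferentiation(frM, "Gst")$values["P1", "P2"], 0)
  expect_error(pairwiseDifferentiation(frM[1], "Gst"), "2 populations")
})

test_that("between-cluster Gst exceeds within-cluster Gst when fct > fsc", {
  cfg <- simConfig(nSpecies = 1, clustersPerSpecies = 2, popsPerCluster = 2,
                   indsPerPop = 30, nLoci = 8, fctSim = 0.25, fscSim = 0.03,
                   speciesDivergence = 0, ploidyWeights = c(1, 0, 0),
                   hybridFraction = 0, dropoutProb = 0, seed = 55)
  sim <- simulateDataset(cfg)
  fr <- estimateAlleleFrequencies(recodeDataset(simGenotypes(sim), 2))
  g <- pairwiseDifferentiation(fr, "Gst")$values
  meta <- simMeta(sim)
  cl <- stats::setNames(meta$cluster, meta$population)
  pairs <- which(upper.tri(g), arr.ind = TRUE)
  sameCl <- cl[rownames(g)[pairs[, 1]]] == cl[colnames(g)[pairs[, 2]]]
  expect_gt(mean(g[pairs[!sameCl, , drop = FALSE]]),
            mean(g[pairs[sameCl, , drop = FALSE]]))
})
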