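test_that("zero-drift and monomorphic frequency sets copy the parent exactly", {
  cfg <- simConfig(nSpecies = 2, clustersPerSpecies = 2, popsPerCluster = 2,
                   indsPerPop = 2, nLoci = 4, fctSim = 0, fscSim = 0,
                   speciesDivergence = 0, seed = 3)
  fs <- drawFrequencySet(cfg)
  for (s in 1:2) for (cc in 1:2) for (p in 1:2) for (l in 1:4)
    expect_identical(popFrequencies(fs, s, cc, p, l), fs@rootFreqs[[l]])

  cfg1 <- simConfig(allelesPerLocus = 1, nLoci = 3, seed = 3)
  fs1 <- drawFrequencySet(cfg1)
  for (l in 1:3)
    expect_equal(unname(popFrequencies(fs1, 1, 1, 1, l)), 1.0)
})

test_that("cluster-level differentiation matches the Balding-Nichols expectation", {
  # Wright-style F from the variance of p across cluster vectors
  cfg <- simConfig(nSpecies = 1, clustersPerSpecies = 8, popsPerCluster = 1,
                   indsPerPop = 1, nLoci = 50, allelesPerLocus = 2,
                   fctSim = 0.25, fscSim = 0, speciesDivergence = 0, seed = 42)
  fs <- drawFrequencySet(cfg)
  # Wright-style ratio-of-sums estimator over loci: sum var(p) / sum pbar qbar
  num <- den <- 0
  for (l in 1:50) {
    p <- vapply(1:8, function(cc) fs@clusterFreqs[[1]][[cc]][[l]][1], 0)
    pbar <- mean(p)
    num <- num + stats::var(p)
    den <- den + pbar * (1 - pbar)
  }
  expect_equal(num / den, 0.25, tolerance = 0.03 / 0.25)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(fctSim = 1), "\\[0, 1\\)")
  expect_error(simConfig(ploidyWeights = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(simConfig(nLoci = 0), ">= 1")
})

test_that("sporophytes carry ploidy/2 maternal + ploidy/2 paternal copies", {
  fixed <- list(L1 = c(`100` = 1.0))
  sp <- makeSporophyte(fixed, 4)
  expect_identical(sp$alleles$L1, rep(100L, 4))

  two <- list(L1 = c(`100` = 0.5, `103` = 0.5))
  set.seed(1)
  for (i in 1:20) expect_length(makeSporophyte(two, 2)$alleles$L1, 2L)

  set.seed(7)
  het <- mean(vapply(seq_len(1e4), function(i) {
    a <- makeSporophyte(two, 2)$alleles$L1
    a[1] != a[2]
  }, TRUE))
  expect_equal(het, 0.5, tolerance = 0.02 / 0.5)

  expect_error(makeSporophyte(list(L1 = numeric(0)), 2), "empty frequency")
  expect_error(makeSporophyte(two, 3), "ploidy")
})

test_that("blade genotype is the sporophyte distinct-allele set (tetrad union)", {
  sp2 <- structure(list(ploidy = 2L, alleles = list(L1 = c(100L, 103L))),
                   class = "SporophyteGenotype")
  expect_identical(bladeFromSporophyte(sp2, 0)$L1, c(100L, 103L))

  sp4 <- structure(list(ploidy = 4L,
                        alleles = list(L1 = c(100L, 100L, 103L, 106L))),
                   class = "SporophyteGenotype")
  expect_identical(bladeFromSporophyte(sp4, 0)$L1, c(100L, 103L, 106L))

  sp8 <- structure(list(ploidy = 8L,
                        alleles = list(L1 = c(100L, 100L, 103L, 106L, 109L,
                                              112L, 115L, 115L))),
                   class = "SporophyteGenotype")
  expect_length(bladeFromSporophyte(sp8, 0)$L1, 6L)

  # full dropout empties the locus (missing)
  set.seed(1)
  expect_length(bladeFromSporophyte(sp2, 1)$L1, 0L)
})

test_that("all-diploid datasets never show more than 2 alleles at a locus", {
  cfg <- simConfig(nSpecies = 1, clustersPerSpecies = 2, popsPerCluster = 2,
                   indsPerPop = 15, nLoci = 6, ploidyWeights = c(1, 0, 0),
                   hybridFraction = 0, seed = 9)
  sim <- simulateDataset(cfg)
  ds <- simGenotypes(sim)
  maxA <- max(vapply(ds@calls, function(ci) max(lengths(ci)), 0L))
  expect_lte(maxA, 2L)
})

test_that("dataset bookkeeping, determinism and cp-introgression contract hold", {
  cfg <- simConfig(nSpecies = 2, clustersPerSpecies = 2, popsPerCluster = 3,
                   indsPerPop = 20, nLoci = 4, hybridFraction = 0, seed = 21)
  sim <- simulateDataset(cfg)
  expect_equal(nInd(simGenotypes(sim)), 2 * 2 * 3 * 20)
  tr <- simTruth(sim)$individuals
  # no hybrids -> cpDNA always from the nuclear species
  expect_true(all(tr$cpSpecies == tr$species))
  expect_true(all(nchar(as.character(sim@cpSequences)) == cfg@cpSeqLength))

  # byte-identical output files under a fixed seed
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  writeSimDataset(simulateDataset(cfg), d1)
  writeSimDataset(simulateDataset(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("naive allele counting on a large diploid population recovers truth", {
  cfg <- simConfig(nSpecies = 1, clustersPerSpecies = 1, popsPerCluster = 1,
                   indsPerPop = 600, nLoci = 3, allelesPerLocus = 4,
                   fctSim = 0, fscSim = 0, speciesDivergence = 0,
                   ploidyWeights = c(1, 0, 0), hybridFraction = 0,
                   dropoutProb = 0, seed = 31)
  sim <- simulateDataset(cfg)
  fs <- simTruth(sim)$frequencies
  ds <- simGenotypes(sim)
  for (l in lociNames(ds)) {
    li <- match(l, lociNames(ds))
    counts <- stats::setNames(rep(0, 4), as.character(fs@alleles))
    for (i in seq_len(nInd(ds))) {
      a <- ds@calls[[i]][[l]]
      # diploid blade: singleton set = homozygote (2 copies), pair = 1+1
      if (length(a) == 1L) counts[as.character(a)] <- counts[as.character(a)] + 2
      else for (x in a) counts[as.character(x)] <- counts[as.character(x)] + 1
    }
    phat <- counts / sum(counts)
    truth <- popFrequencies(fs, 1, 1, 1, li)
    expect_lt(max(abs(phat - truth)), 3 * sqrt(0.25 / (2 * 600)) + 0.02)
  }
})
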