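test_that("recoding retains observed alleles, flags ambiguity, keeps missingness", {
  ds <- toyDataset(list(
    BEL = list(list(L1 = c(120L, 124L, 128L), L2 = 120L, L3 = integer(0)))),
    loci = c("L1", "L2", "L3"))

  cod4 <- recodeDataset(ds, 4)
  expect_identical(cod4@retained[[1]]$L1, c(120L, 124L, 128L))
  expect_true(cod4@ambiguous[1, "L1"])
  expect_false(cod4@ambiguous[1, "L2"])   # singleton: unambiguous homozygote
  expect_length(cod4@retained[[1]]$L3, 0L)

  cod2 <- recodeDataset(ds, 2, seed = 5)
  expect_length(cod2@retained[[1]]$L1, 2L)
  expect_true(all(cod2@retained[[1]]$L1 %in% c(120L, 124L, 128L)))
  expect_identical(cod2@retained[[1]]$L2, 120L)
  expect_false(cod2@ambiguous[1, "L2"])
  expect_false(cod2@ambiguous[1, "L1"])   # pair at m=2: dosage known (1+1)
})

test_that("subsampling is reproducible and independent of processing order", {
  dsAB <- toyDataset(list(
    P1 = list(list(L1 = c(120L, 124L, 128L), L2 = c(100L, 103L, 106L, 109L))),
    P2 = list(list(L1 = c(120L, 124L, 128L))),
    P2b = list(list(L1 = 120L))), loci = c("L1", "L2"))
  # same (seed, id, locus) => same subset no matter what else is in the set
  codA <- recodeDataset(dsAB, 2, seed = 99)
  single <- toyDataset(list(
    P1 = list(list(L1 = c(120L, 124L, 128L), L2 = c(100L, 103L, 106L, 109L)))),
    loci = c("L1", "L2"))
  codB <- recodeDataset(single, 2, seed = 99)
  expect_identical(codA@retained[[1]], codB@retained[[1]])
  # and repeat calls are identical
  expect_identical(recodeDataset(dsAB, 2, seed = 99)@retained, codA@retained)
})

test_that("uniform 2-subsets of a 3-allele set occur with frequency 1/3", {
  ds <- toyDataset(list(P1 = list(list(L1 = c(120L, 124L, 128L)))), "L1")
  n <- 6000L
  picks <- vapply(seq_len(n), function(s)
    paste(recodeDataset(ds, 2, seed = s)@retained[[1]]$L1, collapse = ";"), "")
  freq <- table(picks) / n
  expect_length(freq, 3L)
  expect_lt(max(abs(freq - 1 / 3)), 0.02)
})

test_that("compatible-genotype enumeration counts compositions correctly", {
  expect_length(enumerateCompatibleGenotypes(c(1L, 2L), 4), 3L)
  expect_length(enumerateCompatibleGenotypes(c(1L, 2L, 3L), 4), 3L)
  expect_length(enumerateCompatibleGenotypes(1L, 8), 1L)
  expect_identical(enumerateCompatibleGenotypes(c(5L, 9L), 2)[[1]], c(5L, 9L))
  gens <- enumerateCompatibleGenotypes(c(1L, 2L), 4)
  # every observed allele appears at least once, nothing else appears
  for (g in gens) {
    expect_length(g, 4L)
    expect_setequal(unique(g), c(1L, 2L))
  }
  expect_error(enumerateCompatibleGenotypes(c(1L, 2L, 3L), 2), "larger")
  # choose(m-1, k-1) compositions in general
  expect_length(enumerateCompatibleGenotypes(1:4, 8), choose(7, 3))
})

test_that("EM equals direct allele counting at m = 2 and handles fixed loci", {
  est <- emAlleleFrequencies(list(100L), 4)
  expect_equal(unname(est$freqs), 1)

  ph <- list(c(100L, 103L), 100L, 100L, c(100L, 103L), 103L)
  est2 <- emAlleleFrequencies(ph, 2)
  # direct diploid counting: p_100 = (2*2 + 2)/10
  expect_equal(unname(est2$freqs["100"]), 0.6, tolerance = 1e-12)
  expect_true(est2$converged)

  # symmetric tetraploid phenotypes: exact 0.5/0.5 by symmetry
  est3 <- emAlleleFrequencies(rep(list(c(100L, 103L)), 5), 4)
  expect_equal(unname(est3$freqs), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  set.seed(4)
  for (rep in 1:5) {
    sets <- replicate(30, sort(sample(c(100L, 103L, 106L, 109L),
                                      sample(1:4, 1))), simplify = FALSE)
    est <- emAlleleFrequencies(sets, 4)
    expect_true(all(diff(est$logLikTrace) >= -1e-9))
  }
})

test_that("EM matches the brute-force grid-search MLE on tetraploid cases", {
  cases <- list(
    list(100L, c(100L, 103L), c(100L, 103L)),
    list(c(100L, 103L), c(100L, 103L), 103L, 100L, 100L),
    list(c(100L, 103L, 106L), c(100L, 103L), 106L, c(100L, 106L)))
  for (ph in cases) {
    em <- emAlleleFrequencies(ph, 4)$freqs
    k <- length(unique(unlist(ph)))
    oracle <- gridSearchMLE(ph, 4, step = if (k == 2) 1e-4 else 2.5e-4)
    expect_lt(max(abs(em - oracle)), 1e-3)
  }
})

test_that("EM recovers truth on simulated autotetraploids (n = 500)", {
  cfg <- simConfig(nSpecies = 1, clustersPerSpecies = 1, popsPerCluster = 1,
                   indsPerPop = 500, nLoci = 2, allelesPerLocus = 4,
                   fctSim = 0, fscSim = 0, speciesDivergence = 0,
                   ploidyWeights = c(0, 1, 0), hybridFraction = 0,
                   dropoutProb = 0, seed = 77)
  sim <- simulateDataset(cfg)
  ds <- simGenotypes(sim)
  cod <- recodeDataset(ds, 4)
  fr <- estimateAlleleFrequencies(cod)
  fs <- simTruth(sim)$frequencies
  for (l in seq_along(lociNames(ds))) {
    est <- fr[[1]][[l]]
    truth <- popFrequencies(fs, 1, 1, 1, l)
    al <- union(names(est), names(truth))
    e <- stats::setNames(rep(0, length(al)), al); e[names(est)] <- est
    tt <- stats::setNames(rep(0, length(al)), al); tt[names(truth)] <- truth
    expect_lt(max(abs(e - tt)), 0.03)
  }
})

test_that("per-population frequency estimation covers all scored cells", {
  ds <- toyDataset(list(
    P1 = list(list(L1 = c(120L, 124L)), list(L1 = 120L)),
    P2 = list(list(L1 = 124L), list(L1 = integer(0)))), "L1")
  fr <- estimateAlleleFrequencies(recodeDataset(ds, 4))
  expect_equal(sum(fr$P1$L1), 1)
  expect_equal(unname(fr$P2$L1["124"]), 1)
  conv <- attr(fr, "converged")
  expect_true(all(conv[, "L1"]))
})
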