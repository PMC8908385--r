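## Forward simulator: chimeric, mixoploid blade genotypes with known truth.
##
## The life cycle being modelled: a sporophyte of ploidy 2, 4 or 8 undergoes
## meiosis; the four tetrad products grow together into one chimeric
## gametophytic blade. Genotyping a slice of that blade detects the union of
## the tetrad products' alleles, which (the four products jointly carrying
## every parental allele copy) is exactly the sporophyte's distinct-allele
## set, minus dropout.

#' Hierarchically structured allele frequencies (FrequencySet)
#'
#' @slot alleles integer allele sizes shared by all loci.
#' @slot rootFreqs list over loci of root frequency vectors.
#' @slot speciesFreqs,clusterFreqs,popFreqs nested lists
#'   (`[[species]]`, `[[species]][[cluster]]`, `[[species]][[cluster]][[pop]]`)
#'   of per-locus frequency vectors.
#' @export
setClass("FrequencySet", representation(
  alleles = "integer", rootFreqs = "list", speciesFreqs = "list",
  clusterFreqs = "list", popFreqs = "list"))

setValidity("FrequencySet", function(object) {
  ok <- function(v) abs(sum(v) - 1) < 1e-9 && all(v >= 0)
  for (l in object@rootFreqs) if (!ok(l)) return("root frequency vector does not sum to 1")
  for (s in object@popFreqs) for (cl in s) for (p in cl) for (v in p)
    if (!ok(v)) return("population frequency vector does not sum to 1")
  TRUE
})

#' @describeIn drawFrequencySet population-level frequency vector accessor
#' @param fs a FrequencySet
#' @param species,cluster,pop,locus integer indices
#' @export
popFrequencies <- function(fs, species, cluster, pop, locus = NULL) {
  p <- fs@popFreqs[[species]][[cluster]][[pop]]
  if (is.null(locus)) p else p[[locus]]
}

#' Draw a hierarchical Balding-Nichols frequency set
#'
#' Per locus, a root frequency vector is drawn symmetric-Dirichlet(1) over
#' the allele grid; species gene pools are drawn
#' Dirichlet(root * (1 - d)/d) with d = `speciesDivergence`; cluster vectors
#' from the species vector with parameter `fctSim`; population vectors from
#' the cluster vector with `fscSim`. A zero parameter copies the parent
#' vector exactly, so each differentiation parameter is the Wright-style F
#' the corresponding hierarchy level should recover.
#'
#' @param config a [SimConfig-class].
#' @return A [FrequencySet-class].
#' @export
drawFrequencySet <- function(config) {
  validObject(config)
  .withSeed(.fnv1a(paste0("freqset|", config@seed)), .drawFrequencySetImpl(config))
}

.drawFrequencySetImpl <- function(config) {
  A <- config@allelesPerLocus
  alleles <- config@alleleOffset + (seq_len(A) - 1L) * config@repeatUnit
  nm <- as.character(alleles)
  rootFreqs <- lapply(seq_len(config@nLoci), function(l)
    stats::setNames(.rdirichlet(rep(1, A)), nm))
  speciesFreqs <- lapply(seq_len(config@nSpecies), function(s)
    lapply(rootFreqs, function(r)
      stats::setNames(.bnChild(r, config@speciesDivergence), nm)))
  clusterFreqs <- lapply(seq_len(config@nSpecies), function(s)
    lapply(seq_len(config@clustersPerSpecies), function(cc)
      lapply(speciesFreqs[[s]], function(v)
        stats::setNames(.bnChild(v, config@fctSim), nm))))
  popFreqs <- lapply(seq_len(config@nSpecies), function(s)
    lapply(seq_len(config@clustersPerSpecies), function(cc)
      lapply(seq_len(config@popsPerCluster), function(p)
        lapply(clusterFreqs[[s]][[cc]], function(v)
          stats::setNames(.bnChild(v, config@fscSim), nm)))))
  new("FrequencySet", alleles = as.integer(alleles), rootFreqs = rootFreqs,
      speciesFreqs = speciesFreqs, clusterFreqs = clusterFreqs,
      popFreqs = popFreqs)
}

#' Simulate a sporophyte genotype by random union of gametes
#'
#' Each locus receives `ploidy/2` maternal and `ploidy/2` paternal allele
#' copies drawn i.i.d. from the designated frequency vectors. With an
#' interspecific `hybridFreqs` source, paternal copies come from the other
#' species' gene pool. Under within-population panmixia the selfing decision
#' does not change the allele-copy distribution (both gamete pools are the
#' same population vector); it is accepted for interface completeness.
#'
#' @param popFreqs list over loci of named allele frequency vectors (maternal).
#' @param ploidy 2, 4 or 8.
#' @param selfingRate probability the paternal pool is the maternal one.
#' @param hybridFreqs optional second species' per-locus frequency vectors.
#' @return A `SporophyteGenotype`: list with `ploidy` and per-locus allele
#'   multisets of size `ploidy`.
#' @export
makeSporophyte <- function(popFreqs, ploidy, selfingRate = 0, hybridFreqs = NULL) {
  if (!ploidy %in% c(2L, 4L, 8L)) stop("ploidy must be 2, 4 or 8")
  .assertProb(selfingRate, "selfingRate")
  half <- ploidy / 2L
  paternal <- if (!is.null(hybridFreqs)) hybridFreqs else popFreqs
  if (is.null(hybridFreqs) && stats::runif(1) < selfingRate) paternal <- popFreqs
  alleles <- vector("list", length(popFreqs))
  for (l in seq_along(popFreqs)) {
    pm <- popFreqs[[l]]; pp <- paternal[[l]]
    if (!length(pm) || !length(pp)) stop("empty frequency vector at locus ", l)
    mSizes <- as.integer(names(pm)); pSizes <- as.integer(names(pp))
    mat <- mSizes[sample.int(length(mSizes), half, replace = TRUE, prob = pm)]
    pat <- pSizes[sample.int(length(pSizes), half, replace = TRUE, prob = pp)]
    alleles[[l]] <- sort(c(mat, pat))
  }
  names(alleles) <- names(popFreqs)
  structure(list(ploidy = as.integer(ploidy), alleles = alleles),
            class = "SporophyteGenotype")
}

#' Observed blade genotype from a sporophyte (tetrad union with dropout)
#'
#' The four meiotic products of one sporophyte jointly carry all parental
#' allele copies, so the chimeric blade's observable allele set per locus is
#' the sporophyte's *distinct* allele set. Each distinct allele is then
#' independently lost with probability `dropoutProb` (subsuming both PCR
#' dropout and unsampled chimera sectors); a locus losing every allele is
#' recorded missing (`integer(0)`).
#'
#' @param sporophyte a `SporophyteGenotype` from [makeSporophyte()].
#' @param dropoutProb per-allele non-detection probability.
#' @return Named list over loci of sorted integer allele sets.
#' @export
bladeFromSporophyte <- function(sporophyte, dropoutProb = 0) {
  .assertProb(dropoutProb, "dropoutProb")
  lapply(sporophyte$alleles, function(a) {
    u <- sort(unique(a))
    if (dropoutProb > 0) u <- u[stats::runif(length(u)) >= dropoutProb]
    u
  })
}

#' Simulate a full chimeric-blade dataset with known truth
#'
#' Deterministic given `config@seed`. Per individual: sporophyte ploidy is
#' drawn from `ploidyWeights`, an interspecific-hybrid flag from
#' `hybridFraction`, the blade genotype via [bladeFromSporophyte()], and a
#' cpDNA haplotype from a population-specific pool of `cpHapsPerPool`
#' sequences generated by single-substitution steps from a species root
#' sequence (star-like, matching shallow empirical networks). Hybrid-lineage
#' blades carry the other species' haplotype with probability
#' `introgressionProb` (maternal inheritance with introgression).
#'
#' @param config a [SimConfig-class].
#' @return A [SimDataset-class].
#' @export
simulateDataset <- function(config) {
  validObject(config)
  fs <- drawFrequencySet(config)
  .withSeed(.fnv1a(paste0("dataset|", config@seed)), {
    nS <- config@nSpecies; nC <- config@clustersPerSpecies
    nP <- config@popsPerCluster; nI <- config@indsPerPop
    lociNm <- sprintf("L%02d", seq_len(config@nLoci))

    ## population table; clusters get a north/south flavoured latitude
    meta <- do.call(rbind, lapply(seq_len(nS), function(s)
      do.call(rbind, lapply(seq_len(nC), function(cc)
        do.call(rbind, lapply(seq_len(nP), function(p)
          data.frame(population = sprintf("S%dC%dP%d", s, cc, p),
                     cluster = sprintf("S%dC%d", s, cc),
                     species = sprintf("SP%d", s),
                     lat = 55 - 15 * (cc - 1) - 0.5 * p,
                     lon = -9 + 0.2 * s,
                     country = NA_character_,
                     stringsAsFactors = FALSE)))))))

    ## cpDNA pools: species root + single-step derivatives, per population
    bases <- c("A", "C", "G", "T")
    roots <- lapply(seq_len(nS), function(s)
      sample(bases, config@cpSeqLength, replace = TRUE))
    pools <- vector("list", nrow(meta))
    names(pools) <- meta$population
    for (r in seq_len(nrow(meta))) {
      s <- as.integer(sub("SP", "", meta$species[r]))
      pool <- vector("list", config@cpHapsPerPool)
      pool[[1]] <- roots[[s]]
      if (config@cpHapsPerPool > 1L) {
        sites <- sample.int(config@cpSeqLength, config@cpHapsPerPool - 1L)
        for (h in seq_len(config@cpHapsPerPool - 1L)) {
          v <- roots[[s]]
          v[sites[h]] <- sample(setdiff(bases, v[sites[h]]), 1L)
          pool[[h + 1L]] <- v
        }
      }
      names(pool) <- sprintf("%s_H%d", meta$population[r], seq_along(pool))
      pools[[r]] <- pool
    }

    nTot <- nrow(meta) * nI
    indId <- sprintf("IND%04d", seq_len(nTot))
    calls <- vector("list", nTot)
    truth <- data.frame(individual_id = indId,
                        population = rep(meta$population, each = nI),
                        cluster = rep(meta$cluster, each = nI),
                        species = rep(meta$species, each = nI),
                        ploidy = NA_integer_, hybrid = FALSE,
                        cpHaplotype = NA_character_,
                        cpSpecies = NA_character_,
                        stringsAsFactors = FALSE)
    cpSeq <- character(nTot)
    ploidies <- c(2L, 4L, 8L)

    for (i in seq_len(nTot)) {
      r <- match(truth$population[i], meta$population)
      s <- as.integer(sub("SP", "", meta$species[r]))
      cc <- as.integer(sub(".*C(\\d+)P.*", "\\1", meta$population[r]))
      p <- as.integer(sub(".*P(\\d+)$", "\\1", meta$population[r]))
      mFreqs <- stats::setNames(fs@popFreqs[[s]][[cc]][[p]], lociNm)
      ploidy <- sample(ploidies, 1L, prob = config@ploidyWeights)
      hybrid <- nS > 1L && stats::runif(1) < config@hybridFraction
      hybFreqs <- NULL
      if (hybrid) {
        s2 <- if (s == nS) 1L else s + 1L
        hybFreqs <- stats::setNames(fs@popFreqs[[s2]][[cc]][[p]], lociNm)
      }
      sp <- makeSporophyte(mFreqs, ploidy, config@selfingRate, hybFreqs)
      calls[[i]] <- bladeFromSporophyte(sp, config@dropoutProb)

      ## maternal cpDNA, introgressed along hybrid lineages
      cpFrom <- truth$population[i]
      cpSp <- truth$species[i]
      if (hybrid && stats::runif(1) < config@introgressionProb) {
        s2 <- if (s == nS) 1L else s + 1L
        cpFrom <- sprintf("S%dC%dP%d", s2, cc, p)
        cpSp <- sprintf("SP%d", s2)
      }
      pool <- pools[[cpFrom]]
      h <- sample.int(length(pool), 1L)
      truth$ploidy[i] <- ploidy
      truth$hybrid[i] <- hybrid
      truth$cpHaplotype[i] <- names(pool)[h]
      truth$cpSpecies[i] <- cpSp
      cpSeq[i] <- paste(pool[[h]], collapse = "")
    }

    gd <- genotypeDataset(
      individuals = data.frame(individual_id = indId,
                               population = truth$population,
                               species = truth$species,
                               stringsAsFactors = FALSE),
      loci = lociNm, calls = calls)
    cp <- Biostrings::DNAStringSet(stats::setNames(cpSeq, indId))
    new("SimDataset", genotypes = gd, meta = meta, cpSequences = cp,
        truth = list(individuals = truth, frequencies = fs, config = config))
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the native genotype CSV and population-metadata CSV, a FASTA of the
#' per-individual cpDNA sequences (headers `id population`), and a JSON
#' truth file (per-individual ploidy/hybrid/haplotype plus the seed).
#'
#' @param sim a [SimDataset-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeSimDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gPath <- file.path(dir, "genotypes.csv")
  mPath <- file.path(dir, "populations.csv")
  fPath <- file.path(dir, "cp_sequences.fasta")
  tPath <- file.path(dir, "truth.json")
  writeGenotypes(sim@genotypes, gPath)
  utils::write.csv(sim@meta, mPath, row.names = FALSE, quote = FALSE)
  hdr <- paste(names(sim@cpSequences),
               sim@truth$individuals$population[
                 match(names(sim@cpSequences), sim@truth$individuals$individual_id)])
  seqs <- sim@cpSequences
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, fPath, width = 80L)
  cfg <- sim@truth$config
  jsonlite::write_json(list(
    seed = cfg@seed,
    individuals = sim@truth$individuals), tPath, auto_unbox = TRUE, digits = NA)
  invisible(c(gPath, mPath, fPath, tPath))
}
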