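#' @import methods
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for chimeric, mixoploid blade datasets
#'
#' Holds every parameter of the forward simulator: the hierarchical
#' population design (species / clusters / populations / individuals), the
#' microsatellite panel, hierarchical differentiation parameters, the
#' sporophyte ploidy mixture, hybridisation and chloroplast introgression
#' rates, allele dropout, and the cpDNA model.
#'
#' Differentiation parameters follow a nested Balding-Nichols model:
#' `speciesDivergence` separates the species gene pools from a common root,
#' `fctSim` separates regional clusters within species and `fscSim` separates
#' populations within clusters. Each is the F-statistic the corresponding
#' AMOVA layer should recover.
#'
#' @slot nSpecies,clustersPerSpecies,popsPerCluster,indsPerPop integer design.
#' @slot nLoci,allelesPerLocus microsatellite panel size.
#' @slot repeatUnit,alleleOffset allele sizes are `alleleOffset + k * repeatUnit` bp.
#' @slot fctSim,fscSim,speciesDivergence differentiation parameters in [0, 1).
#' @slot ploidyWeights probability vector over sporophyte ploidies 2, 4, 8.
#' @slot selfingRate probability that the paternal gamete pool is the maternal one.
#' @slot hybridFraction probability that a sporophyte is an interspecific hybrid.
#' @slot introgressionProb probability that a hybrid-lineage blade carries the
#'   other species' chloroplast haplotype.
#' @slot dropoutProb per-allele non-detection probability.
#' @slot cpSeqLength,cpHapsPerPool cpDNA sequence length (bp) and pool size.
#' @slot seed integer RNG seed; the whole dataset is a pure function of it.
#' @export
setClass("SimConfig", representation(
  nSpecies = "integer", clustersPerSpecies = "integer",
  popsPerCluster = "integer", indsPerPop = "integer",
  nLoci = "integer", allelesPerLocus = "integer",
  repeatUnit = "integer", alleleOffset = "integer",
  fctSim = "numeric", fscSim = "numeric", speciesDivergence = "numeric",
  ploidyWeights = "numeric", selfingRate = "numeric",
  hybridFraction = "numeric", introgressionProb = "numeric",
  dropoutProb = "numeric", cpSeqLength = "integer", cpHapsPerPool = "integer",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  cnt <- c(nSpecies = object@nSpecies, clustersPerSpecies = object@clustersPerSpecies,
           popsPerCluster = object@popsPerCluster, indsPerPop = object@indsPerPop,
           nLoci = object@nLoci, allelesPerLocus = object@allelesPerLocus,
           repeatUnit = object@repeatUnit, cpSeqLength = object@cpSeqLength,
           cpHapsPerPool = object@cpHapsPerPool)
  if (any(cnt < 1L)) msgs <- c(msgs, "all counts must be >= 1")
  for (f in c("fctSim", "fscSim", "speciesDivergence")) {
    v <- slot(object, f)
    if (!is.finite(v) || v < 0 || v >= 1)
      msgs <- c(msgs, sprintf("%s must lie in [0, 1)", f))
  }
  for (f in c("selfingRate", "hybridFraction", "introgressionProb", "dropoutProb")) {
    v <- slot(object, f)
    if (!is.finite(v) || v < 0 || v > 1)
      msgs <- c(msgs, sprintf("%s must lie in [0, 1]", f))
  }
  if (length(object@ploidyWeights) != 3L || any(object@ploidyWeights < 0) ||
      abs(sum(object@ploidyWeights) - 1) > 1e-12)
    msgs <- c(msgs, "ploidyWeights must be 3 non-negative values summing to 1 (ploidies 2, 4, 8)")
  if (length(msgs)) msgs else TRUE
})

#' Build a simulation configuration
#'
#' Defaults describe the study system the simulator emulates: two species
#' gene pools, two regional clusters per species (north/south), moderate
#' within-species structure with higher differentiation among clusters than
#' among populations, a panel of 10 trinucleotide microsatellites, a
#' sporophyte ploidy mixture dominated by diploids, rare interspecific
#' hybrids, and maternally inherited cpDNA of 1141 bp with occasional
#' introgression along hybrid lineages.
#'
#' @param nSpecies,clustersPerSpecies,popsPerCluster,indsPerPop design counts.
#' @param nLoci,allelesPerLocus panel size.
#' @param repeatUnit,alleleOffset allele size grid in bp.
#' @param fctSim,fscSim,speciesDivergence Balding-Nichols differentiation in [0,1).
#' @param ploidyWeights probabilities of sporophyte ploidy 2, 4, 8.
#' @param selfingRate,hybridFraction,introgressionProb,dropoutProb probabilities.
#' @param cpSeqLength,cpHapsPerPool cpDNA model.
#' @param seed integer seed.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(nSpecies = 2L, clustersPerSpecies = 2L, popsPerCluster = 3L,
                      indsPerPop = 18L, nLoci = 10L, allelesPerLocus = 8L,
                      repeatUnit = 3L, alleleOffset = 100L,
                      fctSim = 0.20, fscSim = 0.08, speciesDivergence = 0.25,
                      ploidyWeights = c(0.5, 0.35, 0.15), selfingRate = 0.1,
                      hybridFraction = 0.02, introgressionProb = 0.5,
                      dropoutProb = 0.05, cpSeqLength = 1141L, cpHapsPerPool = 3L,
                      seed = 1L) {
  new("SimConfig",
      nSpecies = as.integer(nSpecies), clustersPerSpecies = as.integer(clustersPerSpecies),
      popsPerCluster = as.integer(popsPerCluster), indsPerPop = as.integer(indsPerPop),
      nLoci = as.integer(nLoci), allelesPerLocus = as.integer(allelesPerLocus),
      repeatUnit = as.integer(repeatUnit), alleleOffset = as.integer(alleleOffset),
      fctSim = fctSim, fscSim = fscSim, speciesDivergence = speciesDivergence,
      ploidyWeights = as.numeric(ploidyWeights),
      selfingRate = selfingRate, hybridFraction = hybridFraction,
      introgressionProb = introgressionProb, dropoutProb = dropoutProb,
      cpSeqLength = as.integer(cpSeqLength), cpHapsPerPool = as.integer(cpHapsPerPool),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:",
      object@nSpecies, "species x", object@clustersPerSpecies, "clusters x",
      object@popsPerCluster, "pops x", object@indsPerPop, "inds;",
      object@nLoci, "loci\n")
  cat("  divergence (species/cluster/pop):", object@speciesDivergence,
      object@fctSim, object@fscSim, "\n")
  cat("  ploidy weights (2x,4x,8x):", paste(object@ploidyWeights, collapse = ", "),
      " seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## GenotypeDataset
## ---------------------------------------------------------------------------

#' Multi-allele microsatellite genotypes with unknown dosage
#'
#' The central genotype container: one row of metadata per individual blade
#' and, per individual and locus, the *set* of distinct allele sizes (bp)
#' detected. Because the blades are chimeric and possibly mixoploid, the copy
#' number of each allele is unknown; a locus may show 0 (missing) to 8
#' distinct alleles.
#'
#' @slot individuals data.frame with columns `individual_id`, `population`,
#'   `species`.
#' @slot loci character vector of locus names.
#' @slot calls list (one element per individual) of named lists (one per
#'   locus) of sorted integer allele sizes; `integer(0)` marks a missing locus.
#' @export
setClass("GenotypeDataset", representation(
  individuals = "data.frame", loci = "character", calls = "list"))

setValidity("GenotypeDataset", function(object) {
  msgs <- character()
  ind <- object@individuals
  need <- c("individual_id", "population", "species")
  if (!all(need %in% names(ind)))
    return(paste("individuals must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(ind$individual_id)) msgs <- c(msgs, "individual_id values must be unique")
  if (length(object@calls) != nrow(ind))
    msgs <- c(msgs, "calls must have one element per individual")
  for (i in seq_along(object@calls)) {
    ci <- object@calls[[i]]
    if (!all(object@loci %in% names(ci))) {
      msgs <- c(msgs, sprintf("individual %d lacks entries for all loci", i)); break
    }
    for (l in object@loci) {
      a <- ci[[l]]
      if (length(a)) {
        if (any(a <= 0) || anyDuplicated(a)) {
          msgs <- c(msgs, "allele sizes must be positive and distinct"); break
        }
        if (length(a) > 8L) { msgs <- c(msgs, "more than 8 distinct alleles at a locus"); break }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeDataset
#' @param individuals data.frame with `individual_id`, `population`, `species`.
#' @param loci character vector of locus names.
#' @param calls nested list of integer allele-size vectors, `calls[[i]][[locus]]`.
#' @return A [GenotypeDataset-class].
#' @export
genotypeDataset <- function(individuals, loci, calls) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  calls <- lapply(calls, function(ci) {
    ci <- lapply(ci, function(a) sort(unique(as.integer(a))))
    full <- stats::setNames(rep(list(integer(0)), length(loci)), loci)
    keep <- intersect(names(ci), loci)
    full[keep] <- ci[keep]
    full
  })
  new("GenotypeDataset", individuals = individuals, loci = as.character(loci),
      calls = calls)
}

#' @describeIn genotypeDataset number of individuals
#' @param x a GenotypeDataset
#' @export
nInd <- function(x) nrow(x@individuals)

#' @describeIn genotypeDataset locus names
#' @export
lociNames <- function(x) x@loci

#' @describeIn genotypeDataset per-individual metadata data.frame
#' @export
indMeta <- function(x) x@individuals

#' @describeIn genotypeDataset allele set for one individual x locus
#' @param individual individual id (character) or index
#' @param locus locus name
#' @export
alleleCalls <- function(x, individual, locus) {
  i <- if (is.character(individual))
    match(individual, x@individuals$individual_id) else individual
  x@calls[[i]][[locus]]
}

setMethod("show", "GenotypeDataset", function(object) {
  cat("GenotypeDataset:", nrow(object@individuals), "individuals,",
      length(object@loci), "loci,",
      length(unique(object@individuals$population)), "populations\n")
  maxA <- max(vapply(object@calls, function(ci) max(lengths(ci)), 0L))
  cat("  max distinct alleles at a locus:", maxA, "\n")
})

## ---------------------------------------------------------------------------
## PloidyCoding
## ---------------------------------------------------------------------------

#' Genotypes recoded under an assumed ploidy
#'
#' The result of assumed-ploidy recoding: per individual and locus, the
#' retained allele set (at most `ploidy` distinct alleles, uniformly
#' subsampled when the observed set is larger) plus a flag marking cells
#' whose allele dosage remains ambiguous under the assumed ploidy.
#'
#' @slot ploidy assumed ploidy, 2, 4 or 8.
#' @slot retained nested list parallel to the source dataset's calls.
#' @slot ambiguous logical matrix individuals x loci.
#' @slot seed the subsampling seed.
#' @slot individuals,loci copied from the source dataset.
#' @export
setClass("PloidyCoding", representation(
  ploidy = "integer", retained = "list", ambiguous = "matrix",
  seed = "integer", individuals = "data.frame", loci = "character"))

setValidity("PloidyCoding", function(object) {
  if (!object@ploidy %in% c(2L, 4L, 8L)) return("ploidy must be 2, 4 or 8")
  for (ci in object@retained)
    for (a in ci) if (length(a) > object@ploidy)
      return("retained set larger than assumed ploidy")
  TRUE
})

setMethod("show", "PloidyCoding", function(object) {
  cat("PloidyCoding: assumed ploidy", object@ploidy, "x,",
      nrow(object@individuals), "individuals,", length(object@loci), "loci\n")
  cat("  ambiguous-dosage cells:", sum(object@ambiguous), "/",
      length(object@ambiguous), "\n")
})

#' @describeIn recodeDataset assumed ploidy of a coding
#' @export
assumedPloidy <- function(coding) coding@ploidy

## ---------------------------------------------------------------------------
## AmovaResult
## ---------------------------------------------------------------------------

#' Four-level AMOVA result
#'
#' Method-of-moments variance components for the hierarchy allele copies
#' within individuals / individuals within populations / populations within
#' groups / among groups, with the fixation indices F_IT, F_IS, F_SC, F_CT,
#' percent variance per level, and dispersion over loci and over
#' dosage-resolution replicates.
#'
#' Components are *not* truncated at zero; negative method-of-moments
#' estimates propagate. Percent variance sums to 100.
#'
#' @slot components named numeric: sigma2 for groups, pops, individuals, within.
#' @slot fStats named numeric: F_IT, F_IS, F_SC, F_CT.
#' @slot pctVariance named numeric, sums to 100.
#' @slot sdLoci,sdReplicates named numeric SDs of the F statistics.
#' @slot perLocus data.frame of per-locus F statistics (replicate-averaged).
#' @slot perReplicate data.frame of per-replicate multilocus F statistics.
#' @slot ploidy assumed ploidy used for the expansion.
#' @export
setClass("AmovaResult", representation(
  components = "numeric", fStats = "numeric", pctVariance = "numeric",
  sdLoci = "numeric", sdReplicates = "numeric",
  perLocus = "data.frame", perReplicate = "data.frame", ploidy = "integer"))

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (assumed ploidy ", object@ploidy, "x)\n", sep = "")
  lev <- c("Among groups", "Among pops within groups",
           "Among individuals within pops", "Within individuals")
  comp <- object@components
  pct <- object@pctVariance
  for (i in seq_along(lev))
    cat(sprintf("  %-32s sigma2 = %8.4f  (%5.1f%%)\n", lev[i], comp[i], pct[i]))
  f <- object@fStats
  cat(sprintf("  F_CT = %.3f  F_SC = %.3f  F_IS = %.3f  F_IT = %.3f\n",
              f["F_CT"], f["F_SC"], f["F_IS"], f["F_IT"]))
})

#' @describeIn amova extract the fixation indices of an AmovaResult
#' @param result an AmovaResult
#' @export
fStatistics <- function(result) result@fStats

#' @describeIn amova extract the variance components
#' @export
varianceComponents <- function(result) result@components

## ---------------------------------------------------------------------------
## Sequence alignment + haplotypes
## ---------------------------------------------------------------------------

#' Aligned cpDNA sequences with sampling locations
#'
#' Thin wrapper around a [Biostrings::DNAStringSet] of equal-width aligned
#' sequences, with a parallel location code per record.
#'
#' @slot sequences DNAStringSet, all of equal width.
#' @slot location character vector of location codes, one per record.
#' @export
setClass("SeqAlignment", representation(
  sequences = "ANY", location = "character"))

setValidity("SeqAlignment", function(object) {
  s <- object@sequences
  if (!methods::is(s, "DNAStringSet")) return("sequences must be a DNAStringSet")
  if (length(s) && length(unique(Biostrings::width(s))) != 1L)
    return("alignment is ragged: sequences differ in length")
  if (length(object@location) != length(s))
    return("one location code required per sequence")
  TRUE
})

#' Construct a SeqAlignment
#' @param sequences DNAStringSet or named character vector of aligned sequences.
#' @param location character location codes (defaults to record names).
#' @return A [SeqAlignment-class].
#' @export
seqAlignment <- function(sequences, location = NULL) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(location)) location <- rep(NA_character_, length(sequences))
  new("SeqAlignment", sequences = sequences, location = as.character(location))
}

setMethod("show", "SeqAlignment", function(object) {
  cat("SeqAlignment:", length(object@sequences), "sequences of width",
      if (length(object@sequences)) Biostrings::width(object@sequences)[1] else 0, "\n")
})

#' @describeIn seqAlignment number of aligned positions
#' @param x a SeqAlignment
#' @export
alignmentWidth <- function(x)
  if (length(x@sequences)) Biostrings::width(x@sequences)[1] else 0L

#' Collapsed haplotypes with per-location counts
#'
#' @slot haplotypeId character labels (A, B, ...), in order of first appearance.
#' @slot representative character representative sequence per haplotype.
#' @slot members list of input record ids per haplotype.
#' @slot countsByLocation integer matrix haplotypes x locations.
#' @export
setClass("HaplotypeTable", representation(
  haplotypeId = "character", representative = "character",
  members = "list", countsByLocation = "matrix"))

setValidity("HaplotypeTable", function(object) {
  n <- length(object@haplotypeId)
  if (length(object@representative) != n || length(object@members) != n ||
      nrow(object@countsByLocation) != n)
    return("slot lengths disagree")
  if (sum(object@countsByLocation) != sum(lengths(object@members)))
    return("location counts do not sum to the number of member records")
  TRUE
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", length(object@haplotypeId), "haplotypes,",
      sum(lengths(object@members)), "sequences\n")
  print(data.frame(haplotype = object@haplotypeId, n = lengths(object@members)))
})

#' @describeIn collapseHaplotypes number of haplotypes in a table
#' @export
nHaplotypes <- function(table) length(table@haplotypeId)

#' @describeIn collapseHaplotypes per-haplotype total counts
#' @export
haplotypeCounts <- function(table)
  stats::setNames(lengths(table@members), table@haplotypeId)

#' Mutation-step haplotype network
#'
#' @slot edges data.frame with columns `from`, `to`, `steps`.
#' @slot nodes data.frame with columns `haplotype`, `n`.
#' @slot maxSteps the connection limit used (NA = unlimited).
#' @export
setClass("HaploNetwork", representation(
  edges = "data.frame", nodes = "data.frame", maxSteps = "numeric"))

setMethod("show", "HaploNetwork", function(object) {
  cat("HaploNetwork:", nrow(object@nodes), "haplotypes,",
      nrow(object@edges), "edges",
      if (is.finite(object@maxSteps)) sprintf("(connection limit %d steps)",
                                              as.integer(object@maxSteps)) else "",
      "\n")
})

## ---------------------------------------------------------------------------
## SimDataset
## ---------------------------------------------------------------------------

#' Simulated chimeric-blade dataset with known truth
#'
#' Bundles the observable data (genotypes, population metadata, cpDNA
#' sequences) with the generating truth (per-individual sporophyte ploidy,
#' hybrid flags, haplotype ids, the frequency set and the configuration).
#'
#' @slot genotypes a [GenotypeDataset-class].
#' @slot meta data.frame of population metadata (population, cluster, species,
#'   lat, lon, country).
#' @slot cpSequences DNAStringSet of per-individual cpDNA haplotype sequences.
#' @slot truth list: `individuals` data.frame (ploidy, hybrid, cpHaplotype,
#'   cpSpecies, cluster, species), `frequencies` the FrequencySet, `config`.
#' @export
setClass("SimDataset", representation(
  genotypes = "GenotypeDataset", meta = "data.frame",
  cpSequences = "ANY", truth = "list"))

setMethod("show", "SimDataset", function(object) {
  cat("SimDataset:\n  ")
  show(object@genotypes)
  tr <- object@truth$individuals
  cat("  sporophyte ploidies:",
      paste(sprintf("%dx:%d", c(2L, 4L, 8L), tabulate(match(tr$ploidy, c(2L, 4L, 8L)), 3L)),
            collapse = " "), "\n")
  cat("  hybrids:", sum(tr$hybrid), " cp-introgressed:",
      sum(tr$cpSpecies != tr$species), "\n")
})

#' @describeIn simulateDataset genotypes of a simulated dataset
#' @export
simGenotypes <- function(sim) sim@genotypes

#' @describeIn simulateDataset generating truth of a simulated dataset
#' @export
simTruth <- function(sim) sim@truth

#' @describeIn simulateDataset population metadata of a simulated dataset
#' @export
simMeta <- function(sim) sim@meta
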