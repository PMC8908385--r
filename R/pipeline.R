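## End-to-end orchestration: simulate or load -> recode at 2x/4x/8x ->
## EM frequencies -> diversity / pairwise / AMOVA / PCA -> cpDNA haplotype
## network, with a manifest recording seeds and file hashes.

#' Build a pipeline configuration
#'
#' Either `sim` (a [SimConfig-class]) or `genotypesPath` (+
#' `populationsPath`) must be given. Hierarchies are declared, not
#' inferred: each entry of `hierarchies` is a named character vector
#' mapping population codes to group labels, or one of the keywords
#' `"species"` / `"cluster"` which are resolved from the population
#' metadata.
#'
#' @param sim optional [SimConfig-class] for simulated input.
#' @param genotypesPath,populationsPath,fastaPath optional file inputs.
#' @param assumedPloidies subset of c(2, 4, 8).
#' @param replicates dosage/subsample replicates for the AMOVA.
#' @param seed master seed.
#' @param hierarchies named list of grouping schemes (see Details).
#' @param maxSteps optional connection limit for the haplotype network.
#' @param outDir optional output directory for tables + manifest.
#' @return List of class `PipelineConfig`.
#' @export
pipelineConfig <- function(sim = NULL, genotypesPath = NULL,
                           populationsPath = NULL, fastaPath = NULL,
                           assumedPloidies = c(2L, 4L, 8L), replicates = 10L,
                           seed = 1L, hierarchies = list(species = "species"),
                           maxSteps = NULL, outDir = NULL) {
  if (is.null(sim) && is.null(genotypesPath))
    stop("either 'sim' or 'genotypesPath' is required")
  if (!all(assumedPloidies %in% c(2L, 4L, 8L)) || !length(assumedPloidies))
    stop("assumedPloidies must be a non-empty subset of {2, 4, 8}")
  structure(list(sim = sim, genotypesPath = genotypesPath,
                 populationsPath = populationsPath, fastaPath = fastaPath,
                 assumedPloidies = as.integer(assumedPloidies),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 hierarchies = hierarchies, maxSteps = maxSteps,
                 outDir = outDir),
            class = "PipelineConfig")
}

.resolveHierarchy <- function(spec, meta) {
  if (is.character(spec) && length(spec) == 1L && spec %in% c("species", "cluster")) {
    if (!spec %in% names(meta))
      stop("metadata lacks a '", spec, "' column for the requested hierarchy")
    return(stats::setNames(as.character(meta[[spec]]), meta$population))
  }
  if (is.null(names(spec))) stop("hierarchy must be a named population->group vector")
  spec
}

#' Run the full analysis pipeline
#'
#' For each assumed ploidy: recode, estimate EM allele frequencies, build
#' the diversity table, pairwise Gst and Jost's D, one AMOVA per declared
#' hierarchy, and the PCA. A cross-ploidy comparison table of F-statistics
#' is assembled (the robustness check: how much do the fixation indices
#' move when the assumed ploidy changes?). With cpDNA input (or simulated
#' data), haplotypes are collapsed and the minimum-spanning network built.
#' When `outDir` is set, all tables are written as CSV under it together
#' with a `manifest.json` recording the seed, the package version and an
#' md5 per artifact. Deterministic given the config.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @param verbose log per-stage progress to standard error.
#' @return Invisibly, a list with `data`, `byPloidy` (per-ploidy results),
#'   `fComparison` (cross-ploidy F-statistics per hierarchy), `haplotypes`,
#'   `network`, `manifest`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(sprintf("[%s] %s",
                                                    format(Sys.time(), "%H:%M:%S"),
                                                    paste0(...)))
  t0 <- proc.time()[3]
  stage <- function(name, expr) {
    say("stage ", name, " ...")
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage ", name, " done (", round(proc.time()[3] - t0, 1), "s elapsed)")
    out
  }

  ## ---- input -------------------------------------------------------------
  simData <- NULL
  if (!is.null(config$sim)) {
    simData <- stage("simulate", simulateDataset(config$sim))
    ds <- simData@genotypes
    meta <- simData@meta
    aln <- seqAlignment(simData@cpSequences,
                        simData@truth$individuals$population)
  } else {
    ds <- stage("load", readGenotypes(config$genotypesPath))
    meta <- if (!is.null(config$populationsPath))
      utils::read.csv(config$populationsPath, stringsAsFactors = FALSE)
    else unique(data.frame(population = ds@individuals$population,
                           species = ds@individuals$species,
                           stringsAsFactors = FALSE))
    aln <- if (!is.null(config$fastaPath)) readFastaAlignment(config$fastaPath)
           else NULL
  }

  ## ---- per-ploidy analyses ------------------------------------------------
  byPloidy <- list()
  for (m in config$assumedPloidies) {
    key <- paste0("ploidy", m)
    byPloidy[[key]] <- stage(key, {
      coding <- recodeDataset(ds, m, seed = config$seed)
      freqs <- estimateAlleleFrequencies(coding)
      div <- diversityTable(coding, freqs)
      gst <- pairwiseDifferentiation(freqs, "Gst")
      jost <- pairwiseDifferentiation(freqs, "JostD")
      amovas <- lapply(config$hierarchies, function(h)
        amova(coding, .resolveHierarchy(h, meta),
              replicates = config$replicates, seed = config$seed))
      pca <- pcaGenotypes(coding)
      list(coding = coding, frequencies = freqs, diversity = div,
           gst = gst, jostD = jost, amova = amovas, pca = pca)
    })
  }

  ## ---- cross-ploidy F comparison -------------------------------------------
  fComparison <- do.call(rbind, lapply(names(config$hierarchies), function(hn)
    do.call(rbind, lapply(config$assumedPloidies, function(m) {
      f <- fStatistics(byPloidy[[paste0("ploidy", m)]]$amova[[hn]])
      data.frame(hierarchy = hn, ploidy = m, t(f), row.names = NULL)
    }))))

  ## ---- cpDNA --------------------------------------------------------------
  haplotypes <- network <- NULL
  if (!is.null(aln)) {
    haplotypes <- stage("haplotypes", collapseHaplotypes(aln))
    network <- stage("network",
                     minimumSpanningNetwork(haplotypes, config$maxSteps))
  }

  ## ---- outputs -------------------------------------------------------------
  manifest <- NULL
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    wr <- function(df, name) {
      p <- file.path(config$outDir, name)
      utils::write.csv(df, p, row.names = FALSE)
      paths <<- c(paths, p); p
    }
    for (m in config$assumedPloidies) {
      res <- byPloidy[[paste0("ploidy", m)]]
      wr(res$diversity, sprintf("diversity_%dx.csv", m))
      wr(as.data.frame(res$gst$values), sprintf("pairwise_gst_%dx.csv", m))
      wr(as.data.frame(res$jostD$values), sprintf("pairwise_jostd_%dx.csv", m))
      wr(data.frame(res$pca$scores), sprintf("pca_scores_%dx.csv", m))
      for (hn in names(res$amova)) {
        a <- res$amova[[hn]]
        wr(data.frame(level = names(varianceComponents(a)),
                      sigma2 = varianceComponents(a),
                      pct = a@pctVariance),
           sprintf("amova_components_%s_%dx.csv", hn, m))
      }
    }
    wr(fComparison, "f_statistics_by_ploidy.csv")
    if (!is.null(network)) {
      p2 <- writeHaploNetwork(network, haplotypes, config$outDir)
      paths <- c(paths, p2)
    }
    manifest <- list(seed = config$seed,
                     assumedPloidies = config$assumedPloidies,
                     replicates = config$replicates,
                     package = as.character(utils::packageVersion("ChimeraPopGen")),
                     files = lapply(stats::setNames(paths, basename(paths)),
                                    function(p) unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(data = ds, meta = meta, sim = simData, byPloidy = byPloidy,
                 fComparison = fComparison, haplotypes = haplotypes,
                 network = network, manifest = manifest))
}
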