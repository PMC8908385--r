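## Four-level hierarchical AMOVA on assumed-ploidy codings.
##
## Each individual is expanded to m allele copies per locus (unknown dosage
## resolved per replicate by a uniform draw over the compatible dosage
## multisets), squared distance between copies is 0/1 identity-in-state,
## and nested method-of-moments ANOVA with the standard unequal-size
## coefficients yields variance components for
##   among groups / among populations within groups /
##   among individuals within populations / within individuals
## and the fixation indices F_CT, F_SC, F_IS, F_IT. No permutation p-values
## are computed: when the grouping itself comes from a clustering of the
## same data, testing it would be circular.

## sum over unordered pairs of 0/1 mismatches within a cell, divided by the
## cell size: for allele counts n_a in a cell of n copies this is
## (C(n,2) - sum_a C(n_a,2)) / n
.ssdCell <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(0)
  (n * (n - 1) / 2 - sum(counts * (counts - 1) / 2)) / n
}

## per-locus variance components for one dosage-resolved allele-copy matrix
## copies: integer matrix (individuals x m), NA rows = missing individuals
## pop, grp: per-individual factors
.amovaLocus <- function(copies, pop, grp) {
  keep <- !is.na(copies[, 1L])
  if (sum(keep) < 2L) return(NULL)
  copies <- copies[keep, , drop = FALSE]
  pop <- droplevels(factor(pop[keep]))
  grp <- droplevels(factor(grp[keep]))
  m <- ncol(copies)
  I <- nrow(copies); P <- nlevels(pop); G <- nlevels(grp)
  N <- I * m
  alleles <- sort(unique(as.vector(copies)))
  countsOf <- function(rows) tabulate(match(as.vector(copies[rows, , drop = FALSE]),
                                            alleles), length(alleles))
  ## sums of squared deviations by nesting level
  ssdWI <- sum(vapply(seq_len(I), function(i)
    .ssdCell(tabulate(match(copies[i, ], alleles), length(alleles))), 0))
  ssdWP <- sum(vapply(levels(pop), function(pp)
    .ssdCell(countsOf(which(pop == pp))), 0))
  ssdWG <- sum(vapply(levels(grp), function(gg)
    .ssdCell(countsOf(which(grp == gg))), 0))
  ssdT <- .ssdCell(countsOf(seq_len(I)))
  ssAI <- ssdWP - ssdWI
  ssAP <- ssdWG - ssdWP
  ssAG <- ssdT - ssdWG

  dfWI <- N - I; dfAI <- I - P; dfAP <- P - G; dfAG <- G - 1L
  nP <- m * as.vector(table(pop))          # copies per population
  nG <- m * as.vector(table(grp))          # copies per group
  grpOfPop <- vapply(levels(pop), function(pp)
    as.character(grp[which(pop == pp)[1]]), "")

  ## Searle-style coefficients for the fully nested random model
  A <- sum((m^2 * as.vector(table(pop))) / nP)            # sum_p sum_i n_i^2 / n_p
  B <- sum((m^2 * as.vector(table(grp))) / nG)
  Cc <- I * m^2 / N
  Dd <- sum(tapply(nP^2, grpOfPop, sum)[levels(grp)] / nG)
  Ee <- sum(nP^2) / N
  Ff <- sum(nG^2) / N

  sig4 <- if (dfWI > 0) ssdWI / dfWI else 0
  sig3 <- if (dfAI > 0) (ssAI / dfAI - sig4) / ((N - A) / dfAI) else 0
  sig2 <- if (dfAP > 0) {
    k2 <- (A - B) / dfAP; k3 <- (N - Dd) / dfAP
    (ssAP / dfAP - sig4 - k2 * sig3) / k3
  } else 0
  sig1 <- if (dfAG > 0) {
    k4 <- (B - Cc) / dfAG; k5 <- (Dd - Ee) / dfAG; k6 <- (N - Ff) / dfAG
    (ssAG / dfAG - sig4 - k4 * sig3 - k5 * sig2) / k6
  } else 0
  c(groups = sig1, pops = sig2, individuals = sig3, within = sig4)
}

## F statistics from components, with the 0/0 -> 0 convention; all-NaN with
## warning when total variance is 0
.fFromComponents <- function(comp, warnZero = TRUE) {
  tot <- sum(comp)
  ratio0 <- function(num, den) if (den == 0) 0 else num / den
  if (tot == 0) {
    if (warnZero)
      warning("total variance is zero; F-statistics undefined (NaN)")
    return(c(F_IT = NaN, F_IS = NaN, F_SC = NaN, F_CT = NaN))
  }
  c(F_IT = (comp[["groups"]] + comp[["pops"]] + comp[["individuals"]]) / tot,
    F_IS = ratio0(comp[["individuals"]], comp[["individuals"]] + comp[["within"]]),
    F_SC = ratio0(comp[["pops"]],
                  comp[["pops"]] + comp[["individuals"]] + comp[["within"]]),
    F_CT = comp[["groups"]] / tot)
}

## resolve dosage for one replicate: list over loci of (ind x m) matrices
.resolveDosage <- function(coding, repSeed) {
  ind <- coding@individuals; loci <- coding@loci; m <- coding@ploidy
  .withSeed(repSeed, {
    lapply(loci, function(l) {
      mat <- matrix(NA_integer_, nrow(ind), m)
      for (i in seq_len(nrow(ind))) {
        a <- coding@retained[[i]][[l]]
        if (!length(a)) next
        gens <- enumerateCompatibleGenotypes(a, m)
        g <- if (length(gens) > 1L) gens[[sample.int(length(gens), 1L)]]
             else gens[[1L]]
        mat[i, ] <- g
      }
      mat
    })
  })
}

#' Hierarchical AMOVA under an assumed ploidy
#'
#' Runs the four-level AMOVA on a [PloidyCoding-class]: allele copies within
#' individuals, individuals within populations, populations within groups,
#' among groups. Unknown dosage is resolved independently in each of
#' `replicates` passes by a uniform draw among the dosage multisets
#' compatible with each retained allele set; reported values are means over
#' replicates, with SDs over replicates and over loci. Per-locus variance
#' components use each locus's own non-missing sample sizes and are summed
#' over loci for the multilocus statistics. Components may be negative
#' (method of moments) and are propagated, not truncated.
#'
#' @param coding a [PloidyCoding-class].
#' @param groups named character vector mapping population codes to group
#'   labels, or a data.frame with columns `population` and `group`.
#' @param replicates number of dosage-resolution replicates.
#' @param seed integer seed for the dosage draws.
#' @return An [AmovaResult-class].
#' @export
amova <- function(coding, groups, replicates = 10L, seed = 1L) {
  ind <- coding@individuals
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$population))
  pops <- unique(ind$population)
  if (!all(pops %in% names(groups)))
    stop("groups must cover every population; missing: ",
         paste(setdiff(pops, names(groups)), collapse = ", "))
  grpOfPop <- groups[pops]
  if (length(unique(grpOfPop)) < 2L) stop("need at least 2 groups")
  single <- names(which(table(grpOfPop) < 2L))
  if (length(single))
    stop("group(s) with a single population: ", paste(single, collapse = ", "),
         "; merge them into another group or drop their populations ",
         "(among-populations-within-group variance is undefined there)")
  popF <- ind$population
  grpF <- as.character(groups[popF])
  loci <- coding@loci

  perRepComp <- matrix(NA_real_, replicates, 4L,
                       dimnames = list(NULL, c("groups", "pops", "individuals", "within")))
  perRepF <- matrix(NA_real_, replicates, 4L,
                    dimnames = list(NULL, c("F_IT", "F_IS", "F_SC", "F_CT")))
  perLocusF <- array(NA_real_, c(replicates, length(loci), 4L),
                     dimnames = list(NULL, loci, c("F_IT", "F_IS", "F_SC", "F_CT")))

  for (r in seq_len(replicates)) {
    copies <- .resolveDosage(coding, .fnv1a(paste("amova", seed, r, sep = "|")))
    compByLocus <- matrix(NA_real_, length(loci), 4L,
                          dimnames = list(loci, c("groups", "pops", "individuals", "within")))
    for (l in seq_along(loci)) {
      cl <- .amovaLocus(copies[[l]], popF, grpF)
      if (!is.null(cl)) {
        compByLocus[l, ] <- cl
        perLocusF[r, l, ] <- .fFromComponents(cl, warnZero = FALSE)
      }
    }
    multi <- colSums(compByLocus, na.rm = TRUE)
    perRepComp[r, ] <- multi
    perRepF[r, ] <- suppressWarnings(.fFromComponents(multi))
  }

  comp <- colMeans(perRepComp)
  f <- .fFromComponents(comp)
  tot <- sum(comp)
  pct <- if (tot == 0) rep(NaN, 4L) else 100 * comp / tot
  names(pct) <- names(comp)
  perLocusMean <- apply(perLocusF, c(2L, 3L), mean, na.rm = TRUE)
  sdLoci <- apply(perLocusMean, 2L, stats::sd, na.rm = TRUE)
  sdRep <- apply(perRepF, 2L, stats::sd)
  new("AmovaResult",
      components = comp, fStats = f, pctVariance = pct,
      sdLoci = sdLoci, sdReplicates = sdRep,
      perLocus = data.frame(locus = loci, perLocusMean,
                            stringsAsFactors = FALSE, row.names = NULL),
      perReplicate = data.frame(replicate = seq_len(replicates), perRepF,
                                row.names = NULL),
      ploidy = coding@ploidy)
}
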