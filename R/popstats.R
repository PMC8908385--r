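## Diversity and differentiation statistics from dosage-corrected allele
## frequencies: gene diversity Hs, effective number of alleles EN, Nei's
## Gst and Jost's D.

#' Gene diversity (expected heterozygosity) of a frequency vector
#'
#' `Hs = 1 - sum(p^2)`, uncorrected for sample size: a finite-sample
#' correction needs a defined number of allele copies, which is ill-posed
#' when dosage is ambiguous.
#'
#' @param freqs probability vector (sums to 1).
#' @return Hs in [0, 1).
#' @export
geneDiversity <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  1 - sum(freqs^2)
}

#' Effective number of alleles
#'
#' `EN = 1 / (1 - Hs)`: the number of equally frequent alleles giving the
#' same gene diversity.
#'
#' @param Hs gene diversity in [0, 1).
#' @return EN >= 1.
#' @export
effectiveAlleles <- function(Hs) {
  if (any(Hs >= 1) || any(Hs < 0)) stop("Hs must lie in [0, 1)")
  1 / (1 - Hs)
}

#' Per-population diversity table under an assumed ploidy
#'
#' Per population: locus-wise gene diversity from the EM-corrected allele
#' frequencies, averaged over scored loci; EN computed from the mean Hs
#' (so `EN = 1/(1 - Hs)` holds exactly at the population level); the SD of
#' Hs over loci; and the number of individuals. Populations with zero
#' scored loci are excluded with a warning.
#'
#' @param coding a [PloidyCoding-class].
#' @param freqEstimates optional output of [estimateAlleleFrequencies()]
#'   (recomputed if missing).
#' @return data.frame with columns `population`, `ploidy`, `N`, `EN`, `Hs`,
#'   `sdHs`, `nLoci`.
#' @export
diversityTable <- function(coding, freqEstimates = NULL) {
  if (is.null(freqEstimates)) freqEstimates <- estimateAlleleFrequencies(coding)
  ind <- coding@individuals
  pops <- names(freqEstimates)
  rows <- lapply(pops, function(pp) {
    hs <- vapply(Filter(Negate(is.null), freqEstimates[[pp]]),
                 geneDiversity, 0)
    if (!length(hs)) {
      warning("population ", pp, " has no scored loci; excluded")
      return(NULL)
    }
    data.frame(population = pp, ploidy = coding@ploidy,
               N = sum(ind$population == pp),
               EN = effectiveAlleles(mean(hs)), Hs = mean(hs),
               sdHs = if (length(hs) > 1L) stats::sd(hs) else NA_real_,
               nLoci = length(hs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## align two named frequency vectors on the union of their alleles
.alignFreqs <- function(a, b) {
  al <- sort(unique(c(names(a), names(b))))
  pa <- stats::setNames(rep(0, length(al)), al); pa[names(a)] <- a
  pb <- stats::setNames(rep(0, length(al)), al); pb[names(b)] <- b
  list(a = pa, b = pb)
}

#' Pairwise population differentiation (Nei's Gst or Jost's D)
#'
#' Per pair and locus: `Hs_bar` is the mean within-population gene
#' diversity, `Ht` the gene diversity of the mean frequency vector;
#' `Gst = (Ht - Hs_bar)/Ht` and, with the pairwise factor k/(k-1) = 2,
#' `D = 2 (Ht - Hs_bar)/(1 - Hs_bar)`. When both populations are
#' monomorphic for the same allele (`Ht = 0`) the statistic is defined as 0.
#' Multi-locus values: ratio of averages for Gst; harmonic mean of
#' per-locus values for D (a non-positive per-locus D propagates as the
#' harmonic limit 0). Raw (possibly slightly negative) per-locus values are
#' retained in the per-locus array.
#'
#' @param freqEstimates output of [estimateAlleleFrequencies()].
#' @param statistic `"Gst"` or `"JostD"`.
#' @return List of class `PairwiseMatrix`: `statistic`, `values` (symmetric
#'   matrix, zero diagonal), `perLocus` (3-D array pop x pop x locus).
#' @export
pairwiseDifferentiation <- function(freqEstimates, statistic = c("Gst", "JostD")) {
  statistic <- match.arg(statistic)
  pops <- names(freqEstimates)
  if (length(pops) < 2L) stop("need at least 2 populations")
  loci <- unique(unlist(lapply(freqEstimates, names)))
  vals <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  per <- array(NA_real_, c(length(pops), length(pops), length(loci)),
               dimnames = list(pops, pops, loci))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    ht <- hs <- dlocus <- rep(NA_real_, length(loci))
    for (k in seq_along(loci)) {
      fa <- freqEstimates[[pops[i]]][[loci[k]]]
      fb <- freqEstimates[[pops[j]]][[loci[k]]]
      if (is.null(fa) || is.null(fb)) next
      al <- .alignFreqs(fa, fb)
      hsk <- mean(c(geneDiversity(al$a), geneDiversity(al$b)))
      htk <- geneDiversity((al$a + al$b) / 2)
      hs[k] <- hsk; ht[k] <- htk
      dlocus[k] <- if (statistic == "Gst") {
        if (htk == 0) 0 else (htk - hsk) / htk
      } else {
        if (htk == 0) 0 else 2 * (htk - hsk) / (1 - hsk)
      }
    }
    per[pops[i], pops[j], ] <- per[pops[j], pops[i], ] <- dlocus
    ok <- !is.na(ht)
    v <- if (!any(ok)) NA_real_
    else if (statistic == "Gst") {
      if (sum(ht[ok]) == 0) 0 else sum(ht[ok] - hs[ok]) / sum(ht[ok])
    } else {
      d <- dlocus[ok]
      if (any(d <= 0)) 0 else 1 / mean(1 / d)
    }
    vals[i, j] <- vals[j, i] <- v
  }
  structure(list(statistic = statistic, values = vals, perLocus = per),
            class = "PairwiseMatrix")
}

#' @export
print.PairwiseMatrix <- function(x, ...) {
  cat("Pairwise", x$statistic, "over", nrow(x$values), "populations\n")
  print(round(x$values, 3))
  invisible(x)
}
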