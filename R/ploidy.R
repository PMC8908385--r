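## Assumed-ploidy recoding and the EM maximum-likelihood correction for
## unknown allele dosage.
##
## A chimeric blade's genotype is a *set* of allele sizes: neither the
## dosage of each allele nor the ploidy of the genotyped slice is known.
## The analysis strategy is to recode the whole dataset under each assumed
## ploidy m in {2, 4, 8} -- subsampling alleles within individuals when an
## observed set exceeds m -- and to estimate population allele frequencies
## by maximum likelihood over the dosages compatible with each observed set.

#' Recode a dataset under an assumed ploidy
#'
#' For each individual x locus, if the observed allele set exceeds `m`
#' distinct alleles a uniform random `m`-subset is retained; otherwise all
#' observed alleles are kept. The subset draw is keyed by
#' `(seed, individual_id, locus)` through a deterministic hash, so the
#' retained subset is reproducible and independent of processing order.
#' Candidate subsets are enumerated in lexicographic allele order. Cells
#' whose dosage cannot be read off the set under ploidy `m` are flagged
#' ambiguous. Recoding never invents alleles and never changes missingness.
#'
#' @param ds a [GenotypeDataset-class].
#' @param m assumed ploidy: 2, 4 or 8.
#' @param seed integer subsampling seed.
#' @return A [PloidyCoding-class].
#' @export
recodeDataset <- function(ds, m, seed = 1L) {
  if (!m %in% c(2L, 4L, 8L)) stop("assumed ploidy must be 2, 4 or 8")
  m <- as.integer(m)
  ind <- ds@individuals; loci <- ds@loci
  retained <- vector("list", nrow(ind))
  amb <- matrix(FALSE, nrow(ind), length(loci),
                dimnames = list(ind$individual_id, loci))
  for (i in seq_len(nrow(ind))) {
    ri <- vector("list", length(loci)); names(ri) <- loci
    for (j in seq_along(loci)) {
      a <- sort(ds@calls[[i]][[loci[j]]])
      if (length(a) > m) {
        subs <- utils::combn(a, m)  # lexicographic over sorted alleles
        idx <- .withSeed(
          .fnv1a(paste(seed, ind$individual_id[i], loci[j], sep = "|")),
          sample.int(ncol(subs), 1L))
        a <- subs[, idx]
      }
      ri[[j]] <- a
      k <- length(a)
      amb[i, j] <- (k > 1L && k < m) || (k >= 2L && m > 2L)
    }
    retained[[i]] <- ri
  }
  new("PloidyCoding", ploidy = m, retained = retained, ambiguous = amb,
      seed = as.integer(seed), individuals = ind, loci = loci)
}

#' All dosage multisets compatible with an observed allele set
#'
#' Enumerates every multiset of `m` allele copies whose support is exactly
#' the observed set: each observed allele gets at least one copy and no
#' unobserved allele appears. These are the compositions of `m` into
#' `|set|` positive parts, enumerated in lexicographic order.
#'
#' @param alleleSet integer vector of distinct allele sizes (1 to m of them).
#' @param m assumed ploidy.
#' @return List of sorted integer vectors of length `m`.
#' @export
enumerateCompatibleGenotypes <- function(alleleSet, m) {
  alleleSet <- sort(unique(as.integer(alleleSet)))
  k <- length(alleleSet)
  if (k < 1L) stop("empty allele set")
  if (k > m) stop("allele set larger than assumed ploidy ", m)
  comps <- .compositions(m, k)
  lapply(seq_len(nrow(comps)), function(r)
    rep(alleleSet, times = comps[r, ]))
}

## compositions of n into k positive parts, lexicographic, as a matrix
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- list()
  for (first in seq_len(n - k + 1L)) {
    rest <- .compositions(n - first, k - 1L)
    out[[first]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

#' EM allele-frequency estimation under unknown dosage
#'
#' Maximum-likelihood allele frequencies for one population x locus from
#' dosage-ambiguous phenotypes (allele sets). The genotype prior is the
#' multinomial random union of `m` gametes at the current frequencies (the
#' Hardy-Weinberg analogue for ploidy `m`). E-step: each phenotype gets
#' posterior weights over its compatible dosage multisets; M-step:
#' frequencies are re-estimated from expected allele counts. Initialisation
#' is uniform over the observed alleles; iteration stops when the largest
#' frequency change falls below `tol`. The log-likelihood is monotone
#' non-decreasing; at `m = 2` dosage is never ambiguous and the result
#' equals direct allele counting exactly.
#'
#' @param phenotypes list of integer allele-set vectors; empty sets
#'   (missing loci) are dropped.
#' @param m assumed ploidy.
#' @param tol convergence tolerance on the max frequency change.
#' @param maxIter iteration cap; non-convergence is flagged, not an error.
#' @return List with `freqs` (named probability vector), `logLik`,
#'   `nIterations`, `converged`, and `logLikTrace`.
#' @export
emAlleleFrequencies <- function(phenotypes, m, tol = 1e-8, maxIter = 10000L) {
  phenotypes <- Filter(length, phenotypes)
  if (!length(phenotypes)) stop("no non-missing phenotypes")
  if (any(lengths(phenotypes) > m))
    stop("a phenotype carries more than ", m, " alleles; recode first")
  alleles <- sort(unique(unlist(phenotypes)))
  A <- length(alleles)
  phenoKey <- vapply(phenotypes, function(p) paste(sort(p), collapse = ";"), "")
  tab <- table(phenoKey)
  uniq <- names(tab); nPh <- as.numeric(tab)
  N <- sum(nPh)

  ## per unique phenotype: count matrix (genotypes x alleles) and multinomial
  ## coefficients of the compatible dosage multisets
  info <- lapply(uniq, function(key) {
    set <- as.integer(strsplit(key, ";", fixed = TRUE)[[1]])
    gens <- enumerateCompatibleGenotypes(set, m)
    cnt <- t(vapply(gens, function(g) tabulate(match(g, alleles), A),
                    numeric(A)))
    coef <- apply(cnt, 1L, function(cc) exp(lgamma(m + 1) - sum(lgamma(cc + 1))))
    list(cnt = cnt, coef = coef)
  })

  p <- stats::setNames(rep(1 / A, A), alleles)
  ll <- -Inf; trace <- numeric(0)
  converged <- FALSE; it <- 0L
  logp <- function(p) log(pmax(p, 1e-300))
  while (it < maxIter) {
    it <- it + 1L
    counts <- numeric(A)
    llNew <- 0
    for (u in seq_along(info)) {
      cnt <- info[[u]]$cnt
      lw <- log(info[[u]]$coef) + cnt %*% logp(p)
      mx <- max(lw)
      w <- exp(lw - mx)
      sw <- sum(w)
      llNew <- llNew + nPh[u] * (mx + log(sw))
      counts <- counts + nPh[u] * as.numeric(crossprod(cnt, w / sw))
    }
    pNew <- counts / (m * N)
    delta <- max(abs(pNew - p))
    p <- stats::setNames(pNew, alleles)
    trace <- c(trace, llNew)
    ll <- llNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", maxIter, " iterations; best estimate returned")
  list(freqs = p, logLik = ll, nIterations = it, converged = converged,
       logLikTrace = trace)
}

#' Estimate allele frequencies for every population x locus of a coding
#'
#' Applies [emAlleleFrequencies()] per population and locus on the retained
#' allele sets of a [PloidyCoding-class].
#'
#' @param coding a [PloidyCoding-class].
#' @param tol,maxIter passed to the EM.
#' @return Nested list `freqs[[population]][[locus]]` of named probability
#'   vectors, with attribute `"converged"` (logical matrix) recording EM
#'   convergence per cell. Population x locus cells with no data are `NULL`.
#' @export
estimateAlleleFrequencies <- function(coding, tol = 1e-8, maxIter = 10000L) {
  ind <- coding@individuals; loci <- coding@loci
  pops <- unique(ind$population)
  conv <- matrix(NA, length(pops), length(loci), dimnames = list(pops, loci))
  out <- stats::setNames(vector("list", length(pops)), pops)
  for (pp in pops) {
    rows <- which(ind$population == pp)
    byLocus <- stats::setNames(vector("list", length(loci)), loci)
    for (l in loci) {
      ph <- Filter(length, lapply(rows, function(i) coding@retained[[i]][[l]]))
      if (!length(ph)) next
      est <- emAlleleFrequencies(ph, coding@ploidy, tol = tol, maxIter = maxIter)
      byLocus[[l]] <- est$freqs
      conv[pp, l] <- est$converged
    }
    out[[pp]] <- byLocus
  }
  attr(out, "converged") <- conv
  attr(out, "ploidy") <- coding@ploidy
  out
}
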