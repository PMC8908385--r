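# Independent oracles and small fixture builders shared across tests.

# Build a GenotypeDataset from a list: pops[[pop]] = list of per-individual
# named lists of allele vectors. Species defaults to one label.
toyDataset <- function(pops, loci, species = NULL) {
  inds <- list(); calls <- list(); k <- 0L
  for (pp in names(pops)) for (g in pops[[pp]]) {
    k <- k + 1L
    inds[[k]] <- data.frame(
      individual_id = sprintf("%s_i%02d", pp, k),
      population = pp,
      species = if (is.null(species)) "SP1" else species[[pp]],
      stringsAsFactors = FALSE)
    calls[[k]] <- g
  }
  genotypeDataset(do.call(rbind, inds), loci, calls)
}

# Naive balanced nested ANOVA on one-hot-encoded allele copies: an
# independent route to the AMOVA variance components. copies is an
# (individuals x m) matrix; design must be balanced (equal individuals per
# population, equal populations per group).
naiveAmovaComponents <- function(copies, pop, grp) {
  m <- ncol(copies)
  alleles <- sort(unique(as.vector(copies)))
  onehot <- function(a) as.numeric(alleles == a)
  # copy-level matrix: rows = allele copies, columns = allele indicators
  X <- do.call(rbind, lapply(seq_len(nrow(copies)), function(i)
    t(vapply(copies[i, ], onehot, numeric(length(alleles))))))
  indF <- rep(seq_len(nrow(copies)), each = m)
  popF <- rep(as.character(pop), each = m)
  grpF <- rep(as.character(grp), each = m)
  colMeansBy <- function(f) {
    mu <- rowsum(X, f) / as.vector(table(f)[sort(unique(f))])
    mu[as.character(f), , drop = FALSE]
  }
  grand <- matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
  muI <- colMeansBy(indF); muP <- colMeansBy(popF); muG <- colMeansBy(grpF)
  # 0/1 identity-in-state distance = half squared Euclidean on one-hot rows
  ssWI <- sum((X - muI)^2) / 2
  ssAI <- sum((muI - muP)^2) / 2
  ssAP <- sum((muP - muG)^2) / 2
  ssAG <- sum((muG - grand)^2) / 2
  I <- nrow(copies); P <- length(unique(pop)); G <- length(unique(grp))
  N <- I * m
  i <- I / P  # individuals per population (balanced)
  p <- P / G  # populations per group (balanced)
  msWI <- ssWI / (N - I); msAI <- ssAI / (I - P)
  msAP <- ssAP / (P - G); msAG <- ssAG / (G - 1)
  sig4 <- msWI
  sig3 <- (msAI - sig4) / m
  sig2 <- (msAP - sig4 - m * sig3) / (m * i)
  sig1 <- (msAG - sig4 - m * sig3 - m * i * sig2) / (m * i * p)
  c(groups = sig1, pops = sig2, individuals = sig3, within = sig4)
}

# Brute-force ML allele frequencies by grid search. The phenotype
# likelihood uses inclusion-exclusion (probability that m iid gamete draws
# have support exactly S), independent of the EM's genotype enumeration.
gridSearchMLE <- function(phenotypes, m, step = 1e-4) {
  alleles <- sort(unique(unlist(phenotypes)))
  phenoLik <- function(S, p) {
    idx <- match(S, alleles)
    tot <- 0
    for (mask in 0:(2^length(idx) - 1)) {
      sub <- idx[bitwAnd(mask, 2^(seq_along(idx) - 1)) > 0]
      tot <- tot + (-1)^(length(idx) - length(sub)) * sum(p[sub])^m
    }
    tot
  }
  loglik <- function(p) sum(vapply(phenotypes, function(S)
    log(max(phenoLik(S, p), 1e-300)), 0))
  if (length(alleles) == 2L) {
    pa <- seq(0, 1, by = step)
    ll <- vapply(pa, function(a) loglik(c(a, 1 - a)), 0)
    best <- pa[which.max(ll)]
    return(stats::setNames(c(best, 1 - best), alleles))
  }
  if (length(alleles) == 3L) {
    scan <- function(as, bs) {
      best <- NULL; bestLL <- -Inf
      for (a in as) for (b in bs[bs <= 1 - a + 1e-12]) {
        ll <- loglik(c(a, b, 1 - a - b))
        if (ll > bestLL) { bestLL <- ll; best <- c(a, b, 1 - a - b) }
      }
      best
    }
    # coarse scan of the simplex, then local refinement to `step`
    coarse <- scan(seq(0, 1, by = 0.005), seq(0, 1, by = 0.005))
    fine <- scan(seq(max(0, coarse[1] - 0.01), min(1, coarse[1] + 0.01), by = step),
                 seq(max(0, coarse[2] - 0.01), min(1, coarse[2] + 0.01), by = step))
    return(stats::setNames(fine, alleles))
  }
  stop("grid oracle supports 2 or 3 alleles")
}

# Write a minimal clustering-results file in the standard layout.
writeStructureFixture <- function(path, lnProb, q, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("I%d", seq_len(nrow(q)))
  lines <- c(
    "STRUCTURE by Pritchard, Stephens and Donnelly",
    "",
    sprintf("Estimated Ln Prob of Data   = %.1f", lnProb),
    sprintf("Mean value of ln likelihood = %.1f", lnProb - 1),
    "",
    "Inferred ancestry of individuals:",
    "        Label (%Miss) Pop:  Inferred clusters",
    vapply(seq_len(nrow(q)), function(i)
      sprintf("%3d %10s    (0)    1 :  %s", i, labels[i],
              paste(sprintf("%.3f", q[i, ]), collapse = " ")), ""),
    "",
    "Values of parameters used in structure:")
  writeLines(lines, path)
  path
}

# Balanced diploid design builder: G groups x P pops x I individuals, with
# genotypeFun(g, p, i, l) returning the allele set of one individual/locus.
diploidDesign <- function(G, P, I, genotypeFun, loci = "L1") {
  pops <- list()
  for (g in seq_len(G)) for (p in seq_len(P)) {
    code <- sprintf("G%dP%d", g, p)
    pops[[code]] <- lapply(seq_len(I), function(i)
      stats::setNames(lapply(loci, function(l) genotypeFun(g, p, i, l)), loci))
  }
  toyDataset(pops, loci)
}

# population -> group map for diploidDesign codes (GxPy -> Gx)
groupMap <- function(ds) {
  pops <- unique(indMeta(ds)$population)
  stats::setNames(sub("P\\d+$", "", pops), pops)
}
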