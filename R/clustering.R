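## Support for the external Bayesian clustering workflow: parse result
## files, Evanno delta-K model selection, per-population mean ancestry.
## The MCMC admixture inference itself is never run here; this module only
## consumes its output files.

#' Parse clustering result files into run records
#'
#' Reads files in the standard STRUCTURE results format: the
#' `Estimated Ln Prob of Data` line and the
#' `Inferred ancestry of individuals` block. Ancestry rows off unity by at
#' most 1e-3 are renormalised; larger deviations are an error.
#'
#' @param paths character vector of result-file paths.
#' @return List of runs; each run is a list with `K`, `replicate` (index
#'   among files sharing that K, in input order), `lnProb`, `q` (individuals
#'   x K matrix, row names = labels), `file`.
#' @export
parseStructureOutput <- function(paths) {
  runs <- lapply(paths, function(p) {
    lines <- readLines(p, warn = FALSE)
    lp <- grep("Estimated Ln Prob of Data", lines, value = TRUE)
    if (!length(lp))
      stop("no 'Estimated Ln Prob of Data' line in ", p)
    lnProb <- as.numeric(sub(".*=\\s*", "", lp[1]))
    if (is.na(lnProb)) stop("unparseable ln-prob value in ", p)
    start <- grep("Inferred ancestry of individuals", lines)
    if (!length(start)) stop("no inferred-ancestry block in ", p)
    i <- start[1] + 1L
    rows <- list(); labels <- character()
    while (i <= length(lines)) {
      ln <- lines[i]; i <- i + 1L
      if (grepl("^\\s*$", ln)) { if (length(rows)) break else next }
      if (!grepl(":", ln, fixed = TRUE)) next  # column header line
      parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
      left <- strsplit(trimws(parts[1]), "\\s+")[[1]]
      q <- suppressWarnings(as.numeric(strsplit(trimws(parts[2]), "\\s+")[[1]]))
      q <- q[!is.na(q)]
      if (!length(q)) next
      s <- sum(q)
      if (abs(s - 1) > 1e-3)
        stop("ancestry row sums to ", s, " in ", p, " (beyond 1e-3)")
      rows[[length(rows) + 1L]] <- q / s
      labels <- c(labels, left[2])
    }
    if (!length(rows)) stop("empty inferred-ancestry block in ", p)
    K <- length(rows[[1]])
    qm <- do.call(rbind, rows)
    rownames(qm) <- labels
    list(K = K, replicate = NA_integer_, lnProb = lnProb, q = qm, file = p)
  })
  ks <- vapply(runs, `[[`, 0L, "K")
  for (k in unique(ks)) {
    idx <- which(ks == k)
    for (r in seq_along(idx)) runs[[idx[r]]]$replicate <- r
  }
  runs
}

#' Evanno delta-K statistic over replicate clustering runs
#'
#' For each interior K, `deltaK(K)` is the mean over replicates of
#' `|L(K+1) - 2 L(K) + L(K-1)|` divided by the standard deviation of `L(K)`
#' over replicates; it is translation-invariant in L and undefined at the
#' boundary K values. Requires at least 2 replicates per K over a
#' consecutive K range of length >= 3, with equal replicate counts.
#'
#' @param runs list of runs from [parseStructureOutput()], or any list of
#'   lists with `K` and `lnProb`.
#' @return data.frame with columns `K`, `meanLnP`, `sdLnP`, `deltaK`, with
#'   attribute `bestK` = the interior K maximising deltaK.
#' @export
evannoDeltaK <- function(runs) {
  ks <- vapply(runs, `[[`, 0L, "K")
  ls <- vapply(runs, `[[`, 0, "lnProb")
  kk <- sort(unique(ks))
  if (length(kk) < 3L || !all(diff(kk) == 1L))
    stop("need a consecutive K range of length >= 3")
  reps <- table(ks)
  if (any(reps < 2L)) stop("need >= 2 replicates per K")
  if (length(unique(reps)) != 1L)
    stop("replicate counts differ across K; trim to a common count")
  R <- unique(as.integer(reps))
  L <- matrix(NA_real_, R, length(kk), dimnames = list(NULL, kk))
  for (j in seq_along(kk)) L[, j] <- ls[ks == kk[j]]
  sdL <- apply(L, 2L, stats::sd)
  deltaK <- rep(NA_real_, length(kk))
  for (j in 2:(length(kk) - 1L)) {
    if (sdL[j] == 0)
      stop("sd of L is zero at K=", kk[j],
           "; add replicates or jitter (division by zero)")
    second <- L[, j + 1L] - 2 * L[, j] + L[, j - 1L]
    deltaK[j] <- mean(abs(second)) / sdL[j]
  }
  out <- data.frame(K = kk, meanLnP = colMeans(L), sdLnP = sdL,
                    deltaK = deltaK, row.names = NULL)
  attr(out, "bestK") <- kk[which.max(deltaK)]
  out
}

#' @describeIn evannoDeltaK the K maximising deltaK
#' @param table output of `evannoDeltaK`
#' @export
bestK <- function(table) attr(table, "bestK")

## greedy column alignment of q to a reference by correlation
.alignColumns <- function(q, ref) {
  K <- ncol(ref)
  cc <- suppressWarnings(stats::cor(q, ref))
  cc[!is.finite(cc)] <- 0
  perm <- integer(K); used <- logical(K)
  minCor <- Inf
  for (step in seq_len(K)) {
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    perm[best[2]] <- best[1]
    minCor <- min(minCor, cc[best[1], best[2]])
    cc[best[1], ] <- -Inf; cc[, best[2]] <- -Inf
  }
  list(q = q[, perm, drop = FALSE], minCor = minCor)
}

#' Mean ancestry per population across replicate runs
#'
#' Aligns cluster labels across replicates by greedy correlation matching
#' to the first replicate (warning when the weakest matched correlation
#' falls below 0.5, i.e. label switching may be unresolved), averages the
#' ancestry matrices over replicates, then averages over the individuals of
#' each population. Rows sum to 1.
#'
#' @param runs replicate runs at a single K (from [parseStructureOutput()]).
#' @param populations character vector of population codes, one per
#'   individual, aligned with the q-matrix row order.
#' @return Matrix populations x clusters of mean ancestries.
#' @export
ancestryByPopulation <- function(runs, populations) {
  ks <- vapply(runs, `[[`, 0L, "K")
  if (length(unique(ks)) != 1L) stop("runs must share one K")
  ref <- runs[[1]]$q
  if (length(populations) != nrow(ref))
    stop("one population code required per individual")
  qs <- list(ref)
  for (r in runs[-1]) {
    al <- .alignColumns(r$q, ref)
    if (al$minCor < 0.5)
      warning("weak column alignment (correlation ", round(al$minCor, 2),
              "): label switching may be unresolved")
    qs[[length(qs) + 1L]] <- al$q
  }
  qbar <- Reduce(`+`, qs) / length(qs)
  agg <- rowsum(qbar, populations) / as.vector(table(populations)[
    sort(unique(populations))])
  agg <- agg / rowSums(agg)
  colnames(agg) <- paste0("cluster", seq_len(ncol(agg)))
  agg
}

#' Hierarchy from a chosen-K ancestry matrix by max-ancestry assignment
#'
#' Assigns each individual to its maximum-ancestry cluster and applies a
#' mismatch filter: individuals confidently assigned (max ancestry >=
#' `threshold`) to a cluster different from their population's modal
#' cluster are marked excluded, mirroring the removal of stray
#' other-species genotypes before within-species analyses.
#'
#' @param q individuals x clusters ancestry matrix.
#' @param populations population code per individual (q row order).
#' @param threshold confidence threshold for the mismatch filter.
#' @return data.frame: `individual_id`, `population`, `group` (population's
#'   modal cluster), `assigned` (own max-ancestry cluster), `excluded`.
#' @export
maxAncestryHierarchy <- function(q, populations, threshold = 0.5) {
  assigned <- max.col(q, ties.method = "first")
  modal <- vapply(split(assigned, populations), function(a)
    as.integer(names(which.max(table(a)))), 0L)
  grp <- modal[populations]
  conf <- q[cbind(seq_len(nrow(q)), assigned)]
  excluded <- assigned != grp & conf >= threshold
  data.frame(individual_id = rownames(q) %||% as.character(seq_len(nrow(q))),
             population = populations,
             group = paste0("cluster", grp),
             assigned = paste0("cluster", assigned),
             excluded = excluded, row.names = NULL,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
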