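## PCA on within-individual relative allele frequencies.

#' Principal components of individual allelic variation
#'
#' Builds the individual x (locus, allele) matrix in which each allele
#' retained at a locus is weighted 1/|retained set| (so every scored locus
#' contributes total weight 1 regardless of how many alleles a chimeric
#' blade shows), imputes missing loci with the population mean of each
#' column (preventing missingness from mimicking structure; set
#' `impute = "global"` for a global-mean fill), centres columns and
#' eigendecomposes the covariance.
#'
#' @param coding a [PloidyCoding-class].
#' @param nAxes number of leading axes to return.
#' @param impute `"population"` (default) or `"global"` mean imputation.
#' @return List of class `PcaResult`: `scores` (individuals x axes),
#'   `eigenvalues`, `pctVariance`, `dictionary` (data.frame locus/allele per
#'   column), `dropped` (ids of all-missing individuals, removed with a
#'   warning).
#' @export
pcaGenotypes <- function(coding, nAxes = 5L, impute = c("population", "global")) {
  impute <- match.arg(impute)
  ind <- coding@individuals; loci <- coding@loci
  if (nrow(ind) < 2L) stop("need at least 2 individuals")

  alleleByLocus <- lapply(loci, function(l)
    sort(unique(unlist(lapply(coding@retained, function(ci) ci[[l]])))))
  names(alleleByLocus) <- loci
  dict <- do.call(rbind, lapply(loci, function(l)
    if (length(alleleByLocus[[l]]))
      data.frame(locus = l, allele = alleleByLocus[[l]]) else NULL))
  X <- matrix(NA_real_, nrow(ind), nrow(dict),
              dimnames = list(ind$individual_id,
                              paste(dict$locus, dict$allele, sep = ".")))
  for (i in seq_len(nrow(ind))) for (l in loci) {
    cols <- which(dict$locus == l)
    if (!length(cols)) next
    a <- coding@retained[[i]][[l]]
    if (!length(a)) next
    v <- numeric(length(cols))
    v[match(a, dict$allele[cols])] <- 1 / length(a)
    X[i, cols] <- v
  }

  dropped <- ind$individual_id[rowSums(!is.na(X)) == 0L]
  if (length(dropped)) {
    warning("dropping all-missing individuals: ", paste(dropped, collapse = ", "))
    keep <- !(ind$individual_id %in% dropped)
    X <- X[keep, , drop = FALSE]
    ind <- ind[keep, , drop = FALSE]
  }

  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (!any(nas)) next
    if (impute == "population") {
      for (pp in unique(ind$population[nas])) {
        rows <- nas & ind$population == pp
        mu <- mean(X[ind$population == pp, j], na.rm = TRUE)
        if (is.nan(mu)) mu <- mean(X[, j], na.rm = TRUE)
        X[rows, j] <- mu
      }
    } else X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }

  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  nAxes <- min(nAxes, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(nAxes), drop = FALSE],
                 eigenvalues = ev,
                 pctVariance = 100 * ev / sum(ev),
                 dictionary = dict, dropped = dropped),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PCA on", nrow(x$scores), "individuals,", nrow(x$dictionary),
      "(locus, allele) columns\n")
  cat("  % variance, leading axes:",
      paste(sprintf("%.1f", utils::head(x$pctVariance, ncol(x$scores))),
            collapse = ", "), "\n")
  invisible(x)
}
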