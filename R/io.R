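## Readers/writers: native genotype CSV, population metadata, FASTA
## alignments, and exports to STRUCTURE / GenAlEx layouts.
##
## Native genotype CSV (one row per individual x locus):
##   individual_id,population,species,locus,alleles
## where `alleles` is a semicolon-separated list of integer sizes in bp and
## an empty field marks a missing locus. The writer canonicalises allele
## order ascending and rows by individual then locus, so write/read is an
## identity on canonical files.

#' Read a genotype CSV into a GenotypeDataset
#'
#' @param path CSV path with header
#'   `individual_id,population,species,locus,alleles`.
#' @return A [GenotypeDataset-class].
#' @export
readGenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = NULL)
  need <- c("individual_id", "population", "species", "locus", "alleles")
  if (!all(need %in% names(df)))
    stop("genotype CSV must have columns ", paste(need, collapse = ", "))
  key <- paste(df$individual_id, df$locus, sep = "\r")
  if (anyDuplicated(key)) {
    ln <- which(duplicated(key))[1] + 1L
    stop(sprintf("duplicate (individual, locus) row at line %d", ln))
  }
  parseAlleles <- function(s, line) {
    if (!nzchar(s)) return(integer(0))
    tok <- strsplit(s, ";", fixed = TRUE)[[1]]
    tok <- trimws(tok)
    if (any(!grepl("^[0-9]+$", tok)))
      stop(sprintf("malformed allele size token '%s' at line %d",
                   tok[!grepl("^[0-9]+$", tok)][1], line))
    a <- as.integer(tok)
    if (anyDuplicated(a)) {
      warning(sprintf("repeated allele sizes at line %d deduplicated", line))
      a <- unique(a)
    }
    if (length(a) > 8L)
      stop(sprintf("more than 8 distinct alleles at line %d", line))
    sort(a)
  }
  inds <- unique(df[, c("individual_id", "population", "species")])
  if (anyDuplicated(inds$individual_id))
    stop("individual assigned to more than one population/species")
  loci <- unique(df$locus)
  calls <- rep(list(stats::setNames(rep(list(integer(0)), length(loci)), loci)),
               nrow(inds))
  idx <- match(df$individual_id, inds$individual_id)
  for (r in seq_len(nrow(df)))
    calls[[idx[r]]][[df$locus[r]]] <- parseAlleles(df$alleles[r], r + 1L)
  genotypeDataset(inds, loci, calls)
}

#' Write a GenotypeDataset as the canonical genotype CSV
#' @param ds a [GenotypeDataset-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGenotypes <- function(ds, path) {
  ind <- ds@individuals
  rows <- vector("list", nrow(ind) * length(ds@loci))
  k <- 0L
  for (i in seq_len(nrow(ind))) for (l in ds@loci) {
    k <- k + 1L
    a <- ds@calls[[i]][[l]]
    rows[[k]] <- data.frame(individual_id = ind$individual_id[i],
                            population = ind$population[i],
                            species = ind$species[i], locus = l,
                            alleles = paste(sort(a), collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Snap fragment sizes to the repeat-unit grid
#'
#' Maps each raw (fractional bp) size to the nearest value in
#' `{offset + k * repeatUnit, k >= 0}`, ties broken downward. Idempotent on
#' already-binned sizes. This is a deliberately simple binning utility;
#' chromatogram peak calling is out of scope.
#'
#' @param rawSizes numeric fragment sizes in bp.
#' @param repeatUnit integer repeat unit (>= 1).
#' @param offset integer grid offset in bp.
#' @return Integer vector of binned sizes.
#' @export
binAlleleSizes <- function(rawSizes, repeatUnit, offset) {
  if (repeatUnit < 1) stop("repeatUnit must be >= 1")
  if (any(rawSizes < 0)) stop("negative fragment sizes")
  k <- (rawSizes - offset) / repeatUnit
  kLo <- pmax(floor(k), 0)
  kHi <- kLo + 1
  lo <- offset + kLo * repeatUnit
  hi <- offset + kHi * repeatUnit
  # ties (exact midpoints) broken downward via <=
  out <- ifelse(rawSizes - lo <= hi - rawSizes, lo, hi)
  as.integer(round(out))
}

#' Read an aligned FASTA into a SeqAlignment
#'
#' Record headers are parsed as `id[ location_code]`; the first
#' whitespace-separated token is the record id, the second (if present) the
#' location code. A ragged alignment is an error naming the offending record.
#'
#' @param path FASTA path.
#' @return A [SeqAlignment-class].
#' @export
readFastaAlignment <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  if (!length(s)) stop("empty alignment: ", path)
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) {
    bad <- names(s)[which(w != w[1])[1]]
    stop("ragged alignment: record '", bad, "' has length ",
         w[which(w != w[1])[1]], ", expected ", w[1])
  }
  tok <- strsplit(names(s), "\\s+")
  ids <- vapply(tok, `[`, "", 1L)
  loc <- vapply(tok, function(t) if (length(t) > 1L) t[2] else NA_character_, "")
  names(s) <- ids
  seqAlignment(s, loc)
}

#' Export a ploidy coding in STRUCTURE's one-row-per-allele-copy layout
#'
#' Writes `m` rows per individual at assumed ploidy `m`: columns are the
#' individual label, an integer population index, then one allele size per
#' locus. Unknown dosage is filled by cycling the retained alleles up to `m`
#' copies (`fill = "cycle"`, the default, logged prominently) or by padding
#' with missing values (`fill = "missing"`). Missing data are coded -9.
#'
#' @param x a [PloidyCoding-class], or a [GenotypeDataset-class] whose allele
#'   sets already fit within `ploidy` (otherwise an error asks to recode).
#' @param path output path.
#' @param ploidy required when `x` is a GenotypeDataset.
#' @param fill `"cycle"` or `"missing"`.
#' @return Invisibly, `path`.
#' @export
exportStructure <- function(x, path, ploidy = NULL, fill = c("cycle", "missing")) {
  fill <- match.arg(fill)
  if (methods::is(x, "GenotypeDataset")) {
    if (is.null(ploidy)) stop("supply 'ploidy' when exporting a GenotypeDataset")
    m <- as.integer(ploidy)
    sets <- x@calls; ind <- x@individuals; loci <- x@loci
    over <- any(vapply(sets, function(ci) any(lengths(ci) > m), TRUE))
    if (over)
      stop("some individuals carry more than ", m,
           " alleles at a locus; recode the dataset first (recodeDataset)")
  } else if (methods::is(x, "PloidyCoding")) {
    m <- x@ploidy; sets <- x@retained; ind <- x@individuals; loci <- x@loci
  } else stop("x must be a GenotypeDataset or PloidyCoding")
  message("exportStructure: unknown dosage filled by '", fill,
          "' rule at assumed ploidy ", m, "x")
  popIdx <- as.integer(factor(ind$population, levels = unique(ind$population)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("id", "pop", loci), collapse = "\t"), con)
  for (i in seq_len(nrow(ind))) {
    rows <- matrix(-9L, nrow = m, ncol = length(loci))
    for (j in seq_along(loci)) {
      a <- sets[[i]][[loci[j]]]
      if (length(a)) {
        if (fill == "cycle") rows[, j] <- rep_len(sort(a), m)
        else rows[seq_along(a), j] <- sort(a)
      }
    }
    for (r in seq_len(m))
      writeLines(paste(c(ind$individual_id[i], popIdx[i], rows[r, ]),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Export a ploidy coding in a GenAlEx-style codominant layout
#'
#' One row per individual; each locus occupies `m` columns holding the
#' cycled allele copies (0 = missing), preceded by the three GenAlEx header
#' lines (counts, title, population names).
#'
#' @param coding a [PloidyCoding-class].
#' @param path output path.
#' @param title dataset title written on the second header line.
#' @return Invisibly, `path`.
#' @export
writeGenalex <- function(coding, path, title = "ChimeraPopGen export") {
  m <- coding@ploidy; ind <- coding@individuals; loci <- coding@loci
  pops <- unique(ind$population)
  con <- file(path, "w"); on.exit(close(con))
  counts <- table(factor(ind$population, levels = pops))
  writeLines(paste(c(length(loci), nrow(ind), length(pops), as.integer(counts)),
                   collapse = ","), con)
  writeLines(title, con)
  writeLines(paste(c("", "", pops), collapse = ","), con)
  hdr <- c("Sample", "Pop",
           unlist(lapply(loci, function(l) c(l, rep("", m - 1L)))))
  writeLines(paste(hdr, collapse = ","), con)
  for (i in seq_len(nrow(ind))) {
    cells <- unlist(lapply(loci, function(l) {
      a <- coding@retained[[i]][[l]]
      if (!length(a)) rep(0L, m) else rep_len(sort(a), m)
    }))
    writeLines(paste(c(ind$individual_id[i], ind$population[i], cells),
                     collapse = ","), con)
  }
  invisible(path)
}
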