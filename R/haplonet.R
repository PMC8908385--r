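## cpDNA haplotype analysis: collapse aligned sequences into haplotypes,
## tabulate frequencies by location, and build a minimum-spanning mutation
## network with an optional connection limit.

.AMBIG <- function(ch) !(ch %in% c("A", "C", "G", "T", "-"))

#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences are merged into haplotypes labelled A, B, ... in
#' order of first appearance. Under the default `"pairwise"` ambiguity
#' policy, IUPAC ambiguity codes and N act as wildcards: a record joins the
#' first existing haplotype it matches at every position where both have a
#' determined state (gaps are a fifth state and always compared, since the
#' coding alignments this targets are gap-free). `"strict"` requires exact
#' string identity. The haplotype representative is the member with the
#' fewest ambiguous positions.
#'
#' @param aln a [SeqAlignment-class].
#' @param ambiguousPolicy `"pairwise"` or `"strict"`.
#' @return A [HaplotypeTable-class].
#' @export
collapseHaplotypes <- function(aln, ambiguousPolicy = c("pairwise", "strict")) {
  ambiguousPolicy <- match.arg(ambiguousPolicy)
  seqs <- as.character(aln@sequences)
  if (!length(seqs)) stop("empty alignment")
  ids <- names(seqs) %||% sprintf("seq%d", seq_along(seqs))
  loc <- aln@location
  loc[is.na(loc)] <- "unknown"

  chars <- lapply(toupper(seqs), function(s) strsplit(s, "")[[1]])
  matches <- function(a, b) {
    if (ambiguousPolicy == "strict") return(identical(a, b))
    cmp <- !(.AMBIG(a) | .AMBIG(b))
    all(a[cmp] == b[cmp])
  }
  repIdx <- integer(0)       # representative record per haplotype
  assign <- integer(length(seqs))
  for (i in seq_along(chars)) {
    hit <- 0L
    for (h in seq_along(repIdx)) {
      if (matches(chars[[i]], chars[[repIdx[h]]])) { hit <- h; break }
    }
    if (hit == 0L) {
      repIdx <- c(repIdx, i)
      assign[i] <- length(repIdx)
    } else {
      assign[i] <- hit
      # prefer the cleanest member as representative
      if (sum(.AMBIG(chars[[i]])) < sum(.AMBIG(chars[[repIdx[hit]]])))
        repIdx[hit] <- i
    }
  }
  H <- length(repIdx)
  labels <- .hapLabels(H)
  members <- split(ids, assign)
  names(members) <- labels[as.integer(names(members))]
  members <- members[labels]
  locLevels <- sort(unique(loc))
  counts <- matrix(0L, H, length(locLevels), dimnames = list(labels, locLevels))
  for (i in seq_along(seqs))
    counts[assign[i], loc[i]] <- counts[assign[i], loc[i]] + 1L
  new("HaplotypeTable", haplotypeId = labels,
      representative = vapply(repIdx, function(i) seqs[i], ""),
      members = members, countsByLocation = counts)
}

.hapLabels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

#' Pairwise mutation steps between haplotypes
#'
#' Hamming distance between haplotype representatives over the positions
#' where both have a determined state (A/C/G/T or gap); symmetric with a
#' zero diagonal.
#'
#' @param table a [HaplotypeTable-class].
#' @return Integer distance matrix.
#' @export
pairwiseSteps <- function(table) {
  H <- length(table@haplotypeId)
  if (H < 2L) stop("need at least 2 haplotypes")
  chars <- lapply(toupper(table@representative), function(s) strsplit(s, "")[[1]])
  d <- matrix(0L, H, H, dimnames = list(table@haplotypeId, table@haplotypeId))
  for (i in seq_len(H)) for (j in seq_len(i - 1L)) {
    cmp <- !(.AMBIG(chars[[i]]) | .AMBIG(chars[[j]]))
    d[i, j] <- d[j, i] <- sum(chars[[i]][cmp] != chars[[j]][cmp])
  }
  d
}

#' Minimum-spanning haplotype network with tie edges retained
#'
#' Kruskal-style growth over candidate edges in increasing mutation-step
#' order: within each distance class, *every* edge joining two components
#' that were distinct at the start of the class is added (a network, not a
#' tree), so equally short alternative connections are kept. Edges longer
#' than `maxSteps` are excluded, which can leave divergent haplotypes
#' isolated -- a pragmatic stand-in for a statistical parsimony connection
#' limit.
#'
#' @param table a [HaplotypeTable-class].
#' @param maxSteps integer connection limit (NULL = unlimited).
#' @return A [HaploNetwork-class].
#' @export
minimumSpanningNetwork <- function(table, maxSteps = NULL) {
  if (!is.null(maxSteps) && maxSteps < 1) stop("maxSteps must be >= 1")
  d <- pairwiseSteps(table)
  H <- nrow(d)
  labels <- table@haplotypeId
  cand <- which(upper.tri(d), arr.ind = TRUE)
  steps <- d[cand]
  cap <- if (is.null(maxSteps)) Inf else maxSteps
  keep <- steps >= 1L & steps <= cap
  cand <- cand[keep, , drop = FALSE]; steps <- steps[keep]
  ord <- order(steps)
  cand <- cand[ord, , drop = FALSE]; steps <- steps[ord]

  comp <- seq_len(H)
  edges <- list()
  for (s in unique(steps)) {
    inClass <- which(steps == s)
    snapshot <- comp
    added <- inClass[snapshot[cand[inClass, 1L]] != snapshot[cand[inClass, 2L]]]
    for (e in added) {
      edges[[length(edges) + 1L]] <-
        data.frame(from = labels[cand[e, 1L]], to = labels[cand[e, 2L]],
                   steps = s, stringsAsFactors = FALSE)
      # merge components after the whole class is scanned against snapshot
    }
    for (e in added) {
      c1 <- comp[cand[e, 1L]]; c2 <- comp[cand[e, 2L]]
      if (c1 != c2) comp[comp == c2] <- c1
    }
  }
  new("HaploNetwork",
      edges = if (length(edges)) do.call(rbind, edges)
              else data.frame(from = character(), to = character(),
                              steps = integer()),
      nodes = data.frame(haplotype = labels,
                         n = as.integer(lengths(table@members)),
                         stringsAsFactors = FALSE),
      maxSteps = if (is.null(maxSteps)) NA_real_ else as.numeric(maxSteps))
}

#' Write a haplotype network as an edge-list CSV and the table as CSV
#'
#' @param network a [HaploNetwork-class].
#' @param table the matching [HaplotypeTable-class].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
writeHaploNetwork <- function(network, table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ePath <- file.path(dir, "haplotype_network_edges.csv")
  tPath <- file.path(dir, "haplotype_table.csv")
  utils::write.csv(network@edges, ePath, row.names = FALSE, quote = FALSE)
  tab <- data.frame(haplotype = table@haplotypeId,
                    n = lengths(table@members),
                    table@countsByLocation, check.names = FALSE)
  utils::write.csv(tab, tPath, row.names = FALSE, quote = FALSE)
  invisible(c(ePath, tPath))
}
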