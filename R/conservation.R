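## Per-column conservation (Shannon entropy, relative entropy) from
## superfamily/subfamily alignments, plus the structure-to-column mapping.

#' Read an aligned FASTA file into an Alignment
#'
#' Rows must all have equal length; symbols are upper-cased, \code{.} and
#' \code{-} both read as gaps, and any non-standard residue becomes \code{X}
#' (excluded from counts like a gap).
#'
#' @param path Aligned FASTA file.
#' @param level \code{"subfamily"} (default) or \code{"superfamily"}.
#' @param structure Optional \code{ProteinStructure}; when given, the
#'   structure sequence is mapped onto the first alignment row to build the
#'   column map (see \code{\link{mapAlignmentColumns}}).
#' @return An \code{\linkS4class{Alignment}}.
#' @export
readAlignment <- function(path, level = "subfamily", structure = NULL) {
  aln <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(aln))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("alignment rows have unequal lengths")
  rows <- do.call(rbind, strsplit(chartr(".", "-", seqs), ""))
  dimnames(rows) <- NULL
  rows[!(rows %in% c(aaAlphabet(), "-"))] <- "X"
  cm <- if (is.null(structure)) rep(NA_integer_, 0) else
    mapAlignmentColumns(structure, rows[1, ])
  new("Alignment", rows = rows, level = level, columnMap = cm)
}

#' Construct an Alignment from a character matrix
#'
#' @param rows character matrix of single symbols (sequences x columns).
#' @param level alignment level.
#' @param columnMap integer map from structure seq_index to column (1-based),
#'   NA where unmapped; defaults to the identity over the columns.
#' @return An \code{Alignment}.
#' @export
makeAlignment <- function(rows, level = "subfamily",
                          columnMap = seq_len(ncol(rows))) {
  dimnames(rows) <- NULL
  new("Alignment", rows = rows, level = level,
      columnMap = as.integer(columnMap))
}

#' Map structure positions to alignment columns
#'
#' Aligns the structure's one-letter sequence against the ungapped first row
#' of the alignment (global pairwise alignment) and returns, for each
#' structure position, the alignment column of its matched row-1 residue.
#' More than 5\% mismatching aligned positions is a hard error.
#'
#' @param structure A \code{ProteinStructure}.
#' @param row1 Character vector: the first alignment row (with gaps).
#' @return Integer vector over structure positions (NA = unmapped).
#' @export
mapAlignmentColumns <- function(structure, row1) {
  cols <- which(row1 != "-")
  ungapped <- paste(row1[cols], collapse = "")
  sseq <- chainSequence(structure)
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(sseq),
                                      Biostrings::AAString(ungapped),
                                      type = "global",
                                      substitutionMatrix = NULL,
                                      gapOpening = 10, gapExtension = 0.5)
  sAln <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  rAln <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  map <- rep(NA_integer_, nchar(sseq))
  si <- 0L; ri <- 0L; matched <- 0L; mismatched <- 0L
  for (k in seq_along(sAln)) {
    isS <- sAln[k] != "-"; isR <- rAln[k] != "-"
    if (isS) si <- si + 1L
    if (isR) ri <- ri + 1L
    if (isS && isR) {
      map[si] <- cols[ri]
      if (sAln[k] == rAln[k]) matched <- matched + 1L else mismatched <- mismatched + 1L
    }
  }
  if (matched + mismatched == 0 ||
      mismatched / (matched + mismatched) > 0.05)
    stop("structure sequence does not match the alignment's first row ",
         "(>5% mismatches)")
  map
}

.column_freqs <- function(alignment, col, gapAsSymbol = FALSE) {
  sym <- alignment@rows[, col]
  if (gapAsSymbol) sym[sym == "-"] <- "gap" else sym <- sym[sym %in% aaAlphabet()]
  sym <- sym[sym != "X"]
  if (!length(sym)) return(NULL)
  lv <- if (gapAsSymbol) c(aaAlphabet(), "gap") else aaAlphabet()
  tab <- table(factor(sym, levels = lv))
  tab / sum(tab)
}

#' Shannon entropy of an alignment column
#'
#' \eqn{H = -\sum_a p_a \log_2 p_a} over the 20 amino acids; gaps are
#' excluded from the counts (optionally counted as a 21st symbol).
#'
#' @param alignment An \code{Alignment}.
#' @param col 1-based column index.
#' @param gapAsSymbol Count the gap as a 21st symbol (default FALSE).
#' @return Entropy in bits, or NA for an all-gap column.
#' @export
columnEntropy <- function(alignment, col, gapAsSymbol = FALSE) {
  p <- .column_freqs(alignment, col, gapAsSymbol)
  if (is.null(p)) return(NA_real_)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Relative entropy of an alignment column
#'
#' \eqn{RE = \sum_a p_a \log_2(p_a/q_a)} against a background distribution
#' \code{q}; by default \code{q} is the amino-acid composition pooled over
#' the whole alignment.
#'
#' @inheritParams columnEntropy
#' @param background Named 20-simplex over the amino acids; NULL = pooled
#'   alignment composition.
#' @return Relative entropy in bits, or NA for an all-gap column.
#' @export
columnRelativeEntropy <- function(alignment, col, background = NULL) {
  p <- .column_freqs(alignment, col)
  if (is.null(p)) return(NA_real_)
  if (is.null(background)) background <- pooledComposition(alignment)
  q <- background[names(p)]
  stopifnot(all(q > 0))
  q <- q / sum(q)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Pooled amino-acid composition of an alignment
#'
#' @param alignment An \code{Alignment}.
#' @return Named 20-vector summing to 1 (a pseudocount of 1 per amino acid
#'   keeps every component strictly positive).
#' @export
pooledComposition <- function(alignment) {
  sym <- alignment@rows[alignment@rows %in% aaAlphabet()]
  tab <- table(factor(sym, levels = aaAlphabet())) + 1
  as.numeric(tab / sum(tab)) -> p
  setNames(p, aaAlphabet())
}

#' Per-structure-position conservation profile
#'
#' Entropy, relative entropy and non-gap coverage for every structure
#' position, using the alignment's column map; unmapped positions are NA.
#'
#' @param alignment An \code{Alignment} with a column map.
#' @param background Optional background for relative entropy.
#' @return data.frame: seq_index, entropy, rel_entropy, coverage.
#' @export
conservationProfile <- function(alignment, background = NULL) {
  cm <- alignment@columnMap
  if (!length(cm)) stop("alignment has no column map; supply a structure")
  if (is.null(background)) background <- pooledComposition(alignment)
  n <- length(cm)
  ent <- re <- cov <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(cm[i])) next
    ent[i] <- columnEntropy(alignment, cm[i])
    re[i] <- columnRelativeEntropy(alignment, cm[i], background)
    cov[i] <- mean(alignment@rows[, cm[i]] %in% aaAlphabet())
  }
  data.frame(seq_index = 0:(n - 1L), entropy = ent, rel_entropy = re,
             coverage = cov)
}

#' Mean conservation over a neighborhood
#'
#' Arithmetic mean of entropy and relative entropy over the neighborhood
#' members that are mapped to alignment columns; NA if none are mapped or
#' the neighborhood is empty.
#'
#' @param profile data.frame from \code{\link{conservationProfile}}.
#' @param neighborhood A \code{Neighborhood}.
#' @return Named list: mean_entropy, mean_rel_entropy.
#' @export
neighborhoodConservation <- function(profile, neighborhood) {
  m <- members(neighborhood)
  if (!length(m)) return(list(mean_entropy = NA_real_,
                              mean_rel_entropy = NA_real_))
  i <- match(m, profile$seq_index)
  e <- profile$entropy[i]; r <- profile$rel_entropy[i]
  if (all(is.na(e))) return(list(mean_entropy = NA_real_,
                                 mean_rel_entropy = NA_real_))
  list(mean_entropy = mean(e, na.rm = TRUE),
       mean_rel_entropy = mean(r, na.rm = TRUE))
}

#' Write a conservation profile as TSV
#'
#' @param profile data.frame from \code{\link{conservationProfile}}.
#' @param path Output file.
#' @export
writeConservationTSV <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
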