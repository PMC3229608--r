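## Synthetic structures, alignments and labeled mutation cohorts with known
## ground truth, emitted through the package's standard formats so that every
## stage of the pipeline can be exercised and calibrated without downloads.

.local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
}

#' Specification of a synthetic protein system
#'
#' Collects the generator parameters: chain length, compactness of the
#' C-alpha random walk, the B-factor model (mean, spread, burial coupling),
#' the alignment model (rows, conserved-column fraction, conservation
#' strength), and the seed that fully determines every generated artifact.
#'
#' @param nResidues Chain length (>= 4).
#' @param compactness In [0,1): strength of the bias pulling the chain walk
#'   back toward its centroid (0.55 gives a compact globule).
#' @param bMean,bSd Mean and spread of residue B-factors (A^2).
#' @param bBurialCoupling Weight of the distance-from-centroid term in the
#'   B-factor (buried residues are more rigid).
#' @param alignRows Sequences in the generated alignment.
#' @param conservedFraction Fraction of columns drawn conserved.
#' @param conservationStrength Probability that a conserved column's row
#'   repeats the consensus residue (1 = invariant column).
#' @param gapFraction Per-cell gap probability in non-first rows.
#' @param seed Integer seed.
#' @return A list with class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(nResidues = 120, compactness = 0.55,
                          bMean = 25, bSd = 8, bBurialCoupling = 0.8,
                          alignRows = 40, conservedFraction = 0.4,
                          conservationStrength = 0.9, gapFraction = 0.02,
                          seed = 1) {
  stopifnot(nResidues >= 4, compactness >= 0, compactness < 1,
            alignRows >= 2)
  structure(list(nResidues = as.integer(nResidues),
                 compactness = compactness, bMean = bMean, bSd = bSd,
                 bBurialCoupling = bBurialCoupling,
                 alignRows = as.integer(alignRows),
                 conservedFraction = conservedFraction,
                 conservationStrength = conservationStrength,
                 gapFraction = gapFraction, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic protein structure
#'
#' Grows a self-avoiding compact C-alpha chain with consecutive virtual
#' bonds of 3.8 +/- 0.01 Angstrom and all non-consecutive C-alpha pairs at
#' least 4.0 Angstrom apart, adds schematic backbone atoms (N, C, O) and one
#' pseudo side-chain atom (CB, absent for Gly), and assigns B-factors that
#' increase with distance from the centroid (burial coupling). The result is
#' written as PDB text and re-read through \code{\link{readStructure}}, so
#' it is guaranteed to round-trip the standard reader.
#'
#' @param spec A \code{\link{syntheticSpec}}.
#' @param chain Chain identifier for the emitted PDB.
#' @param returnText Return the PDB text lines instead of the parsed
#'   structure.
#' @return A \code{\linkS4class{ProteinStructure}} (or PDB lines).
#' @export
generateStructure <- function(spec, chain = "A", returnText = FALSE) {
  restore <- .local_seed(spec$seed)
  on.exit(restore())
  n <- spec$nResidues
  r0 <- 3.3 * n^(1 / 3)          # target globule radius for the walk
  for (restart in 1:25) {
    ca <- matrix(NA_real_, n, 3)
    ca[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:300) {
        cen <- colMeans(ca[1:(i - 1), , drop = FALSE])
        pull <- cen - ca[i - 1, ]
        np <- sqrt(sum(pull^2))
        ## inward bias grows with distance outside the target radius, so the
        ## chain stays globular without forcing collisions in the core
        dir <- .runit() + if (np > 1e-9)
          spec$compactness * (np / r0) * pull / np else 0
        dir <- dir / sqrt(sum(dir^2))
        cand <- ca[i - 1, ] + dir * (3.8 + runif(1, -0.01, 0.01))
        if (i > 2) {
          d <- sqrt(colSums((t(ca[1:(i - 2), , drop = FALSE]) - cand)^2))
          if (any(d < 4.0)) next
        }
        ca[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) stop("chain placement failed; try a lower compactness")

  aa <- sample(aaAlphabet(), n, replace = TRUE)
  cen <- colMeans(ca)
  dcen <- sqrt(colSums((t(ca) - cen)^2))
  zd <- (dcen - mean(dcen)) / max(sd(dcen), 1e-9)
  b_res <- pmax(2, spec$bMean + spec$bBurialCoupling * spec$bSd * zd +
                     rnorm(n, 0, spec$bSd * sqrt(1 - min(spec$bBurialCoupling^2, 1))))
  b_side <- pmax(2, b_res + abs(rnorm(n, 0, 2)))

  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    ## schematic local frame for backbone + pseudo side chain
    bdir <- if (i < n) ca[min(i + 1, n), ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
    bdir <- bdir / sqrt(sum(bdir^2))
    perp <- c(-bdir[2], bdir[1], 0)
    if (sum(perp^2) < 1e-6) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    up <- c(bdir[2] * perp[3] - bdir[3] * perp[2],
            bdir[3] * perp[1] - bdir[1] * perp[3],
            bdir[1] * perp[2] - bdir[2] * perp[1])
    atoms <- list(c("N", "N", ca[i, ] - bdir * 1.46),
                  c("CA", "C", ca[i, ]),
                  c("C", "C", ca[i, ] + bdir * 1.52),
                  c("O", "O", ca[i, ] + bdir * 1.52 + up * 1.23))
    if (aa[i] != "G")
      atoms <- c(atoms, list(c("CB", "C", ca[i, ] + perp * 1.54)))
    for (a in atoms) {
      serial <- serial + 1L
      bfac <- if (a[[1]] == "CB") b_side[i] else b_res[i]
      name4 <- sprintf(" %-3s", a[[1]])
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name4, AA1TO3[aa[i]], chain, i,
        as.numeric(a[[3]]), as.numeric(a[[4]]), as.numeric(a[[5]]),
        1.0, round(bfac, 2), a[[2]]))
    }
  }
  txt <- c(lines, "END")
  if (returnText) return(txt)
  readStructure(txt, chain, sourceId = sprintf("SYN%04d_%s", spec$seed, chain))
}

#' Generate a synthetic alignment for a structure
#'
#' The first row is the structure's own sequence (so the column map is the
#' identity). Conserved columns repeat the consensus residue with the
#' configured strength; non-conserved columns are near-uniform over the 20
#' amino acids. Gaps appear at the configured rate in non-first rows.
#'
#' @param spec A \code{\link{syntheticSpec}}.
#' @param structure The structure whose sequence heads the alignment.
#' @param level Alignment level label.
#' @return An \code{\linkS4class{Alignment}}.
#' @export
generateAlignment <- function(spec, structure, level = "subfamily") {
  restore <- .local_seed(spec$seed + 104729L)
  on.exit(restore())
  seqv <- strsplit(chainSequence(structure), "")[[1]]
  n <- length(seqv)
  conserved <- runif(n) < spec$conservedFraction
  rows <- matrix("", spec$alignRows, n)
  rows[1, ] <- seqv
  for (j in seq_len(n)) {
    if (conserved[j]) {
      hit <- runif(spec$alignRows - 1) < spec$conservationStrength
      rows[-1, j] <- ifelse(hit, seqv[j],
                            sample(aaAlphabet(), spec$alignRows - 1,
                                   replace = TRUE))
    } else {
      rows[-1, j] <- sample(aaAlphabet(), spec$alignRows - 1, replace = TRUE)
    }
    gap <- runif(spec$alignRows - 1) < spec$gapFraction
    if (any(gap)) rows[-1, j][gap] <- "-"
  }
  makeAlignment(rows, level = level, columnMap = seq_len(n))
}

#' Write an Alignment as aligned FASTA
#'
#' @param alignment An \code{Alignment}.
#' @param path Output file.
#' @export
writeAlignmentFasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment@rows))) {
    cat(">seq", i, "\n", paste(alignment@rows[i, ], collapse = ""), "\n",
        sep = "", file = con)
  }
  invisible(path)
}

#' Generate a labeled mutation cohort from a logistic truth model
#'
#' Samples random substitutions, computes their features through the real
#' pipeline, and draws TS/neutral labels from
#' \eqn{P(TS) = 1/(1+e^{-(\beta_0 + \beta^T x)})} over the named truth
#' features (on their raw feature scale). The ground-truth probabilities and
#' coefficients are stored in the result's attributes.
#'
#' @param structure A \code{ProteinStructure}.
#' @param alignment An \code{Alignment} (subfamily) or NULL.
#' @param truthBeta Named numeric: true coefficients over registry features.
#' @param truthBeta0 True intercept.
#' @param n Number of mutations to draw (with replacement over sites).
#' @param seed Integer seed.
#' @param config A \code{\link{featureConfig}}.
#' @param standardizeTruth Apply the truth model to z-scored features
#'   (across the cohort) instead of raw values; keeps the logit range
#'   controlled independently of feature units.
#' @return list(mutations = labeled data.frame, features = FeatureMatrix,
#'   probabilities = true P(TS)); truth parameters in attributes.
#' @export
generateLabeledMutations <- function(structure, alignment, truthBeta,
                                     truthBeta0 = 0, n = 500, seed = 1,
                                     config = featureConfig(),
                                     standardizeTruth = TRUE) {
  res <- residueData(structure)
  nres <- nrow(res)
  npossible <- nres * 19
  if (n > npossible * 50)
    stop("requested cohort larger than available substitutions")
  restore <- .local_seed(seed)
  pos <- sample(nres, n, replace = TRUE)
  wt <- res$aa[pos]
  mut <- vapply(wt, function(a) sample(setdiff(aaAlphabet(), a), 1),
                character(1))
  restore()
  muts <- data.frame(protein_id = sourceId(structure),
                     chain = res$chain[1],
                     position = res$author_number[pos],
                     wt = wt, mut = mut, label = "unknown",
                     stringsAsFactors = FALSE)
  fm <- featurize(muts, structure,
                  alignments = if (is.null(alignment)) list() else
                    list(subfamily = alignment),
                  config = config)
  X <- featureValues(fm)
  stopifnot(all(names(truthBeta) %in% colnames(X)))
  Z <- X[, names(truthBeta), drop = FALSE]
  if (anyNA(Z)) stop("truth features contain masked values")
  if (standardizeTruth)
    Z <- scale(Z, center = TRUE,
               scale = apply(Z, 2, function(v) max(sd(v), 1e-9)))
  eta <- truthBeta0 + drop(Z %*% truthBeta)
  p <- plogis(eta)
  restore2 <- .local_seed(seed + 7919L)
  lab <- rbinom(n, 1, p)
  restore2()
  muts$label <- ifelse(lab == 1, "TS", "neutral")
  fm@mutations$label <- muts$label
  out <- list(mutations = muts, features = fm, probabilities = p)
  attr(out, "truth") <- list(beta = truthBeta, beta0 = truthBeta0,
                             standardized = standardizeTruth, seed = seed)
  out
}

#' Write a mutation list as TSV
#'
#' @param mutations data.frame from \code{\link{readMutations}} /
#'   \code{\link{generateLabeledMutations}}.
#' @param path Output file.
#' @export
writeMutations <- function(mutations, path) {
  write.table(mutations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
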