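## Amino-acid constant tables used throughout the feature registry.
## All tables are keyed by one-letter code in fixed alphabetical order.

#' Canonical amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes in alphabetical order. This order fixes
#' the component order of every 20-dimensional residue-count feature vector.
#'
#' @return Character vector of length 20.
#' @export
aaAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

## Kyte-Doolittle hydropathy index (default hydrophobicity scale).
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8, G = -0.4, H = -3.2,
  I =  4.5, K = -3.9, L =  3.8, M =  1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

## Residue volumes (A^3), Zamyatnin.
AA_VOLUME <- c(
  A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G =  60.1,
  H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1,
  P = 112.7, Q = 143.8, R = 173.4, S =  89.0, T = 116.1, V = 140.0,
  W = 227.8, Y = 193.6)

## Formal side-chain charge at pH 7. His treated as neutral numerically
## (pKa ~6) but grouped with the charged class below.
AA_CHARGE <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0, K = 1,
  L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
  W = 0, Y = 0)

## Three-class physicochemical grouping: non-polar / polar / charged.
AA_CLASS <- c(
  A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
  P = "nonpolar", F = "nonpolar", M = "nonpolar", W = "nonpolar",
  G = "polar", S = "polar", T = "polar", C = "polar", Y = "polar",
  N = "polar", Q = "polar",
  D = "charged", E = "charged", K = "charged", R = "charged", H = "charged")

## Maximum attainable solvent-accessible area per residue type (A^2),
## theoretical values (Tien et al. 2013). A configuration constant for RSA
## normalization, not a fidelity claim about any particular legacy program.
AA_MAX_ASA <- c(
  A = 129, C = 167, D = 193, E = 223, F = 240, G = 104, H = 224, I = 197,
  K = 236, L = 201, M = 224, N = 195, P = 159, Q = 225, R = 274, S = 155,
  T = 172, V = 174, W = 285, Y = 263)

## Grantham (1974) residue properties: composition c, polarity p, volume v.
GRANTHAM_C <- c(
  A = 0.00, C = 2.75, D = 1.38, E = 0.92, F = 0.00, G = 0.74, H = 0.58,
  I = 0.00, K = 0.33, L = 0.00, M = 0.00, N = 1.33, P = 0.39, Q = 0.89,
  R = 0.65, S = 1.42, T = 0.71, V = 0.00, W = 0.13, Y = 0.20)
GRANTHAM_P <- c(
  A =  8.1, C =  5.5, D = 13.0, E = 12.3, F =  5.2, G =  9.0, H = 10.4,
  I =  5.2, K = 11.3, L =  4.9, M =  5.7, N = 11.6, P =  8.0, Q = 10.5,
  R = 10.5, S =  9.2, T =  8.6, V =  5.9, W =  5.4, Y =  6.2)
GRANTHAM_V <- c(
  A =  31.0, C =  55.0, D =  54.0, E =  83.0, F = 132.0, G =   3.0,
  H =  96.0, I = 111.0, K = 119.0, L = 111.0, M = 105.0, N =  56.0,
  P =  32.5, Q =  85.0, R = 124.0, S =  32.0, T =  61.0, V =  84.0,
  W = 170.0, Y = 136.0)

.grantham_matrix <- local({
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  co <- GRANTHAM_C[aa]; po <- GRANTHAM_P[aa]; vo <- GRANTHAM_V[aa]
  raw <- sqrt(1.833 * outer(co, co, "-")^2 +
              0.1018 * outer(po, po, "-")^2 +
              0.000399 * outer(vo, vo, "-")^2)
  ## normalize so the mean over the 190 unordered pairs is 100, as Grantham did
  m <- round(raw * 100 / mean(raw[upper.tri(raw)]))
  dimnames(m) <- list(aa, aa)
  m
})

#' Grantham distance between two amino acids
#'
#' Physicochemical dissimilarity combining composition, polarity and volume,
#' computed from Grantham's 1974 formula and normalized so the mean pairwise
#' distance is 100 (reproducing the published integer table, e.g.
#' \code{granthamDistance("L","I") == 5}, \code{granthamDistance("C","W") == 215}).
#'
#' @param aa1,aa2 One-letter amino-acid codes (vectorized).
#' @return Numeric distance(s); 0 for identical residues.
#' @export
granthamDistance <- function(aa1, aa2) {
  stopifnot(all(aa1 %in% aaAlphabet()), all(aa2 %in% aaAlphabet()))
  .grantham_matrix[cbind(aa1, aa2)]
}

## Van der Waals radii (A) by element for SASA.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
VDW_DEFAULT <- 1.80

#' Default feature configuration
#'
#' Collects the tunable constants of the feature registry: hydrophobicity
#' scale, buried-RSA threshold, unusual-residue set, neighborhood cutoffs,
#' hydrophobic-moment turn angle, and interaction-geometry thresholds.
#'
#' @param hydrophobicity Named numeric scale over the 20 amino acids.
#' @param buriedThreshold RSA at or below which a residue counts as buried.
#' @param unusualResidues Residues flagged by the unusual-residue indicators.
#' @param seqWindow Sequence-neighborhood half-width (residues each side).
#' @param euclideanRadius,topologicalRadius Structural cutoffs in Angstrom.
#' @param momentAngle Hydrophobic-moment turn angle in degrees (100 = helix).
#' @param hbondMax,saltBridgeMax Donor-acceptor distance cutoffs in Angstrom.
#' @param turnBreakers Residues treated as turn breakers when mutated into a
#'   turn/coil position.
#' @param includeSite Logical; include the mutated residue itself in
#'   neighborhood aggregates (default FALSE: the site is not its own neighbor).
#' @return A named list, suitable for the \code{config} argument of
#'   \code{\link{featurize}}.
#' @export
featureConfig <- function(hydrophobicity = KD_HYDROPATHY,
                          buriedThreshold = 0.05,
                          unusualResidues = c("G", "P", "C"),
                          seqWindow = 11,
                          euclideanRadius = 13,
                          topologicalRadius = 13,
                          momentAngle = 100,
                          hbondMax = 3.5,
                          saltBridgeMax = 4.0,
                          turnBreakers = c("P", "G"),
                          includeSite = FALSE) {
  list(hydrophobicity = hydrophobicity,
       buriedThreshold = buriedThreshold,
       unusualResidues = unusualResidues,
       seqWindow = seqWindow,
       euclideanRadius = euclideanRadius,
       topologicalRadius = topologicalRadius,
       momentAngle = momentAngle,
       hbondMax = hbondMax,
       saltBridgeMax = saltBridgeMax,
       turnBreakers = turnBreakers,
       includeSite = includeSite)
}
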