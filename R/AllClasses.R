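#' @import methods
#' @importFrom stats sd var cor quantile rnorm runif rbinom plogis qlogis
#'   setNames dist
#' @importFrom utils head read.delim write.table
#' @importFrom tools file_path_sans_ext
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ProteinStructure: a single-chain residue model
#'
#' Ordered residues of one protein chain parsed from a PDB file: residue
#' identity, C-alpha coordinates, all atoms, and per-residue thermal factors
#' (mean over all atoms, and over side-chain atoms; for Gly the side-chain
#' value falls back to the residue value).
#'
#' @slot residues data.frame with one row per retained residue:
#'   \code{seq_index} (0-based rank), \code{chain}, \code{author_number},
#'   \code{insert}, \code{aa} (one-letter), \code{ca_x,ca_y,ca_z},
#'   \code{b_residue}, \code{b_sidechain}.
#' @slot atoms data.frame with one row per atom: \code{seq_index},
#'   \code{elety} (atom name), \code{elesy} (element), \code{x,y,z}, \code{b}.
#' @slot sourceId character, e.g. \code{"2LZM_A"}.
#' @slot resolution numeric or NULL (Angstrom).
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(residues = "data.frame", atoms = "data.frame",
                 sourceId = "character", resolution = "numericOrNULL"))

setValidity("ProteinStructure", function(object) {
  r <- object@residues
  msg <- character()
  need <- c("seq_index", "chain", "author_number", "insert", "aa",
            "ca_x", "ca_y", "ca_z", "b_residue", "b_sidechain")
  if (!all(need %in% names(r)))
    msg <- c(msg, "residues is missing required columns")
  else {
    if (nrow(r) && !identical(r$seq_index, 0:(nrow(r) - 1L)))
      msg <- c(msg, "seq_index must be contiguous 0..n-1")
    if (anyNA(r$ca_x) || anyNA(r$ca_y) || anyNA(r$ca_z))
      msg <- c(msg, "every retained residue needs a C-alpha coordinate")
    if (any(!is.finite(r$b_residue)) || any(r$b_residue < 0))
      msg <- c(msg, "b_residue must be finite and >= 0")
    if (!all(r$aa %in% aaAlphabet()))
      msg <- c(msg, "non-canonical amino-acid code in residues")
    ord <- order(r$author_number, match(r$insert, c("", LETTERS)))
    if (nrow(r) > 1 && any(diff(r$author_number[ord]) < 0))
      msg <- c(msg, "author_number must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ProteinStructure number of residues
#' @param x,object a \code{ProteinStructure}
#' @export
nResidues <- function(x) nrow(x@residues)

#' @describeIn ProteinStructure residue table accessor
#' @export
residueData <- function(x) x@residues

#' @describeIn ProteinStructure atom table accessor
#' @export
atomData <- function(x) x@atoms

#' @describeIn ProteinStructure n x 3 matrix of C-alpha coordinates
#' @export
caCoords <- function(x) {
  m <- as.matrix(x@residues[, c("ca_x", "ca_y", "ca_z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' @describeIn ProteinStructure one-letter chain sequence
#' @export
chainSequence <- function(x) paste(x@residues$aa, collapse = "")

#' @describeIn ProteinStructure source identifier ("PDBID_chain")
#' @export
sourceId <- function(x) x@sourceId

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure", object@sourceId, "\n",
      " ", nResidues(object), "residues,", nrow(object@atoms), "atoms\n")
})

#' Alignment: a multiple sequence alignment mapped to a structure
#'
#' Aligned rows over the 20 amino acids plus gap, at superfamily or subfamily
#' level, with a map from structure positions (0-based \code{seq_index}) to
#' alignment columns.
#'
#' @slot rows character matrix (sequences x columns) of single characters.
#' @slot level \code{"superfamily"} or \code{"subfamily"}.
#' @slot columnMap integer vector: for structure seq_index i (1-based element
#'   i+1), the 1-based alignment column, or NA if unmapped.
#' @exportClass Alignment
setClass("Alignment",
  representation(rows = "matrix", level = "character", columnMap = "integer"))

setValidity("Alignment", function(object) {
  msg <- character()
  if (!object@level %in% c("superfamily", "subfamily"))
    msg <- c(msg, "level must be superfamily or subfamily")
  ok <- object@rows %in% c(aaAlphabet(), "-", "X")
  if (!all(ok)) msg <- c(msg, "alignment symbols must be AA, '-' or 'X'")
  cm <- object@columnMap[!is.na(object@columnMap)]
  if (anyDuplicated(cm)) msg <- c(msg, "columnMap must be injective")
  if (length(cm) && (any(cm < 1) || any(cm > ncol(object@rows))))
    msg <- c(msg, "columnMap out of range")
  if (length(msg)) msg else TRUE
})

#' @describeIn Alignment number of aligned rows
#' @param x,object an \code{Alignment}
#' @export
nAlignedRows <- function(x) nrow(x@rows)

#' @describeIn Alignment number of alignment columns
#' @export
nAlignedCols <- function(x) ncol(x@rows)

#' @describeIn Alignment structure-to-column map accessor
#' @export
columnMap <- function(x) x@columnMap

setMethod("show", "Alignment", function(object) {
  cat("Alignment (", object@level, "): ", nrow(object@rows), " rows x ",
      ncol(object@rows), " columns; ",
      sum(!is.na(object@columnMap)), " structure positions mapped\n", sep = "")
})

#' Neighborhood of a mutation site
#'
#' A set of residue indices around a site, together with the definition that
#' produced it. The site itself is never a member.
#'
#' @slot kind \code{"sequence"}, \code{"euclidean"} or \code{"topological"}.
#' @slot site 0-based seq_index of the mutation site.
#' @slot cutoff residues (sequence kind) or Angstrom (structural kinds).
#' @slot members integer vector of 0-based seq_index, sorted, excluding site.
#' @exportClass Neighborhood
setClass("Neighborhood",
  representation(kind = "character", site = "integer", cutoff = "numeric",
                 members = "integer"))

setValidity("Neighborhood", function(object) {
  msg <- character()
  if (!object@kind %in% c("sequence", "euclidean", "topological"))
    msg <- c(msg, "unknown neighborhood kind")
  if (object@site %in% object@members)
    msg <- c(msg, "site must not be one of its own members")
  if (is.unsorted(object@members, strictly = TRUE) && length(object@members) > 1)
    msg <- c(msg, "members must be strictly sorted")
  if (length(msg)) msg else TRUE
})

#' @describeIn Neighborhood member indices (0-based)
#' @param x,object a \code{Neighborhood}
#' @export
members <- function(x) x@members

setMethod("show", "Neighborhood", function(object) {
  cat("Neighborhood [", object@kind, "] site=", object@site,
      " cutoff=", object@cutoff, ": ", length(object@members),
      " members\n", sep = "")
})

#' Delaunay tessellation of a C-alpha point set
#'
#' @slot tetrahedra integer matrix (k x 4) of 0-based vertex seq_index,
#'   each row sorted ascending.
#' @slot dtType factor of length k with levels I..V: backbone-connectivity
#'   class of each tetrahedron (run-length partition of its sorted vertices:
#'   \{4\}=I, \{3,1\}=II, \{2,2\}=III, \{2,1,1\}=IV, \{1,1,1,1\}=V).
#' @exportClass Tessellation
setClass("Tessellation",
  representation(tetrahedra = "matrix", dtType = "factor"))

setValidity("Tessellation", function(object) {
  msg <- character()
  if (ncol(object@tetrahedra) != 4)
    msg <- c(msg, "tetrahedra must have 4 columns")
  if (any(apply(object@tetrahedra, 1, anyDuplicated) > 0))
    msg <- c(msg, "tetrahedron vertices must be distinct")
  if (!identical(levels(object@dtType), c("I", "II", "III", "IV", "V")))
    msg <- c(msg, "dtType levels must be I..V")
  if (length(object@dtType) != nrow(object@tetrahedra))
    msg <- c(msg, "one dtType per tetrahedron required")
  if (length(msg)) msg else TRUE
})

#' @describeIn Tessellation tetrahedron vertex matrix (rows sorted)
#' @param x,object a \code{Tessellation}
#' @export
tetrahedra <- function(x) x@tetrahedra

#' @describeIn Tessellation unique Delaunay edges as a 2-column matrix
#' @export
tessellationEdges <- function(x) {
  tt <- x@tetrahedra
  if (!nrow(tt)) return(matrix(integer(), ncol = 2))
  pairs <- rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
                 tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)])
  unique(pairs)
}

#' @describeIn Tessellation backbone-connectivity class per tetrahedron
#' @export
dtTypes <- function(x) x@dtType

setMethod("show", "Tessellation", function(object) {
  cat("Tessellation:", nrow(object@tetrahedra), "tetrahedra;",
      nrow(tessellationEdges(object)), "edges\n")
  print(table(object@dtType))
})

#' FeatureMatrix: named feature values per mutation
#'
#' One row per mutation, one column per registry feature, with an explicit
#' missing-value mask (masked cells are NA in \code{values} and TRUE in
#' \code{mask}).
#'
#' @slot values numeric matrix, mutations x features.
#' @slot mask logical matrix, same shape; TRUE = missing.
#' @slot mutations data.frame describing the rows (protein_id, chain,
#'   position, wt, mut, label, ...).
#' @slot registry character vector of feature names in stable order.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", mask = "matrix",
                 mutations = "data.frame", registry = "character"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must have identical shape")
  if (!identical(colnames(object@values), object@registry))
    msg <- c(msg, "column names must equal the registry")
  if (nrow(object@values) != nrow(object@mutations))
    msg <- c(msg, "one mutation row per matrix row required")
  bad <- !object@mask & !is.finite(object@values)
  if (any(bad)) msg <- c(msg, "non-finite value outside the mask")
  if (any(object@mask & !is.na(object@values)))
    msg <- c(msg, "masked cells must be NA")
  if (length(msg)) msg else TRUE
})

#' @describeIn FeatureMatrix numeric value matrix (NA where masked)
#' @param x,object a \code{FeatureMatrix}
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureMatrix logical missing-value mask
#' @export
featureMask <- function(x) x@mask

#' @describeIn FeatureMatrix mutation description table
#' @export
mutationInfo <- function(x) x@mutations

#' @describeIn FeatureMatrix registry (feature names, stable order)
#' @export
featureRegistry <- function(x) x@registry

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "mutations x",
      ncol(object@values), "features;",
      sum(object@mask), "masked cells\n")
})

#' FittedModel: class-weighted logistic regression on selected features
#'
#' @slot selectedFeatures character vector of feature names in the model.
#' @slot beta numeric coefficients on the original feature scale.
#' @slot beta0 intercept on the original feature scale.
#' @slot classWeights named numeric: per-observation weight for TS and
#'   neutral examples (inverse class frequency, normalized to mean 1).
#' @slot standardization data.frame (feature, mean, sd) used internally.
#' @slot imputeMeans named numeric: training means used to fill masked cells.
#' @slot lassoPath data.frame describing the LARS path (step, feature,
#'   action, bound).
#' @exportClass FittedModel
setClass("FittedModel",
  representation(selectedFeatures = "character", beta = "numeric",
                 beta0 = "numeric", classWeights = "numeric",
                 standardization = "data.frame", imputeMeans = "numeric",
                 lassoPath = "data.frame"))

setValidity("FittedModel", function(object) {
  msg <- character()
  if (length(object@beta) != length(object@selectedFeatures))
    msg <- c(msg, "one coefficient per selected feature required")
  if (length(object@beta0) != 1) msg <- c(msg, "single intercept required")
  if (nrow(object@standardization) &&
      any(object@standardization$sd <= 0))
    msg <- c(msg, "standardization sd must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn FittedModel selected feature names
#' @param x,object a \code{FittedModel}
#' @export
selectedFeatures <- function(x) x@selectedFeatures

#' @describeIn FittedModel LARS path record
#' @export
lassoPath <- function(x) x@lassoPath

setMethod("show", "FittedModel", function(object) {
  cat("FittedModel:", length(object@selectedFeatures), "features,",
      "intercept", signif(object@beta0, 4), "\n")
  if (length(object@selectedFeatures)) {
    co <- setNames(object@beta, object@selectedFeatures)
    print(head(sort(abs(co), decreasing = TRUE), 10))
  }
})

#' EvaluationReport: the five performance measures plus curves
#'
#' @slot measures named numeric: ACC, MCC, KL, DD, AUC.
#' @slot roc data.frame (fpr, tpr), starting (0,0) and ending (1,1).
#' @slot pr data.frame (recall, precision).
#' @slot threshold probability threshold used for ACC/MCC/KL.
#' @slot folds data.frame of per-fold detail (may be empty).
#' @slot predictions data.frame (prob, label, fold, ...) pooled predictions.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(measures = "numeric", roc = "data.frame", pr = "data.frame",
                 threshold = "numeric", folds = "data.frame",
                 predictions = "data.frame"))

setValidity("EvaluationReport", function(object) {
  m <- object@measures
  msg <- character()
  if (!all(c("ACC", "MCC", "KL", "DD", "AUC") %in% names(m)))
    msg <- c(msg, "measures must contain ACC, MCC, KL, DD, AUC")
  else {
    if (is.finite(m["ACC"]) && (m["ACC"] < 0 || m["ACC"] > 1))
      msg <- c(msg, "ACC out of [0,1]")
    if (is.finite(m["MCC"]) && abs(m["MCC"]) > 1 + 1e-12)
      msg <- c(msg, "MCC out of [-1,1]")
    if (is.finite(m["AUC"]) && (m["AUC"] < 0 || m["AUC"] > 1))
      msg <- c(msg, "AUC out of [0,1]")
    if (is.finite(m["DD"]) && m["DD"] < -1e-12)
      msg <- c(msg, "DD must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn EvaluationReport named vector of the five measures
#' @param x,object an \code{EvaluationReport}
#' @export
measures <- function(x) x@measures

#' @describeIn EvaluationReport pooled out-of-fold predictions
#' @export
reportPredictions <- function(x) x@predictions

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (threshold ", object@threshold, "):\n", sep = "")
  print(round(object@measures, 4))
})
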