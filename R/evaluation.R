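## The five performance measures (ACC, MCC, KL, DD, AUC), ROC/PR curves,
## ten-fold and leave-one-protein-out cross-validation, and the
## measure-concordance analysis.

EPS_SMOOTH <- 1e-10

#' Confusion counts at a threshold
#'
#' A probability at or above the threshold predicts TS (inclusive rule).
#' TP = correctly classified TS, FN = TS predicted neutral, TN = correctly
#' classified neutral, FP = neutral predicted TS.
#'
#' @param probs Predicted TS probabilities.
#' @param labels \code{"TS"}/\code{"neutral"} or 0/1.
#' @param t Threshold (default 0.5).
#' @return Named integer vector (TP, FP, TN, FN).
#' @export
confusionCounts <- function(probs, labels, t = 0.5) {
  if (!length(probs)) stop("empty input")
  y <- .as01(labels)
  pred <- probs >= t
  c(TP = sum(pred & y == 1), FP = sum(pred & y == 0),
    TN = sum(!pred & y == 0), FN = sum(!pred & y == 1))
}

#' Accuracy and Matthews correlation from confusion counts
#'
#' \eqn{ACC = (TP+TN)/N};
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
#' defined as 0 when any factor of the denominator is zero.
#'
#' @param conf Named vector from \code{\link{confusionCounts}}.
#' @return Named vector (ACC, MCC).
#' @export
accMcc <- function(conf) {
  tp <- conf[["TP"]]; fp <- conf[["FP"]]; tn <- conf[["TN"]]; fn <- conf[["FN"]]
  total <- tp + fp + tn + fn
  stopifnot(total > 0)
  acc <- (tp + tn) / total
  den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  c(ACC = acc, MCC = mcc)
}

#' Kullback-Leibler divergence between two binary distributions
#'
#' \eqn{KL = \sum_i P(i)\log_2(P(i)/Q(i))} with i ranging over TS and
#' neutral; zeros are smoothed by a tiny epsilon.
#'
#' @param p,q Numeric length-2 distributions (TS, neutral); renormalized.
#' @return KL divergence in bits.
#' @export
klDivergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- pmax(p, EPS_SMOOTH); p <- p / sum(p)
  q <- pmax(q, EPS_SMOOTH); q <- q / sum(q)
  sum(p * log2(p / q))
}

.kl_from_predictions <- function(probs, labels, t) {
  y <- .as01(labels)
  pred_ts <- mean(probs >= t)
  obs_ts <- mean(y)
  klDivergence(c(pred_ts, 1 - pred_ts), c(obs_ts, 1 - obs_ts))
}

#' Distribution distance between predicted TS and neutral probabilities
#'
#' The posterior-probability range is divided into ten equal intervals (the
#' last right-closed); the TS and neutral predictions are histogrammed and
#' normalized, empty bins smoothed by epsilon, and
#' \eqn{DD = \sum_i P(i)\log_2(P(i)/Q(i))} computed over bins. DD is zero
#' exactly when the two binned distributions are identical.
#'
#' @param probs Predicted TS probabilities in [0,1].
#' @param labels \code{"TS"}/\code{"neutral"} or 0/1; both classes required.
#' @param bins Number of intervals (default 10).
#' @param range \code{"unit"} bins [0,1]; \code{"empirical"} bins the
#'   observed probability range.
#' @return DD in bits (>= 0 up to smoothing).
#' @export
distributionDistance <- function(probs, labels, bins = 10,
                                 range = c("unit", "empirical")) {
  range <- match.arg(range)
  y <- .as01(labels)
  if (!any(y == 1) || !any(y == 0)) stop("both classes required for DD")
  lim <- if (range == "unit") c(0, 1) else base::range(probs)
  if (lim[1] == lim[2]) lim <- lim + c(-0.5, 0.5) * 1e-9
  br <- seq(lim[1], lim[2], length.out = bins + 1)
  cut_idx <- function(v) pmin(pmax(findInterval(v, br, rightmost.closed = TRUE),
                                   1L), bins)
  hp <- tabulate(cut_idx(probs[y == 1]), bins)
  hq <- tabulate(cut_idx(probs[y == 0]), bins)
  klDivergence(hp / sum(hp), hq / sum(hq))
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a random TS mutation scores
#' higher than a random neutral one, counting ties as one half; the ROC
#' points (one per distinct score threshold, descending) integrate to the
#' same value by the trapezoidal rule.
#'
#' @param probs Predicted scores.
#' @param labels \code{"TS"}/\code{"neutral"} or 0/1; both classes required.
#' @return list(auc, roc = data.frame(fpr, tpr)).
#' @export
rocAuc <- function(probs, labels) {
  y <- .as01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for ROC")
  r <- rank(probs, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(probs), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(probs >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(probs >= t & y == 0) / n0, numeric(1))
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  roc <- unique(roc)
  list(auc = auc, roc = roc)
}

#' Precision-recall curve
#'
#' Precision TP/(TP+FP) and recall TP/(TP+FN) at descending score
#' thresholds.
#'
#' @inheritParams rocAuc
#' @return data.frame (recall, precision), one row per distinct threshold.
#' @export
precisionRecall <- function(probs, labels) {
  y <- .as01(labels)
  if (!any(y == 1) || !any(y == 0)) stop("both classes required")
  th <- sort(unique(probs), decreasing = TRUE)
  out <- t(vapply(th, function(t) {
    tp <- sum(probs >= t & y == 1); fp <- sum(probs >= t & y == 0)
    c(recall = tp / sum(y == 1),
      precision = if (tp + fp) tp / (tp + fp) else 1)
  }, numeric(2)))
  data.frame(recall = out[, "recall"], precision = out[, "precision"])
}

#' Build an EvaluationReport from predictions
#'
#' @param probs Predicted TS probabilities.
#' @param labels \code{"TS"}/\code{"neutral"} or 0/1.
#' @param threshold Threshold for ACC/MCC/KL (default 0.5).
#' @param folds Optional per-fold detail data.frame.
#' @param extra Optional extra prediction columns (e.g. fold id).
#' @return An \code{\linkS4class{EvaluationReport}}.
#' @export
evaluationReport <- function(probs, labels, threshold = 0.5,
                             folds = data.frame(), extra = NULL) {
  y <- .as01(labels)
  conf <- confusionCounts(probs, y, threshold)
  am <- accMcc(conf)
  ra <- rocAuc(probs, y)
  meas <- c(am, KL = .kl_from_predictions(probs, y, threshold),
            DD = distributionDistance(probs, y), AUC = ra$auc)
  preds <- data.frame(prob = probs, label = ifelse(y == 1, "TS", "neutral"))
  if (!is.null(extra)) preds <- cbind(preds, extra)
  new("EvaluationReport", measures = meas, roc = ra$roc,
      pr = precisionRecall(probs, y), threshold = threshold,
      folds = folds, predictions = preds)
}

#' Cross-validated evaluation of the two-stage TS model
#'
#' Stratified K-fold cross-validation (default ten-fold): within each
#' training fold the model is selected and refitted from scratch, and the
#' held-out predictions are pooled into a single report. The
#' leave-one-protein-out scheme instead holds out all mutations of one
#' protein per fold and emits one report per held-out protein.
#'
#' @param fm A labeled \code{FeatureMatrix}, or a numeric matrix with
#'   \code{labels} (and \code{proteins} for LOPO).
#' @param labels,proteins Optional overrides when \code{fm} is a matrix.
#' @param k Number of folds (stratified scheme).
#' @param scheme \code{"stratified"} or \code{"leave_one_protein_out"}.
#' @param featureSet Feature group or names passed to the fit.
#' @param lassoSteps NULL (CV choice) or a forced step count.
#' @param seed Seed for fold assignment.
#' @param threshold Report threshold.
#' @return An \code{EvaluationReport} (stratified) or a named list of
#'   reports (LOPO).
#' @export
crossValidate <- function(fm, labels = NULL, proteins = NULL, k = 10,
                          scheme = c("stratified", "leave_one_protein_out"),
                          featureSet = "all", lassoSteps = NULL, seed = 1,
                          threshold = 0.5) {
  scheme <- match.arg(scheme)
  if (is(fm, "FeatureMatrix")) {
    X <- featureValues(fm)
    info <- mutationInfo(fm)
    if (is.null(labels)) labels <- info$label
    if (is.null(proteins)) proteins <- info$protein_id
  } else X <- as.matrix(fm)
  y <- .as01(labels)
  feats <- if (length(featureSet) == 1 && featureSet %in%
               c("all", "site", "neighborhood", "sequence_neighborhood",
                 "euclidean_neighborhood", "topological_neighborhood",
                 "sequence", "structure"))
    featureGroup(featureSet) else featureSet
  feats <- intersect(feats, colnames(X))
  Xf <- X[, feats, drop = FALSE]

  fit_fold <- function(tr, te) {
    w <- classWeights(y[tr])
    imp <- suppressWarnings(imputeFeatures(Xf[tr, , drop = FALSE], w))
    sel <- suppressWarnings(larsSelect(imp$X, y[tr], w, nSteps = lassoSteps,
                                       seed = seed))
    rf <- suppressWarnings(refitAndPredict(imp$X, y[tr], w,
                                           subset = sel$selected,
                                           imputeMeans = imp$means))
    Xt <- Xf[te, colnames(imp$X), drop = FALSE]
    imp_te <- suppressWarnings(imputeFeatures(Xt, means = imp$means))
    predictTS(rf$model, imp_te$X)
  }

  if (scheme == "stratified") {
    stopifnot(k <= sum(y == 1), k <= sum(y == 0))
    for (attempt in seq_len(10)) {
      folds <- .stratified_folds(y, k, seed + attempt - 1L)
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[folds != f])) == 2, logical(1)))
      if (ok) break
    }
    if (!ok) stop("could not build folds with both classes in every ",
                  "training set")
    probs <- numeric(length(y))
    for (f in seq_len(k)) {
      te <- which(folds == f)
      probs[te] <- fit_fold(which(folds != f), te)
    }
    return(evaluationReport(probs, y, threshold,
                            folds = data.frame(fold = seq_len(k),
                                               n = tabulate(folds, k)),
                            extra = data.frame(fold = folds)))
  }
  ## leave-one-protein-out
  stopifnot(!is.null(proteins), length(unique(proteins)) >= 2)
  out <- list()
  for (pr in unique(proteins)) {
    te <- which(proteins == pr)
    tr <- which(proteins != pr)
    if (length(unique(y[tr])) < 2) {
      warning("skipping LOPO fold ", pr, ": one class absent from training")
      next
    }
    probs <- fit_fold(tr, te)
    out[[pr]] <- if (length(unique(y[te])) == 2)
      evaluationReport(probs, y[te], threshold) else
      list(probs = probs, labels = y[te])
  }
  out
}

#' Concordance between the five performance measures
#'
#' Given per-classifier values of the five measures (one row per
#' single-feature classifier), computes the 5x5 Pearson correlation matrix
#' and the 5x5 mutual-information matrix (equal-width discretization).
#' A constant measure yields NA (masked) correlations.
#'
#' @param reports data.frame with columns ACC, MCC, KL, DD, AUC, one row per
#'   classifier (at least 3 rows).
#' @param bins Bins for the mutual-information discretization (default 10).
#' @return list(pearson = 5x5 matrix, mutual_information = 5x5 matrix).
#' @export
measureConcordance <- function(reports, bins = 10) {
  cols <- c("ACC", "MCC", "KL", "DD", "AUC")
  stopifnot(all(cols %in% names(reports)), nrow(reports) >= 3)
  M <- as.matrix(reports[, cols])
  pearson <- suppressWarnings(cor(M))
  disc <- apply(M, 2, function(v) {
    if (diff(range(v)) == 0) return(rep(1L, length(v)))
    pmin(pmax(findInterval(v, seq(min(v), max(v), length.out = bins + 1),
                           rightmost.closed = TRUE), 1L), bins)
  })
  mi <- matrix(NA_real_, 5, 5, dimnames = list(cols, cols))
  for (i in 1:5) for (j in 1:5) {
    tab <- table(disc[, i], disc[, j])
    pxy <- tab / sum(tab)
    px <- rowSums(pxy); py <- colSums(pxy)
    nz <- pxy > 0
    mi[i, j] <- sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
  }
  list(pearson = pearson, mutual_information = mi)
}

#' Per-feature single-classifier evaluation
#'
#' Builds one weighted logistic classifier per feature (no selection) and
#' scores each by stratified K-fold cross-validation, producing the table
#' consumed by \code{\link{measureConcordance}} and by cutoff scans.
#'
#' @param fm A labeled \code{FeatureMatrix} or numeric matrix.
#' @param labels Optional labels override.
#' @param features Feature names to evaluate (default: all with any
#'   observed value).
#' @param k Folds (default 10).
#' @param seed Fold seed.
#' @return data.frame: feature, ACC, MCC, KL, DD, AUC.
#' @export
perFeatureEvaluation <- function(fm, labels = NULL, features = NULL, k = 10,
                                 seed = 1) {
  if (is(fm, "FeatureMatrix")) {
    X <- featureValues(fm)
    if (is.null(labels)) labels <- mutationInfo(fm)$label
  } else X <- as.matrix(fm)
  y <- .as01(labels)
  if (is.null(features))
    features <- colnames(X)[colSums(!is.na(X)) > 0]
  rows <- lapply(features, function(f) {
    rep <- tryCatch(
      crossValidate(X[, f, drop = FALSE], labels = y, k = k,
                    featureSet = f, lassoSteps = 1, seed = seed),
      error = function(e) NULL)
    if (is.null(rep)) return(NULL)
    cbind(data.frame(feature = f), as.data.frame(t(measures(rep))))
  })
  do.call(rbind, rows)
}
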