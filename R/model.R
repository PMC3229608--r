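## The TS classifier: inverse-class-weighted logistic regression fitted by
## damped IRLS, with a Lasso feature subset chosen by Least Angle Regression
## on the weighted squared-error surrogate, then refitted (two-stage).

.as01 <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.numeric(labels))
  }
  stopifnot(all(labels %in% c("TS", "neutral")))
  as.numeric(labels == "TS")
}

#' Inverse-class observation weights
#'
#' Weights each example inversely to its class count, normalized so the
#' weights sum to n: both classes then contribute equal total weight,
#' mimicking a 50-50 mixture. A balanced input gets unit weights.
#'
#' @param labels \code{"TS"}/\code{"neutral"} labels or a 0/1 vector.
#' @return Numeric weight per observation, with the per-class values in
#'   attribute \code{"classWeights"}.
#' @export
classWeights <- function(labels) {
  y <- .as01(labels)
  n <- length(y); n1 <- sum(y); n0 <- n - n1
  stopifnot(n1 > 0, n0 > 0)
  w1 <- n / (2 * n1); w0 <- n / (2 * n0)
  w <- ifelse(y == 1, w1, w0)
  attr(w, "classWeights") <- c(TS = w1, neutral = w0)
  w
}

.weighted_standardize <- function(X, weights) {
  sw <- sum(weights)
  mu <- colSums(X * weights) / sw
  Xc <- sweep(X, 2, mu)
  sdv <- sqrt(colSums(Xc^2 * weights) / sw)
  list(mean = mu, sd = sdv)
}

#' Fit a weighted logistic regression by damped IRLS
#'
#' Maximizes the weighted log-likelihood of
#' \eqn{P(y=1|x) = 1/(1+e^{-(\beta_0 + \beta^T x)})} by Newton steps with
#' step-halving, to a gradient tolerance of 1e-8 (relative to the total
#' weight). Features are standardized internally with weighted moments;
#' coefficients are reported on the original scale. Zero-variance features
#' are dropped with a warning; if the optimizer fails to converge (e.g.
#' perfect separation) it converges under a tiny ridge (1e-6) with a
#' warning.
#'
#' @param X Numeric matrix (n x p), p = 0 allowed (intercept-only).
#' @param y 0/1 response or TS/neutral labels.
#' @param weights Observation weights (default inverse-class weights).
#' @param tol Gradient tolerance (scaled by total weight).
#' @param maxIter Maximum Newton iterations.
#' @param ridge Ridge penalty on the standardized slopes (0 = none).
#' @return list(beta0, beta, standardization, converged, logLik, iterations,
#'   fitted).
#' @export
fitWeightedLogistic <- function(X, y, weights = NULL, tol = 1e-8,
                                maxIter = 100, ridge = 0) {
  y <- .as01(y)
  if (is.null(weights)) weights <- classWeights(y)
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  st <- .weighted_standardize(X, weights)
  zero <- which(st$sd <= 0 | !is.finite(st$sd))
  if (length(zero)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[zero], collapse = ", "))
    X <- X[, -zero, drop = FALSE]
    st <- .weighted_standardize(X, weights)
  }
  p <- ncol(X)
  Xs <- if (p) sweep(sweep(X, 2, st$mean), 2, st$sd, "/") else
    matrix(0, nrow(X), 0)
  fit <- .irls(Xs, y, weights, tol, maxIter, ridge)
  ## a diverging linear predictor signals (quasi-)separation: the MLE does
  ## not exist, so converge under a tiny ridge instead
  if (ridge == 0 && (!fit$converged || fit$etaMax > 30)) {
    warning("IRLS did not converge cleanly (possible separation); ",
            "refitting with ridge 1e-6")
    fit <- .irls(Xs, y, weights, tol, maxIter, ridge = 1e-6)
  }
  bs <- fit$beta
  beta <- if (p) bs / st$sd else numeric(0)
  beta0 <- fit$beta0 - if (p) sum(bs * st$mean / st$sd) else 0
  names(beta) <- colnames(X)
  list(beta0 = beta0, beta = beta,
       standardization = data.frame(feature = colnames(X),
                                    mean = unname(st$mean),
                                    sd = unname(st$sd),
                                    stringsAsFactors = FALSE),
       converged = fit$converged, logLik = fit$logLik,
       iterations = fit$iterations, fitted = fit$fitted)
}

.irls <- function(Xs, y, w, tol, maxIter, ridge) {
  n <- nrow(Xs); p <- ncol(Xs)
  b <- rep(0, p); b0 <- 0
  ll <- function(b0, b) {
    eta <- b0 + if (p) drop(Xs %*% b) else 0
    sum(w * (y * eta - log1p(exp(eta)))) - ridge / 2 * sum(b^2)
  }
  cur <- ll(b0, b)
  gtol <- tol * max(1, sum(w))
  converged <- FALSE
  it <- 0
  while (it < maxIter) {
    it <- it + 1
    eta <- b0 + if (p) drop(Xs %*% b) else 0
    mu <- plogis(eta)
    g0 <- sum(w * (y - mu))
    g <- if (p) drop(crossprod(Xs, w * (y - mu))) - ridge * b else numeric(0)
    if (max(abs(c(g0, g))) < gtol) { converged <- TRUE; break }
    wirls <- pmax(w * mu * (1 - mu), 1e-12)
    Xa <- cbind(1, Xs)
    H <- crossprod(Xa, Xa * wirls)
    if (p) diag(H)[-1] <- diag(H)[-1] + ridge
    step <- tryCatch(solve(H, c(g0, g)), error = function(e) NULL)
    if (is.null(step)) {
      H <- H + diag(1e-8, p + 1)
      step <- solve(H, c(g0, g))
    }
    ## damped update: halve until the objective does not decrease
    fac <- 1
    repeat {
      nb0 <- b0 + fac * step[1]
      nb <- if (p) b + fac * step[-1] else b
      nl <- ll(nb0, nb)
      if (nl >= cur - 1e-12 || fac < 1e-8) break
      fac <- fac / 2
    }
    if (nl < cur - 1e-10) break   # no ascent possible; stop
    b0 <- nb0; b <- nb; cur <- nl
  }
  eta <- b0 + if (p) drop(Xs %*% b) else 0
  list(beta0 = b0, beta = b, converged = converged, logLik = cur,
       iterations = it, fitted = plogis(eta), etaMax = max(abs(eta)))
}

#' Impute masked feature values with weighted training means
#'
#' @param X Numeric matrix with NA at masked cells.
#' @param weights Observation weights (NULL = unweighted).
#' @param means Named means to use (test-time imputation); NULL computes
#'   weighted training means. Features that are entirely masked (and have no
#'   supplied mean) are dropped with a warning.
#' @return list(X = complete matrix, means = named means used).
#' @export
imputeFeatures <- function(X, weights = NULL, means = NULL) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (is.null(means)) {
    means <- vapply(seq_len(ncol(X)), function(j) {
      ok <- !is.na(X[, j])
      if (!any(ok)) return(NA_real_)
      sum(X[ok, j] * weights[ok]) / sum(weights[ok])
    }, numeric(1))
    names(means) <- colnames(X)
  }
  means <- means[colnames(X)]
  drop <- which(is.na(means))
  if (length(drop)) {
    warning("dropping entirely masked feature(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    means <- means[-drop]
  }
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- means[j]
  }
  list(X = X, means = means)
}

#' Lasso feature selection via Least Angle Regression
#'
#' Runs the LARS algorithm with the Lasso modification on the weighted
#' squared-error problem (0/1 response, class weights folded into row
#' weights, features standardized internally with weighted moments) and
#' selects the active set at one point of the path: either after a forced
#' number of steps, or at the path prefix minimizing K-fold cross-validated
#' deviance of the downstream weighted logistic refit.
#'
#' @param X Complete numeric matrix (no NA).
#' @param y 0/1 response or TS/neutral labels.
#' @param weights Observation weights (default inverse-class).
#' @param nSteps Force this many LARS steps (NULL = choose by CV).
#' @param cvFolds Folds for the CV choice (default 5).
#' @param maxSteps Cap on path length.
#' @param seed Seed for the CV fold assignment.
#' @return list(selected = feature names, path = data.frame(step, feature,
#'   action, bound), sets = active set after each step, cv = data.frame or
#'   NULL).
#' @export
larsSelect <- function(X, y, weights = NULL, nSteps = NULL, cvFolds = 5,
                       maxSteps = min(ncol(X), nrow(X) - 1L, 50L), seed = 1) {
  y <- .as01(y)
  if (is.null(weights)) weights <- classWeights(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  st <- .weighted_standardize(X, weights)
  keep <- which(st$sd > 0 & is.finite(st$sd))
  Xk <- X[, keep, drop = FALSE]
  if (!ncol(Xk))
    return(list(selected = character(0),
                path = data.frame(step = integer(), feature = character(),
                                  action = character(), bound = numeric()),
                sets = list(), cv = NULL))
  path <- .lars_path(Xk, y, weights, maxSteps)
  sets <- path$sets
  if (!is.null(nSteps)) {
    k <- min(nSteps, length(sets))
    return(list(selected = sets[[k]], path = path$record, sets = sets,
                cv = NULL))
  }
  ## CV deviance of the logistic refit over path prefixes (plus the
  ## intercept-only model as the null candidate)
  sets_all <- c(list(character(0)), sets)
  uniq <- !duplicated(vapply(sets_all, paste, character(1), collapse = "\r"))
  cand <- sets_all[uniq]
  folds <- .stratified_folds(y, cvFolds, seed)
  dev <- vapply(cand, function(s) {
    d <- 0
    for (f in seq_len(cvFolds)) {
      tr <- folds != f; te <- !tr
      fit <- tryCatch(
        fitWeightedLogistic(Xk[tr, s, drop = FALSE], y[tr], weights[tr]),
        warning = function(w)
          suppressWarnings(fitWeightedLogistic(Xk[tr, s, drop = FALSE],
                                               y[tr], weights[tr])))
      p <- plogis(fit$beta0 + if (length(s))
        drop(Xk[te, names(fit$beta), drop = FALSE] %*% fit$beta) else 0)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      d <- d - 2 * sum(weights[te] * (y[te] * log(p) + (1 - y[te]) * log(1 - p)))
    }
    d
  }, numeric(1))
  best <- which(dev <= min(dev) + 1e-10)[1]
  list(selected = cand[[best]], path = path$record, sets = sets,
       cv = data.frame(size = lengths(cand), deviance = dev))
}

## LARS with the Lasso modification on sqrt(weight)-scaled rows.
.lars_path <- function(X, y, w, maxSteps) {
  st <- .weighted_standardize(X, w)
  Xs <- sweep(sweep(X, 2, st$mean), 2, st$sd, "/")
  sw <- sqrt(w)
  Xw <- Xs * sw
  ybar <- sum(y * w) / sum(w)
  yw <- (y - ybar) * sw
  n <- nrow(Xw); p <- ncol(Xw)
  beta <- rep(0, p)
  active <- integer(0)
  mu <- rep(0, n)
  record <- data.frame(step = integer(), feature = character(),
                       action = character(), bound = numeric(),
                       stringsAsFactors = FALSE)
  sets <- list()
  betas <- list()
  step <- 0L
  eps <- 1e-12
  dropped_next <- integer(0)
  ## one extra iteration once all variables are active, to take the final
  ## unconstrained step down to the least-squares end of the path
  while (step < maxSteps + (length(active) == p)) {
    cvec <- drop(crossprod(Xw, yw - mu))
    inactive <- setdiff(setdiff(seq_len(p), active), dropped_next)
    dropped_next <- integer(0)
    if (!length(active)) {
      j <- inactive[which.max(abs(cvec[inactive]))]
      active <- j
      step <- step + 1L
      record <- rbind(record, data.frame(step = step,
                                         feature = colnames(X)[j],
                                         action = "add",
                                         bound = sum(abs(beta))))
    }
    s <- sign(cvec[active])
    Xa <- sweep(Xw[, active, drop = FALSE], 2, s, "*")
    G <- crossprod(Xa)
    Ginv1 <- tryCatch(solve(G, rep(1, length(active))),
                      error = function(e) NULL)
    if (is.null(Ginv1) || !is.finite(sum(Ginv1)) || sum(Ginv1) <= eps) break
    A <- 1 / sqrt(sum(Ginv1))
    wdir <- A * Ginv1
    u <- drop(Xa %*% wdir)
    Cmax <- max(abs(cvec[active]))
    inact <- setdiff(seq_len(p), active)
    if (length(inact)) {
      a <- drop(crossprod(Xw[, inact, drop = FALSE], u))
      cj <- cvec[inact]
      g1 <- (Cmax - cj) / (A - a)
      g2 <- (Cmax + cj) / (A + a)
      cand <- c(g1[which(g1 > eps)], g2[which(g2 > eps)])
      cand <- cand[is.finite(cand)]
      gamma_hat <- if (length(cand)) min(cand) else Cmax / A
      gamma_hat <- min(gamma_hat, Cmax / A)
    } else gamma_hat <- Cmax / A
    ## lasso drop condition: an active coefficient crossing zero
    d <- s * wdir                     # beta-space direction on active set
    gd <- -beta[active] / d
    dropc <- which(gd > eps & gd < gamma_hat - eps)
    if (length(dropc)) {
      gamma <- min(gd[dropc])
      dj <- active[which(gd == gamma)[1]]
    } else { gamma <- gamma_hat; dj <- NA }
    beta[active] <- beta[active] + gamma * d
    mu <- mu + gamma * u
    if (!is.na(dj)) {
      beta[dj] <- 0
      active <- setdiff(active, dj)
      dropped_next <- dj
      step <- step + 1L
      record <- rbind(record, data.frame(step = step,
                                         feature = colnames(X)[dj],
                                         action = "drop",
                                         bound = sum(abs(beta))))
      sets[[length(sets) + 1]] <- colnames(X)[active]
      betas[[length(betas) + 1]] <- setNames(beta, colnames(X))
      next
    }
    sets[[length(sets) + 1]] <- colnames(X)[active]
    betas[[length(betas) + 1]] <- setNames(beta, colnames(X))
    if (length(active) >= p || gamma >= Cmax / A - eps) break
    ## next entering variable
    cvec2 <- drop(crossprod(Xw, yw - mu))
    inact2 <- setdiff(seq_len(p), active)
    if (!length(inact2)) break
    j <- inact2[which.max(abs(cvec2[inact2]))]
    if (abs(cvec2[j]) < eps) break
    active <- c(active, j)
    step <- step + 1L
    record <- rbind(record, data.frame(step = step, feature = colnames(X)[j],
                                       action = "add", bound = sum(abs(beta))))
  }
  if (!length(sets)) sets <- list(colnames(X)[active])
  ## betas[[k]] holds the coefficients (standardized scale) at breakpoint k
  list(record = record, sets = sets, betas = betas,
       beta = setNames(beta, colnames(X)),
       Xw = Xw, yw = yw)
}

.stratified_folds <- function(y, k, seed) {
  f <- integer(length(y))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (cl in unique(y)) {
    i <- which(y == cl)
    f[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  f
}

#' Two-stage fit: Lasso selection, then weighted logistic refit
#'
#' @param X Complete numeric matrix.
#' @param y 0/1 response or TS/neutral labels.
#' @param weights Observation weights (default inverse-class).
#' @param subset Feature names to refit on (e.g. from
#'   \code{\link{larsSelect}}).
#' @param imputeMeans Named training means stored for test-time imputation.
#' @param path Optional LARS path record to store.
#' @return list(model = \code{\linkS4class{FittedModel}},
#'   probabilities = fitted training probabilities).
#' @export
refitAndPredict <- function(X, y, weights = NULL, subset = colnames(X),
                            imputeMeans = numeric(), path = NULL) {
  y01 <- .as01(y)
  if (is.null(weights)) weights <- classWeights(y01)
  cw <- attr(classWeights(y01), "classWeights")
  stopifnot(all(subset %in% colnames(X)))
  fit <- fitWeightedLogistic(X[, subset, drop = FALSE], y01, weights)
  model <- new("FittedModel",
               selectedFeatures = names(fit$beta),
               beta = unname(fit$beta), beta0 = fit$beta0,
               classWeights = cw,
               standardization = fit$standardization,
               imputeMeans = imputeMeans,
               lassoPath = if (is.null(path))
                 data.frame(step = integer(), feature = character(),
                            action = character(), bound = numeric()) else path)
  list(model = model, probabilities = fit$fitted)
}

#' Fit the TS prediction model from a FeatureMatrix
#'
#' The full two-stage pipeline on a labeled feature matrix: restrict to a
#' named feature group, impute masked cells with weighted training means,
#' select a parsimonious subset by Lasso/LARS, and refit a class-weighted
#' logistic regression on the subset.
#'
#' @param fm A \code{\linkS4class{FeatureMatrix}} whose mutations carry
#'   TS/neutral labels, or a plain numeric matrix.
#' @param labels Optional labels (required when \code{fm} is a matrix).
#' @param featureSet A \code{\link{featureGroup}} name or a character vector
#'   of feature names.
#' @param lassoSteps Force the number of LARS steps (NULL = CV choice).
#' @param cvFolds Folds for the selection CV.
#' @param seed Seed for the selection CV folds.
#' @return A \code{\linkS4class{FittedModel}}.
#' @export
fitTSModel <- function(fm, labels = NULL, featureSet = "all",
                       lassoSteps = NULL, cvFolds = 5, seed = 1) {
  if (is(fm, "FeatureMatrix")) {
    X <- featureValues(fm)
    if (is.null(labels)) labels <- mutationInfo(fm)$label
  } else X <- as.matrix(fm)
  y <- .as01(labels)
  feats <- if (length(featureSet) == 1 && featureSet %in%
               c("all", "site", "neighborhood", "sequence_neighborhood",
                 "euclidean_neighborhood", "topological_neighborhood",
                 "sequence", "structure"))
    featureGroup(featureSet) else featureSet
  feats <- intersect(feats, colnames(X))
  w <- classWeights(y)
  imp <- suppressWarnings(imputeFeatures(X[, feats, drop = FALSE], w))
  sel <- suppressWarnings(
    larsSelect(imp$X, y, w, nSteps = lassoSteps, cvFolds = cvFolds,
               seed = seed))
  suppressWarnings(
    refitAndPredict(imp$X, y, w, subset = sel$selected,
                    imputeMeans = imp$means, path = sel$path))$model
}

#' Posterior TS probabilities from a fitted model
#'
#' Imputes masked cells with the stored training means and applies the
#' logistic model; probabilities are strictly inside (0,1).
#'
#' @param model A \code{\linkS4class{FittedModel}}.
#' @param newdata A \code{FeatureMatrix} or numeric matrix containing the
#'   model's features.
#' @return Numeric vector of TS probabilities.
#' @export
predictTS <- function(model, newdata) {
  X <- if (is(newdata, "FeatureMatrix")) featureValues(newdata) else
    as.matrix(newdata)
  feats <- model@selectedFeatures
  stopifnot(all(feats %in% colnames(X)))
  Xm <- X[, feats, drop = FALSE]
  if (anyNA(Xm)) {
    means <- model@imputeMeans[feats]
    for (j in seq_along(feats)) {
      na <- is.na(Xm[, j])
      if (any(na)) Xm[na, j] <- means[j]
    }
  }
  eta <- model@beta0 + if (length(feats)) drop(Xm %*% model@beta) else 0
  plogis(eta)
}

#' Serialize a fitted model to JSON
#'
#' @param model A \code{FittedModel}.
#' @param path Output path.
#' @export
writeModelJSON <- function(model, path) {
  jsonlite::write_json(list(
    selectedFeatures = model@selectedFeatures,
    beta = model@beta, beta0 = model@beta0,
    classWeights = as.list(model@classWeights),
    standardization = model@standardization,
    imputeMeans = as.list(model@imputeMeans),
    lassoPath = model@lassoPath), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by writeModelJSON
#'
#' @param path JSON path.
#' @return A \code{FittedModel}.
#' @export
readModelJSON <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("FittedModel",
      selectedFeatures = as.character(d$selectedFeatures),
      beta = as.numeric(d$beta), beta0 = as.numeric(d$beta0),
      classWeights = unlist(d$classWeights),
      standardization = as.data.frame(d$standardization),
      imputeMeans = unlist(d$imputeMeans),
      lassoPath = as.data.frame(d$lassoPath))
}
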