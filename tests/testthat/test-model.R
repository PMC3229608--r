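test_that("inverse-class weights mimic a 50-50 mixture", {
  w <- classWeights(rep(c("TS", "neutral"), each = 50))
  expect_equal(as.numeric(w), rep(1, 100))
  ## the published corpus imbalance: 747 TS vs 5484 neutral
  y <- c(rep(1, 747), rep(0, 5484))
  w2 <- classWeights(y)
  cw <- attr(w2, "classWeights")
  expect_equal(unname(cw["TS"] / cw["neutral"]), 5484 / 747)
  expect_equal(sum(w2), length(y))
  expect_equal(sum(w2[y == 1]), sum(w2[y == 0]))   # equal class mass
})

test_that("the weighted intercept-only model is symmetric at 50-50", {
  y <- c(rep(1, 20), rep(0, 140))
  fit <- fitWeightedLogistic(matrix(numeric(0), 160, 0), y, classWeights(y))
  expect_equal(fit$beta0, 0, tolerance = 1e-8)
})

test_that("IRLS agrees with glm on weighted problems", {
  skip_if_not_installed("glmnet")   # glm is base; keep one guard for parity
  set.seed(12)
  n <- 400
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  eta <- -0.5 + X %*% c(1, -0.7, 0.3, 0)
  y <- rbinom(n, 1, plogis(eta))
  w <- classWeights(y)
  fit <- fitWeightedLogistic(X, y, w)
  ref <- suppressWarnings(glm.fit(cbind(1, X), y, weights = as.numeric(w),
                                  family = binomial()))
  expect_equal(unname(c(fit$beta0, fit$beta)), unname(ref$coefficients),
               tolerance = 1e-6)
})

test_that("predictions respond monotonically and ignore affine rescaling", {
  set.seed(13)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(X[, 1]))
  fit <- fitWeightedLogistic(X, y)
  expect_true(fit$beta["a"] > 0)
  grid <- seq(-2, 2, length.out = 9)
  p <- plogis(fit$beta0 + grid * fit$beta["a"])
  expect_true(all(diff(p) > 0))
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  ## rescaling a feature leaves the fitted probabilities unchanged
  X2 <- X; X2[, 2] <- X2[, 2] * 1000 + 5
  fit2 <- fitWeightedLogistic(X2, y)
  expect_equal(fit2$fitted, fit$fitted, tolerance = 1e-8)
})

test_that("degenerate fits are handled with warnings", {
  set.seed(99)
  y <- rep(c(0, 1), each = 25)
  X <- cbind(sep = c(rnorm(25, -1), rnorm(25, 1)), cst = 1)
  expect_warning(fit <- fitWeightedLogistic(X, y), "zero-variance")
  ## perfectly separated data converge under the ridge fallback
  Xp <- matrix(c(seq(-1, -0.1, length.out = 25),
                 seq(0.1, 1, length.out = 25)), ncol = 1)
  expect_warning(fit2 <- fitWeightedLogistic(Xp, y), "ridge")
  expect_true(fit2$converged)
})

test_that("weighted log-likelihood never decreases across IRLS iterations", {
  set.seed(77)
  X <- matrix(rnorm(200 * 2), 200, 2)
  y <- rbinom(200, 1, plogis(2 * X[, 1]))
  ## run the optimizer with growing iteration caps and track the objective
  w <- classWeights(y)
  Xs <- scale(X)[, ]
  lls <- vapply(1:8, function(it)
    tsmut:::.irls(Xs, y, w, tol = 1e-8, maxIter = it, ridge = 0)$logLik,
    numeric(1))
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("LARS reproduces soft-thresholding on an orthogonal design", {
  set.seed(21)
  n <- 64; p <- 6
  Q <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE)))
  X <- Q * sqrt(n)                        # exactly orthogonal, psd = 1
  colnames(X) <- paste0("f", 1:p)
  beta_true <- c(3, -2, 1.2, 0.6, 0, 0)
  y <- drop(X %*% beta_true) + rnorm(n, 0, 0.3)
  w <- rep(1, n)
  path <- tsmut:::.lars_path(X, y, w, maxSteps = p)
  b <- drop(crossprod(X, y - mean(y)))    # per-feature inner products
  ord <- order(abs(b), decreasing = TRUE)
  for (k in seq_along(path$betas)) {
    act <- which(abs(path$betas[[k]]) > 1e-10)
    expect_setequal(act, ord[seq_len(length(act))])
    gam <- if (length(act) < p) max(abs(b[-act])) else 0
    soft <- sign(b[act]) * (abs(b[act]) - gam) / n
    expect_equal(unname(path$betas[[k]][act]), unname(soft),
                 tolerance = 1e-8)
  }
})

test_that("every LARS breakpoint satisfies the Lasso KKT conditions", {
  set.seed(33)
  for (rep in 1:8) {
    n <- 80; p <- 12
    X <- matrix(rnorm(n * p), n, p) %*%
      (diag(p) + 0.3 * matrix(runif(p * p), p, p))   # correlated design
    colnames(X) <- paste0("f", 1:p)
    y <- rbinom(n, 1, plogis(X[, 1] - X[, 3]))
    if (length(unique(y)) < 2) next
    w <- classWeights(y)
    path <- tsmut:::.lars_path(X, y, w, maxSteps = p)
    for (k in seq_along(path$betas))
      expect_lt(kkt_violation(path$Xw, path$yw, path$betas[[k]]), 1e-6)
  }
})

test_that("the unconstrained end of the path is weighted least squares", {
  set.seed(41)
  n <- 100; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, plogis(X[, 2]))
  w <- classWeights(y)
  path <- tsmut:::.lars_path(X, y, w, maxSteps = p + 2)
  final <- path$betas[[length(path$betas)]]
  ols <- solve(crossprod(path$Xw), crossprod(path$Xw, path$yw))
  expect_equal(unname(final), unname(drop(ols)), tolerance = 1e-8)
})

test_that("larsSelect honors a forced step count and equiangular ties", {
  set.seed(51)
  X <- matrix(rnorm(150 * 8), 150, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rbinom(150, 1, plogis(1.5 * X[, 1] - X[, 2]))
  sel3 <- larsSelect(X, y, nSteps = 3)
  expect_lte(length(sel3$selected), 3)
  expect_true(all(c("f1", "f2") %in% sel3$sets[[min(3, length(sel3$sets))]]))
  ## active-set correlations tie at each breakpoint (equiangular property)
  path <- tsmut:::.lars_path(X, y, classWeights(y), maxSteps = 8)
  for (k in seq_along(path$betas)) {
    r <- drop(crossprod(path$Xw, path$yw - path$Xw %*% path$betas[[k]]))
    act <- which(abs(path$betas[[k]]) > 1e-10)
    if (length(act) > 1)
      expect_lt(diff(range(abs(r[act]))), 1e-6)
  }
  ## CV-chosen selection returns a subset of the candidate features
  selcv <- larsSelect(X, y, cvFolds = 4, seed = 2)
  expect_true(all(selcv$selected %in% colnames(X)))
})

test_that("selection agrees with an independent Lasso implementation", {
  skip_if_not_installed("glmnet")
  set.seed(61)
  n <- 300; p <- 10
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, plogis(2 * X[, 1] - 1.5 * X[, 2] + X[, 3]))
  sel <- larsSelect(X, y, nSteps = 3)
  g <- glmnet::glmnet(X, y, family = "gaussian", weights =
                        as.numeric(classWeights(y)), standardize = TRUE)
  ## first three variables to enter the glmnet path
  enter <- apply(g$beta != 0, 1, function(r) if (any(r)) which(r)[1] else Inf)
  first3 <- names(sort(enter))[1:3]
  expect_setequal(sel$selected, first3)
})

test_that("imputation fills masked cells with weighted training means", {
  X <- matrix(c(1, 2, 3, 4, NA, 2, 2, 2), 4, 2,
              dimnames = list(NULL, c("a", "b")))
  out <- imputeFeatures(X)
  expect_equal(unname(out$X[1, "b"]), 2)
  expect_equal(out$means[["a"]], 2.5)
  ## no masked cells: unchanged
  expect_equal(imputeFeatures(X[2:4, ])$X, X[2:4, ])
  ## test-time fill uses the stored training mean, not the test mean
  Xtest <- matrix(c(10, NA), 1, 2, dimnames = list(NULL, c("a", "b")))
  out2 <- imputeFeatures(Xtest, means = out$means)
  expect_equal(unname(out2$X[1, "b"]), 2)
  ## an all-masked feature is dropped with a warning
  X3 <- matrix(c(1, 2, NA, NA), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(out3 <- imputeFeatures(X3), "entirely masked")
  expect_equal(colnames(out3$X), "a")
})

test_that("the two-stage refit recovers known coefficients", {
  set.seed(71)
  n <- 2000; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(1.2, -0.8, 0.5, 0, 0)
  y <- rbinom(n, 1, plogis(0.4 + drop(X %*% beta)))
  rf <- refitAndPredict(X, y, subset = paste0("f", 1:5))
  est <- setNames(rf$model@beta, rf$model@selectedFeatures)
  expect_lt(max(abs(est - beta)), 0.15)
  expect_true(all(rf$probabilities > 0 & rf$probabilities < 1))
})

test_that("models survive JSON serialization", {
  set.seed(81)
  X <- matrix(rnorm(120 * 4), 120, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(120, 1, plogis(X[, 1]))
  m <- fitTSModel(X, labels = y, featureSet = paste0("f", 1:4), lassoSteps = 2)
  tf <- tempfile(fileext = ".json")
  writeModelJSON(m, tf)
  m2 <- readModelJSON(tf)
  expect_equal(predictTS(m2, X), predictTS(m, X), tolerance = 1e-12)
  expect_equal(m2@selectedFeatures, m@selectedFeatures)
})
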