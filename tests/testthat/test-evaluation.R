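test_that("confusion counts follow the inclusive threshold rule", {
  probs <- c(1, 1, 0, 0)
  labels <- c("TS", "TS", "neutral", "neutral")
  cc <- confusionCounts(probs, labels)
  expect_equal(unname(cc), c(2, 0, 2, 0))
  ## everything at exactly the threshold is predicted TS
  cc2 <- confusionCounts(rep(0.5, 4), labels)
  expect_equal(unname(cc2["TP"] + cc2["FP"]), 4)
  expect_error(confusionCounts(numeric(0), character(0)), "empty")
  ## random vectors match a direct recount
  set.seed(5)
  p <- runif(50); y <- rbinom(50, 1, 0.4)
  cc3 <- confusionCounts(p, y, 0.3)
  expect_equal(unname(cc3["TP"]), sum(p >= 0.3 & y == 1))
  expect_equal(unname(cc3["FN"]), sum(p < 0.3 & y == 1))
})

test_that("ACC and MCC match the closed formulas", {
  expect_equal(unname(accMcc(c(TP = 50, FP = 0, TN = 50, FN = 0))),
               c(1, 1))
  expect_equal(unname(accMcc(c(TP = 0, FP = 50, TN = 0, FN = 50))["MCC"]),
               -1)
  got <- accMcc(c(TP = 40, FN = 10, TN = 30, FP = 20))
  expect_equal(unname(got["MCC"]), 1000 / sqrt(60 * 50 * 50 * 40))
  expect_equal(unname(got["ACC"]), 0.7)
  ## a zero denominator factor maps to MCC = 0
  expect_equal(unname(accMcc(c(TP = 0, FP = 0, TN = 60, FN = 40))["MCC"]), 0)
  ## inverting the predictions flips the MCC sign and mirrors the ACC
  inv <- accMcc(c(TP = 10, FN = 40, TN = 20, FP = 30))
  fwd <- accMcc(c(TP = 40, FN = 10, TN = 30, FP = 20))
  expect_equal(unname(inv["MCC"]), -unname(fwd["MCC"]))
  expect_equal(unname(inv["ACC"]), 1 - unname(fwd["ACC"]))
})

test_that("KL divergence matches direct summation", {
  expect_equal(klDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), 1, tolerance = 1e-6)
  set.seed(6)
  p <- runif(2); p <- p / sum(p)
  q <- runif(2) + 0.01; q <- q / sum(q)
  expect_equal(klDivergence(p, q), sum(p * log2(p / q)), tolerance = 1e-8)
})

test_that("distribution distance separates and degenerates correctly", {
  ## identical class distributions: DD = 0
  probs <- rep(c(0.1, 0.4, 0.8), times = 2)
  labels <- rep(c("TS", "neutral"), each = 3)
  expect_equal(distributionDistance(probs, labels), 0)
  ## extreme separation: closed form fixed by the epsilon decision
  p2 <- c(rep(0.99, 5), rep(0.01, 5))
  l2 <- rep(c("TS", "neutral"), each = 5)
  eps <- 1e-10
  pd <- pmax(c(rep(0, 9), 1), eps); pd <- pd / sum(pd)
  qd <- pmax(c(1, rep(0, 9)), eps); qd <- qd / sum(qd)
  expect_equal(distributionDistance(p2, l2), sum(pd * log2(pd / qd)))
  ## order invariance and duplication invariance
  set.seed(7)
  p3 <- runif(40); l3 <- rep(c("TS", "neutral"), 20)
  d0 <- distributionDistance(p3, l3)
  perm <- sample(40)
  expect_equal(distributionDistance(p3[perm], l3[perm]), d0)
  expect_equal(distributionDistance(c(p3, p3), c(l3, l3)), d0)
  expect_error(distributionDistance(p3, rep("TS", 40)), "both classes")
})

test_that("AUC equals Mann-Whitney pair counting including ties", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  p <- c(0.9, 0.5, 0.5, 0.3, 0.2, 0.1)
  y <- c(1, 1, 0, 0, 1, 0)
  expect_equal(rocAuc(p, y)$auc, auc_pairs(p, y))
  expect_error(rocAuc(c(0.1, 0.2), c(1, 1)), "both classes")
  ## trapezoidal integration of the ROC curve equals the statistic
  set.seed(8)
  p2 <- runif(60); y2 <- rbinom(60, 1, 0.5)
  ra <- rocAuc(p2, y2)
  trap <- sum(diff(ra$roc$fpr) *
              (head(ra$roc$tpr, -1) + tail(ra$roc$tpr, -1)) / 2)
  expect_equal(trap, ra$auc, tolerance = 1e-12)
  ## ROC endpoints
  expect_equal(unlist(ra$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(ra$roc[nrow(ra$roc), ]), c(fpr = 1, tpr = 1))
})

test_that("precision-recall endpoints behave as expected", {
  ## perfect ranking: precision 1 at every attained recall
  pr <- precisionRecall(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(pr$precision[1:2], c(1, 1))
  expect_equal(pr$recall[1:2], c(0.5, 1))
  ## reversed ranking: precision at full recall equals prevalence
  pr2 <- precisionRecall(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(pr2$precision[pr2$recall == 1], 0.5)
  ## random scores match a loop oracle at each threshold
  set.seed(9)
  p <- runif(30); y <- rbinom(30, 1, 0.5)
  pr3 <- precisionRecall(p, y)
  th <- sort(unique(p), decreasing = TRUE)
  for (i in c(1, 10, 30)) {
    tp <- sum(p >= th[i] & y == 1); fp <- sum(p >= th[i] & y == 0)
    expect_equal(pr3$precision[i], tp / (tp + fp))
    expect_equal(pr3$recall[i], tp / sum(y == 1))
  }
})

test_that("stratified cross-validation partitions the data once", {
  set.seed(10)
  n <- 100
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(1.5 * X[, 1]))
  rep1 <- crossValidate(X, labels = y, k = 10, featureSet = c("a", "b", "c"),
                        lassoSteps = 2, seed = 4)
  preds <- reportPredictions(rep1)
  expect_equal(nrow(preds), n)
  expect_equal(sort(unique(preds$fold)), 1:10)
  expect_equal(unname(table(preds$fold)[1]), 10)
  ## determinism under a fixed seed
  rep2 <- crossValidate(X, labels = y, k = 10, featureSet = c("a", "b", "c"),
                        lassoSteps = 2, seed = 4)
  expect_identical(measures(rep1), measures(rep2))
  ## an informative feature scores above chance
  expect_gt(measures(rep1)["AUC"], 0.6)
})

test_that("leave-one-protein-out emits one report per held-out protein", {
  set.seed(11)
  n <- 150
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(X[, 1]))
  prot <- rep(c("p1", "p2", "p3"), each = 50)
  reps <- crossValidate(X, labels = y, proteins = prot,
                        scheme = "leave_one_protein_out",
                        featureSet = c("a", "b", "c"), lassoSteps = 2)
  expect_setequal(names(reps), c("p1", "p2", "p3"))
  for (r in reps) expect_s4_class(r, "EvaluationReport")
})

test_that("measure concordance matches textbook formulas", {
  set.seed(12)
  d <- data.frame(ACC = runif(20), MCC = runif(20), KL = runif(20),
                  DD = runif(20), AUC = runif(20))
  d$MCC <- -d$ACC                      # exact negative linear relation
  conc <- measureConcordance(d)
  expect_equal(unname(diag(conc$pearson)), rep(1, 5))
  expect_equal(conc$pearson["ACC", "MCC"], -1)
  expect_equal(conc$pearson["ACC", "AUC"], cor(d$ACC, d$AUC))
  ## mutual information equals a direct plug-in computation
  bins <- 10
  cutf <- function(v) pmin(pmax(findInterval(
    v, seq(min(v), max(v), length.out = bins + 1),
    rightmost.closed = TRUE), 1L), bins)
  tab <- table(cutf(d$KL), cutf(d$AUC))
  pxy <- tab / sum(tab); px <- rowSums(pxy); py <- colSums(pxy)
  mi <- sum(pxy[pxy > 0] * log2(pxy[pxy > 0] / outer(px, py)[pxy > 0]))
  expect_equal(conc$mutual_information["KL", "AUC"], mi)
  ## symmetric in its arguments
  expect_equal(conc$mutual_information["AUC", "KL"],
               conc$mutual_information["KL", "AUC"])
  expect_error(measureConcordance(d[1:2, ]), "nrow")
})

test_that("per-feature classifiers feed the concordance analysis", {
  set.seed(14)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(2 * X[, 1]))
  pf <- perFeatureEvaluation(X, labels = y, k = 5, seed = 3)
  expect_equal(pf$feature, c("a", "b", "c"))
  expect_true(all(c("ACC", "MCC", "KL", "DD", "AUC") %in% names(pf)))
  ## the informative feature outranks the noise features
  expect_equal(pf$feature[which.max(pf$AUC)], "a")
  conc <- measureConcordance(pf)
  expect_equal(dim(conc$pearson), c(5, 5))
})

test_that("the evaluation report bundles consistent measures", {
  set.seed(13)
  p <- runif(80); y <- rbinom(80, 1, p)   # calibrated scores
  rep <- evaluationReport(p, y)
  m <- measures(rep)
  expect_true(m["ACC"] >= 0 && m["ACC"] <= 1)
  expect_true(abs(m["MCC"]) <= 1)
  expect_true(m["AUC"] > 0.5)            # calibrated scores are informative
  expect_gte(m["DD"], 0)
  expect_equal(unname(m["AUC"]), auc_pairs(p, y))
})
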