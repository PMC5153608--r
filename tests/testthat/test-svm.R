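blobData <- function(n = 40, sd = 0.1, sep = 3, seed = 0) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n, sep, sd), n / 2, 2),
             matrix(rnorm(n, 0, sd), n / 2, 2))
  featureSet(X, c(rep("positive", n / 2), rep("negative", n / 2)))
}

test_that("grid search separates Gaussian blobs and is seed-deterministic", {
  fs <- blobData(n = 40, seed = 0)
  hp <- gridSearchCV(fs, nFolds = 10L, seed = 0)
  tab <- attr(hp, "cvResults")
  expect_identical(nrow(tab), 48L)  # 6 C-values x 8 gamma-values
  expect_equal(max(tab$accuracy), 1.0)
  hp2 <- gridSearchCV(fs, nFolds = 10L, seed = 0)
  expect_identical(hp[c("cost", "gamma")], hp2[c("cost", "gamma")])
  rep <- leaveOneOut(fs, hp)
  expect_equal(rep@accuracy, 1.0)
})

test_that("grid search refuses classes smaller than the fold count", {
  set.seed(1)
  fs <- featureSet(matrix(rnorm(24), 12, 2),
                   c(rep("positive", 4), rep("negative", 8)))
  expect_error(gridSearchCV(fs, nFolds = 10L, seed = 0),
               class = "amyloidHOG_error_tooSmall")
})

test_that("training handles minimal and XOR-patterned data", {
  fs2 <- list(features = rbind(c(0, 0), c(1, 1)),
              labels = factor(c("negative", "positive"),
                              levels = c("negative", "positive")),
              ids = c("a", "b"))
  m2 <- trainSVM(fs2, cost = 100, gamma = 1)
  p2 <- predictSVM(m2, fs2$features)
  expect_identical(p2$predicted, c("negative", "positive"))

  xor <- list(features = rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)),
              labels = factor(c("negative", "negative", "positive", "positive"),
                              levels = c("negative", "positive")),
              ids = letters[1:4])
  mx <- trainSVM(xor, cost = 100, gamma = 1)
  px <- predictSVM(mx, xor$features)
  expect_identical(px$predicted, as.character(xor$labels))

  expect_error(trainSVM(list(features = matrix(1, 4, 2),
                             labels = factor(c("negative", "positive",
                                               "negative", "positive")),
                             ids = letters[1:4]), 1, 1),
               class = "amyloidHOG_error_degenerate")
})

test_that("models persist and reload to identical decision values", {
  fs <- blobData(n = 20, seed = 2)
  m <- trainSVM(fs, cost = 10, gamma = 1)
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  set.seed(3)
  Xnew <- matrix(rnorm(40, 1.5, 2), 20, 2)
  expect_equal(predictSVM(m2, Xnew)$distance, predictSVM(m, Xnew)$distance,
               tolerance = 1e-12)
})

test_that("leave-one-out is perfect on separable data and chance-level on shuffled labels", {
  fs <- blobData(n = 30, seed = 4)
  rep <- leaveOneOut(fs, list(cost = 10, gamma = 1))
  expect_equal(rep@accuracy, 1.0)
  expect_equal(rep@auc, 1.0)
  expect_identical(nrow(rep@subjects), 30L)

  set.seed(0)
  X <- matrix(rnorm(60), 30, 2)
  lab <- sample(c(rep("positive", 15), rep("negative", 15)))
  fsr <- featureSet(X, lab)
  repr <- leaveOneOut(fsr, list(cost = 10, gamma = 1))
  expect_gte(repr@accuracy, 0.2)
  expect_lte(repr@accuracy, 0.8)

  # confusion bookkeeping: rates recomputable from the subject table
  tab <- table(rep@subjects$label, rep@subjects$predicted)
  expect_identical(sum(tab), 30L)
})

test_that("signed distances agree with predictions and normalize to max 1", {
  fs <- blobData(n = 40, seed = 5)
  m <- trainSVM(fs, cost = 10, gamma = 1)
  set.seed(6)
  Xnew <- matrix(rnorm(200, 1.5, 2), 100, 2)
  p <- predictSVM(m, Xnew)
  expect_identical(p$predicted, ifelse(p$distance > 0, "positive", "negative"))
  nd <- normalizeDistances(p$distance)
  expect_true(all(abs(nd) <= 1))
  expect_equal(max(abs(nd)), 1.0)
  expect_equal(normalizeDistances(-2.5), -1.0)
  expect_error(normalizeDistances(numeric(0)),
               class = "amyloidHOG_error_emptyInput")
})

test_that("ROC/AUC equals the pairwise rank statistic and handles edge cases", {
  r1 <- rocAuc(c(5, 4, 3, 2, 1), c("positive", "positive", "positive",
                                   "negative", "negative"))
  expect_equal(r1$auc, 1.0)

  r2 <- rocAuc(rep(1.7, 10), c(rep("positive", 5), rep("negative", 5)))
  expect_equal(r2$auc, 0.5)

  set.seed(1)
  scores <- rnorm(200)
  labels <- sample(c("positive", "negative"), 200, replace = TRUE,
                   prob = c(0.4, 0.6))
  scores[sample(200, 40)] <- round(scores[sample(200, 40)], 1)  # inject ties
  got <- rocAuc(scores, labels)
  expect_equal(got$auc, oracleAUC(scores, labels), tolerance = 1e-12)

  expect_error(rocAuc(1:5, rep("positive", 5)),
               class = "amyloidHOG_error_singleClass")
  # curve endpoints
  expect_equal(got$points$fpr[1], 0)
  expect_equal(got$points$tpr[nrow(got$points)], 1)
})

test_that("AUC is invariant under strictly monotone score transformations", {
  set.seed(2)
  scores <- rnorm(100)
  labels <- c(rep("positive", 40), rep("negative", 60))
  a0 <- rocAuc(scores, labels)$auc
  expect_equal(rocAuc(3 * scores + 7, labels)$auc, a0, tolerance = 1e-12)
  expect_equal(rocAuc(exp(scores), labels)$auc, a0, tolerance = 1e-12)
  expect_equal(rocAuc(atan(scores), labels)$auc, a0, tolerance = 1e-12)
})

test_that("AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- rnorm(150)
  labels <- sample(c("positive", "negative"), 150, replace = TRUE)
  got <- rocAuc(scores, labels)$auc
  want <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("classification reports serialize to JSON with ROC sidecar", {
  fs <- blobData(n = 20, seed = 7)
  rep <- leaveOneOut(fs, list(cost = 10, gamma = 1))
  path <- tempfile(fileext = ".json")
  writeReport(rep, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$accuracy, rep@accuracy)
  expect_identical(nrow(j$subjects), 20L)
  expect_true(file.exists(paste0(path, ".roc.csv")))
})
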