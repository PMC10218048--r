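test_that("stratified folds partition samples evenly within classes", {
  labels <- rep(c("A", "B"), each = 10)
  fold <- kfoldSplit(labels, k = 10, seed = 1)
  expect_setequal(fold, 1:10)
  for (i in 1:10) {
    expect_equal(sum(fold == i & labels == "A"), 1)
    expect_equal(sum(fold == i & labels == "B"), 1)
  }
  # partition property on ragged classes
  labels <- sample(rep(c("A", "B", "C"), c(23, 17, 41)))
  fold <- kfoldSplit(labels, k = 5, seed = 2)
  expect_length(fold, 81)
  expect_true(all(fold %in% 1:5))
  for (cl in c("A", "B", "C")) {
    counts <- tabulate(fold[labels == cl], 5)
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_identical(kfoldSplit(labels, 5, seed = 9), kfoldSplit(labels, 5, seed = 9))
  expect_error(kfoldSplit(labels, k = 100), "exceeds")
  expect_warning(kfoldSplit(c("A", "A", "B", "B", "B"), k = 3, seed = 1),
                 "best-effort")
})

test_that("rate table rows sum to one and weight into overall accuracy", {
  p <- toyPanel(d = 2, fluids = c("A", "B", "C"))
  truth <- c(rep("A", 4), rep("B", 4), rep("C", 2))
  pred <- c("A", "A", "B", "Other", "B", "B", "inconclusive", "A", "C", "C")
  rt <- rateTable(truth, pred, p)
  expect_equal(rt$fluid, c("A", "B", "C"))
  expect_equal(rt$n, c(4, 4, 2))
  expect_equal(rt$correct + rt$other_bf + rt$other + rt$inconclusive,
               rep(1, 3), tolerance = 1e-12)
  expect_equal(rt$correct, c(0.5, 0.5, 1))
  expect_equal(overallAccuracy(rt), sum(rt$n * rt$correct) / sum(rt$n))
  f <- withr::local_tempfile(fileext = ".csv")
  writeRateTable(rt, f)
  out <- read.csv(f, colClasses = "character")
  expect_equal(out$correct[out$fluid == "overall"], "0.6000")
})

test_that("cross-validation is near-perfect on well-separated classes", {
  panel <- defaultPanel()
  x <- separatedProfiles(panel, nPer = 50, sep = 10, sd = 1, seed = 101)
  cv <- crossValidate(x, k = 10, seed = 7)
  expect_gte(overallAccuracy(cv$rateTable), 0.99)
  expect_equal(sum(cv$rateTable$n), 350)
  expect_equal(cv$rateTable$correct + cv$rateTable$other_bf +
                 cv$rateTable$other + cv$rateTable$inconclusive,
               rep(1, 7), tolerance = 1e-12)
  # every sample appears exactly once in the per-sample results
  expect_setequal(cv$results$sample_id, colnames(x))
})

test_that("cross-validation is at chance when all class means coincide", {
  panel <- defaultPanel()
  withr::with_seed(111, {
    vals <- matrix(rnorm(7 * 350), nrow = 7)
    labs <- rep(fluidClasses(panel), each = 50)
  })
  x <- DeltaCqExperiment(vals, panel, fluidLabels = labs,
                         sampleIds = sprintf("s%03d", 1:350))
  cv <- crossValidate(x, k = 10, seed = 7, gate = FALSE, priors = "uniform")
  acc <- overallAccuracy(cv$rateTable)
  se <- sqrt(0.125 * 0.875 / 350)
  expect_lt(abs(acc - 0.125), 3 * se)
})

test_that("fold parameters are pure functions of the training fold (no leakage)", {
  panel <- defaultPanel()
  cfg <- defaultSimulationConfig()
  x <- simulateProfiles(cfg, seed = 121)
  cv <- crossValidate(x, k = 10, seed = 13)
  for (i in c(1, 5, 10)) {
    fp <- cv$foldParams[[i]]
    train <- x[, fp$trainIds]
    # recompute the pooled imputation MVN from the training fold alone
    mvn2 <- fitMVN(train, ridge = cv$settings$ridge)
    expect_identical(mvnMean(fp$mvn), mvnMean(mvn2))
    expect_identical(mvnCovariance(fp$mvn), mvnCovariance(mvn2))
    # recompute the Other draws from the stored per-fold seed
    other2 <- generateOther(mvn2, n = fp$otherN, radius = cv$settings$radius,
                            inflation = cv$settings$inflation, seed = fp$otherSeed)
    expect_equal(unname(fp$other), unname(other2), tolerance = 0)
    # the held-out samples took no part in training
    heldOut <- cv$results$sample_id[cv$results$fold == i]
    expect_length(intersect(heldOut, fp$trainIds), 0)
  }
})

test_that("repeated cross-validation with one seed is byte-identical", {
  panel <- defaultPanel()
  cfg <- defaultSimulationConfig(classSizes = c(blood = 30L, semen = 30L, saliva = 30L))
  x <- simulateProfiles(cfg, seed = 131)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  cv1 <- crossValidate(x, k = 5, seed = 17)
  cv2 <- crossValidate(x, k = 5, seed = 17)
  utils::write.csv(cv1$results, f1, row.names = FALSE)
  utils::write.csv(cv2$results, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(cv1$rateTable, cv2$rateTable)
  cv3 <- crossValidate(x, k = 5, seed = 18)
  expect_false(identical(cv1$results, cv3$results))
})

test_that("accuracy does not decrease with inter-class separation", {
  panel <- toyPanel(d = 3, fluids = c("A", "B", "C"))
  accs <- vapply(c(1, 3, 6), function(sep) {
    x <- separatedProfiles(panel, nPer = 30, sep = sep, sd = 1, seed = 141)
    overallAccuracy(crossValidate(x, k = 5, seed = 7, gate = FALSE)$rateTable)
  }, numeric(1))
  expect_true(all(diff(accs) > -0.05))
  expect_gt(accs[3], accs[1])
})

test_that("train/predict on files: resubstitution, imputation and determinism", {
  panel <- defaultPanel()
  x <- separatedProfiles(panel, nPer = 30, sep = 10, sd = 1, seed = 151)
  trainF <- withr::local_tempfile(fileext = ".csv")
  queryF <- withr::local_tempfile(fileext = ".csv")
  writeProfiles(x, trainF)
  writeProfiles(x, queryF)
  res <- trainAndPredict(trainF, queryF, panel, seed = 7)
  expect_gte(overallAccuracy(res$rateTable), 0.99)

  # query with one masked marker per sample still yields a call per sample
  vals <- deltaCq(x)
  for (j in seq_len(ncol(vals))) vals[(j %% 7) + 1, j] <- NA
  writeProfiles(DeltaCqExperiment(vals, panel, fluidLabels = fluidLabels(x),
                                  sampleIds = colnames(x)), queryF)
  res2 <- trainAndPredict(trainF, queryF, panel, seed = 7)
  expect_equal(nrow(res2$predictions), ncol(x))
  expect_false(anyNA(res2$predictions$predicted))

  # reruns at one seed write byte-identical prediction files
  o1 <- withr::local_tempfile(fileext = ".csv")
  o2 <- withr::local_tempfile(fileext = ".csv")
  trainAndPredict(trainF, queryF, panel, outPath = o1, seed = 7)
  trainAndPredict(trainF, queryF, panel, outPath = o2, seed = 7)
  expect_identical(readBin(o1, "raw", file.size(o1)),
                   readBin(o2, "raw", file.size(o2)))
})
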