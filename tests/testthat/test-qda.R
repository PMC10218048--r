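test_that("fitQDA estimates per-class moments and priors", {
  p <- toyPanel(d = 1)
  x <- matrix(c(0, 2, 10, 12), ncol = 1)
  labels <- c("A", "A", "B", "B")
  m <- fitQDA(x, labels, p, ridge = 0)
  comp <- classComponents(m)
  expect_equal(unname(mvnMean(comp$A)), 1)
  expect_equal(unname(mvnMean(comp$B)), 11)
  expect_equal(as.numeric(mvnCovariance(comp$A)), 2)   # unbiased
  expect_equal(as.numeric(mvnCovariance(comp$B)), 2)
  expect_equal(unname(classPriors(m)), c(0.5, 0.5))

  # uniform priors over 8 classes
  p8 <- toyPanel(d = 2, fluids = LETTERS[1:7])
  x8 <- separatedProfiles(p8, nPer = 10, seed = 2)
  x8 <- augmentOther(x8, n = 10, seed = 4)
  m8 <- fitQDA(x8, priors = "uniform")
  expect_equal(unname(classPriors(m8)), rep(0.125, 8))
  expect_identical(modelClasses(m8), c(LETTERS[1:7], "Other"))
  m8e <- fitQDA(x8, priors = "empirical")
  expect_equal(sum(classPriors(m8e)), 1)
  expect_equal(unname(classPriors(m8e)), rep(10 / 80, 8))

  # class below the minimum count is a training error naming the class
  bad <- matrix(rnorm(12), ncol = 2)
  expect_error(fitQDA(bad, c(rep("A", 4), "B", "B"), toyPanel(2)), "'B'")
})

test_that("per-class covariance matches an independent two-pass oracle", {
  p <- toyPanel(d = 4, fluids = c("A", "B"))
  withr::with_seed(12, {
    x <- matrix(rnorm(200 * 4), ncol = 4)
    labels <- sample(c("A", "B"), 200, replace = TRUE)
  })
  m <- fitQDA(x, labels, p, ridge = 0)
  for (cl in c("A", "B")) {
    xa <- x[labels == cl, ]
    mu <- colSums(xa) / nrow(xa)
    centered <- sweep(xa, 2, mu)
    sg <- t(centered) %*% centered / (nrow(xa) - 1)
    expect_equal(unname(mvnCovariance(classComponents(m)[[cl]])), unname(sg),
                 tolerance = 1e-12)
    expect_equal(unname(mvnMean(classComponents(m)[[cl]])), unname(mu),
                 tolerance = 1e-12)
  }
})

test_that("posteriors: symmetry, dominance, and the brute-force density oracle", {
  p <- toyPanel(d = 2)
  mirror <- new("QDAModel", panel = p, classes = c("A", "B"),
                components = list(A = MVNParams(c(-3, 0), diag(2)),
                                  B = MVNParams(c(3, 0), diag(2))),
                priors = c(0.5, 0.5), ridge = 0, threshold = 0.5)
  expect_equal(as.numeric(posteriorProbs(mirror, c(0, 5))), c(0.5, 0.5))

  far <- new("QDAModel", panel = p, classes = c("A", "B"),
             components = list(A = MVNParams(c(0, 0), diag(2)),
                               B = MVNParams(c(30, 0), diag(2))),
             priors = c(0.5, 0.5), ridge = 0, threshold = 0.5)
  expect_gt(posteriorProbs(far, c(0, 0))[, "A"], 0.999)
  expect_error(posteriorProbs(far, c(NA, 1)), "finite")

  # brute-force oracle: direct densities with explicit determinant + inverse
  withr::with_seed(33, {
    for (rep in 1:5) {
      d <- 3; K <- 4
      comps <- lapply(1:K, function(k) MVNParams(rnorm(d, sd = 2), randomSPD(d)))
      pr <- runif(K); pr <- pr / sum(pr)
      pk <- toyPanel(d, fluids = paste0("C", 1:K))
      model <- new("QDAModel", panel = pk, classes = paste0("C", 1:K),
                   components = setNames(comps, paste0("C", 1:K)),
                   priors = pr, ridge = 0, threshold = 0.5)
      x <- matrix(rnorm(100 * d, sd = 3), ncol = d)
      dens <- sapply(1:K, function(k) {
        mu <- mvnMean(comps[[k]]); sg <- mvnCovariance(comps[[k]])
        apply(x, 1, function(v) {
          (2 * pi)^(-d / 2) * det(sg)^(-0.5) *
            exp(-0.5 * t(v - mu) %*% solve(sg) %*% (v - mu))
        }) * pr[k]
      })
      brute <- dens / rowSums(dens)
      expect_equal(unname(posteriorProbs(model, x)), unname(brute),
                   tolerance = 1e-10)
      expect_equal(unname(rowSums(posteriorProbs(model, x))), rep(1, 100))
    }
  })
})

test_that("posteriors survive a constant shift of every log-density", {
  # scaling all priors by a constant (renormalized internally via log space)
  # must leave posteriors unchanged: log-sum-exp stability
  p <- toyPanel(d = 2, fluids = c("A", "B", "C"))
  comps <- list(A = MVNParams(c(0, 0), diag(2)),
                B = MVNParams(c(4, 0), diag(2) * 2),
                C = MVNParams(c(0, 4), diag(2) * 0.5))
  m1 <- new("QDAModel", panel = p, classes = names(comps), components = comps,
            priors = c(1, 1, 1) / 3, ridge = 0, threshold = 0.5)
  # a very distant point: naive densities underflow, posteriors must not NaN
  x <- c(200, -200)
  post <- posteriorProbs(m1, x)
  expect_false(anyNA(post))
  expect_equal(sum(post), 1)
})

test_that("classification gate, tie-breaking and single-class behavior", {
  p <- toyPanel(d = 1, fluids = c("A", "B"))
  m <- new("QDAModel", panel = p, classes = c("A", "B"),
           components = list(A = MVNParams(0, matrix(1)),
                             B = MVNParams(6, matrix(1))),
           priors = c(0.5, 0.5), ridge = 0, threshold = 0.5)
  r <- classifyProfiles(m, matrix(c(0, 6), ncol = 1))
  expect_equal(r$predicted, c("A", "B"))
  expect_equal(r$max_posterior, apply(posteriorProbs(m, matrix(c(0, 6))), 1, max))

  # exact midpoint is a 0.5/0.5 tie at threshold 0.5: earlier class wins
  tie <- classifyProfiles(m, matrix(3, ncol = 1))
  expect_equal(tie$predicted, "A")
  expect_equal(tie$max_posterior, 0.5)

  # below the gate the call is inconclusive; without the gate it is the argmax
  m3 <- new("QDAModel", panel = toyPanel(1, fluids = c("A", "B", "C")),
            classes = c("A", "B", "C"),
            components = list(A = MVNParams(-2, matrix(1)),
                              B = MVNParams(0, matrix(1)),
                              C = MVNParams(2, matrix(1))),
            priors = rep(1, 3) / 3, ridge = 0, threshold = 0.5)
  x <- matrix(-1, ncol = 1)   # between A and B: max posterior < 0.5
  expect_lt(max(posteriorProbs(m3, x)), 0.5)
  expect_equal(classifyProfiles(m3, x)$predicted, "inconclusive")
  expect_equal(classifyProfiles(m3, x, gate = FALSE)$predicted, "A")

  single <- new("QDAModel", panel = p, classes = "A",
                components = list(A = MVNParams(0, matrix(1))),
                priors = 1, ridge = 0, threshold = 0.5)
  xs <- matrix(rnorm(20, sd = 10), ncol = 1)
  expect_true(all(posteriorProbs(single, xs) == 1))
  expect_true(all(classifyProfiles(single, xs)$predicted == "A"))
})

test_that("far-outside points are predominantly rejected as Other", {
  panel <- defaultPanel()
  cfg <- defaultSimulationConfig()
  x <- simulateProfiles(cfg, seed = 71)
  mvn <- fitMVN(x)
  xc <- conditionalImpute(x, mvn)
  aug <- augmentOther(xc, seed = 72, params = mvn)
  model <- fitQDA(aug)
  # points at Mahalanobis distance > 6 from the pooled center
  far <- generateOther(mvn, n = 400, radius = 6, inflation = 3, seed = 73)
  pred <- classifyProfiles(model, far, gate = FALSE)$predicted
  expect_gte(mean(pred == "Other"), 0.95)
})

test_that("predicted labels agree with the reference QDA implementation", {
  skip_if_not_installed("MASS")
  panel <- toyPanel(d = 4, fluids = c("A", "B", "C"))
  train <- separatedProfiles(panel, nPer = 40, sep = 3, seed = 81)
  model <- fitQDA(train, ridge = 0, priors = "uniform")
  ref <- MASS::qda(t(deltaCq(train)), grouping = factor(fluidLabels(train)),
                   prior = rep(1, 3) / 3)
  x <- withr::with_seed(82, matrix(rnorm(1000 * 4, sd = 3), ncol = 4))
  ours <- posteriorProbs(model, x)
  theirs <- predict(ref, x)
  ourLab <- modelClasses(model)[apply(ours, 1, which.max)]
  refLab <- as.character(theirs$class)
  margin <- apply(ours, 1, function(r) diff(sort(r, decreasing = TRUE)[2:1]))
  disagree <- ourLab != refLab
  expect_true(all(!disagree | margin < 1e-8))
  # posteriors themselves agree closely
  expect_lt(max(abs(ours[, colnames(theirs$posterior)] - theirs$posterior)), 1e-6)
})
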