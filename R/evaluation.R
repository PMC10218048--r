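#' Stratified k-fold assignment
#'
#' Samples are partitioned into `k` folds so that each class's members are
#' spread as evenly as possible (per-class fold counts differ by at most
#' one). Classes with fewer than `k` members are still spread best-effort,
#' with a warning. Deterministic given `seed`.
#'
#' @param labels class label per sample.
#' @param k number of folds (default 10).
#' @param seed optional integer seed.
#' @return Integer vector of fold indices in `1:k`, one per sample.
#' @export
kfoldSplit <- function(labels, k = 10, seed = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2) .stopf("'k' must be at least 2")
  if (k > n) .stopf("'k' (%d) exceeds the number of samples (%d)", k, n)
  small <- names(which(table(labels) < k))
  if (length(small)) {
    warning(sprintf("class(es) with fewer than k=%d members (%s); stratification is best-effort",
                    k, paste(small, collapse = ", ")), call. = FALSE)
  }
  withSeed(seed, {
    fold <- integer(n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

#' Per-fluid classification rate table
#'
#' The population-table layout: one row per fluid with the sample count and
#' the fractions of calls that were correct, another body fluid, the "Other"
#' rejection class, or inconclusive (sub-threshold). Fractions in each row
#' sum to 1. The overall accuracy is the n-weighted mean of the per-fluid
#' correct rates, stored in `attr(x, "overall_accuracy")`.
#'
#' @param truth true fluid labels.
#' @param predicted predicted labels (fluids, "Other", or "inconclusive").
#' @param panel a [MarkerPanel-class].
#' @return A data.frame with columns `fluid`, `n`, `correct`, `other_bf`,
#'   `other`, `inconclusive`.
#' @export
rateTable <- function(truth, predicted, panel) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  fluids <- intersect(fluidClasses(panel), unique(truth))
  rows <- lapply(fluids, function(f) {
    sel <- truth == f
    n <- sum(sel)
    p <- predicted[sel]
    data.frame(
      fluid = f, n = n,
      correct = mean(p == f),
      other_bf = mean(p %in% setdiff(fluidClasses(panel), f)),
      other = mean(p == otherLabel(panel)),
      inconclusive = mean(p == inconclusiveLabel(panel)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_accuracy") <- sum(out$n * out$correct) / sum(out$n)
  out
}

#' @rdname rateTable
#' @param x a rate table.
#' @export
overallAccuracy <- function(x) attr(x, "overall_accuracy")

#' Write a rate table to CSV
#'
#' Fractions are printed with 4 decimal places; the overall accuracy is
#' appended as a final `overall` row.
#'
#' @param x a rate table from [rateTable] or [crossValidate].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRateTable <- function(x, path) {
  df <- x
  for (cl in c("correct", "other_bf", "other", "inconclusive")) {
    df[[cl]] <- sprintf("%.4f", df[[cl]])
  }
  df <- rbind(df, data.frame(fluid = "overall", n = sum(x$n),
                             correct = sprintf("%.4f", overallAccuracy(x)),
                             other_bf = "", other = "", inconclusive = ""))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Stratified 10-fold cross-validation of the full pipeline
#'
#' For each fold, every data-dependent step is refitted on the training fold
#' only: the pooled MVN used for imputation, the synthetic "Other" draws, and
#' the per-class QDA components. Held-out samples are then imputed and
#' classified with those training-fold parameters, so no information leaks
#' from the validation fold. Setting `imputeFirst = TRUE` instead imputes the
#' whole dataset once from a pooled MVN fitted to all complete cases before
#' splitting, for comparison with pipelines that order the steps that way.
#'
#' @param x a labeled [DeltaCqExperiment-class] spanning all fluid classes
#'   (missingness allowed).
#' @param k number of folds (default 10).
#' @param seed integer seed driving fold assignment and Other draws
#'   (default 7).
#' @param priors,ridge,threshold passed to [fitQDA].
#' @param otherN Other-class size per fold (default: mean training-fold class
#'   size, rounded).
#' @param radius,inflation passed to [generateOther].
#' @param gate apply the posterior confidence gate (default TRUE).
#' @param imputeFirst impute once before splitting instead of per fold.
#' @return An object of class `fluidqda_cv`: a list with `rateTable`,
#'   `results` (per-sample data.frame: `sample_id`, `fold`, `truth`,
#'   `predicted`, `max_posterior`), `foldParams` (per fold: pooled `mvn`,
#'   `other` matrix, `otherSeed`, training sample ids), and the settings.
#' @export
crossValidate <- function(x, k = 10, seed = 7,
                          priors = c("uniform", "empirical"),
                          ridge = 1e-6, threshold = 0.5,
                          otherN = NULL, radius = 3.5, inflation = 2,
                          gate = TRUE, imputeFirst = FALSE) {
  priors <- match.arg(priors)
  labels <- fluidLabels(x)
  if (anyNA(labels)) .stopf("cross-validation requires every profile to be labeled")
  panel <- markerPanel(x)
  fold <- kfoldSplit(labels, k = k, seed = seed)
  otherSeeds <- withSeed(seed + 1L, sample.int(.Machine$integer.max - 1L, k))

  if (imputeFirst) {
    pooledAll <- fitMVN(x, ridge = ridge)
    x <- conditionalImpute(x, pooledAll)
  }

  res <- vector("list", k)
  foldParams <- vector("list", k)
  for (i in seq_len(k)) {
    train <- x[, fold != i]
    test <- x[, fold == i]
    lost <- setdiff(unique(labels), unique(fluidLabels(train)))
    if (length(lost)) {
      .stopf("training fold %d lost class '%s' entirely", i, lost[1L])
    }
    mvn <- fitMVN(train, ridge = ridge)
    trainC <- conditionalImpute(train, mvn)
    nOther <- if (is.null(otherN)) round(mean(table(fluidLabels(trainC)))) else otherN
    aug <- augmentOther(trainC, n = nOther, radius = radius,
                        inflation = inflation, seed = otherSeeds[i], params = mvn)
    model <- fitQDA(aug, priors = priors, ridge = ridge, threshold = threshold)
    testC <- conditionalImpute(test, mvn)
    pred <- classifyProfiles(model, testC, gate = gate)
    res[[i]] <- data.frame(sample_id = pred$sample_id, fold = i,
                           truth = as.character(fluidLabels(test)),
                           predicted = pred$predicted,
                           max_posterior = pred$max_posterior,
                           stringsAsFactors = FALSE)
    otherRows <- t(deltaCq(aug)[, fluidLabels(aug) == otherLabel(panel), drop = FALSE])
    foldParams[[i]] <- list(mvn = mvn, other = otherRows,
                            otherSeed = otherSeeds[i], otherN = nOther,
                            trainIds = colnames(train))
  }
  results <- do.call(rbind, res)
  results <- results[order(match(results$sample_id, colnames(x))), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(
    rateTable = rateTable(results$truth, results$predicted, panel),
    results = results,
    foldParams = foldParams,
    settings = list(k = k, seed = seed, priors = priors, ridge = ridge,
                    threshold = threshold, otherN = otherN, radius = radius,
                    inflation = inflation, gate = gate, imputeFirst = imputeFirst)
  ), class = "fluidqda_cv")
}

#' @export
print.fluidqda_cv <- function(x, ...) {
  cat("Stratified", x$settings$k, "fold cross-validation\n")
  cat(sprintf("overall accuracy: %.4f (n = %d)\n",
              overallAccuracy(x$rateTable), sum(x$rateTable$n)))
  print(x$rateTable, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Train on one profile table and predict another
#'
#' End-to-end orchestration on wide delta-Cq profile CSVs: the training file
#' is read and imputed with its own pooled MVN, augmented with an "Other"
#' class, and used to fit the QDA model; the query file is imputed with the
#' *training* MVN and classified. Every sample with at least one observed
#' marker receives a prediction. When the query file carries fluid labels, a
#' rate table is computed as well. Runs are deterministic given `seed`.
#'
#' @param trainPath,queryPath wide profile CSVs (see [writeProfiles]).
#' @param panel a [MarkerPanel-class] (default [defaultPanel]).
#' @param outPath optional path for the predictions CSV.
#' @param seed integer seed for the Other draws (default 7).
#' @param priors,ridge,threshold passed to [fitQDA].
#' @param otherN,radius,inflation passed to [augmentOther].
#' @param gate apply the posterior confidence gate.
#' @return A list with `predictions` (data.frame from [classifyProfiles]),
#'   `rateTable` (or `NULL` when the query is unlabeled), `model`, and the
#'   pooled `mvn`.
#' @export
trainAndPredict <- function(trainPath, queryPath, panel = defaultPanel(),
                            outPath = NULL, seed = 7,
                            priors = c("uniform", "empirical"),
                            ridge = 1e-6, threshold = 0.5,
                            otherN = NULL, radius = 3.5, inflation = 2,
                            gate = TRUE) {
  priors <- match.arg(priors)
  train <- readProfiles(trainPath, panel)
  query <- readProfiles(queryPath, panel)
  if (anyNA(fluidLabels(train))) .stopf("every training profile must be labeled")
  mvn <- fitMVN(train, ridge = ridge)
  trainC <- conditionalImpute(train, mvn)
  aug <- augmentOther(trainC, n = otherN, radius = radius,
                      inflation = inflation, seed = seed, params = mvn)
  model <- fitQDA(aug, priors = priors, ridge = ridge, threshold = threshold)
  queryC <- conditionalImpute(query, mvn)
  pred <- classifyProfiles(model, queryC, gate = gate)
  rt <- NULL
  qlab <- fluidLabels(query)
  if (!anyNA(qlab)) rt <- rateTable(qlab, pred$predicted, panel)
  if (!is.null(outPath)) {
    out <- pred
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], .num2str)
    utils::write.csv(out, outPath, row.names = FALSE, quote = TRUE)
  }
  list(predictions = pred, rateTable = rt, model = model, mvn = mvn)
}
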