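#' QDAModel: quadratic discriminant classifier over fluids + Other
#'
#' One Gaussian component ([MVNParams-class]) per class with class-specific
#' covariance (hence quadratic decision boundaries), class priors, the ridge
#' used at fit time, and the posterior confidence threshold of the
#' classification gate (default 0.5: a call is only made when the winning
#' posterior reaches 50%).
#'
#' @slot panel the [MarkerPanel-class].
#' @slot classes ordered class names (fluids in panel order, then "Other"
#'   when present).
#' @slot components named list of [MVNParams-class], one per class.
#' @slot priors named numeric class priors, nonnegative, summing to 1.
#' @slot ridge covariance ridge used at fit time.
#' @slot threshold posterior confidence gate in [0, 1].
#'
#' @aliases QDAModel-class
#' @exportClass QDAModel
setClass("QDAModel",
  slots = c(
    panel = "MarkerPanel",
    classes = "character",
    components = "list",
    priors = "numeric",
    ridge = "numeric",
    threshold = "numeric"
  )
)

setValidity("QDAModel", function(object) {
  msgs <- character()
  K <- length(object@classes)
  if (K < 1L) msgs <- c(msgs, "at least one class required")
  if (length(object@components) != K) msgs <- c(msgs, "one component per class required")
  if (length(object@priors) != K) msgs <- c(msgs, "one prior per class required")
  if (any(object@priors < 0)) msgs <- c(msgs, "priors must be nonnegative")
  if (abs(sum(object@priors) - 1) > 1e-12) msgs <- c(msgs, "priors must sum to 1")
  d <- panelDim(object@panel)
  for (k in seq_len(K)) {
    comp <- object@components[[k]]
    if (!is(comp, "MVNParams")) { msgs <- c(msgs, "components must be MVNParams"); break }
    if (length(mvnMean(comp)) != d) {
      msgs <- c(msgs, sprintf("component '%s' dimension differs from panel (%d)",
                              object@classes[k], d))
    }
  }
  if (length(object@threshold) != 1L || object@threshold < 0 || object@threshold > 1) {
    msgs <- c(msgs, "threshold must be a single value in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname QDAModel-class
#' @param x a `QDAModel`.
#' @export
setGeneric("modelClasses", function(x) standardGeneric("modelClasses"))
#' @rdname QDAModel-class
#' @export
setMethod("modelClasses", "QDAModel", function(x) x@classes)

#' @rdname QDAModel-class
#' @export
setGeneric("classPriors", function(x) standardGeneric("classPriors"))
#' @rdname QDAModel-class
#' @export
setMethod("classPriors", "QDAModel", function(x) stats::setNames(x@priors, x@classes))

#' @rdname QDAModel-class
#' @export
setGeneric("classComponents", function(x) standardGeneric("classComponents"))
#' @rdname QDAModel-class
#' @export
setMethod("classComponents", "QDAModel", function(x) {
  stats::setNames(x@components, x@classes)
})

#' @rdname QDAModel-class
#' @export
setGeneric("confidenceThreshold", function(x) standardGeneric("confidenceThreshold"))
#' @rdname QDAModel-class
#' @export
setMethod("confidenceThreshold", "QDAModel", function(x) x@threshold)

#' @rdname QDAModel-class
#' @export
setMethod("markerPanel", "QDAModel", function(x) x@panel)

setMethod("show", "QDAModel", function(object) {
  cat("QDAModel:", length(object@classes), "classes, dimension",
      panelDim(object@panel), "\n")
  cat("  classes :", paste(object@classes, collapse = ", "), "\n")
  cat("  priors  :", paste(signif(object@priors, 3), collapse = ", "), "\n")
  cat("  gate    : posterior >=", object@threshold, "else '",
      inconclusiveLabel(object@panel), "'\n", sep = "")
})

# canonical class order: panel fluids first, Other last, anything else appended
.orderClasses <- function(found, panel) {
  canon <- c(fluidClasses(panel), otherLabel(panel))
  c(intersect(canon, found), setdiff(found, canon))
}

#' Fit the quadratic discriminant model
#'
#' Per class, the mean and unbiased covariance are estimated with [fitMVN]
#' (complete rows; covariance stabilized with `ridge`). Priors are either
#' uniform over all classes (including "Other") or proportional to class
#' counts. Training profiles must be complete (impute first with
#' [conditionalImpute]) and typically include the synthetic Other rows from
#' [augmentOther].
#'
#' @param x a complete, labeled [DeltaCqExperiment-class], or a samples x d
#'   numeric matrix.
#' @param labels class labels per sample (taken from `fluidLabels(x)` for a
#'   `DeltaCqExperiment`).
#' @param panel a [MarkerPanel-class] (taken from `x` when available).
#' @param priors `"uniform"` (default) or `"empirical"`.
#' @param ridge covariance ridge passed to [fitMVN].
#' @param threshold posterior confidence gate (default 0.5).
#' @return A [QDAModel-class].
#' @export
setGeneric("fitQDA", function(x, labels = NULL, panel = NULL,
                              priors = c("uniform", "empirical"),
                              ridge = 1e-6, threshold = 0.5) {
  standardGeneric("fitQDA")
})

#' @rdname fitQDA
#' @export
setMethod("fitQDA", "matrix", function(x, labels = NULL, panel = NULL,
                                       priors = c("uniform", "empirical"),
                                       ridge = 1e-6, threshold = 0.5) {
  priors <- match.arg(priors)
  if (is.null(labels)) .stopf("'labels' are required to train")
  if (is.null(panel)) .stopf("a MarkerPanel is required")
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) .stopf("'labels' must match the number of rows")
  if (anyNA(x)) .stopf("training profiles must be complete; impute first")
  if (anyNA(labels)) .stopf("all training profiles must be labeled")
  d <- ncol(x)
  classes <- .orderClasses(unique(labels), panel)
  counts <- table(factor(labels, levels = classes))
  small <- classes[counts < d + 1L]
  if (length(small)) {
    .stopf("class '%s' has %d complete rows; need at least %d",
           small[1L], counts[[small[1L]]], d + 1L)
  }
  comps <- lapply(classes, function(k) fitMVN(x[labels == k, , drop = FALSE], ridge = ridge))
  pr <- switch(priors,
    uniform = rep(1 / length(classes), length(classes)),
    empirical = as.numeric(counts) / sum(counts)
  )
  new("QDAModel", panel = panel, classes = classes,
      components = stats::setNames(comps, classes),
      priors = pr, ridge = ridge, threshold = threshold)
})

#' @rdname fitQDA
#' @export
setMethod("fitQDA", "DeltaCqExperiment", function(x, labels = NULL, panel = NULL,
                                                  priors = c("uniform", "empirical"),
                                                  ridge = 1e-6, threshold = 0.5) {
  if (is.null(labels)) labels <- fluidLabels(x)
  fitQDA(t(deltaCq(x)), labels = labels, panel = markerPanel(x),
         priors = priors, ridge = ridge, threshold = threshold)
})

# per-class log pi_k + log N(x; mu_k, Sigma_k) for an n x d matrix
.logJoint <- function(model, x) {
  d <- ncol(x)
  K <- length(model@classes)
  out <- matrix(NA_real_, nrow = nrow(x), ncol = K,
                dimnames = list(rownames(x), model@classes))
  for (k in seq_len(K)) {
    comp <- model@components[[k]]
    R <- .cholOrStop(mvnCovariance(comp), paste0("class '", model@classes[k], "' covariance"))
    logdet <- 2 * sum(log(diag(R)))
    z <- backsolve(R, t(x) - mvnMean(comp), transpose = TRUE)
    maha2 <- colSums(z^2)
    out[, k] <- log(model@priors[k]) - 0.5 * (d * log(2 * pi) + logdet + maha2)
  }
  out
}

#' Class posterior probabilities
#'
#' `p(k | x)` proportional to `pi_k N(x; mu_k, Sigma_k)`, evaluated in log
#' space with max-subtraction before exponentiation so that distant points do
#' not underflow to 0/0.
#'
#' @param model a [QDAModel-class].
#' @param x numeric vector of length d, an n x d matrix, or a complete
#'   [DeltaCqExperiment-class].
#' @return An n x K matrix of posteriors; rows sum to 1.
#' @export
posteriorProbs <- function(model, x) {
  if (is(x, "DeltaCqExperiment")) x <- t(deltaCq(x))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d <- panelDim(model@panel)
  if (ncol(x) != d) .stopf("'x' must have %d columns", d)
  if (anyNA(x) || any(!is.finite(x))) .stopf("'x' must be finite and complete")
  lj <- .logJoint(model, x)
  m <- apply(lj, 1, max)
  w <- exp(lj - m)
  w / rowSums(w)
}

#' Classify profiles with the posterior confidence gate
#'
#' The predicted class is the posterior argmax when that posterior reaches
#' the model's confidence threshold; below the threshold the call is the
#' panel's inconclusive label. Exact posterior ties go to the earlier class
#' in canonical order (panel fluid order, then "Other"). Disabling the gate
#' (`gate = FALSE`) always reports the argmax class, reproducing the
#' three-outcome layout (correct / other body fluid / Other) of population
#' rate tables that have no inconclusive column.
#'
#' @param model a [QDAModel-class].
#' @param x profiles as in [posteriorProbs].
#' @param gate apply the confidence threshold (default TRUE).
#' @return A data.frame: `sample_id`, `predicted`, `max_posterior`, then one
#'   `posterior.<class>` column per class.
#' @export
classifyProfiles <- function(model, x, gate = TRUE) {
  ids <- if (is(x, "DeltaCqExperiment")) colnames(x) else rownames(x)
  post <- posteriorProbs(model, x)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(post)))
  best <- apply(post, 1, which.max)       # ties: first (canonical) class wins
  maxp <- post[cbind(seq_len(nrow(post)), best)]
  pred <- model@classes[best]
  if (gate) pred[maxp < model@threshold] <- inconclusiveLabel(model@panel)
  out <- data.frame(sample_id = ids, predicted = pred,
                    max_posterior = maxp, stringsAsFactors = FALSE)
  postdf <- as.data.frame(post)
  names(postdf) <- paste0("posterior.", colnames(post))
  rownames(out) <- NULL
  cbind(out, postdf)
}

#' Augment labeled profiles with a synthetic Other class
#'
#' Fits the pooled MVN to the complete profiles (all fluids together), draws
#' `n` vectors outside the `radius` ellipsoid with [generateOther], and
#' appends them as samples labeled with the panel's Other label. The default
#' `n` is the rounded mean fluid-class size, keeping the augmented design
#' roughly balanced.
#'
#' @param x a complete, labeled [DeltaCqExperiment-class].
#' @param n number of Other rows (default: mean class size, rounded).
#' @param radius,inflation,seed passed to [generateOther].
#' @param ridge passed to [fitMVN] for the pooled component.
#' @param params optional pooled [MVNParams-class] to use instead of
#'   refitting (e.g. the training-fold MVN inside cross-validation).
#' @return A [DeltaCqExperiment-class] with `n` extra "Other" columns.
#' @export
augmentOther <- function(x, n = NULL, radius = 3.5, inflation = 2,
                         ridge = 1e-6, seed = NULL, params = NULL) {
  if (is.null(params)) params <- fitMVN(x, ridge = ridge)
  if (is.null(n)) {
    n <- round(mean(table(fluidLabels(x))))
  }
  other <- generateOther(params, n = n, radius = radius,
                         inflation = inflation, seed = seed)
  oexp <- DeltaCqExperiment(t(other), markerPanel(x),
                            fluidLabels = otherLabel(markerPanel(x)),
                            sampleIds = sprintf("other_%03d", seq_len(n)))
  .bindProfiles(x, oexp)
}

#' Write classification results to CSV
#'
#' @param results data.frame from [classifyProfiles].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
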