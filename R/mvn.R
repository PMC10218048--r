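#' MVNParams: a multivariate-normal component
#'
#' Mean vector (delta-Cq cycles) and symmetric positive-semidefinite
#' covariance (cycles^2) of one Gaussian component, used both for the pooled
#' imputation model and for the per-class components of the quadratic
#' discriminant classifier.
#'
#' @slot mean numeric length-d mean vector.
#' @slot covariance numeric d x d symmetric PSD matrix.
#'
#' @aliases MVNParams-class
#' @exportClass MVNParams
setClass("MVNParams",
  slots = c(mean = "numeric", covariance = "matrix")
)

setValidity("MVNParams", function(object) {
  msgs <- character()
  d <- length(object@mean)
  if (!is.numeric(object@covariance)) msgs <- c(msgs, "covariance must be numeric")
  if (nrow(object@covariance) != d || ncol(object@covariance) != d) {
    msgs <- c(msgs, "covariance dimensions must match the mean length")
  } else {
    if (!.isSymmetric(object@covariance)) {
      msgs <- c(msgs, "covariance must be symmetric")
    } else {
      ev <- eigen(object@covariance, symmetric = TRUE, only.values = TRUE)$values
      scale <- max(1, max(abs(ev)))
      if (min(ev) < -1e-8 * scale) {
        msgs <- c(msgs, "covariance must be positive semidefinite (negative eigenvalue found)")
      }
    }
  }
  if (anyNA(object@mean) || anyNA(object@covariance)) {
    msgs <- c(msgs, "mean and covariance must be free of missing values")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct MVNParams
#'
#' @param mean numeric mean vector; names, if any, name the markers.
#' @param covariance symmetric PSD matrix matching `mean`.
#' @return An [MVNParams-class].
#' @examples
#' MVNParams(c(0, 0), diag(2))
#' @export
MVNParams <- function(mean, covariance) {
  covariance <- as.matrix(covariance)
  if (!is.null(names(mean)) && is.null(rownames(covariance))) {
    dimnames(covariance) <- list(names(mean), names(mean))
  }
  m <- as.numeric(mean)
  names(m) <- names(mean)
  new("MVNParams", mean = m, covariance = covariance)
}

#' @rdname MVNParams
#' @param x an `MVNParams`.
#' @export
setGeneric("mvnMean", function(x) standardGeneric("mvnMean"))
#' @rdname MVNParams
#' @export
setMethod("mvnMean", "MVNParams", function(x) x@mean)

#' @rdname MVNParams
#' @export
setGeneric("mvnCovariance", function(x) standardGeneric("mvnCovariance"))
#' @rdname MVNParams
#' @export
setMethod("mvnCovariance", "MVNParams", function(x) x@covariance)

setMethod("show", "MVNParams", function(object) {
  cat("MVNParams, dimension", length(object@mean), "\n")
  cat("  mean:", paste(signif(object@mean, 4), collapse = ", "), "\n")
  cat("  covariance trace:", signif(sum(diag(object@covariance)), 4), "\n")
})

# Cholesky factor with an actionable error on singularity.
.cholOrStop <- function(sigma, context = "covariance") {
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) {
    .stopf("%s matrix is singular or not positive-definite; increase 'ridge'",
           context)
  }
  R
}

#' Fit a multivariate normal to complete profiles
#'
#' Estimates the mean and the unbiased sample covariance from the fully
#' observed profiles only (samples with any masked marker are ignored), then
#' stabilizes the covariance by adding `ridge * trace/d` to the diagonal.
#' Complete-case estimation avoids the circularity of imputing with a model
#' fitted on imputed values; the ridge keeps the matrix invertible when
#' markers are nearly collinear.
#'
#' @param x a [DeltaCqExperiment-class], or a numeric samples x d matrix
#'   (rows with `NA` are dropped as incomplete).
#' @param ridge nonnegative scalar; `ridge * mean(diag(cov))` is added to the
#'   covariance diagonal (default `1e-6`).
#' @return An [MVNParams-class].
#' @export
setGeneric("fitMVN", function(x, ridge = 1e-6) standardGeneric("fitMVN"))

#' @rdname fitMVN
#' @export
setMethod("fitMVN", "matrix", function(x, ridge = 1e-6) {
  if (ridge < 0) .stopf("'ridge' must be nonnegative")
  ok <- stats::complete.cases(x)
  xc <- x[ok, , drop = FALSE]
  d <- ncol(xc)
  if (nrow(xc) < d + 1L) {
    .stopf("need at least %d fully observed profiles to fit a %d-dim MVN, got %d",
           d + 1L, d, nrow(xc))
  }
  mu <- colMeans(xc)
  sigma <- stats::cov(xc)            # unbiased, divisor n-1
  sigma <- (sigma + t(sigma)) / 2
  if (ridge > 0) {
    sigma <- sigma + diag(ridge * mean(diag(sigma)), d)
  }
  MVNParams(mu, sigma)
})

#' @rdname fitMVN
#' @export
setMethod("fitMVN", "DeltaCqExperiment", function(x, ridge = 1e-6) {
  fitMVN(t(deltaCq(x)), ridge = ridge)
})

#' Mahalanobis distance to an MVN component
#'
#' `sqrt((x - mu)' Sigma^-1 (x - mu))`, the covariance-scaled distance whose
#' level set at radius r is the "r-standard-deviation ellipsoid". Computed
#' through the Cholesky factor of the covariance.
#'
#' @param x numeric vector of length d, or an n x d matrix of row vectors.
#' @param params an [MVNParams-class] with positive-definite covariance.
#' @return Numeric vector of distances (unitless, >= 0).
#' @examples
#' p <- MVNParams(0, matrix(4))
#' mahalanobisDistance(7, p)  # 3.5
#' @export
mahalanobisDistance <- function(x, params) {
  mu <- mvnMean(params)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(mu)) .stopf("'x' must have %d columns", length(mu))
  R <- .cholOrStop(mvnCovariance(params))
  centered <- t(x) - mu
  z <- backsolve(R, centered, transpose = TRUE)
  sqrt(colSums(z^2))
}

#' Conditional-mean imputation of missing markers
#'
#' Fills each profile's missing block with the conditional multivariate-normal
#' mean given its observed block: `mu_m + Sigma_mo Sigma_oo^-1 (x_o - mu_o)`.
#' A single imputation that depends on all observed values of the sample;
#' observed entries are never modified. Profiles with no observed marker
#' cannot be conditioned on anything and raise an error.
#'
#' @param x a [DeltaCqExperiment-class] (any missingness pattern), or a
#'   numeric vector with `NA` for missing entries.
#' @param params pooled [MVNParams-class] (typically from [fitMVN] on the
#'   training profiles).
#' @return Same class as `x`, fully observed.
#' @export
setGeneric("conditionalImpute", function(x, params) standardGeneric("conditionalImpute"))

.imputeVector <- function(v, mu, sigma) {
  m <- is.na(v)
  if (!any(m)) return(v)
  if (all(m)) .stopf("profile is fully missing; cannot condition on nothing")
  o <- !m
  S_oo <- sigma[o, o, drop = FALSE]
  S_mo <- sigma[m, o, drop = FALSE]
  R <- .cholOrStop(S_oo, "observed-block covariance")
  w <- backsolve(R, backsolve(R, v[o] - mu[o], transpose = TRUE))
  v[m] <- mu[m] + as.numeric(S_mo %*% w)
  v
}

#' @rdname conditionalImpute
#' @export
setMethod("conditionalImpute", "numeric", function(x, params) {
  if (length(x) != length(mvnMean(params))) {
    .stopf("profile length %d does not match MVN dimension %d",
           length(x), length(mvnMean(params)))
  }
  .imputeVector(x, mvnMean(params), mvnCovariance(params))
})

#' @rdname conditionalImpute
#' @export
setMethod("conditionalImpute", "DeltaCqExperiment", function(x, params) {
  vals <- deltaCq(x)
  if (nrow(vals) != length(mvnMean(params))) {
    .stopf("panel dimension %d does not match MVN dimension %d",
           nrow(vals), length(mvnMean(params)))
  }
  mu <- mvnMean(params); sigma <- mvnCovariance(params)
  for (j in seq_len(ncol(vals))) {
    if (anyNA(vals[, j])) {
      if (all(is.na(vals[, j]))) {
        .stopf("sample '%s' is fully missing; cannot condition on nothing",
               colnames(vals)[j])
      }
      vals[, j] <- .imputeVector(vals[, j], mu, sigma)
    }
  }
  out <- DeltaCqExperiment(vals, markerPanel(x),
                           fluidLabels = fluidLabels(x),
                           sampleIds = colnames(x))
  metadata(out) <- metadata(x)
  out
})

# draw n samples from N(mu, scale^2 * Sigma)
.rmvnorm <- function(n, mu, sigma, scale = 1) {
  d <- length(mu)
  R <- .cholOrStop(sigma)
  z <- matrix(rnorm(n * d), nrow = n)
  sweep(z %*% (R * scale), 2, mu, `+`)
}

#' Generate the "Other" rejection class
#'
#' Draws vectors outside the `radius`-standard-deviation Mahalanobis
#' ellipsoid of the pooled data distribution by rejection sampling: proposals
#' come from the component with covariance inflated by `inflation^2`, and
#' proposals with Mahalanobis distance (under the original, uninflated
#' parameters) `<= radius` are rejected. Inflating the proposal keeps the
#' acceptance rate workable while concentrating the Other mass near the
#' ellipsoid boundary, where confusions with real fluids arise. Training a
#' classifier with this class lets extreme observations be called "Other"
#' instead of being forced into the nearest body fluid.
#'
#' @param params pooled [MVNParams-class] fitted to the training profiles.
#' @param n number of vectors to generate (> 0).
#' @param radius Mahalanobis radius of the exclusion ellipsoid (default 3.5).
#' @param inflation proposal covariance scale factor (>= 1, default 2).
#' @param seed optional integer; identical seeds give identical samples.
#' @param maxProposals proposal budget before giving up.
#' @return An n x d numeric matrix; every row has
#'   `mahalanobisDistance(row, params) > radius`.
#' @export
generateOther <- function(params, n, radius = 3.5, inflation = 2,
                          seed = NULL, maxProposals = 1e6) {
  if (n <= 0) .stopf("'n' must be positive")
  if (radius <= 0) .stopf("'radius' must be positive")
  if (inflation < 1) .stopf("'inflation' must be >= 1")
  mu <- mvnMean(params)
  withSeed(seed, {
    out <- matrix(numeric(0), ncol = length(mu))
    used <- 0L
    while (nrow(out) < n) {
      batch <- min(max(2L * (n - nrow(out)), 64L), maxProposals - used)
      if (batch <= 0L) {
        .stopf(paste0("proposal budget (%g) exhausted with %d/%d accepted; ",
                      "increase 'inflation'"), maxProposals, nrow(out), n)
      }
      prop <- .rmvnorm(batch, mu, mvnCovariance(params), scale = inflation)
      used <- used + batch
      keep <- mahalanobisDistance(prop, params) > radius
      out <- rbind(out, prop[keep, , drop = FALSE])
    }
    out <- out[seq_len(n), , drop = FALSE]
    colnames(out) <- names(mu)
    out
  })
}
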