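# internal helpers shared across modules

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm cov qnorm
NULL

# Tokens treated as qPCR non-detects in CSV input ("" covered separately).
.NONDETECT_TOKENS <- c("Undetermined", "NA", "undetermined")

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL runs in the ambient stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Full-precision text encoding for doubles: "%.17g" round-trips IEEE doubles
# exactly through as.numeric().
.num2str <- function(x) sprintf("%.17g", as.numeric(x))
.str2num <- function(s) as.numeric(s)

# symmetric check with tolerance relative to magnitude
.isSymmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
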