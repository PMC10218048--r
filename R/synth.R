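#' Simulation configuration for synthetic qPCR panel data
#'
#' A `SimulationConfig` (S3 list) describes a synthetic population of
#' body-fluid samples: per-fluid sample sizes, per-fluid multivariate-normal
#' delta-Cq structure (mean vector and covariance, chosen so classes overlap
#' the way real fluids do), reference-marker Cq level and spread, technical
#' replicate noise, per-marker missing-completely-at-random rates, the
#' non-detect cycle limit, and named treatment shifts (per-marker additive
#' delta-Cq offsets emulating degradation of specific markers).
#'
#' The default configuration mirrors a 355-sample population study: class
#' sizes (blood 51, menstrual 53, feces 50, urine 46, saliva 53, semen 52,
#' vaginal 50), seven target markers, and a per-marker missing rate solved
#' from `(1 - r)^7 = 252/355` so that about 71% of profiles are fully
#' observed. Mean vectors are qualitative fixtures: each fluid is most
#' extreme in its field-reported discriminating markers (e.g. semen in
#' miR-891a, saliva in miR-205, feces in miR-141), with menstrual and
#' vaginal secretions deliberately overlapping; they are not measured values
#' from any real cohort.
#'
#' @param classSizes named integer vector of per-fluid sample counts.
#' @param seed default seed used by [simulateProfiles].
#' @return A list of class `SimulationConfig`.
#' @export
defaultSimulationConfig <- function(classSizes = NULL, seed = 7) {
  panel <- defaultPanel()
  targets <- targetMarkers(panel)
  fluids <- fluidClasses(panel)
  if (is.null(classSizes)) {
    classSizes <- c(blood = 51L, menstrual = 53L, feces = 50L, urine = 46L,
                    saliva = 53L, semen = 52L, vaginal = 50L)
  }
  #           200b  320c  10b  891a  141  412  205
  means <- rbind(
    blood     = c(-3.5,  1.0, -2.5,  6.0,  4.0, 6.5,  5.0),
    menstrual = c(-1.0,  2.0, -0.5,  5.5,  2.5, 2.0,  2.5),
    feces     = c( 2.0,  4.0,  1.5,  6.5, -1.5, 5.5,  3.0),
    urine     = c( 1.5, -1.5,  2.5,  6.0,  0.5, 6.0,  4.5),
    saliva    = c( 2.5,  2.5,  2.0,  5.5,  3.0, 4.0, -2.0),
    semen     = c( 1.0,  1.5,  1.5, -4.0,  1.5, 5.5,  3.5),
    vaginal   = c( 0.5,  2.0,  0.0,  5.0,  1.0, 3.0,  0.5)
  )
  colnames(means) <- targets
  sds <- c(1.3, 1.25, 1.3, 1.5, 1.4, 1.4, 1.5)
  corr <- matrix(0.3, 7, 7); diag(corr) <- 1
  sigma <- diag(sds) %*% corr %*% diag(sds)
  dimnames(sigma) <- list(targets, targets)
  covs <- stats::setNames(rep(list(sigma), length(fluids)), fluids)

  missRate <- 1 - (252 / 355)^(1 / length(targets))   # ~0.0478 per marker
  zero <- stats::setNames(rep(0, length(targets)), targets)
  shift <- function(...) { s <- zero; v <- c(...); s[names(v)] <- v; s }
  cfg <- list(
    panel = panel,
    classSizes = classSizes,
    classMeans = means,
    classCovs = covs,
    referenceCqMean = 22, referenceCqSd = 1.5,
    replicateSd = 0.25, nReplicates = 2L,
    missingRate = stats::setNames(rep(missRate, length(targets)), targets),
    nondetectCqLimit = 40,
    treatmentShifts = list(
      none = zero,
      # heat degrades the semen/saliva discriminators most
      heat = shift("miR-891a" = 4, "miR-205" = 4, "miR-10b" = 1.5),
      # chemical exposure hits miR-200b/10b/205 hardest
      chemical = shift("miR-200b" = 3, "miR-10b" = 3, "miR-205" = 3),
      uv = shift("miR-412" = 2, "miR-205" = 2)
    ),
    seed = seed
  )
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' Validate a SimulationConfig
#'
#' Checks covariance symmetry/PSD, rate ranges, and size consistency.
#'
#' @param config a `SimulationConfig`.
#' @return `config`, invisibly, or an error.
#' @export
validateSimulationConfig <- function(config) {
  panel <- config$panel
  targets <- targetMarkers(panel)
  fluids <- names(config$classSizes)
  if (!all(fluids %in% fluidClasses(panel))) .stopf("classSizes must name panel fluids")
  if (any(config$classSizes < 0)) .stopf("class sizes must be nonnegative")
  if (!all(fluids %in% rownames(config$classMeans))) .stopf("classMeans must cover all fluids")
  if (ncol(config$classMeans) != length(targets)) .stopf("classMeans must have one column per target")
  for (f in fluids) {
    sg <- config$classCovs[[f]]
    if (is.null(sg)) .stopf("missing covariance for fluid '%s'", f)
    if (!.isSymmetric(sg)) .stopf("covariance for '%s' is not symmetric", f)
    ev <- eigen(sg, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
      .stopf("covariance for '%s' is not positive semidefinite", f)
    }
  }
  if (any(config$missingRate < 0 | config$missingRate > 1)) {
    .stopf("missing rates must lie in [0, 1]")
  }
  if (config$replicateSd < 0 || config$referenceCqSd < 0) {
    .stopf("noise standard deviations must be nonnegative")
  }
  invisible(config)
}

#' Simulate synthetic profiles or raw Cq tables
#'
#' At `level = "profile"`, delta-Cq vectors are drawn from each fluid's MVN
#' and masked marker-wise, missing completely at random. At `level = "cq"`,
#' the generator goes one level deeper and emits a long-format qPCR table:
#' per-sample reference Cqs are drawn around `referenceCqMean`, each target's
#' true Cq is the reference average plus the latent delta-Cq, technical
#' replicates add Gaussian noise (`replicateSd`), untested markers are
#' omitted at the MCAR rate, and replicate values beyond `nondetectCqLimit`
#' become `"Undetermined"` non-detects. Running the cq-level output through
#' [buildProfiles] recovers the latent delta-Cq vectors exactly when noise,
#' missingness, and the cycle limit are switched off.
#'
#' @param config a `SimulationConfig`.
#' @param level `"profile"` (default) or `"cq"`.
#' @param seed integer seed (default `config$seed`); identical seeds give
#'   identical output.
#' @return `level = "profile"`: a [DeltaCqExperiment-class].
#'   `level = "cq"`: a long data.frame in the [readCqTable] layout.
#' @export
simulateProfiles <- function(config, level = c("profile", "cq"),
                             seed = config$seed) {
  level <- match.arg(level)
  validateSimulationConfig(config)
  panel <- config$panel
  targets <- targetMarkers(panel)
  refs <- referenceMarkers(panel)
  fluids <- names(config$classSizes)
  d <- length(targets)

  withSeed(seed, {
    # latent per-sample delta-Cq vectors, in fixed fluid order
    lat <- list(); labs <- character(); ids <- character()
    for (f in fluids) {
      n <- config$classSizes[[f]]
      if (n == 0L) next
      draws <- .rmvnorm(n, config$classMeans[f, ], config$classCovs[[f]])
      lat[[f]] <- draws
      labs <- c(labs, rep(f, n))
      ids <- c(ids, sprintf("%s_%03d", f, seq_len(n)))
    }
    latent <- do.call(rbind, lat)
    if (is.null(latent)) latent <- matrix(numeric(0), ncol = d)
    colnames(latent) <- targets
    nTot <- nrow(latent)
    # MCAR mask, independent of the values
    mask <- matrix(rep(config$missingRate, each = nTot), nrow = nTot) >
      stats::runif(nTot * d) # TRUE = observed
    mask <- !mask

    if (level == "profile") {
      vals <- latent
      vals[!mask] <- NA_real_
      return(DeltaCqExperiment(t(vals), panel, fluidLabels = labs, sampleIds = ids))
    }

    nRep <- config$nReplicates
    rows <- vector("list", nTot)
    for (i in seq_len(nTot)) {
      refCq <- rnorm(length(refs), config$referenceCqMean, config$referenceCqSd)
      refAvg <- mean(refCq)
      mk <- character(); rep_i <- integer(); cq <- numeric()
      for (r in seq_along(refs)) {
        reps <- refCq[r] + rnorm(nRep, 0, config$replicateSd)
        mk <- c(mk, rep(refs[r], nRep)); rep_i <- c(rep_i, seq_len(nRep)); cq <- c(cq, reps)
      }
      for (t in seq_len(d)) {
        if (!mask[i, t]) next                     # marker untested
        true <- refAvg + latent[i, t]
        reps <- true + rnorm(nRep, 0, config$replicateSd)
        mk <- c(mk, rep(targets[t], nRep)); rep_i <- c(rep_i, seq_len(nRep)); cq <- c(cq, reps)
      }
      cq[cq > config$nondetectCqLimit] <- NA_real_   # non-detect
      rows[[i]] <- data.frame(sample_id = ids[i], fluid_label = labs[i],
                              marker = mk, replicate = rep_i, cq = cq,
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) {
      df <- data.frame(sample_id = character(), fluid_label = character(),
                       marker = character(), replicate = integer(), cq = numeric())
    }
    rownames(df) <- NULL
    attr(df, "latent") <- latent
    df
  })
}

#' Apply a named treatment shift to profiles
#'
#' Adds the per-marker delta-Cq offsets of `config$treatmentShifts[[shiftName]]`
#' to every observed value, emulating marker-specific degradation (heat,
#' chemical, or UV exposure raises the Cq of susceptible markers, shifting
#' their delta-Cq upward). Masks are unchanged: a treatment never makes an
#' untested marker observed or vice versa.
#'
#' @param x a [DeltaCqExperiment-class].
#' @param shiftName a name in `config$treatmentShifts`.
#' @param config a `SimulationConfig`.
#' @return The shifted [DeltaCqExperiment-class].
#' @export
applyTreatment <- function(x, shiftName, config) {
  sh <- config$treatmentShifts[[shiftName]]
  if (is.null(sh)) {
    .stopf("unknown treatment '%s'; available: %s", shiftName,
           paste(names(config$treatmentShifts), collapse = ", "))
  }
  vals <- deltaCq(x)
  full <- stats::setNames(rep(0, nrow(vals)), rownames(vals))
  full[names(sh)] <- sh
  shifted <- vals + full      # recycles down columns (markers are rows)
  shifted[is.na(vals)] <- NA_real_
  out <- DeltaCqExperiment(shifted, markerPanel(x),
                           fluidLabels = fluidLabels(x), sampleIds = colnames(x))
  metadata(out) <- metadata(x)
  out
}

#' Read and write a SimulationConfig as YAML
#'
#' @param config a `SimulationConfig`.
#' @param path YAML file path.
#' @return `readSimulationConfig` returns the `SimulationConfig`;
#'   `writeSimulationConfig` returns `path` invisibly.
#' @export
writeSimulationConfig <- function(config, path) {
  panel <- config$panel
  obj <- list(
    panel = .panel2list(panel),
    class_sizes = as.list(config$classSizes),
    class_means = apply(config$classMeans, 1, as.list, simplify = FALSE),
    class_covs = lapply(config$classCovs, function(m) apply(unname(m), 1, as.list, simplify = FALSE)),
    reference_cq_mean = config$referenceCqMean,
    reference_cq_sd = config$referenceCqSd,
    replicate_sd = config$replicateSd,
    n_replicates = config$nReplicates,
    missing_rate = as.list(config$missingRate),
    nondetect_cq_limit = config$nondetectCqLimit,
    treatment_shifts = lapply(config$treatmentShifts, as.list),
    seed = config$seed
  )
  writeLines(yaml::as.yaml(obj, precision = 15L), path)
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  panel <- .list2panel(obj$panel)
  targets <- targetMarkers(panel)
  asNamed <- function(lst) stats::setNames(as.numeric(unlist(lst)), names(lst))
  means <- do.call(rbind, lapply(obj$class_means, asNamed))
  colnames(means) <- targets
  covs <- lapply(obj$class_covs, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
    dimnames(m) <- list(targets, targets)
    m
  })
  cfg <- list(
    panel = panel,
    classSizes = stats::setNames(as.integer(unlist(obj$class_sizes)), names(obj$class_sizes)),
    classMeans = means,
    classCovs = covs,
    referenceCqMean = obj$reference_cq_mean,
    referenceCqSd = obj$reference_cq_sd,
    replicateSd = obj$replicate_sd,
    nReplicates = as.integer(obj$n_replicates),
    missingRate = asNamed(obj$missing_rate),
    nondetectCqLimit = obj$nondetect_cq_limit,
    treatmentShifts = lapply(obj$treatment_shifts, asNamed),
    seed = obj$seed
  )
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}
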