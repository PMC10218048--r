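# shared fixtures built in code

# minimal panel with arbitrary dimension/classes for unit tests
toyPanel <- function(d = 2, fluids = c("A", "B")) {
  MarkerPanel(targets = paste0("m", seq_len(d)),
              references = "ref", fluids = fluids)
}

# random symmetric positive-definite matrix
randomSPD <- function(d, seed = NULL) {
  gen <- function() {
    a <- matrix(rnorm(d * d), d)
    crossprod(a) + diag(d) * 0.5
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# labeled complete profiles: K well-separated Gaussian classes in d dims
separatedProfiles <- function(panel, nPer = 50, sep = 8, sd = 1, seed = 1) {
  fluids <- fluidClasses(panel)
  d <- panelDim(panel)
  withr::with_seed(seed, {
    vals <- NULL; labs <- character()
    for (i in seq_along(fluids)) {
      mu <- rep(0, d)
      mu[((i - 1) %% d) + 1] <- sep * ceiling(i / d)
      vals <- cbind(vals, matrix(rnorm(d * nPer, mu, sd), nrow = d))
      labs <- c(labs, rep(fluids[i], nPer))
    }
    DeltaCqExperiment(vals, panel, fluidLabels = labs,
                      sampleIds = sprintf("s%04d", seq_along(labs)))
  })
}

# long-format Cq table for one or more samples, all markers, two replicates
toyCqTable <- function(panel, ids, labels, refCq = 20, deltas = NULL) {
  targets <- targetMarkers(panel)
  refs <- referenceMarkers(panel)
  rows <- list()
  for (j in seq_along(ids)) {
    dd <- if (is.null(deltas)) seq_along(targets) else deltas[[j]]
    for (r in refs) for (k in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids[j], fluid_label = labels[j], marker = r,
        replicate = k, cq = refCq, stringsAsFactors = FALSE)
    }
    for (t in seq_along(targets)) for (k in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids[j], fluid_label = labels[j], marker = targets[t],
        replicate = k, cq = refCq + dd[t], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
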