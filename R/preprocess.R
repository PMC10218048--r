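#' Aggregate technical replicates for one sample/marker
#'
#' qPCR targets are amplified in duplicate (or more) technical replicates.
#' The aggregated Cq is the arithmetic mean of the numeric replicates. Any
#' non-detect replicate (`NA`) makes the aggregate a non-detect and raises the
#' `"nondetect_replicate"` flag. A spread between the extreme numeric
#' replicates larger than `concordanceLimit` raises `"discordant_replicates"`;
#' the mean is still returned — discordance is a QC flag, not a rejection
#' rule.
#'
#' @param cqs numeric vector of replicate Cq values; `NA` marks a non-detect.
#' @param concordanceLimit maximum tolerated max-min replicate spread, in
#'   cycles (default 1.0).
#' @return A list with elements `cq` (mean Cq, or `NA` for non-detect) and
#'   `flags` (character vector of raised QC flags).
#' @examples
#' aggregateReplicates(c(24.0, 24.4))
#' aggregateReplicates(c(24.0, NA))
#' aggregateReplicates(c(20, 22), concordanceLimit = 1)
#' @export
aggregateReplicates <- function(cqs, concordanceLimit = 1.0) {
  if (length(cqs) == 0L) .stopf("replicate Cq vector must be non-empty")
  flags <- character()
  if (anyNA(cqs)) {
    flags <- c(flags, "nondetect_replicate")
    return(list(cq = NA_real_, flags = flags))
  }
  if (length(cqs) > 1L && (max(cqs) - min(cqs)) > concordanceLimit) {
    flags <- c(flags, "discordant_replicates")
  }
  list(cq = mean(cqs), flags = flags)
}

#' Delta-Cq normalization against endogenous references
#'
#' The normalized expression value is the target Cq minus the mean Cq of the
#' endogenous reference markers (let-7g and let-7i in the default panel):
#' lower delta-Cq means higher expression relative to the references.
#'
#' @param targetCq numeric target marker Cq (cycles).
#' @param referenceCqs numeric vector of reference marker Cqs.
#' @return delta-Cq in cycles: `targetCq - mean(referenceCqs)`.
#' @examples
#' computeDeltaCq(25, c(20, 22))  # 4
#' @export
computeDeltaCq <- function(targetCq, referenceCqs) {
  if (length(referenceCqs) == 0L) {
    .stopf("at least one reference Cq is required to normalize")
  }
  if (!is.numeric(targetCq) || !is.numeric(referenceCqs) ||
      anyNA(targetCq) || anyNA(referenceCqs)) {
    .stopf("computeDeltaCq requires numeric, non-missing inputs")
  }
  targetCq - mean(referenceCqs)
}

#' Build delta-Cq profiles from a long Cq table
#'
#' Replicates are aggregated per (sample, marker) with [aggregateReplicates],
#' then each target marker is normalized with [computeDeltaCq] against the
#' sample's aggregated reference Cqs. Target markers that are non-detect or
#' absent become missing values in the profile (masked, to be imputed later).
#' Samples for which any reference marker is non-detect or absent have no
#' defined delta-Cq and are excluded; they are reported in the `exclusions`
#' metadata of the result, never silently dropped.
#'
#' @param cqTable long-format data.frame as returned by [readCqTable]:
#'   columns `sample_id`, `fluid_label`, `marker`, `replicate`, `cq`.
#' @param panel a [MarkerPanel-class].
#' @param concordanceLimit replicate concordance limit in cycles, see
#'   [aggregateReplicates].
#' @return A [DeltaCqExperiment-class]; excluded samples are listed in
#'   `exclusions(result)` (columns `sample_id`, `reason`).
#' @seealso [readCqTable], [writeExclusions]
#' @export
buildProfiles <- function(cqTable, panel, concordanceLimit = 1.0) {
  req <- c("sample_id", "marker", "cq")
  miss <- setdiff(req, names(cqTable))
  if (length(miss)) .stopf("cq table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"fluid_label" %in% names(cqTable)) cqTable$fluid_label <- NA_character_

  targets <- targetMarkers(panel)
  refs <- referenceMarkers(panel)
  ids <- unique(as.character(cqTable$sample_id))

  values <- matrix(NA_real_, nrow = length(targets), ncol = length(ids),
                   dimnames = list(targets, ids))
  labels <- rep(NA_character_, length(ids))
  keep <- rep(TRUE, length(ids))
  ex_id <- character(); ex_reason <- character()

  for (j in seq_along(ids)) {
    rows <- cqTable[cqTable$sample_id == ids[j], , drop = FALSE]
    lab <- unique(rows$fluid_label[!is.na(rows$fluid_label)])
    if (length(lab) > 1L) .stopf("sample '%s' carries conflicting fluid labels", ids[j])
    if (length(lab) == 1L) labels[j] <- lab

    agg <- function(marker) {
      cqs <- rows$cq[rows$marker == marker]
      if (length(cqs) == 0L) return(NA_real_)
      aggregateReplicates(cqs, concordanceLimit)$cq
    }
    refCqs <- vapply(refs, agg, numeric(1))
    if (anyNA(refCqs)) {
      keep[j] <- FALSE
      bad <- refs[is.na(refCqs)]
      ex_id <- c(ex_id, ids[j])
      ex_reason <- c(ex_reason,
                     paste0("reference marker(s) missing or non-detect: ",
                            paste(bad, collapse = ", ")))
      next
    }
    tgtCqs <- vapply(targets, agg, numeric(1))
    obs <- !is.na(tgtCqs)
    values[obs, j] <- tgtCqs[obs] - mean(refCqs)
  }

  prof <- DeltaCqExperiment(values[, keep, drop = FALSE], panel,
                            fluidLabels = labels[keep],
                            sampleIds = ids[keep])
  metadata(prof)$exclusions <- data.frame(
    sample_id = ex_id, reason = ex_reason, stringsAsFactors = FALSE
  )
  prof
}

#' Write the exclusion report of a profile build
#'
#' @param x a [DeltaCqExperiment-class] built by [buildProfiles].
#' @param path output CSV path (columns `sample_id`, `reason`).
#' @return `path`, invisibly.
#' @export
writeExclusions <- function(x, path) {
  utils::write.csv(exclusions(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
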