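#' DeltaCqExperiment: delta-Cq profiles as a SummarizedExperiment
#'
#' Container for a cohort of delta-Cq profiles: a markers x samples assay
#' matrix of normalized expression values (`deltaCq` assay, PCR cycles,
#' signed), where `NA` marks an unobserved (untested or non-detect) marker.
#' Column data carry the fluid label (`NA` when unknown). The
#' [MarkerPanel-class] travels with the object, so rows are always the
#' panel's target markers in panel order.
#'
#' @slot panel the [MarkerPanel-class] the profiles were measured against.
#'
#' @aliases DeltaCqExperiment-class
#' @exportClass DeltaCqExperiment
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
setClass("DeltaCqExperiment",
  contains = "SummarizedExperiment",
  slots = c(panel = "MarkerPanel")
)

setValidity("DeltaCqExperiment", function(object) {
  msgs <- character()
  if (!"deltaCq" %in% assayNames(object)) {
    msgs <- c(msgs, "assay 'deltaCq' is required")
  } else {
    a <- assay(object, "deltaCq")
    if (!is.numeric(a)) msgs <- c(msgs, "deltaCq assay must be numeric")
    if (!identical(rownames(object), targetMarkers(object@panel))) {
      msgs <- c(msgs, "rownames must equal the panel's target markers, in order")
    }
    if (any(is.infinite(a))) msgs <- c(msgs, "deltaCq values must be finite or NA")
  }
  if (!"fluid_label" %in% colnames(colData(object))) {
    msgs <- c(msgs, "colData must contain 'fluid_label'")
  } else {
    lab <- colData(object)$fluid_label
    ok <- c(fluidClasses(object@panel), otherLabel(object@panel))
    bad <- setdiff(unique(lab[!is.na(lab)]), ok)
    if (length(bad)) {
      msgs <- c(msgs, paste0("unknown fluid labels: ", paste(bad, collapse = ", ")))
    }
  }
  if (is.null(colnames(object)) && ncol(object) > 0L) {
    msgs <- c(msgs, "sample ids (colnames) are required")
  }
  if (anyDuplicated(colnames(object))) msgs <- c(msgs, "duplicated sample ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DeltaCqExperiment
#'
#' @param values numeric matrix of delta-Cq values, markers x samples
#'   (`NA` = unobserved). Rows must match the panel's target markers; a
#'   samples x markers matrix is transposed automatically when its columns
#'   match the panel instead.
#' @param panel a [MarkerPanel-class].
#' @param fluidLabels character vector of fluid labels per sample (`NA` for
#'   unknown), recycled if length 1.
#' @param sampleIds sample identifiers; defaults to the matrix column names.
#' @return A [DeltaCqExperiment-class].
#' @examples
#' p <- defaultPanel()
#' m <- matrix(rnorm(14), nrow = 7, dimnames = list(targetMarkers(p), c("s1", "s2")))
#' DeltaCqExperiment(m, p, fluidLabels = c("blood", "semen"))
#' @export
DeltaCqExperiment <- function(values, panel, fluidLabels = NA_character_,
                              sampleIds = colnames(values)) {
  values <- as.matrix(values)
  d <- panelDim(panel)
  if (nrow(values) != d && ncol(values) == d &&
      (is.null(rownames(values)) || !all(targetMarkers(panel) %in% rownames(values)))) {
    values <- t(values)
  }
  if (nrow(values) != d) {
    .stopf("'values' must have %d marker rows (got %d)", d, nrow(values))
  }
  if (is.null(rownames(values))) rownames(values) <- targetMarkers(panel)
  values <- values[targetMarkers(panel), , drop = FALSE]
  if (is.null(sampleIds)) sampleIds <- paste0("sample_", seq_len(ncol(values)))
  colnames(values) <- as.character(sampleIds)
  fluidLabels <- rep_len(as.character(fluidLabels), ncol(values))
  se <- SummarizedExperiment(
    assays = list(deltaCq = values),
    colData = DataFrame(fluid_label = fluidLabels, row.names = colnames(values))
  )
  new("DeltaCqExperiment", se, panel = panel)
}

#' DeltaCqExperiment accessors
#'
#' `deltaCq` returns the markers x samples value matrix (`NA` = unobserved);
#' `observedMask` the logical mask of observed entries; `fluidLabels` the
#' per-sample fluid labels; `markerPanel` the panel; `completeCases` which
#' samples have every target marker observed; `exclusions` the report of
#' samples dropped while building profiles (see [buildProfiles]).
#'
#' @param x a [DeltaCqExperiment-class].
#' @param value replacement fluid labels.
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
setGeneric("deltaCq", function(x) standardGeneric("deltaCq"))
#' @rdname profile-accessors
#' @export
setMethod("deltaCq", "DeltaCqExperiment", function(x) assay(x, "deltaCq"))

#' @rdname profile-accessors
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))
#' @rdname profile-accessors
#' @export
setMethod("observedMask", "DeltaCqExperiment", function(x) !is.na(assay(x, "deltaCq")))

#' @rdname profile-accessors
#' @export
setGeneric("fluidLabels", function(x) standardGeneric("fluidLabels"))
#' @rdname profile-accessors
#' @export
setMethod("fluidLabels", "DeltaCqExperiment", function(x) {
  stats::setNames(colData(x)$fluid_label, colnames(x))
})

#' @rdname profile-accessors
#' @export
setGeneric("fluidLabels<-", function(x, value) standardGeneric("fluidLabels<-"))
#' @rdname profile-accessors
#' @export
setMethod("fluidLabels<-", "DeltaCqExperiment", function(x, value) {
  colData(x)$fluid_label <- rep_len(as.character(value), ncol(x))
  validObject(x)
  x
})

#' @rdname profile-accessors
#' @export
setGeneric("markerPanel", function(x) standardGeneric("markerPanel"))
#' @rdname profile-accessors
#' @export
setMethod("markerPanel", "DeltaCqExperiment", function(x) x@panel)

#' @rdname profile-accessors
#' @export
setGeneric("completeCases", function(x) standardGeneric("completeCases"))
#' @rdname profile-accessors
#' @export
setMethod("completeCases", "DeltaCqExperiment", function(x) {
  stats::setNames(colSums(is.na(assay(x, "deltaCq"))) == 0L, colnames(x))
})

#' @rdname profile-accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname profile-accessors
#' @export
setMethod("exclusions", "DeltaCqExperiment", function(x) {
  ex <- metadata(x)$exclusions
  if (is.null(ex)) {
    ex <- data.frame(sample_id = character(), reason = character())
  }
  ex
})

setMethod("show", "DeltaCqExperiment", function(object) {
  a <- assay(object, "deltaCq")
  cat("DeltaCqExperiment:", nrow(object), "markers x", ncol(object), "samples\n")
  lab <- colData(object)$fluid_label
  tab <- table(ifelse(is.na(lab), "<unknown>", lab))
  cat("  fluids   :", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  complete :", sum(colSums(is.na(a)) == 0L), "of", ncol(object), "samples\n")
  nex <- nrow(exclusions(object))
  if (nex) cat("  exclusions:", nex, "samples dropped upstream\n")
})

# column-bind two experiments sharing a panel (used for Other augmentation)
.bindProfiles <- function(x, y) {
  stopifnot(identical(targetMarkers(x@panel), targetMarkers(y@panel)))
  vals <- cbind(deltaCq(x), deltaCq(y))
  DeltaCqExperiment(vals, x@panel,
                    fluidLabels = c(fluidLabels(x), fluidLabels(y)),
                    sampleIds = colnames(vals))
}
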