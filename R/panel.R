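#' MarkerPanel: the miRNA panel definition
#'
#' A `MarkerPanel` names the target miRNA markers whose expression is
#' classified, the endogenous reference markers used for delta-Cq
#' normalization, the body-fluid class labels, and the two reserved outcome
#' labels: the synthetic rejection class (`"Other"`) and the sub-threshold
#' outcome (`"inconclusive"`).
#'
#' The default panel is the seven-marker forensic body-fluid panel
#' (miR-200b, miR-320c, miR-10b, miR-891a, miR-141, miR-412, miR-205)
#' normalized to the average of let-7g and let-7i, over seven fluid classes.
#'
#' @slot targets character, ordered target marker names (>= 1).
#' @slot references character, ordered endogenous reference marker names (>= 1).
#' @slot fluids character, ordered body-fluid class names (>= 2).
#' @slot otherLabel character(1), reserved label for the rejection class.
#' @slot inconclusiveLabel character(1), reserved label for gated calls.
#'
#' @aliases MarkerPanel-class
#' @exportClass MarkerPanel
setClass("MarkerPanel",
  slots = c(
    targets = "character",
    references = "character",
    fluids = "character",
    otherLabel = "character",
    inconclusiveLabel = "character"
  )
)

setValidity("MarkerPanel", function(object) {
  msgs <- character()
  if (length(object@targets) < 1L) msgs <- c(msgs, "at least one target marker required")
  if (length(object@references) < 1L) msgs <- c(msgs, "at least one reference marker required")
  if (length(object@fluids) < 2L) msgs <- c(msgs, "at least two fluid classes required")
  if (length(object@otherLabel) != 1L || length(object@inconclusiveLabel) != 1L) {
    msgs <- c(msgs, "otherLabel and inconclusiveLabel must be single strings")
  }
  all_names <- list(
    targets = object@targets, references = object@references,
    fluids = object@fluids, reserved = c(object@otherLabel, object@inconclusiveLabel)
  )
  for (nm in names(all_names)) {
    if (anyDuplicated(all_names[[nm]])) msgs <- c(msgs, paste("duplicated names in", nm))
  }
  pool <- unlist(all_names, use.names = FALSE)
  if (anyDuplicated(pool)) {
    msgs <- c(msgs, "target, reference, fluid and reserved names must be mutually disjoint")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MarkerPanel
#'
#' @param targets character vector of target marker names.
#' @param references character vector of endogenous reference marker names.
#' @param fluids character vector of body-fluid class names.
#' @param otherLabel reserved name of the rejection class.
#' @param inconclusiveLabel reserved name for sub-threshold classifications.
#' @return A [MarkerPanel-class] object.
#' @examples
#' defaultPanel()
#' MarkerPanel(targets = c("m1", "m2"), references = "ref",
#'             fluids = c("A", "B"))
#' @export
MarkerPanel <- function(targets, references, fluids,
                        otherLabel = "Other",
                        inconclusiveLabel = "inconclusive") {
  new("MarkerPanel",
    targets = as.character(targets),
    references = as.character(references),
    fluids = as.character(fluids),
    otherLabel = otherLabel,
    inconclusiveLabel = inconclusiveLabel
  )
}

#' @rdname MarkerPanel
#' @export
defaultPanel <- function() {
  MarkerPanel(
    targets = c("miR-200b", "miR-320c", "miR-10b", "miR-891a",
                "miR-141", "miR-412", "miR-205"),
    references = c("let-7g", "let-7i"),
    fluids = c("blood", "menstrual", "feces", "urine",
               "saliva", "semen", "vaginal")
  )
}

#' Panel accessors
#'
#' @param x a [MarkerPanel-class] (or, for `markerPanel`, an object carrying one).
#' @return Character vectors of names, or for `panelDim` the number of target
#'   markers (the dimension of the delta-Cq feature space).
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("targetMarkers", function(x) standardGeneric("targetMarkers"))
#' @rdname panel-accessors
#' @export
setMethod("targetMarkers", "MarkerPanel", function(x) x@targets)

#' @rdname panel-accessors
#' @export
setGeneric("referenceMarkers", function(x) standardGeneric("referenceMarkers"))
#' @rdname panel-accessors
#' @export
setMethod("referenceMarkers", "MarkerPanel", function(x) x@references)

#' @rdname panel-accessors
#' @export
setGeneric("fluidClasses", function(x) standardGeneric("fluidClasses"))
#' @rdname panel-accessors
#' @export
setMethod("fluidClasses", "MarkerPanel", function(x) x@fluids)

#' @rdname panel-accessors
#' @export
setGeneric("otherLabel", function(x) standardGeneric("otherLabel"))
#' @rdname panel-accessors
#' @export
setMethod("otherLabel", "MarkerPanel", function(x) x@otherLabel)

#' @rdname panel-accessors
#' @export
setGeneric("inconclusiveLabel", function(x) standardGeneric("inconclusiveLabel"))
#' @rdname panel-accessors
#' @export
setMethod("inconclusiveLabel", "MarkerPanel", function(x) x@inconclusiveLabel)

#' @rdname panel-accessors
#' @export
setGeneric("panelDim", function(x) standardGeneric("panelDim"))
#' @rdname panel-accessors
#' @export
setMethod("panelDim", "MarkerPanel", function(x) length(x@targets))

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel\n")
  cat("  targets   (", length(object@targets), "): ",
      paste(object@targets, collapse = ", "), "\n", sep = "")
  cat("  references(", length(object@references), "): ",
      paste(object@references, collapse = ", "), "\n", sep = "")
  cat("  fluids    (", length(object@fluids), "): ",
      paste(object@fluids, collapse = ", "), "\n", sep = "")
  cat("  reserved  : ", object@otherLabel, ", ", object@inconclusiveLabel,
      "\n", sep = "")
})

# all marker names the long Cq table may contain
.panelMarkers <- function(panel) c(panel@targets, panel@references)
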