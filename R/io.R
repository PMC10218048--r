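#' Read a long-format qPCR Cq table
#'
#' Expects a comma-separated UTF-8 file with header columns `sample_id`,
#' `fluid_label`, `marker`, `replicate`, `cq` — one row per qPCR well. The
#' tokens `"Undetermined"`, `"NA"` and the empty cell denote non-detects and
#' are preserved as missing Cq values, never coerced to numbers. Marker
#' names must belong to the panel (targets or references); numeric Cq values
#' must lie within `[0, cycleMax]`.
#'
#' @param path CSV file path.
#' @param panel a [MarkerPanel-class].
#' @param cycleMax thermal-protocol cycle count; Cq values above it are
#'   rejected (default 40).
#' @return A data.frame with columns `sample_id`, `fluid_label`, `marker`,
#'   `replicate`, `cq` (numeric; `NA` = non-detect).
#' @seealso [buildProfiles] to turn the table into delta-Cq profiles.
#' @export
readCqTable <- function(path, panel, cycleMax = 40) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(), fileEncoding = "UTF-8")
  req <- c("sample_id", "fluid_label", "marker", "replicate", "cq")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    .stopf("cq table is missing required column(s): %s", paste(miss, collapse = ", "))
  }
  bad_marker <- setdiff(unique(df$marker), .panelMarkers(panel))
  if (length(bad_marker)) {
    .stopf("unknown marker name(s): %s", paste(bad_marker, collapse = ", "))
  }
  raw <- trimws(df$cq)
  nondetect <- raw %in% .NONDETECT_TOKENS | raw == ""
  cq <- rep(NA_real_, nrow(df))
  num <- suppressWarnings(as.numeric(raw[!nondetect]))
  if (anyNA(num)) {
    row <- which(!nondetect)[which(is.na(num))[1L]]
    .stopf("unparseable Cq value '%s' at data row %d", raw[!nondetect][is.na(num)][1L], row)
  }
  out_of_range <- num < 0 | num > cycleMax
  if (any(out_of_range)) {
    row <- which(!nondetect)[which(out_of_range)[1L]]
    .stopf("Cq value %g at data row %d outside [0, %g]",
           num[out_of_range][1L], row, cycleMax)
  }
  cq[!nondetect] <- num
  lab <- trimws(df$fluid_label)
  lab[lab %in% c("", "NA", "unknown")] <- NA_character_
  bad_lab <- setdiff(unique(lab[!is.na(lab)]),
                     c(fluidClasses(panel), otherLabel(panel)))
  if (length(bad_lab)) {
    .stopf("unknown fluid label(s): %s", paste(bad_lab, collapse = ", "))
  }
  data.frame(sample_id = df$sample_id, fluid_label = lab,
             marker = df$marker, replicate = df$replicate, cq = cq,
             stringsAsFactors = FALSE)
}

#' Write a long-format Cq table
#'
#' Inverse of [readCqTable]; non-detect Cq values are written as
#' `"Undetermined"`.
#'
#' @param cqTable data.frame in the [readCqTable] layout.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCqTable <- function(cqTable, path) {
  df <- cqTable
  df$cq <- ifelse(is.na(df$cq), "Undetermined", .num2str(df$cq))
  df$fluid_label[is.na(df$fluid_label)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write wide delta-Cq profile tables
#'
#' The wide layout has columns `sample_id`, `fluid_label`, then one column
#' per panel target marker; masked (unobserved) values are serialized as
#' `"NA"`. Values round-trip at full floating precision.
#'
#' @param x a [DeltaCqExperiment-class].
#' @param path CSV file path.
#' @param panel a [MarkerPanel-class].
#' @return `readProfiles` returns a [DeltaCqExperiment-class];
#'   `writeProfiles` returns `path` invisibly.
#' @export
writeProfiles <- function(x, path) {
  vals <- deltaCq(x)
  chr <- matrix("NA", nrow = ncol(vals), ncol = nrow(vals),
                dimnames = list(NULL, rownames(vals)))
  obs <- t(!is.na(vals))
  chr[obs] <- .num2str(t(vals)[obs])
  lab <- as.character(fluidLabels(x))
  lab[is.na(lab)] <- ""
  ids <- colnames(vals)
  if (is.null(ids)) ids <- character(0)   # 0-column matrices drop colnames
  df <- data.frame(sample_id = ids, fluid_label = lab,
                   chr, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path, panel) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(), fileEncoding = "UTF-8")
  targets <- targetMarkers(panel)
  need <- c("sample_id", "fluid_label", targets)
  if (!setequal(names(df), need) || !all(c("sample_id", "fluid_label") %in% names(df))) {
    miss <- setdiff(need, names(df)); extra <- setdiff(names(df), need)
    .stopf("profile table columns do not match the panel%s%s",
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")) else "",
           if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else "")
  }
  if (anyDuplicated(df$sample_id)) {
    .stopf("duplicate sample_id: %s", df$sample_id[duplicated(df$sample_id)][1L])
  }
  n <- nrow(df)
  vals <- matrix(NA_real_, nrow = length(targets), ncol = n,
                 dimnames = list(targets, df$sample_id))
  for (m in targets) {
    raw <- trimws(df[[m]])
    nondetect <- raw %in% .NONDETECT_TOKENS | raw == ""
    num <- suppressWarnings(as.numeric(raw[!nondetect]))
    if (anyNA(num)) .stopf("unparseable value '%s' in column '%s'",
                           raw[!nondetect][is.na(num)][1L], m)
    vals[m, !nondetect] <- num
  }
  lab <- trimws(df$fluid_label)
  lab[lab %in% c("", "NA", "unknown")] <- NA_character_
  DeltaCqExperiment(vals, panel, fluidLabels = lab, sampleIds = df$sample_id)
}

## ---- model serialization ----------------------------------------------

.panel2list <- function(panel) {
  list(targets = targetMarkers(panel),
       references = referenceMarkers(panel),
       fluids = fluidClasses(panel),
       other_label = otherLabel(panel),
       inconclusive_label = inconclusiveLabel(panel))
}

.list2panel <- function(lst) {
  for (f in c("targets", "references", "fluids", "other_label", "inconclusive_label")) {
    if (is.null(lst[[f]])) .stopf("model file is missing panel field '%s'", f)
  }
  MarkerPanel(targets = unlist(lst$targets), references = unlist(lst$references),
              fluids = unlist(lst$fluids), otherLabel = unlist(lst$other_label),
              inconclusiveLabel = unlist(lst$inconclusive_label))
}

#' Save and load a trained QDA model
#'
#' The model is serialized as self-describing JSON text with the panel
#' embedded. Floating-point parameters are written as 17-significant-digit
#' decimal strings, which reproduce IEEE doubles bit-identically on reload.
#'
#' @param model a [QDAModel-class].
#' @param path JSON file path.
#' @return `loadModel` returns the [QDAModel-class]; `saveModel` returns
#'   `path` invisibly.
#' @export
saveModel <- function(model, path) {
  d <- panelDim(model@panel)
  comps <- lapply(seq_along(model@classes), function(k) {
    comp <- model@components[[k]]
    list(class = model@classes[k],
         mean = .num2str(mvnMean(comp)),
         covariance = .num2str(as.numeric(mvnCovariance(comp))))  # column-major
  })
  obj <- list(
    format = "fluidQDA-model", version = 1L, dimension = d,
    panel = .panel2list(model@panel),
    classes = model@classes,
    priors = .num2str(model@priors),
    ridge = .num2str(model@ridge),
    threshold = .num2str(model@threshold),
    components = comps
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) .stopf("cannot parse model file: %s", conditionMessage(e)))
  if (!identical(obj$format, "fluidQDA-model")) {
    .stopf("model file load failed: field 'format' is missing or incompatible")
  }
  for (f in c("panel", "classes", "priors", "ridge", "threshold", "components", "dimension")) {
    if (is.null(obj[[f]])) .stopf("model file load failed: field '%s' is missing", f)
  }
  panel <- .list2panel(obj$panel)
  d <- as.integer(obj$dimension)
  comps_in <- obj$components
  # fromJSON may simplify the component list to a data.frame
  getComp <- function(k) {
    if (is.data.frame(comps_in)) {
      list(class = comps_in$class[k], mean = comps_in$mean[[k]],
           covariance = comps_in$covariance[[k]])
    } else comps_in[[k]]
  }
  K <- if (is.data.frame(comps_in)) nrow(comps_in) else length(comps_in)
  classes <- unlist(obj$classes)
  if (K != length(classes)) .stopf("model file load failed: field 'components' has wrong length")
  comps <- vector("list", K)
  for (k in seq_len(K)) {
    ck <- getComp(k)
    for (f in c("class", "mean", "covariance")) {
      if (is.null(ck[[f]])) {
        .stopf("model file load failed: component %d is missing field '%s'", k, f)
      }
    }
    mu <- .str2num(unlist(ck$mean))
    sg <- .str2num(unlist(ck$covariance))
    if (length(mu) != d || length(sg) != d * d) {
      .stopf("model file load failed: component '%s' has wrong dimensions", ck$class)
    }
    names(mu) <- targetMarkers(panel)
    comps[[k]] <- MVNParams(mu, matrix(sg, nrow = d))
  }
  comps <- stats::setNames(comps, vapply(seq_len(K), function(k) getComp(k)$class, character(1)))
  comps <- comps[classes]
  new("QDAModel", panel = panel, classes = classes, components = comps,
      priors = .str2num(unlist(obj$priors)),
      ridge = .str2num(obj$ridge), threshold = .str2num(obj$threshold))
}
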