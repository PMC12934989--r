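#' @rdname MSIDataset-class
setMethod("nPixels", "MSIDataset", function(x) ncol(x))

#' @rdname MSIDataset-class
setMethod("featureIds", "MSIDataset", function(x) rownames(x))

#' @rdname MSIDataset-class
setMethod("featureMz", "MSIDataset", function(x) {
  if ("mz" %in% colnames(rowData(x))) rowData(x)$mz else NULL
})

#' @rdname MSIDataset-class
setMethod("pixelCoords", "MSIDataset", function(x)
  as.data.frame(colData(x)[, c("x", "y")]))

#' @rdname MSIDataset-class
setMethod("sectionId", "MSIDataset", function(x) metadata(x)$section_id)

#' @rdname MSIDataset-class
setMethod("subjectId", "MSIDataset", function(x) metadata(x)$subject_id)

#' @rdname MSIDataset-class
#' @details `pixelMatrix()` returns the requested assay transposed to the
#'   pixels-by-features orientation used by the statistical routines.
setMethod("pixelMatrix", "MSIDataset", function(x, assayName = "intensities") {
  if (!assayName %in% assayNames(x))
    .msiError("msiValidationError",
              sprintf("assay '%s' not present; run normalizePixels() first?",
                      assayName))
  t(assay(x, assayName))
})

setMethod("show", "MSIDataset", function(object) {
  cat(sprintf("MSIDataset '%s' (subject %s): %d features x %d pixels\n",
              sectionId(object), subjectId(object),
              nrow(object), ncol(object)))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})

#' @rdname SegmentationResult-class
setMethod("clusterLabels", "SegmentationResult", function(x) x@labels)

#' @rdname SegmentationResult-class
setMethod("nicheLabels", "SegmentationResult", function(x) x@nicheLabels)

#' @rdname SegmentationResult-class
setMethod("nicheFraction", "SegmentationResult", function(x) x@nicheFraction)

#' @rdname SegmentationResult-class
setMethod("splitTree", "SegmentationResult", function(x) x@tree)

#' @rdname SegmentationResult-class
#' @details `isNichePixel()` returns a logical vector over pixels, `TRUE`
#'   where the pixel's cluster was called plasma-cell-rich.
setMethod("isNichePixel", "SegmentationResult", function(x)
  x@labels %in% x@nicheLabels)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d pixels in %d clusters\n",
              length(object@labels), object@K))
  if (length(object@nicheLabels))
    cat(sprintf("  niche clusters: %s (fraction %.3f)\n",
                paste(object@nicheLabels, collapse = ","),
                object@nicheFraction))
  else cat("  niche clusters: not called\n")
})

#' @rdname superPathway
setMethod("superPathway", "PathwayMap", function(map, metabolites) {
  i <- match(metabolites, map@assignments$metabolite)
  if (anyNA(i))
    message(sprintf("%d metabolite(s) without pathway annotation assigned to 'other'",
                    sum(is.na(i))))
  out <- map@assignments$super_pathway[i]
  out[is.na(i)] <- "other"
  out
})

#' @rdname superPathway
setMethod("subPathway", "PathwayMap", function(map, metabolites) {
  i <- match(metabolites, map@assignments$metabolite)
  out <- map@assignments$sub_pathway[i]
  out[is.na(i)] <- "other"
  out
})

setMethod("show", "PathwayMap", function(object) {
  a <- object@assignments
  cat(sprintf("PathwayMap: %d metabolites, %d super-pathways\n",
              nrow(a), length(unique(a$super_pathway))))
})
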