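#' @rdname MSIDataset-class
#' @param x an object.
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname MSIDataset-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname MSIDataset-class
#' @export
setGeneric("featureMz", function(x) standardGeneric("featureMz"))

#' @rdname MSIDataset-class
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname MSIDataset-class
#' @export
setGeneric("sectionId", function(x) standardGeneric("sectionId"))

#' @rdname MSIDataset-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname MSIDataset-class
#' @param assayName which assay to return.
#' @export
setGeneric("pixelMatrix", function(x, assayName = "intensities")
  standardGeneric("pixelMatrix"))

#' @rdname SegmentationResult-class
#' @param x an object.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("nicheLabels", function(x) standardGeneric("nicheLabels"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("nicheFraction", function(x) standardGeneric("nicheFraction"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("splitTree", function(x) standardGeneric("splitTree"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("isNichePixel", function(x) standardGeneric("isNichePixel"))

#' Look up super-pathway membership
#'
#' @param map a [PathwayMap-class].
#' @param metabolites character vector of metabolite identifiers.
#' @return character vector of super-pathways; unannotated metabolites map to
#'   `"other"` (one message is emitted per call when this happens).
#' @export
setGeneric("superPathway", function(map, metabolites)
  standardGeneric("superPathway"))

#' @rdname superPathway
#' @export
setGeneric("subPathway", function(map, metabolites)
  standardGeneric("subPathway"))
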