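#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assays<- assayNames colData rowData
NULL

#' MSIDataset: one imaged tissue section
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' pixel-level metabolite intensity matrix of a single mass-spectrometry-imaging
#' (MSI) section. Rows are metabolite features, columns are pixels; `colData`
#' carries the integer grid coordinates `x`, `y` (0-based, row-major);
#' `metadata` carries `section_id` and `subject_id`; `rowData$mz` optionally
#' carries feature m/z values (Da). The `"intensities"` assay is the raw,
#' non-negative matrix; normalisation adds `"tic"` and `"norm"` assays
#' (see [normalizePixels()]).
#'
#' @seealso [MSIDataset()], [readPixelTable()], [normalizePixels()]
#' @name MSIDataset-class
#' @exportClass MSIDataset
setClass("MSIDataset", contains = "SummarizedExperiment")

setValidity("MSIDataset", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("x", "y") %in% colnames(cd)))
    msg <- c(msg, "colData must contain pixel coordinates 'x' and 'y'")
  else {
    key <- paste(cd$x, cd$y)
    if (anyDuplicated(key))
      msg <- c(msg, sprintf("duplicated pixel coordinate: (%s)",
                            key[duplicated(key)][1L]))
  }
  if (!"intensities" %in% assayNames(object))
    msg <- c(msg, "assay 'intensities' is required")
  else {
    a <- assay(object, "intensities")
    if (any(!is.finite(a)))
      msg <- c(msg, "intensities must be finite")
    else if (any(a < 0))
      msg <- c(msg, "intensities must be non-negative")
  }
  if ("mz" %in% colnames(rowData(object))) {
    mz <- rowData(object)$mz
    if (any(!is.na(mz) & mz <= 0))
      msg <- c(msg, "feature m/z values must be positive")
  }
  for (f in c("section_id", "subject_id"))
    if (is.null(metadata(object)[[f]]))
      msg <- c(msg, sprintf("metadata field '%s' is required", f))
  if (length(msg)) msg else TRUE
})

#' Construct an MSIDataset
#'
#' @param intensities numeric matrix of raw intensities, features in rows and
#'   pixels in columns, with feature identifiers as rownames.
#' @param coords data.frame (or DataFrame) with integer columns `x`, `y`,
#'   one row per pixel.
#' @param sectionId,subjectId identifiers for the section and the subject it
#'   was taken from (one section per subject in the default design).
#' @param mz optional numeric vector of feature m/z values (Da), same length
#'   as `nrow(intensities)`.
#' @return a validated [MSIDataset-class] object.
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), NULL))
#' d <- MSIDataset(m, data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)), "s1")
#' nPixels(d)
#' @export
MSIDataset <- function(intensities, coords, sectionId,
                       subjectId = sectionId, mz = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("feature_%03d", seq_len(nrow(intensities)))
  if (nrow(coords) != ncol(intensities))
    .msiError("msiValidationError",
              "coords must have one row per pixel (column of intensities)")
  rd <- if (is.null(mz)) NULL else {
    if (length(mz) != nrow(intensities))
      .msiError("msiValidationError",
                "mz must have one value per feature")
    DataFrame(mz = as.numeric(mz))
  }
  se <- SummarizedExperiment(
    assays  = list(intensities = intensities),
    colData = DataFrame(x = as.integer(coords$x), y = as.integer(coords$y)),
    rowData = rd,
    metadata = list(section_id = as.character(sectionId),
                    subject_id = as.character(subjectId)))
  new("MSIDataset", se)
}

#' SegmentationResult: bisecting k-means partition of one section
#'
#' Holds the per-pixel cluster labels (1..K), the ordered split tree, and —
#' after [callNicheClusters()] — the cluster ids designated plasma-cell-rich
#' together with the resulting niche pixel fraction and per-cluster mean
#' marker z-scores.
#'
#' @slot labels integer vector, one cluster id (1..K) per pixel.
#' @slot K number of final clusters.
#' @slot tree data.frame with one row per split: `step`, `parent`,
#'   `sse_before`, `sse_after`, `child1`, `child2`.
#' @slot nicheLabels cluster ids called plasma-cell-rich (may be empty).
#' @slot nicheFraction fraction of pixels carrying a niche label.
#' @slot clusterMarkerZ per-cluster mean marker z-score (filled by
#'   [callNicheClusters()]).
#' @name SegmentationResult-class
#' @exportClass SegmentationResult
setClass("SegmentationResult", representation(
  labels = "integer",
  K = "integer",
  tree = "data.frame",
  nicheLabels = "integer",
  nicheFraction = "numeric",
  clusterMarkerZ = "numeric"))

setValidity("SegmentationResult", function(object) {
  msg <- character()
  K <- object@K
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > K))
    msg <- c(msg, "labels must lie in 1..K")
  if (nrow(object@tree) != K - 1L)
    msg <- c(msg, "tree must record exactly K - 1 splits")
  if (length(object@nicheFraction) &&
      (object@nicheFraction < 0 || object@nicheFraction > 1))
    msg <- c(msg, "nicheFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' PathwayMap: metabolite to pathway annotation
#'
#' Maps each metabolite to exactly one super-pathway (e.g. nucleotide,
#' amino acid, lipid, carbohydrate, energy, vitamin, other) and optionally a
#' sub-pathway. Lookups of unannotated metabolites return `"other"`.
#'
#' @slot assignments data.frame with columns `metabolite`, `super_pathway`,
#'   `sub_pathway`.
#' @seealso [loadPathwayMap()], [superPathway()]
#' @name PathwayMap-class
#' @exportClass PathwayMap
setClass("PathwayMap", representation(assignments = "data.frame"))

setValidity("PathwayMap", function(object) {
  a <- object@assignments
  msg <- character()
  need <- c("metabolite", "super_pathway", "sub_pathway")
  if (!all(need %in% colnames(a)))
    msg <- c(msg, "assignments needs columns metabolite, super_pathway, sub_pathway")
  else if (anyDuplicated(a$metabolite))
    msg <- c(msg, "each metabolite must map to exactly one super-pathway")
  if (length(msg)) msg else TRUE
})
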