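#' Read a pixel-level intensity table
#'
#' Reads a delimited text table with columns `x`, `y` followed by one column
#' per metabolite (one row per pixel) into an [MSIDataset-class].
#'
#' @param path path to a TSV file.
#' @param sectionId,subjectId identifiers recorded in the dataset metadata;
#'   default to the file name without extension.
#' @param sep field separator (default tab).
#' @return an [MSIDataset-class].
#' @seealso [writePixelTable()]
#' @export
readPixelTable <- function(path, sectionId = NULL, subjectId = NULL,
                           sep = "\t") {
  if (is.null(sectionId))
    sectionId <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(subjectId)) subjectId <- sectionId
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% colnames(tab)))
    .msiError("msiFormatError",
              sprintf("pixel table '%s' must have 'x' and 'y' columns", path))
  key <- paste(tab$x, tab$y)
  if (anyDuplicated(key))
    .msiError("msiValidationError",
              sprintf("duplicated pixel coordinate (%s) in '%s'",
                      sub(" ", ", ", key[duplicated(key)][1L]), path))
  feat <- setdiff(colnames(tab), c("x", "y"))
  if (!length(feat))
    .msiError("msiFormatError", "pixel table has no metabolite columns")
  m <- as.matrix(tab[, feat, drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0)) {
    bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
    cells <- apply(utils::head(bad, 5L), 1L, function(ij)
      sprintf("row %d / %s", ij[1L], feat[ij[2L]]))
    .msiError("msiValidationError",
              sprintf("negative or non-finite intensity at: %s%s",
                      paste(cells, collapse = "; "),
                      if (nrow(bad) > 5L) " ..." else ""))
  }
  MSIDataset(t(m), tab[, c("x", "y")], sectionId, subjectId)
}

#' Write a pixel-level intensity table
#'
#' Inverse of [readPixelTable()]; values are written with 17 significant
#' digits so that a read/write round trip preserves doubles exactly.
#'
#' @param data an [MSIDataset-class].
#' @param path output TSV path.
#' @export
writePixelTable <- function(data, path) {
  stopifnot(is(data, "MSIDataset"))
  m <- pixelMatrix(data)
  co <- pixelCoords(data)
  num <- apply(m, 2, function(v) sprintf("%.17g", v))
  out <- cbind(x = as.character(co$x), y = as.character(co$y), num)
  colnames(out) <- c("x", "y", featureIds(data))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.GROUPS <- c("MGUS", "MM")
.STAGES <- c("MGUS_nonprog", "MGUS_prog", "MM")

#' Read subject metadata and matched bulk plasma profiles
#'
#' The metadata table needs columns `subject_id`, `group`, `pc_percent`,
#' `sphase`; `stage` and `progression` are optional (stage is inferred:
#' MM subjects get stage `"MM"`, MGUS subjects default to `"MGUS_nonprog"`
#' unless a truthy `progression` column marks them `"MGUS_prog"`).
#' `pc_percent` is a fraction in `[0, 1]` and is epsilon-clamped so it can
#' enter logit transforms. Plasma profiles come from a companion wide table
#' (rows = subjects, first column `subject_id`, one column per metabolite).
#'
#' @param metaPath path to the metadata TSV.
#' @param plasmaPath optional path to the wide plasma-profile TSV.
#' @param eps clamping epsilon for `pc_percent`.
#' @return an [S4Vectors::DataFrame] with the metadata columns plus a matrix
#'   column `plasma` (all-`NA` rows, with a warning, for subjects missing
#'   from the plasma table).
#' @export
readSubjectTable <- function(metaPath, plasmaPath = NULL, eps = 1e-6) {
  meta <- utils::read.table(metaPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "pc_percent", "sphase")
  if (!all(need %in% colnames(meta)))
    .msiError("msiFormatError",
              sprintf("subject table must have columns: %s",
                      paste(need, collapse = ", ")))
  if (!all(meta$group %in% .GROUPS))
    .msiError("msiValidationError",
              sprintf("unknown group '%s' (expected MGUS or MM)",
                      setdiff(meta$group, .GROUPS)[1L]))
  if (!"stage" %in% colnames(meta)) {
    prog <- if ("progression" %in% colnames(meta))
      as.logical(meta$progression) else rep(FALSE, nrow(meta))
    meta$stage <- ifelse(meta$group == "MM", "MM",
                         ifelse(prog, "MGUS_prog", "MGUS_nonprog"))
  }
  if (!all(meta$stage %in% .STAGES))
    .msiError("msiValidationError", "unknown stage label")
  if (any(meta$group == "MM" & meta$stage != "MM"))
    .msiError("msiValidationError", "MM subjects must have stage 'MM'")
  meta$pc_percent <- clampProportion(as.numeric(meta$pc_percent), eps)

  plasma <- NULL
  if (!is.null(plasmaPath)) {
    wide <- utils::read.table(plasmaPath, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE)
    pm <- as.matrix(wide[, -1, drop = FALSE])
    rownames(pm) <- wide[[1L]]
    missing <- setdiff(meta$subject_id, rownames(pm))
    if (length(missing))
      warning(sprintf("no plasma profile for subject(s): %s",
                      paste(missing, collapse = ", ")))
    plasma <- matrix(NA_real_, nrow(meta), ncol(pm),
                     dimnames = list(meta$subject_id, colnames(pm)))
    hit <- intersect(meta$subject_id, rownames(pm))
    plasma[hit, ] <- pm[hit, ]
  }
  out <- DataFrame(subject_id = meta$subject_id,
                   group = meta$group,
                   stage = meta$stage,
                   pc_percent = meta$pc_percent,
                   sphase = as.numeric(meta$sphase))
  if (!is.null(plasma)) out$plasma <- plasma
  rownames(out) <- meta$subject_id
  out
}

#' Write subject metadata (and plasma profiles)
#'
#' @param subjects DataFrame as returned by [readSubjectTable()] or
#'   [simulateCohort()].
#' @param metaPath output TSV for the metadata columns.
#' @param plasmaPath optional output TSV for the wide plasma matrix.
#' @export
writeSubjectTable <- function(subjects, metaPath, plasmaPath = NULL) {
  meta <- as.data.frame(subjects[, c("subject_id", "group", "stage",
                                     "pc_percent", "sphase")])
  utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(plasmaPath) && "plasma" %in% colnames(subjects)) {
    pm <- subjects$plasma
    out <- data.frame(subject_id = subjects$subject_id,
                      apply(pm, 2, function(v) sprintf("%.17g", v)),
                      check.names = FALSE)
    utils::write.table(out, plasmaPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(metaPath)
}

#' Load a metabolite-to-pathway annotation map
#'
#' Expects a TSV with columns `metabolite`, `super_pathway` and optionally
#' `sub_pathway`. Exact duplicate rows are deduplicated silently; the same
#' metabolite listed with conflicting super-pathways is an error.
#'
#' @param path path to the TSV.
#' @return a [PathwayMap-class].
#' @export
loadPathwayMap <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("metabolite", "super_pathway") %in% colnames(tab)))
    .msiError("msiFormatError",
              "pathway map needs columns metabolite, super_pathway")
  if (!"sub_pathway" %in% colnames(tab)) tab$sub_pathway <- "unspecified"
  tab <- unique(tab[, c("metabolite", "super_pathway", "sub_pathway")])
  dup <- tab$metabolite[duplicated(tab$metabolite)]
  if (length(dup))
    .msiError("msiValidationError",
              sprintf("conflicting pathway assignment for '%s'", dup[1L]))
  new("PathwayMap", assignments = tab)
}

#' Build a PathwayMap in code
#'
#' @param metabolite,super_pathway,sub_pathway equal-length character vectors.
#' @return a [PathwayMap-class].
#' @export
pathwayMap <- function(metabolite, super_pathway,
                       sub_pathway = rep("unspecified", length(metabolite))) {
  new("PathwayMap", assignments = unique(data.frame(
    metabolite = metabolite, super_pathway = super_pathway,
    sub_pathway = sub_pathway, stringsAsFactors = FALSE)))
}

#' Analysis configuration
#'
#' Bundles the tunable knobs shared across pipeline stages. Defaults follow
#' the analysis conventions used throughout the package: a 1.5-fold change
#' threshold on the log2 scale (`log2(1.5)` rounded to two decimals, 0.58),
#' a Pearson `r` cut of 0.30 for correlation-partner sets, `K = 6` clusters
#' per section with marker-based niche calling (enough splits to isolate a
#' small niche from a patchy microenvironment), and `K = 6` for the spatial
#' heterogeneity scan.
#'
#' @param seed master random seed.
#' @param k_sections clusters per section for niche segmentation.
#' @param k_spatial clusters for the spatial-heterogeneity (Simpson) scan.
#' @param fc_threshold log2 fold-change threshold.
#' @param corr_threshold Pearson r threshold for correlation-partner sets.
#' @param n_permutations permutations for PERMANOVA (>= 99).
#' @param alpha significance level.
#' @param epsilon clamping epsilon for proportions entering logits.
#' @return a list of class `"msiConfig"`.
#' @export
analysisConfig <- function(seed = 1L, k_sections = 6L, k_spatial = 6L,
                           fc_threshold = 0.58, corr_threshold = 0.30,
                           n_permutations = 999L, alpha = 0.05,
                           epsilon = 1e-6) {
  if (fc_threshold <= 0)
    .msiError("msiValidationError", "fc_threshold must be positive")
  if (corr_threshold <= 0 || corr_threshold >= 1)
    .msiError("msiValidationError", "corr_threshold must lie in (0, 1)")
  if (n_permutations < 99)
    .msiError("msiValidationError", "n_permutations must be >= 99")
  structure(list(seed = as.integer(seed), k_sections = as.integer(k_sections),
                 k_spatial = as.integer(k_spatial),
                 fc_threshold = fc_threshold,
                 corr_threshold = corr_threshold,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, epsilon = epsilon),
            class = "msiConfig")
}

#' @export
print.msiConfig <- function(x, ...) {
  cat("msiNiche analysis configuration:\n")
  for (f in names(x)) cat(sprintf("  %-15s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return [readAnalysisConfig()] returns an `"msiConfig"`;
#'   [writeAnalysisConfig()] returns `path` invisibly.
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysisConfig, vals[names(vals) %in% names(formals(analysisConfig))])
}

#' @rdname readAnalysisConfig
#' @param config an `"msiConfig"` list.
#' @export
writeAnalysisConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
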