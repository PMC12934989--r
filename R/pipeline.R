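#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> normalise/segment/niche-call -> concordance ->
#' differential (tissue and plasma volcanoes, FC-FC classification, pathway
#' tally) -> proliferation coupling -> Hill-number diversity -> multivariate
#' (PCA, PERMANOVA, VIP, stage trend), writing TSV/JSON outputs and a
#' machine-readable manifest to `workdir`. Stage seeds are derived from the
#' master seed by fixed offsets so stages can be re-run in isolation;
#' re-running with an identical config reproduces identical outputs.
#'
#' @param config an `"msiConfig"` from [analysisConfig()].
#' @param workdir output directory (created if needed).
#' @param params optional `"SimulationParams"`; defaults to
#'   `simParams(seed = config$seed)`.
#' @param map optional [PathwayMap-class]; when absent all metabolites are
#'   tallied under `"other"` (a warning is emitted, the pipeline completes).
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
runAll <- function(config = analysisConfig(), workdir,
                   params = NULL, map = NULL) {
  stopifnot(inherits(config, "msiConfig"))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params)) params <- simParams(seed = config$seed)
  if (is.null(map)) {
    warning("no pathway map supplied; all metabolites tallied under 'other'")
    map <- pathwayMap(character(), character())
  }
  manifest <- list(seed = config$seed, config = unclass(config),
                   stages = list(), outputs = character())
  stamp <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- fn()
    manifest$stages[[stage]] <<- list(status = "ok",
                                      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }
  emit <- function(obj, file) {
    path <- file.path(workdir, file)
    if (is.data.frame(obj))
      utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    manifest$outputs <<- c(manifest$outputs, file)
  }

  cohort <- stamp("simulate", function() simulateCohort(params))
  datasets <- cohort$datasets
  subjects <- cohort$subjects
  emit(as.data.frame(subjects[, setdiff(colnames(subjects), "plasma")]),
       "subjects.tsv")

  seg <- stamp("segment", function() {
    out <- vector("list", length(datasets)); names(out) <- names(datasets)
    for (i in seq_along(datasets))
      out[[i]] <- segmentSection(datasets[[i]], K = config$k_sections,
                                 markers = cohort$truth$nicheMarkers,
                                 seed = config$seed + 100L + i)
    out
  })
  fractions <- vapply(seg, function(s) nicheFraction(s$seg), numeric(1))
  masks <- lapply(seg, function(s) isNichePixel(s$seg))
  labTab <- do.call(rbind, lapply(names(seg), function(id) {
    co <- pixelCoords(seg[[id]]$data)
    data.frame(section = id, x = co$x, y = co$y,
               label = clusterLabels(seg[[id]]$seg),
               is_niche = isNichePixel(seg[[id]]$seg))
  }))
  emit(labTab, "segmentation_labels.tsv")

  conc <- stamp("concordance", function()
    concordance(fractions, subjects$pc_percent, eps = config$epsilon))
  emit(list(niche_fractions = as.list(round(fractions, 6)),
            pearson_r = conc$pearson_r, pearson_p = conc$pearson_p,
            spearman_rho = conc$spearman_rho, spearman_p = conc$spearman_p),
       "concordance.json")

  nicheMeans <- subjectMeanMatrix(datasets, masks, "niche")
  plasma <- subjects$plasma
  shared <- intersect(colnames(nicheMeans), colnames(plasma))
  manifest$shared_metabolites <- length(shared)

  diffres <- stamp("diffexpr", function() {
    tv <- volcano(nicheMeans, subjects$group, alpha = config$alpha,
                  fcThreshold = config$fc_threshold)
    pv <- volcano(plasma, subjects$group, alpha = config$alpha,
                  fcThreshold = config$fc_threshold)
    list(tissue = tv, plasma = pv)
  })
  emit(diffres$tissue, "volcano_tissue.tsv")
  emit(diffres$plasma, "volcano_plasma.tsv")

  fcfc <- stamp("fcfc", function() {
    tFC <- stats::setNames(diffres$tissue$log2fc, diffres$tissue$metabolite)
    pFC <- stats::setNames(diffres$plasma$log2fc, diffres$plasma$metabolite)
    fcfcTable(tFC[shared], pFC[shared], threshold = config$fc_threshold)
  })
  emit(fcfc, "fcfc_classes.tsv")
  emit(suppressMessages(pathwayTally(fcfc, map)), "fcfc_pathway_tally.tsv")

  coup <- stamp("coupling", function() {
    cc <- proliferationCorrelations(nicheMeans, subjects$sphase,
                                    subjects$group)
    whole <- subjectMeanMatrix(datasets, masks, "whole")
    rhoN <- vapply(colnames(nicheMeans), function(m)
      stats::cor(nicheMeans[, m], subjects$sphase, method = "spearman"),
      numeric(1))
    rhoW <- vapply(colnames(whole), function(m)
      stats::cor(whole[, m], subjects$sphase, method = "spearman"),
      numeric(1))
    list(coupling = cc, gain = segmentationGain(rhoN, rhoW))
  })
  emit(coup$coupling, "coupling.tsv")
  emit(coup$gain, "segmentation_gain.tsv")
  emit(suppressMessages(pathwaySlopeSummary(coup$coupling, map)),
       "pathway_slopes.tsv")

  div <- stamp("diversity", function()
    diversityReport(datasets, masks, subjects))
  emit(div$perSubject, "diversity_per_subject.tsv")
  emit(div$cohort, "diversity_cohort.json")

  multi <- stamp("multivariate", function() {
    microMeans <- subjectMeanMatrix(datasets, masks, "micro")
    prof <- rbind(nicheMeans, microMeans)
    grp <- c(paste0(subjects$group, "_niche"), rep("micro", nrow(microMeans)))
    pca <- pcaScores(log1p(prof), nComponents = 2)
    pm <- permanova(log1p(prof), grp, nPerm = config$n_permutations,
                    seed = config$seed + 500L)
    trend <- trendVolcano(nicheMeans, subjects$stage, alpha = config$alpha)
    list(pca = pca, permanova = pm, trend = trend)
  })
  emit(data.frame(sample = rownames(multi$pca$scores), multi$pca$scores),
       "pca_scores.tsv")
  emit(multi$permanova[c("r2", "f_stat", "p", "n_perm")], "permanova.json")
  emit(multi$trend, "trend_volcano.tsv")

  manifest$file_md5 <- as.list(tools::md5sum(
    file.path(workdir, manifest$outputs)))
  names(manifest$file_md5) <- manifest$outputs
  jsonlite::write_json(manifest, file.path(workdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
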