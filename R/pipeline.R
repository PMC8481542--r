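#' Pipeline configuration
#'
#' Collects every tunable of the selection / assembly / cavity pipeline
#' in one validated list. Defaults follow the published protocol where
#' one exists: a score pre-filter of the 5000 best decoys, a clustering
#' ceiling of 0.55 A (0.8 A is the looser alternative used for
#' smaller, pre-thinned sets), DSS/DSSO CA 30 / CB 22 A thresholds via
#' [defaultLinkers()], and a 35 A bilayer span for the helical ruler.
#'
#' @param topN score pre-filter size (default 5000).
#' @param clusterThreshold PNN ceiling, Angstrom (default 0.55).
#' @param minSatisfied restraint filter floor; NULL = all resolvable.
#' @param sd,mode,caFallback see [restraintParams()].
#' @param nStarts,nRefineSteps,clashCutoff rigid-body search settings.
#' @param seed integer seed for all stochastic stages.
#' @param gridSpacing,exclusionRadius cavity grid settings (Angstrom).
#' @param cavityPadding bounding-cuboid inflation (Angstrom).
#' @param bilayerWidth membrane span for the helical ruler (Angstrom).
#' @param helixRise rise per helical residue (A/residue).
#' @param nMolecules molecule count for the concentration estimate.
#' @param referenceVolumesA3 optional vector of reference volumes
#'   (cubic Angstrom) to convert in reports.
#' @param linkers linker dictionary.
#' @return a list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(topN = 5000, clusterThreshold = 0.55,
                           minSatisfied = NULL, sd = 1.0, mode = "all",
                           caFallback = TRUE, nStarts = 32,
                           nRefineSteps = 250, clashCutoff = 3.0,
                           seed = 1, gridSpacing = 1.0,
                           exclusionRadius = 2.0, cavityPadding = 0,
                           bilayerWidth = 35, helixRise = 1.5,
                           nMolecules = 1, referenceVolumesA3 = NULL,
                           linkers = defaultLinkers()) {
  for (v in c(topN, clusterThreshold, sd, nStarts, nRefineSteps,
              gridSpacing, exclusionRadius, bilayerWidth, helixRise,
              nMolecules))
    .stopIfNot(is.numeric(v) && v > 0, "numeric config values must be > 0")
  structure(list(
    topN = topN, clusterThreshold = clusterThreshold,
    minSatisfied = minSatisfied,
    params = restraintParams(sd = sd, mode = mode, caFallback = caFallback),
    nStarts = nStarts, nRefineSteps = nRefineSteps,
    clashCutoff = clashCutoff, seed = as.integer(seed),
    gridSpacing = gridSpacing, exclusionRadius = exclusionRadius,
    cavityPadding = cavityPadding, bilayerWidth = bilayerWidth,
    helixRise = helixRise, nMolecules = nMolecules,
    referenceVolumesA3 = referenceVolumesA3, linkers = linkers),
    class = "pipelineConfig")
}

#' Write a decoy ensemble to disk as PDB files plus a manifest
#'
#' @param ensemble a [DecoyEnsemble-class].
#' @param dir output directory (created if needed).
#' @return path of the manifest TSV (columns id, path, score), invisibly.
#' @export
writeEnsembleManifest <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(decoyIds(ensemble), ".pdb"))
  for (i in seq_along(paths)) writePdb(ensemble@decoys[[i]], paths[i])
  man <- data.frame(id = decoyIds(ensemble), path = paths,
                    score = ensemble@scores, stringsAsFactors = FALSE)
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(man, mf, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mf)
}

#' Read a decoy ensemble from a manifest TSV
#'
#' @param manifest path to a TSV with columns id, path, score; relative
#'   paths are resolved against the manifest's directory.
#' @return a [DecoyEnsemble-class].
#' @export
readEnsembleManifest <- function(manifest) {
  man <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  .stopIfNot(all(c("id", "path", "score") %in% names(man)),
             "manifest needs columns id, path, score")
  paths <- ifelse(file.exists(man$path), man$path,
                  file.path(dirname(manifest), man$path))
  decoys <- lapply(seq_len(nrow(man)), function(i)
    parsePdb(paths[i], id = man$id[i]))
  DecoyEnsemble(decoys, man$score, man$id)
}

#' Run the end-to-end decoy-selection pipeline
#'
#' Orchestrates [rankByScore()], [filterByRestraints()],
#' [pairwiseRmsd()], [pnnCluster()] and the final-model choice, and
#' optionally writes the artifacts: the selected model PDB, the cluster
#' table, the per-link satisfaction TSV of the selected model, and a
#' JSON audit including the configuration snapshot. Rerunning on the
#' same inputs reproduces identical outputs.
#'
#' @param ensemble a [DecoyEnsemble-class] or path to a manifest TSV.
#' @param links cross-link table or path to a cross-link CSV.
#' @param config a [pipelineConfig()].
#' @param outputDir optional artifact directory.
#' @return the [SelectionResult-class], with attribute `"artifacts"`
#'   (named paths) when `outputDir` is given.
#' @export
runSelectionPipeline <- function(ensemble, links,
                                 config = pipelineConfig(),
                                 outputDir = NULL) {
  if (is.character(ensemble)) ensemble <- readEnsembleManifest(ensemble)
  if (is.character(links)) links <- parseCrossLinks(links,
                                                    linkers = config$linkers)
  res <- selectFinalModel(
    ensemble, links, linkers = config$linkers, params = config$params,
    topN = config$topN, threshold = config$clusterThreshold,
    minSatisfied = config$minSatisfied)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    final <- getDecoy(ensemble, selectedId(res))
    art <- c(model = file.path(outputDir, "selected_model.pdb"),
             clusters = file.path(outputDir, "clusters.tsv"),
             satisfaction = file.path(outputDir, "satisfaction.tsv"),
             audit = file.path(outputDir, "selection_audit.json"))
    writePdb(final, art[["model"]])
    cl <- res@clusters
    utils::write.table(
      data.frame(id = cl@ids, cluster = cl@labels),
      art[["clusters"]], sep = "\t", row.names = FALSE, quote = FALSE)
    ev <- evaluateSet(final, links, config$linkers, config$params)
    utils::write.table(ev$table, art[["satisfaction"]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(final_id = selectedId(res), cluster_id = res@clusterId,
           audit = selectionAudit(res),
           cluster_sizes = as.integer(cl@sizes),
           cluster_spread = cl@spread,
           config = lapply(config[setdiff(names(config), "linkers")],
                           function(x) if (is.list(x)) unclass(x) else x),
           linkers = config$linkers),
      art[["audit"]], auto_unbox = TRUE, digits = NA, null = "null")
    attr(res, "artifacts") <- art
  }
  res
}

#' Combined validation, cavity and helical-ruler report
#'
#' Validates an assembly against a cross-link set, estimates the
#' confined volume between its components (bounding cuboid and
#' grid-accessible volume), converts volumes to litres and effective
#' molar concentrations, and reports the helical ruler for the
#' configured bilayer width.
#'
#' @param assembly an [XLStructure-class] or PDB path.
#' @param links cross-link table or CSV path.
#' @param config a [pipelineConfig()]; `referenceVolumesA3` entries are
#'   converted alongside the measured volumes.
#' @param outputDir optional directory for a JSON report.
#' @return a list (validation, cavity, ruler) mirroring the JSON report.
#' @export
runReport <- function(assembly, links, config = pipelineConfig(),
                      outputDir = NULL) {
  if (is.character(assembly)) assembly <- parsePdb(assembly)
  if (is.character(links)) links <- parseCrossLinks(links,
                                                    linkers = config$linkers)
  val <- validateAssembly(assembly, links, config$linkers, config$params)
  cub <- boundingCuboid(atomCoords(assembly, elety = NULL),
                        padding = config$cavityPadding)
  grd <- gridAccessibleVolume(assembly, cub, config$gridSpacing,
                              config$exclusionRadius)
  volRep <- function(v) list(
    method = v@method, dims = v@dims, volume_a3 = volumeA3(v),
    volume_l = signif(volumeLiters(v), 3),
    molarity_mM = round(molarityFromVolume(config$nMolecules,
                                           volumeA3(v)), 1))
  refs <- NULL
  if (!is.null(config$referenceVolumesA3)) {
    refs <- lapply(config$referenceVolumesA3, function(v) list(
      volume_a3 = v, volume_l = signif(angstrom3ToLiters(v), 3),
      molarity_mM = round(molarityFromVolume(config$nMolecules, v), 1)))
  }
  report <- list(
    validation = list(summary = val$summary, by_linker = val$byLinker,
                      by_condition = val$byCondition,
                      n_unresolved = nrow(val$unresolved)),
    cavity = list(cuboid = volRep(cub), grid = volRep(grd),
                  reference = refs),
    ruler = list(bilayer_width_a = config$bilayerWidth,
                 rise_per_residue = config$helixRise,
                 residues_to_span = residuesToSpan(config$bilayerWidth,
                                                   config$helixRise)))
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}
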