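#' @include AllClasses.R
NULL

.dfToBase <- function(df) as.data.frame(df, stringsAsFactors = FALSE)

#' Default pipeline configuration
#'
#' Returns the full configuration list with the conventional defaults:
#' threshold 0.35, positive correlations only, Louvain modules, 1000 null
#' simulations with the focal node forced producer, near-complete pathways
#' counted as producers.
#'
#' @param ... Named overrides of any default.
#' @return A named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    method = "sparcc",            # sparcc | pearson | spearman | precomputed
    sparcc = list(nIterations = 20L, exclusionThreshold = 0.1,
                  pseudocount = 1e-6, nExclusionRounds = 10L,
                  resampleDepth = 1000),
    nPerm = 0L,                   # permutation p-values off by default
    threshold = 0.35,
    positiveOnly = TRUE,
    pMax = NULL,
    hubMethod = "top_k",
    k = NULL,                     # default max(1, round(0.07 n))
    sdMult = 1,
    moduleMethod = "louvain",
    vitamins = NULL,              # default: all catalog vitamins
    nearCompletePolicy = "producer",
    focal = NULL,                 # default: top-ranked producer per vitamin
    nSim = 1000L,
    focalPolicy = "focal_forced_producer",
    presenceThreshold = 0,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop(sprintf("unknown configuration field(s): %s",
                 paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  cfg
}

.validateConfig <- function(cfg) {
  if (!is.numeric(cfg$threshold) || cfg$threshold <= 0 || cfg$threshold > 1)
    stop("configuration error: threshold must lie in (0, 1]")
  if (!cfg$method %in% c("sparcc", "pearson", "spearman", "precomputed"))
    stop("configuration error: unknown correlation method")
  if (cfg$nSim < 1) stop("configuration error: nSim must be >= 1")
  if (!cfg$nearCompletePolicy %in% c("producer", "auxotroph"))
    stop("configuration error: bad nearCompletePolicy")
  if (!cfg$focalPolicy %in% c("focal_forced_producer", "free_relabel"))
    stop("configuration error: bad focalPolicy")
  invisible(cfg)
}

#' Run the full vitamin-network pipeline
#'
#' Chains the stages end-to-end: correlation (or a precomputed matrix),
#' network construction at the configured threshold, betweenness/hub/module
#' topology, pathway calls and role labels per vitamin, vitamin-hubness
#' ranking with a label-randomization null for the focal node, and (when
#' metadata are supplied) condition-stratified comparisons. The run is a pure
#' function of (inputs, config, seed): identical reruns give identical
#' reports.
#'
#' @param abundance An [AbundanceTable] or a path to an abundance TSV.
#' @param annotations An [AnnotationSet] or a path to an annotation TSV
#'   (in which case `lengthsPath` may supply genome lengths).
#' @param catalog A [PathwayCatalog], a path to a catalog JSON, or `NULL`
#'   for the shipped catalog.
#' @param metadata Optional [SampleMetadata] or path.
#' @param correlation Optional precomputed [CorrelationMatrix] or path
#'   (used when `config$method == "precomputed"`).
#' @param config Configuration list from [pipelineConfig()].
#' @param outDir Optional directory; when given, `report.json` and per-stage
#'   TSVs are written there.
#' @param lengthsPath Optional path to a genome-length TSV.
#' @return The report as a nested list (invisibly when `outDir` is given).
#' @export
runPipeline <- function(abundance, annotations, catalog = NULL,
                        metadata = NULL, correlation = NULL,
                        config = pipelineConfig(), outDir = NULL,
                        lengthsPath = NULL) {
  cfg <- .validateConfig(config)

  tab <- if (is(abundance, "AbundanceTable")) abundance
         else readAbundanceTable(abundance)
  ann <- if (is(annotations, "AnnotationSet")) annotations
         else readAnnotations(annotations, lengthsPath)
  cat <- if (is.null(catalog)) defaultPathwayCatalog()
         else if (is(catalog, "PathwayCatalog")) catalog
         else readPathwayCatalog(catalog)
  meta <- if (is.null(metadata) || is(metadata, "SampleMetadata")) metadata
          else readSampleMetadata(metadata)

  onlyAbund <- setdiff(genomeIds(tab), genomeIds(ann))
  onlyAnn <- setdiff(genomeIds(ann), genomeIds(tab))
  if (length(onlyAbund) || length(onlyAnn))
    stop(sprintf(
      "genome-id mismatch between abundance and annotations; only in abundance: %s; only in annotations: %s",
      paste(utils::head(onlyAbund, 5), collapse = ", "),
      paste(utils::head(onlyAnn, 5), collapse = ", ")))

  ## stage: correlation
  corr <- if (cfg$method == "precomputed") {
    if (is.null(correlation)) stop("precomputed method requires 'correlation'")
    if (is(correlation, "CorrelationMatrix")) correlation
    else readCorrelationMatrix(correlation)
  } else if (cfg$method == "sparcc") {
    sp <- do.call(SparccParams, cfg$sparcc)
    sparccCorrelations(tab, sp, seed = cfg$seed)
  } else {
    naiveCorrelations(tab, cfg$method)
  }
  if (cfg$nPerm > 0)
    corr <- permutationPvalues(tab, corr, cfg$nPerm, seed = cfg$seed,
                               backend = if (cfg$method %in%
                                             c("pearson", "spearman"))
                                 cfg$method else "pearson")

  ## stage: network topology
  net <- buildNetwork(corr, threshold = cfg$threshold,
                      positiveOnly = cfg$positiveOnly, pMax = cfg$pMax)
  if (numNodes(net) == 0) stop("stage 'network' failed: the network is empty")
  cent <- betweennessCentrality(net)
  hubs <- delineateHubs(cent, method = cfg$hubMethod, k = cfg$k,
                        sdMult = cfg$sdMult)
  part <- detectModules(net, method = cfg$moduleMethod, seed = cfg$seed)
  summ <- networkSummary(net, part)

  ## stage: pathways and roles
  vitamins <- if (is.null(cfg$vitamins)) vitaminNames(cat) else cfg$vitamins
  calls <- callAllPathways(ann, cat, vitamins = vitamins)
  perVitamin <- list()
  for (vit in vitamins) {
    labAll <- classifyRoles(calls, vit, cfg$nearCompletePolicy)
    lab <- restrictRoles(labAll, net)
    ranked <- rankHubScores(net, lab)
    focal <- cfg$focal
    if (is.null(focal) && nrow(ranked) > 0) focal <- ranked$node[1L]
    null <- NULL
    if (!is.null(focal) && nrow(ranked) > 0)
      null <- randomizationNull(net, lab, focal, nSim = cfg$nSim,
                                seed = cfg$seed, focalPolicy = cfg$focalPolicy)
    perVitamin[[vit]] <- list(
      nProducers = nProducers(lab),
      nAuxotrophs = nAuxotrophs(lab),
      ranked = .dfToBase(ranked),
      focal = focal,
      null = if (is.null(null)) NULL else list(
        focal = null@focal, nSim = null@nSim,
        focalPolicy = null@focalPolicy, observed = null@observed,
        mean = null@nullMean, sd = null@nullSd, z = null@z,
        empiricalP = null@empiricalP, nIllDefined = null@nIllDefined))
  }

  ## stage: ecology (optional)
  ecology <- NULL
  if (!is.null(meta)) {
    modvec <- moduleMembership(part)
    ecology <- list(
      lifestyle = .dfToBase(compareCategories(
        tab, meta, "lifestyle", entities = hubs,
        presenceThreshold = cfg$presenceThreshold)),
      scn_level = .dfToBase(compareCategories(
        tab, meta, "scn_level", entities = hubs,
        presenceThreshold = cfg$presenceThreshold)),
      modules_lifestyle = .dfToBase(compareCategories(
        tab, meta, "lifestyle", modules = modvec,
        presenceThreshold = cfg$presenceThreshold)))
  }

  report <- list(
    config = cfg[!vapply(cfg, is.null, NA)],
    summary = list(nNodes = summ@nNodes, nEdges = summ@nEdges,
                   density = summ@density, meanDegree = summ@meanDegree,
                   modularity = summ@modularity,
                   nDropped = length(net@dropped)),
    hubs = hubs,
    centrality = .dfToBase(cent),
    modules = as.list(moduleMembership(part)),
    calls = .dfToBase(calls),
    vitamins = perVitamin,
    ecology = ecology)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeNetwork(net, file.path(outDir, "network.graphml"), "graphml")
    writeNetwork(net, file.path(outDir, "network.edges.tsv"), "edge_tsv")
    utils::write.table(.dfToBase(cent), file.path(outDir, "centrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(node = names(moduleMembership(part)),
                 module = moduleMembership(part)),
      file.path(outDir, "modules.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(.dfToBase(calls), file.path(outDir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    return(invisible(report))
  }
  report
}
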