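## End-to-end orchestration from a single YAML configuration.

#' Assemble a pipeline run configuration
#'
#' @param stageEdgeFiles named (or stage-ordered) character vector of edge
#'   list TSV paths, one per stage.
#' @param typeFile molecule type map TSV.
#' @param gmtFile GMT gene-set collection.
#' @param outDir output directory for all artifacts.
#' @param walk,screen,core configuration objects; defaults as documented in
#'   their constructors.
#' @param qMax enrichment q screen; default 0.05.
#' @param kinds molecule kinds admitted to enrichment; default
#'   \code{"gene"}.
#' @return a named list understood by [runPipeline()].
#' @export
runConfig <- function(stageEdgeFiles, typeFile, gmtFile, outDir,
                      walk = walkConfig(), screen = screenConfig(),
                      core = coreConfig(), qMax = 0.05, kinds = "gene") {
  list(stageEdgeFiles = stageEdgeFiles, typeFile = typeFile,
       gmtFile = gmtFile, outDir = outDir, walk = walk, screen = screen,
       core = core, qMax = qMax, kinds = kinds)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised blocks: \code{paths} (stage_edges list, types, gmt, out_dir)
#' and optional \code{walk}, \code{screen}, \code{core}, \code{enrich}
#' parameter blocks whose entries override the constructor defaults.
#'
#' @param path YAML file path.
#' @return a configuration list for [runPipeline()].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  p <- y$paths
  if (is.null(p$stage_edges) || is.null(p$types) || is.null(p$gmt))
    stop("config must provide paths: stage_edges, types, gmt")
  wc <- do.call(walkConfig, as.list(y$walk))
  sc <- do.call(screenConfig, as.list(y$screen))
  cc <- do.call(coreConfig, as.list(y$core))
  runConfig(unlist(p$stage_edges), p$types, p$gmt,
            if (is.null(p$out_dir)) "moduleEvo_run" else p$out_dir,
            walk = wc, screen = sc, core = cc,
            qMax = if (is.null(y$enrich$q_max)) 0.05 else y$enrich$q_max,
            kinds = if (is.null(y$enrich$kinds)) "gene" else y$enrich$kinds)
}

.stageLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.runStep <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full module-evolution pipeline
#'
#' Reads the stage networks, accumulates walk weights, screens modules,
#' builds the global module network, enriches modules against the GMT
#' collection, builds the functional, comprehensive and core evolution
#' networks, runs the design comparison, and writes every artifact plus a
#' YAML manifest (configuration echo, seed, package version, per-stage
#' counts) into the output directory.
#'
#' @param config list from [runConfig()] or [readRunConfig()].
#' @return invisibly, the output directory path.
#' @export
runPipeline <- function(config) {
  out <- config$outDir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  missing_f <- Filter(Negate(file.exists),
                      c(config$stageEdgeFiles, config$typeFile,
                        config$gmtFile))
  if (length(missing_f))
    stop("pipeline input file(s) not found: ",
         paste(missing_f, collapse = ", "))
  nS <- length(config$stageEdgeFiles)
  networks <- .runStep("graph_io", lapply(seq_len(nS), function(s)
    readStageNetwork(config$stageEdgeFiles[[s]], config$typeFile,
                     paste0("S", s))))
  counts <- list()
  moduleSets <- vector("list", nS)
  for (s in seq_len(nS)) {
    net <- networks[[s]]
    .stageLog(net@stage, "%d molecules, %d edges",
              igraph::vcount(net@graph), igraph::ecount(net@graph))
    wt <- .runStep("rw_cluster", accumulateWeights(net, config$walk))
    writeWeightTable(wt, file.path(out, sprintf("S%d_weights.tsv", s)), net)
    sel <- selectVertices(wt, config$walk)
    ms <- .runStep("module_screen", {
      if (length(sel) < 2L)
        finalizeModules(list(), net, config$screen, selected = sel)
      else
        finalizeModules(mergeUnions(screenPairs(sel, net, config$screen)),
                        net, config$screen, selected = sel)
    })
    .stageLog(net@stage, "%d selected vertices -> %d modules",
              length(sel), length(ms@modules))
    moduleSets[[s]] <- ms
    counts[[net@stage]] <- list(molecules = igraph::vcount(net@graph),
                                edges = igraph::ecount(net@graph),
                                selected = length(sel),
                                modules = length(ms@modules))
  }
  utils::write.table(moduleTable(moduleSets), file.path(out, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gmn <- .runStep("stage_network",
                  buildGlobalModuleNetwork(moduleSets, networks))
  writeNetwork(gmn, file.path(out, "global_module_network.graphml"))
  collection <- .runStep("enrichment", readGmt(config$gmtFile))
  results <- .runStep("enrichment",
    enrichModules(moduleSets, collection, qMax = config$qMax,
                  kinds = config$kinds))
  res_flat <- results[, setdiff(names(results), "overlap_members")]
  utils::write.table(res_flat, file.path(out, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fn <- .runStep("enrichment", buildFunctionalNetwork(results, collection))
  writeNetwork(fn, file.path(out, "functional_network.graphml"))
  cn <- .runStep("core_evolution", buildComprehensive(gmn, fn, results))
  writeNetwork(cn, file.path(out, "comprehensive_network.graphml"))
  core <- .runStep("core_evolution", selectCore(cn, config$core))
  cen <- .runStep("core_evolution",
                  buildCoreEvolution(cn, core, gmn, fn, config$core))
  writeNetwork(cen, file.path(out, "core_evolution_network.graphml"))
  ds <- degreeSummary(cn, threshold = config$core@coreDegreeMin)
  cmp <- .runStep("enrichment",
    compareDesigns(networks, moduleSets, collection, kinds = config$kinds))
  utils::write.table(data.frame(term = rownames(cmp), cmp,
                                check.names = FALSE),
                     file.path(out, "design_comparison.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("moduleEvo")),
    seed = config$walk@seed,
    walk = list(walkLength = config$walk@walkLength,
                walksPerVertex = config$walk@walksPerVertex,
                penaltyExponent = config$walk@penaltyExponent,
                vertexQuantile = config$walk@vertexQuantile),
    screen = list(overlapThreshold = config$screen@overlapThreshold,
                  minModuleSize = config$screen@minModuleSize,
                  unionMode = config$screen@unionMode),
    core = list(coreDegreeMin = config$core@coreDegreeMin,
                evolutionJaccardMin = config$core@evolutionJaccardMin),
    q_max = config$qMax,
    inputs = list(stage_edges = as.list(unname(config$stageEdgeFiles)),
                  types = config$typeFile, gmt = config$gmtFile),
    stage_counts = counts,
    core_modules = length(core$modules),
    core_functions = length(core$functions),
    fraction_modules_below_degree_threshold = ds$fraction_below)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(out)
}
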