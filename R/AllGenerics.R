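#' Underlying igraph of a network container
#' @param x a [MolecularNetwork-class] object.
#' @return the wrapped \pkg{igraph} graph.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "MolecularNetwork", function(x) x@graph)

#' Stage label of an object
#' @param x an object carrying a stage label.
#' @return the stage label, e.g. \code{"S2"}.
#' @export
setGeneric("stageId", function(x) standardGeneric("stageId"))

#' @rdname stageId
#' @export
setMethod("stageId", "StageNetwork", function(x) x@stage)
#' @rdname stageId
#' @export
setMethod("stageId", "VertexWeightTable", function(x) x@stage)
#' @rdname stageId
#' @export
setMethod("stageId", "ModuleSet", function(x) x@stage)

#' Molecule table of a stage network
#' @param x a [StageNetwork-class].
#' @return data.frame with columns \code{id} and \code{kind}.
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname molecules
#' @export
setMethod("molecules", "StageNetwork", function(x) {
  g <- x@graph
  data.frame(id = igraph::V(g)$name,
             kind = if (igraph::vcount(g)) igraph::V(g)$kind else character(),
             stringsAsFactors = FALSE)
})

#' Edge table of a network
#' @param x a [MolecularNetwork-class].
#' @return data.frame with columns \code{src}, \code{dst} and one column per
#'   edge attribute.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "MolecularNetwork", function(x) {
  df <- igraph::as_data_frame(x@graph, what = "edges")
  names(df)[1:2] <- c("src", "dst")
  df
})

#' Module member sets
#' @param x a [ModuleSet-class] or a network that retains module members.
#' @return named list of member id vectors.
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' @rdname moduleMembers
#' @export
setMethod("moduleMembers", "ModuleSet", function(x) x@modules)
#' @rdname moduleMembers
#' @export
setMethod("moduleMembers", "GlobalModuleNetwork", function(x) x@members)
#' @rdname moduleMembers
#' @export
setMethod("moduleMembers", "ComprehensiveNetwork", function(x) x@members)
#' @rdname moduleMembers
#' @export
setMethod("moduleMembers", "CoreEvolutionNetwork", function(x) x@members)

#' Gene sets of a GMT collection
#' @param x a [GmtCollection-class].
#' @return named list of member id vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setMethod("geneSets", "GmtCollection", function(x) x@sets)

#' Annotation universe of a GMT collection
#' @param x a [GmtCollection-class].
#' @return character vector of ids.
#' @export
setGeneric("setUniverse", function(x) standardGeneric("setUniverse"))

#' @rdname setUniverse
#' @export
setMethod("setUniverse", "GmtCollection", function(x) x@universe)

#' Accumulated vertex weights
#' @param x a [VertexWeightTable-class].
#' @return named numeric vector of penalty-adjusted weights.
#' @export
setGeneric("vertexWeights", function(x) standardGeneric("vertexWeights"))

#' @rdname vertexWeights
#' @export
setMethod("vertexWeights", "VertexWeightTable", function(x) x@weights)

#' Write a network to GraphML or TSV
#'
#' GraphML goes through \pkg{igraph} and round-trips all node and edge
#' attributes. TSV writes an edge table at \code{path} with columns
#' \code{src}, \code{dst} and all edge attributes, plus a companion node
#' table \code{<path-sans-ext>_nodes.tsv} with \code{id} and all vertex
#' attributes. For a [StageNetwork-class], TSV instead reproduces the input
#' formats: a two-column edge list and a companion \code{_types.tsv} molecule
#' type map, so [readStageNetwork()] round-trips it.
#'
#' @param x a [MolecularNetwork-class] object.
#' @param path output file path.
#' @param format \code{"graphml"} or \code{"tsv"}.
#' @return invisibly, the paths written.
#' @export
setGeneric("writeNetwork", function(x, path, format = c("graphml", "tsv"))
  standardGeneric("writeNetwork"))

## show methods --------------------------------------------------------------

setMethod("show", "StageNetwork", function(object) {
  g <- object@graph
  kinds <- if (igraph::vcount(g)) table(igraph::V(g)$kind) else table(character())
  cat(sprintf("StageNetwork %s: %d molecules (%s), %d edges\n",
              object@stage, igraph::vcount(g),
              paste(sprintf("%s %d", names(kinds), kinds), collapse = ", "),
              igraph::ecount(g)))
})

setMethod("show", "GlobalModuleNetwork", function(object) {
  g <- object@graph
  cls <- if (igraph::ecount(g)) table(igraph::E(g)$edge_class) else table(character())
  cat(sprintf("GlobalModuleNetwork: %d modules, %d edges (%s)\n",
              igraph::vcount(g), igraph::ecount(g),
              paste(sprintf("%s %d", names(cls), cls), collapse = ", ")))
})

setMethod("show", "FunctionalNetwork", function(object) {
  cat(sprintf("FunctionalNetwork: %d terms, %d edges\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
})

setMethod("show", "ComprehensiveNetwork", function(object) {
  g <- object@graph
  nc <- if (igraph::vcount(g)) table(igraph::V(g)$node_class) else table(character())
  cat(sprintf("ComprehensiveNetwork: %s; %d edges\n",
              paste(sprintf("%d %ss", nc, names(nc)), collapse = ", "),
              igraph::ecount(g)))
})

setMethod("show", "CoreEvolutionNetwork", function(object) {
  g <- object@graph
  nc <- if (igraph::vcount(g)) table(igraph::V(g)$node_class) else table(character())
  cat(sprintf("CoreEvolutionNetwork: %s; %d edges\n",
              paste(sprintf("%d core %ss", nc, names(nc)), collapse = ", "),
              igraph::ecount(g)))
})

setMethod("show", "ModuleSet", function(object) {
  cat(sprintf("ModuleSet %s: %d modules (sizes %s) from %d selected vertices\n",
              object@stage, length(object@modules),
              paste(lengths(object@modules), collapse = ", "),
              length(object@selected)))
})

setMethod("show", "VertexWeightTable", function(object) {
  cat(sprintf("VertexWeightTable %s: %d vertices, weight range [%.3g, %.3g]\n",
              object@stage, length(object@weights),
              if (length(object@weights)) min(object@weights) else NA,
              if (length(object@weights)) max(object@weights) else NA))
})

setMethod("show", "GmtCollection", function(object) {
  sz <- if (length(object@sets))
    paste(range(lengths(object@sets)), collapse = "-") else "0"
  cat(sprintf("GmtCollection: %d sets (sizes %s), universe of %d ids\n",
              length(object@sets), sz, length(object@universe)))
})
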