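#' @import methods
#' @import igraph
NULL

setOldClass("igraph")

## ---------------------------------------------------------------------------
## Network containers
## ---------------------------------------------------------------------------

#' Virtual parent of all network containers
#'
#' Every network produced by the pipeline (stage networks, the global module
#' network, the functional interaction network, the comprehensive network and
#' the core evolution network) wraps an undirected simple \pkg{igraph} graph
#' whose vertices are named. Subclasses add semantics and validity rules.
#'
#' @slot graph an \pkg{igraph} object.
#' @export
setClass("MolecularNetwork", representation("VIRTUAL", graph = "igraph"))

#' Stage-specific heterogeneous molecular network
#'
#' An undirected simple graph over differentially expressed molecules of one
#' clinical stage. Vertices carry a \code{kind} attribute (\code{gene},
#' \code{miRNA} or \code{lncRNA}); edges carry an \code{edge_kind} attribute
#' restricted to the four admissible endpoint-type pairs: gene--gene,
#' miRNA--lncRNA, gene--miRNA and gene--lncRNA. Same-kind miRNA or lncRNA
#' edges are invalid. Isolated vertices (typed but absent from the edge list)
#' are permitted.
#'
#' @slot graph the \pkg{igraph} graph.
#' @slot stage stage label of the form \code{"S<k>"}.
#' @seealso [readStageNetwork()], [stageNetwork()]
#' @export
setClass("StageNetwork", contains = "MolecularNetwork",
         representation(stage = "character"))

setValidity("StageNetwork", function(object) {
  g <- object@graph
  msgs <- character()
  if (length(object@stage) != 1L || !grepl("^S[0-9]+$", object@stage))
    msgs <- c(msgs, "stage must be a single label of the form 'S<k>'")
  if (igraph::is_directed(g))
    msgs <- c(msgs, "stage networks are undirected")
  if (igraph::vcount(g) > 0L) {
    if (is.null(igraph::V(g)$name) || anyNA(igraph::V(g)$name) ||
        any(!nzchar(igraph::V(g)$name)))
      msgs <- c(msgs, "all vertices must carry non-empty names")
    else if (anyDuplicated(igraph::V(g)$name))
      msgs <- c(msgs, "vertex names must be unique")
    kind <- igraph::V(g)$kind
    if (is.null(kind) || !all(kind %in% .MOLECULE_KINDS))
      msgs <- c(msgs, paste0("every vertex needs a kind in {",
                             paste(.MOLECULE_KINDS, collapse = ", "), "}"))
  }
  if (igraph::ecount(g) > 0L) {
    if (igraph::any_loop(g) || igraph::any_multiple(g))
      msgs <- c(msgs, "stage networks are simple (no loops or multi-edges)")
    ep <- igraph::ends(g, igraph::E(g), names = FALSE)
    kind <- igraph::V(g)$kind
    ek <- .edgeKind(kind[ep[, 1L]], kind[ep[, 2L]])
    if (anyNA(ek)) {
      bad <- which(is.na(ek))[1L]
      nm <- igraph::V(g)$name[ep[bad, ]]
      msgs <- c(msgs, sprintf(
        "edge %s--%s has endpoint kinds %s--%s, outside the four admissible kinds",
        nm[1L], nm[2L], kind[ep[bad, 1L]], kind[ep[bad, 2L]]))
    } else {
      stored <- igraph::E(g)$edge_kind
      if (is.null(stored) || !identical(stored, ek))
        msgs <- c(msgs, "edge_kind attribute must match endpoint kinds")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Global module network across the four stages
#'
#' Modules are nodes labelled \code{S<i>M<k>}. Intra-stage edges carry the
#' raw count of stage-network edges crossing the two modules; inter-stage
#' edges exist between adjacent stages only and carry the Jaccard coefficient
#' of the member sets. Member sets are retained in \code{members} for
#' downstream core-network extraction.
#'
#' @slot graph the \pkg{igraph} graph with node attributes \code{stage},
#'   \code{module_id}, \code{size} and edge attributes \code{edge_class}
#'   (\code{intra}/\code{inter}) and \code{weight}.
#' @slot members named list mapping node label to its member molecule ids.
#' @export
setClass("GlobalModuleNetwork", contains = "MolecularNetwork",
         representation(members = "list"))

setValidity("GlobalModuleNetwork", function(object) {
  g <- object@graph
  if (igraph::ecount(g) == 0L) return(TRUE)
  cls <- igraph::E(g)$edge_class
  w <- igraph::E(g)$weight
  ep <- igraph::ends(g, igraph::E(g))
  s1 <- .stageNum(igraph::V(g)$stage[match(ep[, 1L], igraph::V(g)$name)])
  s2 <- .stageNum(igraph::V(g)$stage[match(ep[, 2L], igraph::V(g)$name)])
  msgs <- character()
  if (!all(cls %in% c("intra", "inter")))
    msgs <- c(msgs, "edge_class must be 'intra' or 'inter'")
  if (any(cls == "intra" & s1 != s2))
    msgs <- c(msgs, "intra edges must join modules of the same stage")
  if (any(cls == "intra" & w < 1))
    msgs <- c(msgs, "intra edge counts must be >= 1")
  if (any(cls == "inter" & abs(s1 - s2) != 1L))
    msgs <- c(msgs, "inter edges must join adjacent stages")
  if (any(cls == "inter" & (w <= 0 | w > 1)))
    msgs <- c(msgs, "inter edge Jaccard weights must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Functional interaction network
#'
#' Enriched terms are nodes (one node per term, with the set of stages in
#' which it passed the q-value screen and the minimum q); edges join term
#' pairs whose annotated gene sets overlap, weighted by the Jaccard
#' coefficient of those sets.
#'
#' @slot graph \pkg{igraph} graph; node attributes \code{stages}
#'   (comma-separated), \code{min_q}; edge attribute \code{weight} (Jaccard,
#'   strictly positive).
#' @export
setClass("FunctionalNetwork", contains = "MolecularNetwork")

#' Comprehensive module--function network
#'
#' Node-disjoint union of the global module network and per-stage instances
#' of the enriched functions, plus module--function edges for every
#' enrichment that passed the q screen.
#'
#' @slot graph \pkg{igraph} graph; node attribute \code{node_class}
#'   (\code{module}/\code{function}); edge attribute \code{edge_class}
#'   (\code{intra}, \code{inter}, \code{function}, \code{module-function}).
#' @slot members module member sets carried over from the global network.
#' @export
setClass("ComprehensiveNetwork", contains = "MolecularNetwork",
         representation(members = "list"))

#' Core evolution network
#'
#' Induced on core modules (degree at or above the threshold in the
#' comprehensive network) and core functions (adjacent to a core module),
#' with inter-stage module edges filtered by the evolution Jaccard bound and
#' function-evolution edges between adjacent stages.
#'
#' @slot graph \pkg{igraph} graph.
#' @slot members module member sets of the retained core modules.
#' @export
setClass("CoreEvolutionNetwork", contains = "MolecularNetwork",
         representation(members = "list"))

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' Random-walk configuration
#'
#' @slot walkLength basic weight N: the start vertex of every walk weighs N,
#'   each subsequent step one less, down to 1 at the last possible step; the
#'   walk length equals N.
#' @slot walksPerVertex Monte-Carlo replicates started from every vertex.
#' @slot penaltyExponent exponent beta of the degree penalty
#'   \code{(deg/mean_deg)^beta}; visit contributions are divided by it.
#' @slot vertexQuantile vertices with weight strictly above this empirical
#'   quantile of the weight distribution are selected.
#' @slot seed master RNG seed from which every walk derives its substream.
#' @export
setClass("WalkConfig", representation(
  walkLength = "integer", walksPerVertex = "integer",
  penaltyExponent = "numeric", vertexQuantile = "numeric", seed = "integer"))

setValidity("WalkConfig", function(object) {
  msgs <- character()
  if (object@walkLength < 2L) msgs <- c(msgs, "walkLength must be >= 2")
  if (object@walksPerVertex < 1L) msgs <- c(msgs, "walksPerVertex must be >= 1")
  if (object@vertexQuantile < 0 || object@vertexQuantile >= 1)
    msgs <- c(msgs, "vertexQuantile must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Module-screening configuration
#'
#' @slot overlapThreshold pairs of selected vertices whose restricted closed
#'   neighborhoods overlap with ratio strictly above this value are retained.
#' @slot minModuleSize minimum number of vertices of an emitted module.
#' @slot unionMode what a retained pair contributes to the merge step: the
#'   vertex pair itself (\code{"pair"}, single linkage over the overlap
#'   relation) or the union of the two restricted closed neighborhoods
#'   (\code{"neighborhood"}).
#' @export
setClass("ScreenConfig", representation(
  overlapThreshold = "numeric", minModuleSize = "integer",
  unionMode = "character"))

setValidity("ScreenConfig", function(object) {
  msgs <- character()
  if (object@overlapThreshold < 0 || object@overlapThreshold > 1)
    msgs <- c(msgs, "overlapThreshold must lie in [0, 1]")
  if (object@minModuleSize < 1L) msgs <- c(msgs, "minModuleSize must be >= 1")
  if (!object@unionMode %in% c("pair", "neighborhood"))
    msgs <- c(msgs, "unionMode must be 'pair' or 'neighborhood'")
  if (length(msgs)) msgs else TRUE
})

#' Core-network configuration
#'
#' @slot coreDegreeMin minimum comprehensive-network degree (all edge classes
#'   counted) for a module to be core; the comparison is inclusive.
#' @slot evolutionJaccardMin inclusive lower bound on the Jaccard weight of
#'   inter-stage edges retained in the core evolution network.
#' @export
setClass("CoreConfig", representation(
  coreDegreeMin = "integer", evolutionJaccardMin = "numeric"))

setValidity("CoreConfig", function(object) {
  msgs <- character()
  if (object@coreDegreeMin < 0L) msgs <- c(msgs, "coreDegreeMin must be >= 0")
  if (object@evolutionJaccardMin < 0 || object@evolutionJaccardMin > 1)
    msgs <- c(msgs, "evolutionJaccardMin must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic-study specification
#'
#' Parameters of the planted-partition benchmark generator; see
#' [generateSyntheticStudy()].
#'
#' @slot nStages number of disease stages.
#' @slot modulesPerStage number K of planted modules per stage.
#' @slot moduleSize planted module size m.
#' @slot backgroundVertices number b of background vertices per stage.
#' @slot pIn,pOut Bernoulli edge probabilities inside planted modules and
#'   elsewhere; \code{pIn > pOut}.
#' @slot driftRho fraction of each module's members replaced between
#'   adjacent stages (\code{ceiling(driftRho * moduleSize)} members).
#' @slot typeFractions named proportions of gene/miRNA/lncRNA among the
#'   background vertices (planted modules are gene-only); must sum to 1.
#' @slot nNoiseSets number of decoy gene sets added to the GMT collection.
#' @slot seed generator seed.
#' @export
setClass("SyntheticSpec", representation(
  nStages = "integer", modulesPerStage = "integer", moduleSize = "integer",
  backgroundVertices = "integer", pIn = "numeric", pOut = "numeric",
  driftRho = "numeric", typeFractions = "numeric", nNoiseSets = "integer",
  seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (object@pIn <= object@pOut)
    msgs <- c(msgs, "pIn must exceed pOut")
  if (object@driftRho < 0 || object@driftRho > 1)
    msgs <- c(msgs, "driftRho must lie in [0, 1]")
  tf <- object@typeFractions
  if (length(tf) != 3L || !setequal(names(tf), .MOLECULE_KINDS) ||
      abs(sum(tf) - 1) > 1e-8 || any(tf < 0))
    msgs <- c(msgs, "typeFractions must be named gene/miRNA/lncRNA proportions summing to 1")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Results containers
## ---------------------------------------------------------------------------

#' Record of one random walk
#'
#' @slot start the start vertex id.
#' @slot vertices visited vertex ids in order; element t+1 is the vertex at
#'   step index t (step 0 is the start).
#' @slot truncated TRUE if a dead end was reached before the walk spent its
#'   N steps.
#' @export
setClass("WalkRecord", representation(
  start = "character", vertices = "character", truncated = "logical"))

#' Accumulated, penalty-adjusted vertex weights of one stage
#'
#' @slot stage stage label.
#' @slot weights named non-negative weights; every network vertex appears.
#' @slot config the [WalkConfig-class] that produced the table.
#' @export
setClass("VertexWeightTable", representation(
  stage = "character", weights = "numeric", config = "WalkConfig"))

setValidity("VertexWeightTable", function(object) {
  w <- object@weights
  if (length(w) && (is.null(names(w)) || anyNA(w) || any(!is.finite(w)) || any(w < 0)))
    return("weights must be a named, finite, non-negative vector")
  TRUE
})

#' Modules of one stage
#'
#' Disjoint connected vertex sets of at least the configured minimum size,
#' labelled M1, M2, ... in decreasing size order.
#'
#' @slot stage stage label.
#' @slot modules named list of member id vectors.
#' @slot kinds named character vector giving the molecule kind of every
#'   member across modules.
#' @slot selected the screened high-weight vertex set the modules were
#'   built from.
#' @export
setClass("ModuleSet", representation(
  stage = "character", modules = "list", kinds = "character",
  selected = "character"))

setValidity("ModuleSet", function(object) {
  mods <- object@modules
  if (!length(mods)) return(TRUE)
  msgs <- character()
  if (is.null(names(mods)) || anyDuplicated(names(mods)))
    msgs <- c(msgs, "module ids must be unique")
  all_m <- unlist(mods, use.names = FALSE)
  if (anyDuplicated(all_m))
    msgs <- c(msgs, "modules within a stage must be pairwise disjoint")
  if (length(msgs)) msgs else TRUE
})

#' GMT gene-set collection
#'
#' @slot sets named list of member id vectors, one per term.
#' @slot descriptions named descriptions, parallel to \code{sets}.
#' @slot universe annotation universe; every set is a subset of it.
#' @export
setClass("GmtCollection", representation(
  sets = "list", descriptions = "character", universe = "character"))

setValidity("GmtCollection", function(object) {
  msgs <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msgs <- c(msgs, "term ids must be unique")
    if (any(lengths(object@sets) == 0L))
      msgs <- c(msgs, "gene sets must be non-empty")
    if (!all(unlist(object@sets) %in% object@universe))
      msgs <- c(msgs, "every set must be contained in the universe")
  }
  if (length(msgs)) msgs else TRUE
})
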