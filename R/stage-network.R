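## The global module network: modules as nodes, intra-stage edges weighted
## by raw cross-edge counts, inter-stage edges (adjacent stages only)
## weighted by the Jaccard coefficient of the member sets.

#' Intra-stage module--module edges
#'
#' For every unordered pair of modules of one stage, counts the
#' stage-network edges with one endpoint in each; pairs with no crossing
#' edge are omitted.
#'
#' @param moduleSet a [ModuleSet-class].
#' @param network the [StageNetwork-class] of the same stage.
#' @return data.frame with columns \code{src}, \code{dst} (module ids),
#'   \code{weight} (edge count).
#' @export
intraStageEdges <- function(moduleSet, network) {
  if (!identical(moduleSet@stage, network@stage))
    stop("module set and network belong to different stages")
  mods <- moduleSet@modules
  empty <- data.frame(src = character(), dst = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(mods) < 2L) return(empty)
  g <- networkGraph(network)
  ep <- igraph::ends(g, igraph::E(g))
  memb <- stats::setNames(rep(names(mods), lengths(mods)),
                          unlist(mods, use.names = FALSE))
  m1 <- memb[ep[, 1L]]
  m2 <- memb[ep[, 2L]]
  cross <- !is.na(m1) & !is.na(m2) & m1 != m2
  if (!any(cross)) return(empty)
  key <- paste(pmin(m1[cross], m2[cross]), pmax(m1[cross], m2[cross]),
               sep = "\t")
  cnt <- table(key)
  parts <- strsplit(names(cnt), "\t", fixed = TRUE)
  data.frame(src = vapply(parts, `[`, "", 1L),
             dst = vapply(parts, `[`, "", 2L),
             weight = as.numeric(cnt), stringsAsFactors = FALSE)
}

#' Inter-stage module--module edges
#'
#' Modules of two adjacent stages are linked by the Jaccard coefficient of
#' their member sets; pairs with coefficient strictly above
#' \code{minJaccard} are emitted. Non-adjacent stage pairs are an error:
#' module correspondence is only defined along the stage sequence.
#'
#' @param moduleSetA,moduleSetB [ModuleSet-class] objects of stages i and
#'   i+1.
#' @param minJaccard strict lower bound; default 0 (keep all positive
#'   similarities).
#' @return data.frame with columns \code{src}, \code{dst}, \code{weight}
#'   (Jaccard).
#' @export
interStageEdges <- function(moduleSetA, moduleSetB, minJaccard = 0) {
  if (.stageNum(moduleSetB@stage) != .stageNum(moduleSetA@stage) + 1L)
    stop("stages must be adjacent (got ", moduleSetA@stage, " and ",
         moduleSetB@stage, ")")
  out <- data.frame(src = character(), dst = character(), weight = numeric(),
                    stringsAsFactors = FALSE)
  for (a in names(moduleSetA@modules)) {
    for (b in names(moduleSetB@modules)) {
      j <- jaccardCoefficient(moduleSetA@modules[[a]],
                              moduleSetB@modules[[b]])
      if (j > minJaccard)
        out[nrow(out) + 1L, ] <- list(a, b, j)
    }
  }
  out
}

#' Build the global module network
#'
#' Nodes are all modules of all stages, labelled \code{S<i>M<k>}; intra-stage
#' edges carry raw cross-edge counts and inter-stage edges (adjacent stages
#' only) carry member-set Jaccard coefficients. All positive inter-stage
#' similarities are kept here; the stricter evolution bound is applied only
#' at core-network extraction.
#'
#' @param moduleSets list of [ModuleSet-class] objects, one per stage, in
#'   stage order.
#' @param networks list of the matching [StageNetwork-class] objects.
#' @return a [GlobalModuleNetwork-class].
#' @export
buildGlobalModuleNetwork <- function(moduleSets, networks) {
  stopifnot(length(moduleSets) == length(networks))
  ord <- order(vapply(moduleSets, function(m) .stageNum(m@stage), integer(1L)))
  moduleSets <- moduleSets[ord]
  networks <- networks[ord]
  labels <- character()
  stages <- character()
  module_ids <- character()
  sizes <- integer()
  members <- list()
  for (ms in moduleSets) {
    lab <- if (length(ms@modules)) paste0(ms@stage, names(ms@modules))
           else character()
    labels <- c(labels, lab)
    stages <- c(stages, rep(ms@stage, length(lab)))
    module_ids <- c(module_ids, names(ms@modules))
    sizes <- c(sizes, unname(lengths(ms@modules)))
    members <- c(members, stats::setNames(ms@modules, lab))
  }
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(labels), name = labels, stage = stages,
                            module_id = module_ids, size = sizes)
  for (i in seq_along(moduleSets)) {
    ie <- intraStageEdges(moduleSets[[i]], networks[[i]])
    if (nrow(ie)) {
      st <- moduleSets[[i]]@stage
      g <- igraph::add_edges(g,
             rbind(paste0(st, ie$src), paste0(st, ie$dst)),
             edge_class = "intra", weight = ie$weight)
    }
    if (i < length(moduleSets)) {
      xe <- interStageEdges(moduleSets[[i]], moduleSets[[i + 1L]])
      if (nrow(xe)) {
        g <- igraph::add_edges(g,
               rbind(paste0(moduleSets[[i]]@stage, xe$src),
                     paste0(moduleSets[[i + 1L]]@stage, xe$dst)),
               edge_class = "inter", weight = xe$weight)
      }
    }
  }
  methods::new("GlobalModuleNetwork", graph = g, members = members)
}
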