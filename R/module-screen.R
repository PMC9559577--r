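## Turning selected high-weight vertices into modules: pairwise
## neighborhood-overlap screening, transitive union merging, the minimum
## size rule and programmatic connectivity repair.

#' Module-screening configuration constructor
#'
#' @param overlapThreshold retain a pair of selected vertices when the
#'   Jaccard-style ratio of their restricted closed neighborhoods is
#'   strictly above this value. Default \code{1/3}, placed between the
#'   expected within-module overlap of a dense planted module
#'   (about \code{p_in / (2 - p_in)}) and the near-zero overlap of
#'   vertices in different modules.
#' @param minModuleSize minimum module size; default 5.
#' @param unionMode \code{"pair"} (default) feeds the retained vertex pairs
#'   to the merge step (single linkage over the overlap relation);
#'   \code{"neighborhood"} feeds the full neighborhood unions instead, which
#'   is far more aggressive because a single cross-module neighbor chains
#'   otherwise separate clusters.
#' @return a validated [ScreenConfig-class].
#' @export
screenConfig <- function(overlapThreshold = 1 / 3, minModuleSize = 5L,
                         unionMode = c("pair", "neighborhood")) {
  methods::new("ScreenConfig",
               overlapThreshold = as.numeric(overlapThreshold),
               minModuleSize = as.integer(minModuleSize),
               unionMode = match.arg(unionMode))
}

# Closed neighborhoods of the selected vertices, restricted to the selected
# set: N[u] = {u} union (neighbors(u) intersect selected).
.restrictedNeighborhoods <- function(selected, network) {
  g <- networkGraph(network)
  nms <- igraph::V(g)$name
  unknown <- setdiff(selected, nms)
  if (length(unknown)) stop("selected vertex not in network: ", unknown[1L])
  adj <- igraph::as_adj_list(g)
  sel_set <- selected
  out <- lapply(match(selected, nms), function(i) {
    nb <- nms[as.integer(adj[[i]])]
    c(nms[i], intersect(nb, sel_set))
  })
  names(out) <- selected
  out
}

#' Neighborhood overlap of a pair of selected vertices
#'
#' Let A and B be the closed neighborhoods of \code{u} and \code{v}
#' restricted to the selected set. Returns the ratio
#' \code{|A intersect B| / |A union B|} and the union A ∪ B. The union
#' always contains both vertices, so the ratio is defined.
#'
#' @param u,v distinct selected vertex ids.
#' @param selected the selected vertex set.
#' @param network the [StageNetwork-class] the selection came from.
#' @return \code{list(ratio = , union = )}.
#' @export
pairOverlap <- function(u, v, selected, network) {
  if (!u %in% selected || !v %in% selected)
    stop("both vertices must be selected")
  if (identical(u, v)) stop("u and v must differ")
  g <- networkGraph(network)
  adj <- igraph::as_adj_list(g)
  nms <- igraph::V(g)$name
  A <- c(u, intersect(nms[as.integer(adj[[match(u, nms)]])], selected))
  B <- c(v, intersect(nms[as.integer(adj[[match(v, nms)]])], selected))
  un <- union(A, B)
  list(ratio = length(intersect(A, B)) / length(un), union = un)
}

#' Screen all pairs of selected vertices
#'
#' Evaluates every unordered pair; pairs whose restricted-neighborhood
#' overlap ratio is strictly above \code{overlapThreshold} are retained.
#' Depending on \code{unionMode} the retained unit is the vertex pair or the
#' neighborhood union.
#'
#' @param selected selected vertex ids (at least 2).
#' @param network the [StageNetwork-class].
#' @param config a [ScreenConfig-class].
#' @return list of retained vertex sets (possibly empty).
#' @export
screenPairs <- function(selected, network, config) {
  if (length(selected) < 2L) stop("need at least two selected vertices")
  nbhd <- .restrictedNeighborhoods(selected, network)
  thr <- config@overlapThreshold
  out <- vector("list", 0L)
  n <- length(selected)
  for (i in seq_len(n - 1L)) {
    A <- nbhd[[i]]
    for (j in (i + 1L):n) {
      B <- nbhd[[j]]
      un <- union(A, B)
      ratio <- (length(A) + length(B) - length(un)) / length(un)
      if (ratio > thr)
        out[[length(out) + 1L]] <- if (config@unionMode == "pair")
          c(selected[i], selected[j]) else un
    }
  }
  out
}

#' Merge overlapping vertex sets transitively
#'
#' Union-find closure of the overlap relation: any two input sets sharing a
#' vertex end up in the same output set. Outputs are pairwise disjoint and
#' their union equals the union of the inputs; the result does not depend on
#' input order.
#'
#' @param unions list of vertex id vectors.
#' @return list of disjoint vertex sets.
#' @examples
#' mergeUnions(list(c("a", "b"), c("b", "c"), c("d", "e")))
#' @export
mergeUnions <- function(unions) {
  if (!length(unions)) return(list())
  elems <- sort(unique(unlist(unions)))
  parent <- seq_along(elems)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (u in unions) {
    idx <- match(unique(u), elems)
    r <- find(idx[1L])
    for (j in idx[-1L]) {
      rj <- find(j)
      if (rj != r) parent[rj] <- r
    }
  }
  roots <- vapply(seq_along(elems), find, integer(1L))
  unname(split(elems, roots))
}

#' Finalize merged vertex sets into modules
#'
#' For each merged set, connected components are computed on the subgraph it
#' induces in the original stage network. This automates the visual
#' connectivity check: when a low-weight cut vertex was screened out, the
#' remaining high-weight vertices may fall apart, and each connected piece
#' is judged on its own. Components with at least \code{minModuleSize}
#' vertices become modules; smaller ones are dropped with a message.
#' Modules are numbered M1, M2, ... in decreasing size, ties broken by the
#' lexicographically smallest member id.
#'
#' @param merged list of disjoint vertex sets (from [mergeUnions()]).
#' @param network the [StageNetwork-class].
#' @param config a [ScreenConfig-class].
#' @param selected optionally, the selected vertex set for provenance.
#' @return a [ModuleSet-class].
#' @export
finalizeModules <- function(merged, network, config, selected = character()) {
  g <- networkGraph(network)
  mods <- list()
  dropped <- 0L
  for (s in merged) {
    sub <- igraph::induced_subgraph(g, s)
    cmp <- igraph::components(sub)
    for (k in seq_len(cmp$no)) {
      mem <- sort(names(cmp$membership)[cmp$membership == k])
      if (length(mem) >= config@minModuleSize)
        mods[[length(mods) + 1L]] <- mem
      else dropped <- dropped + 1L
    }
  }
  if (dropped)
    message(dropped, " connected component(s) below the minimum module size (",
            config@minModuleSize, ") dropped in stage ", network@stage)
  if (length(mods)) {
    ord <- order(-lengths(mods), vapply(mods, `[`, "", 1L))
    mods <- mods[ord]
    names(mods) <- paste0("M", seq_along(mods))
  }
  mol <- molecules(network)
  mem_all <- unlist(mods, use.names = FALSE)
  kinds <- stats::setNames(mol$kind[match(mem_all, mol$id)], mem_all)
  methods::new("ModuleSet", stage = network@stage, modules = mods,
               kinds = kinds, selected = as.character(selected))
}

#' Identify the modules of one stage end-to-end
#'
#' Convenience wrapper chaining [accumulateWeights()], [selectVertices()],
#' [screenPairs()], [mergeUnions()] and [finalizeModules()].
#'
#' @param network a [StageNetwork-class].
#' @param walkCfg a [WalkConfig-class].
#' @param screenCfg a [ScreenConfig-class].
#' @return a [ModuleSet-class] (empty when fewer than two vertices are
#'   selected).
#' @export
findModules <- function(network, walkCfg = walkConfig(),
                        screenCfg = screenConfig()) {
  wt <- accumulateWeights(network, walkCfg)
  sel <- selectVertices(wt, walkCfg)
  if (length(sel) < 2L)
    return(finalizeModules(list(), network, screenCfg, selected = sel))
  unions <- screenPairs(sel, network, screenCfg)
  merged <- mergeUnions(unions)
  finalizeModules(merged, network, screenCfg, selected = sel)
}

#' Long-format module table
#'
#' @param x a [ModuleSet-class] or list of them.
#' @return data.frame with columns \code{stage}, \code{module_id},
#'   \code{vertex}, \code{kind}.
#' @export
moduleTable <- function(x) {
  if (methods::is(x, "ModuleSet")) x <- list(x)
  rows <- lapply(x, function(ms) {
    if (!length(ms@modules))
      return(data.frame(stage = character(), module_id = character(),
                        vertex = character(), kind = character()))
    data.frame(stage = ms@stage,
               module_id = rep(names(ms@modules), lengths(ms@modules)),
               vertex = unlist(ms@modules, use.names = FALSE),
               kind = unname(ms@kinds[unlist(ms@modules, use.names = FALSE)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a long-format module table back into module sets
#'
#' Inverse of writing [moduleTable()] to TSV: reconstructs one
#' [ModuleSet-class] per stage (in stage order) from columns \code{stage},
#' \code{module_id}, \code{vertex}, \code{kind}. The provenance
#' \code{selected} slot is set to the module members.
#'
#' @param path TSV path with a header row.
#' @return list of [ModuleSet-class] objects.
#' @export
readModuleTable <- function(path) {
  if (!file.exists(path)) stop("module table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("stage", "module_id", "vertex", "kind")
  if (!all(need %in% names(df)))
    stop("module table must have columns: ", paste(need, collapse = ", "))
  stages <- unique(df$stage)
  stages <- stages[order(vapply(stages, .stageNum, integer(1L)))]
  lapply(stages, function(st) {
    sub <- df[df$stage == st, , drop = FALSE]
    mods <- split(sub$vertex, sub$module_id)
    mods <- mods[order(-lengths(mods), vapply(mods, min, ""))]
    methods::new("ModuleSet", stage = st, modules = mods,
                 kinds = stats::setNames(sub$kind, sub$vertex),
                 selected = sub$vertex)
  })
}
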