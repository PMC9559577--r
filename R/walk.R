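## Monte-Carlo random-walk vertex weighting.
##
## From every vertex, R independent walks of up to N-1 uniform-random
## neighbor steps are run. A visit at step index t contributes N - t (the
## start weighs N, the last possible step weighs 1); the contribution is
## divided by the vertex's degree penalty so aggregate weights are not an
## artifact of degree alone. Walks are not self-avoiding; dead ends truncate.

#' Random-walk configuration constructor
#'
#' @param walkLength basic weight N; also the walk length. Default 20.
#' @param walksPerVertex Monte-Carlo replicates R per start vertex.
#'   Default 100.
#' @param penaltyExponent exponent beta of the degree penalty
#'   \code{(deg/mean_deg)^beta} dividing each visit contribution. The default
#'   \code{-1} boosts visits to relatively high-degree vertices, countering
#'   the tendency of decaying, start-everywhere walks to favor peripheral
#'   low-degree vertices; \code{0} disables the penalty; \code{+1} penalises
#'   hubs instead.
#' @param vertexQuantile empirical quantile of the weight distribution above
#'   which (strictly) vertices are selected. Default 0.5.
#' @param seed master seed; every walk derives a deterministic substream
#'   from it, so results do not depend on execution order.
#' @return a validated [WalkConfig-class].
#' @export
walkConfig <- function(walkLength = 20L, walksPerVertex = 100L,
                       penaltyExponent = -1, vertexQuantile = 0.5,
                       seed = 1L) {
  methods::new("WalkConfig",
               walkLength = as.integer(walkLength),
               walksPerVertex = as.integer(walksPerVertex),
               penaltyExponent = as.numeric(penaltyExponent),
               vertexQuantile = as.numeric(vertexQuantile),
               seed = as.integer(seed))
}

#' Weight of a walk step
#'
#' A visit at step index \code{t} (0 for the start) contributes
#' \code{N - t}: the start vertex weighs N, the final possible step weighs 1.
#'
#' @param t step index or vector of indices in \code{0..N-1}.
#' @param config a [WalkConfig-class].
#' @return non-negative weights.
#' @examples
#' stepWeight(0, walkConfig(walkLength = 5))  # 5
#' stepWeight(4, walkConfig(walkLength = 5))  # 1
#' @export
stepWeight <- function(t, config) {
  N <- config@walkLength
  if (any(t < 0L) || any(t > N - 1L))
    stop("step index must lie in 0..N-1 (N = ", N, ")")
  N - t
}

#' Degree penalty coefficients
#'
#' \code{(deg(v) / mean_deg)^beta}, where the mean degree is taken over
#' non-isolated vertices. Visit contributions are divided by this
#' coefficient. Isolated vertices get coefficient 1; \code{beta = 0}
#' disables the penalty.
#'
#' @param network a [StageNetwork-class] (any [MolecularNetwork-class]
#'   works).
#' @param config a [WalkConfig-class]; only \code{penaltyExponent} is used.
#' @param vertices ids to report; default all.
#' @return named positive coefficients.
#' @export
penaltyCoefficient <- function(network, config, vertices = NULL) {
  g <- networkGraph(network)
  deg <- igraph::degree(g)
  pos <- deg > 0
  pen <- rep(1, length(deg))
  if (any(pos)) {
    dbar <- mean(deg[pos])
    pen[pos] <- (deg[pos] / dbar)^config@penaltyExponent
  }
  names(pen) <- igraph::V(g)$name
  if (is.null(vertices)) return(pen)
  unknown <- setdiff(vertices, names(pen))
  if (length(unknown)) stop("unknown vertex: ", unknown[1L])
  pen[vertices]
}

# Core walk over an integer adjacency list; returns visited vertex indices
# in order (length <= N, shorter only when a dead end truncates the walk).
.walkIndices <- function(adj, start, N) {
  path <- integer(N)
  path[1L] <- start
  cur <- start
  len <- 1L
  for (t in seq_len(N - 1L)) {
    nb <- adj[[cur]]
    if (!length(nb)) break
    cur <- nb[sample.int(length(nb), 1L)]
    len <- len + 1L
    path[len] <- cur
  }
  path[seq_len(len)]
}

#' Run one seeded random walk
#'
#' Performs up to \code{N - 1} uniform-random neighbor steps from
#' \code{start}, recording every visit (revisits included). If the current
#' vertex has no neighbor the walk stops early and is flagged truncated.
#'
#' @param network a [StageNetwork-class].
#' @param start start vertex id.
#' @param config a [WalkConfig-class].
#' @param seed optional integer seeding this single walk; when \code{NULL}
#'   the current RNG state is used.
#' @return a [WalkRecord-class].
#' @export
runWalk <- function(network, start, config, seed = NULL) {
  g <- networkGraph(network)
  nms <- igraph::V(g)$name
  i <- match(start, nms)
  if (is.na(i)) stop("start vertex not in network: ", start)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  if (!is.null(seed)) set.seed(seed)
  idx <- .walkIndices(adj, i, config@walkLength)
  methods::new("WalkRecord", start = start, vertices = nms[idx],
               truncated = length(idx) < config@walkLength)
}

#' Raw (pre-penalty) weight contribution of a walk
#'
#' Sum of the step weights of all recorded visits. A walk that spends its
#' full length contributes exactly \code{N(N+1)/2}.
#'
#' @param record a [WalkRecord-class].
#' @param config the [WalkConfig-class] used to run it.
#' @return a single number.
#' @export
walkContribution <- function(record, config) {
  sum(stepWeight(seq_along(record@vertices) - 1L, config))
}

#' Accumulate penalty-adjusted walk weights over a stage network
#'
#' Runs \code{walksPerVertex} independent walks from every vertex. The
#' weight of vertex v is the sum over all its recorded visits (revisits
#' each count) of \code{stepWeight(t) / penaltyCoefficient(v)}, divided by
#' the replicate count so values are comparable across configurations. Each
#' walk's RNG substream is derived from \code{(seed, stage, start,
#' replicate)}, making the table independent of execution order and
#' reproducible.
#'
#' @param network a [StageNetwork-class].
#' @param config a [WalkConfig-class].
#' @return a [VertexWeightTable-class] covering every network vertex.
#' @export
accumulateWeights <- function(network, config) {
  g <- networkGraph(network)
  nms <- igraph::V(g)$name
  nv <- length(nms)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  pen <- unname(penaltyCoefficient(network, config))
  N <- config@walkLength
  R <- config@walksPerVertex
  w <- numeric(nv)
  for (i in seq_len(nv)) {
    for (r in seq_len(R)) {
      set.seed(.hashSeed(config@seed, network@stage, nms[i], r))
      idx <- .walkIndices(adj, i, N)
      # revisited vertices must accumulate once per visit, so do not use
      # vectorized assignment (w[idx] collapses duplicate indices)
      for (j in seq_along(idx))
        w[idx[j]] <- w[idx[j]] + (N - j + 1L) / pen[idx[j]]
    }
  }
  methods::new("VertexWeightTable", stage = network@stage,
               weights = stats::setNames(w / R, nms), config = config)
}

#' Select high-weight vertices
#'
#' Returns the vertices whose accumulated weight lies strictly above the
#' \code{vertexQuantile} empirical quantile of the stage's weight
#' distribution. With all weights equal nothing is selected; with quantile 0
#' everything strictly above the minimum is.
#'
#' @param table a [VertexWeightTable-class].
#' @param config a [WalkConfig-class]; only \code{vertexQuantile} is used.
#' @return character vector of selected vertex ids.
#' @export
selectVertices <- function(table, config) {
  w <- table@weights
  if (!length(w)) stop("empty weight table")
  thr <- stats::quantile(w, config@vertexQuantile, names = FALSE, type = 7)
  names(w)[w > thr]
}

#' Write a vertex weight table to TSV
#'
#' Columns: \code{vertex}, \code{kind} (when the originating network is
#' supplied), \code{weight}.
#'
#' @param table a [VertexWeightTable-class].
#' @param path output path.
#' @param network optional [StageNetwork-class] supplying molecule kinds.
#' @return invisibly, \code{path}.
#' @export
writeWeightTable <- function(table, path, network = NULL) {
  df <- data.frame(vertex = names(table@weights),
                   weight = unname(table@weights),
                   stringsAsFactors = FALSE)
  if (!is.null(network)) {
    mol <- molecules(network)
    df$kind <- mol$kind[match(df$vertex, mol$id)]
    df <- df[, c("vertex", "kind", "weight")]
  }
  .writeTsvTable(df, path)
  invisible(path)
}
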