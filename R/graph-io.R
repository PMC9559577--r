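## Reading, validating and writing the per-stage molecular networks and all
## derived networks. TSV inputs are UTF-8, tab-separated, '#' comments ignored.

.readTsv <- function(path, n_cols, what) {
  if (!file.exists(path)) stop("cannot read ", what, ": file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE,
                          colClasses = "character", fill = FALSE,
                          encoding = "UTF-8")
  if (ncol(df) < n_cols)
    stop(what, " must have at least ", n_cols, " tab-separated columns: ", path)
  df[, seq_len(n_cols), drop = FALSE]
}

#' Construct a stage network from an edge table and a type map
#'
#' Builds a validated [StageNetwork-class] directly from in-memory data;
#' [readStageNetwork()] is the file-based front end. Duplicate and reversed
#' edges collapse to one undirected edge; self-loops are rejected; molecules
#' present in \code{types} but absent from \code{edges} are retained as
#' isolated vertices.
#'
#' @param edges two-column data.frame (or matrix) of molecule id pairs.
#' @param types named character vector mapping molecule id to kind
#'   (\code{gene}, \code{miRNA} or \code{lncRNA}); must cover all edge ids.
#' @param stage stage label \code{"S<k>"}.
#' @return a [StageNetwork-class].
#' @export
stageNetwork <- function(edges, types, stage) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) && ncol(edges) < 2L) stop("edges needs two columns")
  if (is.null(names(types)) || anyDuplicated(names(types)))
    stop("types must be a named vector with unique ids")
  bad_kind <- setdiff(unique(types), .MOLECULE_KINDS)
  if (length(bad_kind))
    stop("unknown molecule kind(s): ", paste(bad_kind, collapse = ", "))
  ids_used <- unique(c(edges[[1L]], edges[[2L]]))
  missing_t <- setdiff(ids_used, names(types))
  if (length(missing_t))
    stop("molecule(s) missing from the type map: ",
         paste(utils::head(missing_t, 5L), collapse = ", "))
  if (nrow(edges)) {
    if (any(edges[[1L]] == edges[[2L]])) {
      i <- which(edges[[1L]] == edges[[2L]])[1L]
      stop("self-loop on line ", i, ": ", edges[i, 1L])
    }
    ek <- .edgeKind(types[edges[[1L]]], types[edges[[2L]]])
    if (anyNA(ek)) {
      i <- which(is.na(ek))[1L]
      stop(sprintf(
        "edge on line %d (%s--%s) has kinds %s--%s, not one of the four admissible edge kinds",
        i, edges[i, 1L], edges[i, 2L],
        types[[edges[i, 1L]]], types[[edges[i, 2L]]]))
    }
    # canonical undirected key for dedup
    key <- paste(pmin(edges[[1L]], edges[[2L]]), pmax(edges[[1L]], edges[[2L]]))
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    ek <- ek[keep]
  } else ek <- character()
  verts <- union(names(types), ids_used)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts,
                            kind = unname(types[verts]))
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges[[1L]], edges[[2L]]), edge_kind = ek)
  iso <- setdiff(names(types), ids_used)
  if (length(iso))
    message(length(iso), " isolated molecule(s) retained in stage ", stage)
  methods::new("StageNetwork", graph = g, stage = stage)
}

#' Read a stage network from TSV files
#'
#' The edge file is a two-column tab-separated list of molecule id pairs; the
#' type file maps every id (including isolates) to its molecule kind. Lines
#' starting with \code{#} are ignored in both. Edges whose endpoint kinds are
#' not one of gene--gene, miRNA--lncRNA, gene--miRNA, gene--lncRNA raise a
#' validation error naming the offending line.
#'
#' @param edgePath path to the edge list TSV.
#' @param typePath path to the id-to-kind TSV.
#' @param stage stage label \code{"S<k>"}.
#' @return a validated [StageNetwork-class].
#' @examples
#' ef <- tempfile(); tf <- tempfile()
#' writeLines("g1\tg2", ef)
#' writeLines(c("g1\tgene", "g2\tgene"), tf)
#' readStageNetwork(ef, tf, "S1")
#' @export
readStageNetwork <- function(edgePath, typePath, stage) {
  edges <- tryCatch(.readTsv(edgePath, 2L, "edge list"), error = function(e) {
    if (grepl("file not found", conditionMessage(e))) stop(e)
    # an empty edge file is a legal degenerate input
    if (length(readLines(edgePath, warn = FALSE)) == 0L ||
        all(grepl("^#|^\\s*$", readLines(edgePath, warn = FALSE))))
      return(data.frame(V1 = character(), V2 = character()))
    stop(e)
  })
  tdf <- .readTsv(typePath, 2L, "molecule type map")
  if (anyDuplicated(tdf[[1L]]))
    stop("duplicate molecule id in type map: ",
         tdf[[1L]][duplicated(tdf[[1L]])][1L])
  types <- stats::setNames(tdf[[2L]], tdf[[1L]])
  stageNetwork(edges, types, stage)
}

## --- writers ---------------------------------------------------------------

.nodesPath <- function(path, suffix) {
  ext <- tools::file_ext(path)
  base <- tools::file_path_sans_ext(path)
  paste0(base, suffix, if (nzchar(ext)) paste0(".", ext) else ".tsv")
}

.writeTsvTable <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

.writeGraphTsv <- function(g, path) {
  edf <- igraph::as_data_frame(g, what = "edges")
  names(edf)[1:2] <- c("src", "dst")
  ndf <- igraph::as_data_frame(g, what = "vertices")
  if (!nrow(ndf) && igraph::vcount(g) == 0L)
    ndf <- data.frame(name = character())
  names(ndf)[1L] <- "id"
  npath <- .nodesPath(path, "_nodes")
  .writeTsvTable(edf, path)
  .writeTsvTable(ndf, npath)
  c(path, npath)
}

#' @rdname writeNetwork
#' @export
setMethod("writeNetwork", "MolecularNetwork", function(x, path,
    format = c("graphml", "tsv")) {
  format <- match.arg(format)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("unwritable path (no such directory): ", dirname(path))
  if (format == "graphml") {
    igraph::write_graph(x@graph, path, format = "graphml")
    return(invisible(path))
  }
  invisible(.writeGraphTsv(x@graph, path))
})

#' @rdname writeNetwork
#' @export
setMethod("writeNetwork", "StageNetwork", function(x, path,
    format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("unwritable path (no such directory): ", dirname(path))
  if (format == "graphml") {
    g <- x@graph
    igraph::V(g)$stage <- x@stage
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  # reproduce the package's own input format: edge list + type map
  edf <- igraph::as_data_frame(x@graph, what = "edges")[, 1:2, drop = FALSE]
  names(edf) <- c("molecule_a", "molecule_b")
  tdf <- molecules(x)
  tpath <- .nodesPath(path, "_types")
  utils::write.table(edf, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(tdf, tpath, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(path, tpath))
})

#' Read a network written by [writeNetwork()]
#'
#' Reconstructs the underlying graph (as a plain \pkg{igraph} object) from
#' either format, restoring all vertex and edge attributes.
#'
#' @param path path given to [writeNetwork()].
#' @param format \code{"graphml"} or \code{"tsv"}.
#' @return an \pkg{igraph} graph.
#' @export
readNetworkFile <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  edf <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE, comment.char = "")
  ndf <- utils::read.table(.nodesPath(path, "_nodes"), sep = "\t",
                           header = TRUE, quote = "",
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = NA)
  names(ndf)[1L] <- "name"
  ndf[[1L]] <- as.character(ndf[[1L]])
  if (nrow(edf)) { edf[[1L]] <- as.character(edf[[1L]]); edf[[2L]] <- as.character(edf[[2L]]) }
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = ndf)
}
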