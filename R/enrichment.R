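## Local over-representation analysis of module members against GMT gene
## sets: one-sided hypergeometric tests, Benjamini-Hochberg q-values with a
## q <= 0.05 screen, the functional interaction network and the
## Design1/Design2 comparison matrix Q' = -ln q.

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated as term, description, then
#' member ids. Sets with zero members are skipped with a warning; duplicate
#' term ids are an error. Unless an explicit universe is supplied, the
#' annotation universe is the union of all set members; with an explicit
#' universe, members outside it are dropped (sets emptied that way are
#' skipped with a warning).
#'
#' @param path path to the GMT file.
#' @param universe optional character vector, or path to a one-id-per-line
#'   file, giving the annotation universe.
#' @return a [GmtCollection-class].
#' @export
readGmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    term <- f[1L]
    mem <- unique(f[-(1:2)])
    mem <- mem[nzchar(mem)]
    if (!length(mem)) {
      warning("skipping empty gene set: ", term)
      next
    }
    if (term %in% names(sets)) stop("duplicate term id in GMT: ", term)
    sets[[term]] <- mem
    descs[term] <- if (length(f) >= 2L) f[2L] else ""
  }
  if (!is.null(universe) && length(universe) == 1L && file.exists(universe))
    universe <- readLines(universe, warn = FALSE)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)))
  } else {
    universe <- unique(universe)
    sets <- lapply(sets, intersect, universe)
    empty <- lengths(sets) == 0L
    if (any(empty)) {
      warning("set(s) empty after universe restriction skipped: ",
              paste(names(sets)[empty], collapse = ", "))
      sets <- sets[!empty]
      descs <- descs[!empty]
    }
  }
  methods::new("GmtCollection", sets = sets, descriptions = descs,
               universe = universe)
}

#' Write a GMT gene-set collection
#'
#' @param collection a [GmtCollection-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(collection, path) {
  lines <- vapply(names(collection@sets), function(term) {
    paste(c(term, collection@descriptions[[term]],
            collection@sets[[term]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the realised overlap when
#' \code{|module| ∩ universe} ids are drawn without replacement from the
#' universe, of which the term's members are the successes — the standard
#' over-representation (Fisher one-sided) test. The module is intersected
#' with the universe first.
#'
#' @param moduleMembers module member ids.
#' @param termSet term member ids (a subset of the universe).
#' @param universe annotation universe.
#' @return the p-value in (0, 1].
#' @examples
#' # universe 10, term 5, module 4, overlap 4: C(5,4)/C(10,4) = 5/210
#' hypergeomTest(letters[1:4], letters[1:5], letters[1:10])
#' @export
hypergeomTest <- function(moduleMembers, termSet, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  termSet <- unique(termSet)
  if (length(setdiff(termSet, universe)))
    stop("term set must be contained in the universe")
  m <- intersect(unique(moduleMembers), universe)
  k <- length(intersect(m, termSet))
  stats::phyper(k - 1L, length(termSet), length(universe) - length(termSet),
                length(m), lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input. Inputs outside (0, 1] are an error.
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values, same order as \code{p}.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Filter a member vector to the requested molecule kinds. kinds = NULL
# admits everything (fully synthetic runs may have no annotated genes).
.filterKinds <- function(members, kindMap, kinds) {
  if (is.null(kinds)) return(members)
  members[kindMap[members] %in% kinds]
}

#' Enrich modules against a gene-set collection
#'
#' Tests every (module, term) pair with at least one overlapping member,
#' adjusts with Benjamini-Hochberg across all tests of a stage (or across
#' everything with \code{scope = "global"}), and keeps results with
#' \code{q <= qMax}. Only gene-kind members are tested by default,
#' mirroring annotation databases that cover genes; \code{kinds = NULL}
#' admits all molecule kinds.
#'
#' @param moduleSets a [ModuleSet-class] or list of them.
#' @param collection a [GmtCollection-class].
#' @param qMax q-value screen; default 0.05. Use 1 to disable.
#' @param kinds molecule kinds admitted to testing; default \code{"gene"}.
#' @param scope BH-adjustment scope: \code{"stage"} (default) or
#'   \code{"global"}.
#' @return data.frame with columns \code{stage}, \code{module}, \code{term},
#'   \code{overlap}, \code{p}, \code{q} and list-column
#'   \code{overlap_members}, sorted by stage then q.
#' @export
enrichModules <- function(moduleSets, collection, qMax = 0.05,
                          kinds = "gene", scope = c("stage", "global")) {
  scope <- match.arg(scope)
  if (methods::is(moduleSets, "ModuleSet")) moduleSets <- list(moduleSets)
  uni <- collection@universe
  rows <- list()
  for (ms in moduleSets) {
    for (mid in names(ms@modules)) {
      mem <- .filterKinds(ms@modules[[mid]], ms@kinds, kinds)
      mem <- intersect(mem, uni)
      if (!length(mem)) next
      for (term in names(collection@sets)) {
        ov <- intersect(mem, collection@sets[[term]])
        if (!length(ov)) next
        rows[[length(rows) + 1L]] <- data.frame(
          stage = ms@stage, module = mid, term = term,
          overlap = length(ov),
          p = hypergeomTest(mem, collection@sets[[term]], uni),
          stringsAsFactors = FALSE)
        rows[[length(rows)]]$overlap_members <- I(list(sort(ov)))
      }
    }
  }
  if (!length(rows))
    return(data.frame(stage = character(), module = character(),
                      term = character(), overlap = integer(),
                      p = numeric(), q = numeric()))
  res <- do.call(rbind, rows)
  if (scope == "global") {
    res$q <- bhAdjust(res$p)
  } else {
    res$q <- NA_real_
    for (st in unique(res$stage)) {
      i <- res$stage == st
      res$q[i] <- bhAdjust(res$p[i])
    }
  }
  res <- res[res$q <= qMax, , drop = FALSE]
  res <- res[order(res$stage, res$q, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the functional interaction network
#'
#' Passing terms become nodes annotated with the stages in which they passed
#' and the minimum q; edges join term pairs whose annotated gene sets have a
#' positive Jaccard coefficient, which is the edge weight. A term passing in
#' several stages is one node flagged with all of them.
#'
#' @param results enrichment results from [enrichModules()].
#' @param collection the [GmtCollection-class] the results were computed
#'   against.
#' @return a [FunctionalNetwork-class].
#' @export
buildFunctionalNetwork <- function(results, collection) {
  terms <- unique(results$term)
  unknown <- setdiff(terms, names(collection@sets))
  if (length(unknown)) stop("term not in collection: ", unknown[1L])
  g <- igraph::make_empty_graph(0, directed = FALSE)
  if (!length(terms))
    return(methods::new("FunctionalNetwork", graph = g))
  stages <- vapply(terms, function(tm)
    paste(sort(unique(results$stage[results$term == tm])), collapse = ","), "")
  min_q <- vapply(terms, function(tm)
    min(results$q[results$term == tm]), numeric(1L))
  g <- igraph::add_vertices(g, length(terms), name = terms,
                            stages = unname(stages), min_q = unname(min_q))
  if (length(terms) >= 2L) {
    for (i in seq_len(length(terms) - 1L)) {
      for (j in (i + 1L):length(terms)) {
        jc <- jaccardCoefficient(collection@sets[[terms[i]]],
                                 collection@sets[[terms[j]]])
        if (jc > 0)
          g <- igraph::add_edges(g, c(terms[i], terms[j]),
                                 edge_class = "function", weight = jc)
      }
    }
  }
  methods::new("FunctionalNetwork", graph = g)
}

#' Compare module-wise enrichment against two pooled designs
#'
#' Per stage, three gene lists are scored against every term: Design1 pools
#' all molecules of the stage network; Design2 pools the molecules the
#' clustering placed in modules, without dividing them; the module-wise
#' method tests each module separately and reports the minimum q per term.
#' The comparative index is \code{Q' = -ln q}, with 0 encoding absence or
#' q = 1.
#'
#' @param networks list of [StageNetwork-class] objects.
#' @param moduleSets matching list of [ModuleSet-class] objects.
#' @param collection a [GmtCollection-class].
#' @param kinds molecule kinds admitted; default \code{"gene"}.
#' @return matrix of Q' values, rows = collection terms, columns =
#'   \code{<method>.<stage>} for methods Design1, Design2, modulewise.
#' @export
compareDesigns <- function(networks, moduleSets, collection, kinds = "gene") {
  stopifnot(length(networks) == length(moduleSets))
  terms <- names(collection@sets)
  uni <- collection@universe
  stages <- vapply(networks, stageId, "")
  methodsv <- c("Design1", "Design2", "modulewise")
  out <- matrix(0, nrow = length(terms),
                ncol = length(methodsv) * length(stages),
                dimnames = list(terms, paste(rep(methodsv, each = length(stages)),
                                             rep(stages, length(methodsv)),
                                             sep = ".")))
  qs_for <- function(members) {
    members <- intersect(members, uni)
    p <- rep(NA_real_, length(terms))
    for (i in seq_along(terms)) {
      if (length(intersect(members, collection@sets[[terms[i]]])))
        p[i] <- hypergeomTest(members, collection@sets[[terms[i]]], uni)
    }
    q <- rep(NA_real_, length(terms))
    tested <- !is.na(p)
    if (any(tested)) q[tested] <- bhAdjust(p[tested])
    q
  }
  for (si in seq_along(stages)) {
    net <- networks[[si]]
    ms <- moduleSets[[si]]
    mol <- molecules(net)
    kindMap <- stats::setNames(mol$kind, mol$id)
    d1 <- .filterKinds(mol$id, kindMap, kinds)
    d2 <- .filterKinds(unlist(ms@modules, use.names = FALSE), ms@kinds, kinds)
    q1 <- qs_for(d1)
    q2 <- if (length(d2)) qs_for(d2) else rep(NA_real_, length(terms))
    # module-wise: min q per term over the stage's modules, stage-scoped BH
    res <- enrichModules(ms, collection, qMax = 1, kinds = kinds)
    q3 <- rep(NA_real_, length(terms))
    if (nrow(res)) {
      agg <- tapply(res$q, res$term, min)
      q3[match(names(agg), terms)] <- agg
    }
    qprime <- function(q) ifelse(is.na(q) | q >= 1, 0, -log(q))
    out[, paste("Design1", stages[si], sep = ".")] <- qprime(q1)
    out[, paste("Design2", stages[si], sep = ".")] <- qprime(q2)
    out[, paste("modulewise", stages[si], sep = ".")] <- qprime(q3)
  }
  out
}
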