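## The comprehensive module--function network and the core evolution
## network distilled from it.

#' Core-network configuration constructor
#'
#' @param coreDegreeMin minimum degree (all edge classes counted) in the
#'   comprehensive network for a module to be core; default 5, inclusive.
#' @param evolutionJaccardMin inclusive lower bound on inter-stage Jaccard
#'   weights retained in the core evolution network; default 0.1.
#' @return a validated [CoreConfig-class].
#' @export
coreConfig <- function(coreDegreeMin = 5L, evolutionJaccardMin = 0.1) {
  methods::new("CoreConfig", coreDegreeMin = as.integer(coreDegreeMin),
               evolutionJaccardMin = as.numeric(evolutionJaccardMin))
}

.functionNodeLabel <- function(term, stage) paste0(term, "@", stage)

#' Build the comprehensive network
#'
#' Node-disjoint union of the global module network and the enriched
#' functions, instantiated per (term, stage), plus one module--function edge
#' for every enrichment result that passed the q screen. Function instances
#' of the same stage are linked when the functional network links their
#' terms (weight = gene-set Jaccard).
#'
#' @param gmn a [GlobalModuleNetwork-class].
#' @param fn a [FunctionalNetwork-class].
#' @param results the screened enrichment results the functional network was
#'   built from.
#' @return a [ComprehensiveNetwork-class].
#' @export
buildComprehensive <- function(gmn, fn, results) {
  g <- gmn@graph
  igraph::V(g)$node_class <- "module"
  igraph::V(g)$term <- NA_character_
  igraph::V(g)$q <- NA_real_
  if (nrow(results)) {
    mod_lab <- paste0(results$stage, results$module)
    missing_mod <- setdiff(mod_lab, igraph::V(g)$name)
    if (length(missing_mod))
      stop("enrichment result references unknown module: ", missing_mod[1L])
    missing_term <- setdiff(results$term, igraph::V(fn@graph)$name)
    if (length(missing_term))
      stop("enrichment result references term absent from the functional network: ",
           missing_term[1L])
    inst <- unique(results[, c("term", "stage")])
    inst_lab <- .functionNodeLabel(inst$term, inst$stage)
    inst$q <- mapply(function(tm, st)
      min(results$q[results$term == tm & results$stage == st]),
      inst$term, inst$stage)
    g <- igraph::add_vertices(g, nrow(inst), name = inst_lab,
                              node_class = "function", stage = inst$stage,
                              term = inst$term, q = inst$q,
                              module_id = NA_character_, size = NA_integer_)
    # module--function edges, one per passing (module, term, stage) result
    g <- igraph::add_edges(g,
           rbind(mod_lab, .functionNodeLabel(results$term, results$stage)),
           edge_class = "module-function", weight = 1,
           q = results$q)
    # same-stage function--function edges inherited from the functional network
    fg <- fn@graph
    if (igraph::ecount(fg)) {
      fe <- igraph::as_data_frame(fg, what = "edges")
      for (i in seq_len(nrow(fe))) {
        s1 <- inst$stage[inst$term == fe$from[i]]
        s2 <- inst$stage[inst$term == fe$to[i]]
        for (st in intersect(s1, s2)) {
          g <- igraph::add_edges(g,
                 c(.functionNodeLabel(fe$from[i], st),
                   .functionNodeLabel(fe$to[i], st)),
                 edge_class = "function", weight = fe$weight[i],
                 q = NA_real_)
        }
      }
    }
  }
  methods::new("ComprehensiveNetwork", graph = g, members = gmn@members)
}

#' Degree summary of the comprehensive network's module side
#'
#' Reports the fraction of module nodes whose degree (all edge classes)
#' falls below the threshold, together with the analytic standard-normal
#' mass of the one-sigma interval (mu - sigma, mu + sigma) that the
#' three-sigma rule compares it against. The normal mass is computed, not a
#' stored constant.
#'
#' @param net a [ComprehensiveNetwork-class] with at least one module node.
#' @param threshold degree threshold; default 5.
#' @return \code{list(fraction_below = , one_sigma_normal_mass = )}.
#' @export
degreeSummary <- function(net, threshold = 5L) {
  g <- net@graph
  mod <- igraph::V(g)$node_class == "module"
  if (!any(mod)) stop("no module nodes in the comprehensive network")
  deg <- igraph::degree(g)[mod]
  list(fraction_below = mean(deg < threshold),
       one_sigma_normal_mass = stats::pnorm(1) - stats::pnorm(-1))
}

#' Select core modules and core functions
#'
#' Core modules are module nodes whose total degree in the comprehensive
#' network is at least \code{coreDegreeMin}; core functions are function
#' nodes adjacent to at least one core module.
#'
#' @param net a [ComprehensiveNetwork-class].
#' @param config a [CoreConfig-class].
#' @return \code{list(modules = , functions = )} of node labels.
#' @export
selectCore <- function(net, config = coreConfig()) {
  g <- net@graph
  deg <- igraph::degree(g)
  cls <- igraph::V(g)$node_class
  nms <- igraph::V(g)$name
  core_mod <- nms[cls == "module" & deg >= config@coreDegreeMin]
  fun_nodes <- nms[cls == "function"]
  core_fun <- character()
  if (length(fun_nodes) && length(core_mod)) {
    adj <- igraph::adjacent_vertices(g, fun_nodes)
    keep <- vapply(adj, function(a) any(nms[as.integer(a)] %in% core_mod), TRUE)
    core_fun <- fun_nodes[keep]
  }
  list(modules = core_mod, functions = core_fun)
}

#' Extract the core evolution network
#'
#' Induces the comprehensive network on core modules and core functions,
#' keeps intra-stage module edges and module--function edges, filters
#' inter-stage module edges to Jaccard at or above
#' \code{evolutionJaccardMin}, drops same-stage function--function edges,
#' and adds function-evolution edges between function instances of adjacent
#' stages that carry the same term (weight 1) or whose terms' gene sets have
#' Jaccard at or above the bound. Both evolution-edge rules can be toggled.
#'
#' @param net a [ComprehensiveNetwork-class].
#' @param core core sets from [selectCore()].
#' @param gmn the [GlobalModuleNetwork-class] (module member provenance).
#' @param fn the [FunctionalNetwork-class] (term--term similarities).
#' @param config a [CoreConfig-class].
#' @param sameTermEdges link same-term instances of adjacent stages.
#' @param similarTermEdges link adjacent-stage instances of different terms
#'   with gene-set Jaccard at or above the bound.
#' @return a [CoreEvolutionNetwork-class].
#' @export
buildCoreEvolution <- function(net, core, gmn, fn, config = coreConfig(),
                               sameTermEdges = TRUE, similarTermEdges = TRUE) {
  g <- igraph::induced_subgraph(net@graph,
                                c(core$modules, core$functions))
  drop <- igraph::E(g)[igraph::E(g)$edge_class == "function" |
                       (igraph::E(g)$edge_class == "inter" &
                        igraph::E(g)$weight < config@evolutionJaccardMin)]
  g <- igraph::delete_edges(g, drop)
  # function-evolution edges between adjacent stages
  cls <- igraph::V(g)$node_class
  fun <- which(cls == "function")
  if (length(fun) >= 2L) {
    terms <- igraph::V(g)$term[fun]
    stgs <- .stageNum(igraph::V(g)$stage[fun])
    nms <- igraph::V(g)$name[fun]
    fe <- if (igraph::ecount(fn@graph))
      igraph::as_data_frame(fn@graph, what = "edges")
    else data.frame(from = character(), to = character(), weight = numeric())
    termJ <- function(t1, t2) {
      hit <- (fe$from == t1 & fe$to == t2) | (fe$from == t2 & fe$to == t1)
      if (any(hit)) fe$weight[hit][1L] else 0
    }
    for (i in seq_len(length(fun) - 1L)) {
      for (j in (i + 1L):length(fun)) {
        if (abs(stgs[i] - stgs[j]) != 1L) next
        if (terms[i] == terms[j]) {
          if (sameTermEdges)
            g <- igraph::add_edges(g, c(nms[i], nms[j]),
                   edge_class = "function-evolution", weight = 1,
                   q = NA_real_)
        } else if (similarTermEdges) {
          jc <- termJ(terms[i], terms[j])
          if (jc >= config@evolutionJaccardMin)
            g <- igraph::add_edges(g, c(nms[i], nms[j]),
                   edge_class = "function-evolution", weight = jc,
                   q = NA_real_)
        }
      }
    }
  }
  methods::new("CoreEvolutionNetwork", graph = g,
               members = net@members[intersect(names(net@members),
                                               core$modules)])
}
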