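## Planted-partition benchmark generator: multi-stage heterogeneous
## networks with drifting planted modules and a matched GMT collection, so
## the whole pipeline is testable without any external download.

#' Synthetic-study specification constructor
#'
#' Defaults describe the benchmark the package is validated on: four
#' stages of 88 molecules each (4 planted modules of 12 genes plus 40
#' background vertices), dense within-module wiring (\code{pIn = 0.6})
#' against sparse background (\code{pOut = 0.02}), a quarter of each
#' module's membership drifting between adjacent stages, and a background
#' population containing the miRNA/lncRNA molecules.
#'
#' @param nStages number of stages; default 4.
#' @param modulesPerStage planted modules K per stage; default 4.
#' @param moduleSize planted module size m; default 12.
#' @param backgroundVertices background vertices b per stage; default 40.
#' @param pIn within-module Bernoulli edge probability; default 0.6.
#' @param pOut background/cross edge probability; default 0.02.
#' @param driftRho fraction of module members resampled between adjacent
#'   stages; default 0.25.
#' @param typeFractions gene/miRNA/lncRNA proportions of the background
#'   block (planted modules are gene-only); default 0.7/0.15/0.15.
#' @param nNoiseSets decoy gene sets in the GMT collection; default 10.
#' @param seed generator seed; default 7.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nStages = 4L, modulesPerStage = 4L, moduleSize = 12L,
                          backgroundVertices = 40L, pIn = 0.6, pOut = 0.02,
                          driftRho = 0.25,
                          typeFractions = c(gene = 0.7, miRNA = 0.15,
                                            lncRNA = 0.15),
                          nNoiseSets = 10L, seed = 7L) {
  methods::new("SyntheticSpec",
               nStages = as.integer(nStages),
               modulesPerStage = as.integer(modulesPerStage),
               moduleSize = as.integer(moduleSize),
               backgroundVertices = as.integer(backgroundVertices),
               pIn = as.numeric(pIn), pOut = as.numeric(pOut),
               driftRho = as.numeric(driftRho),
               typeFractions = typeFractions,
               nNoiseSets = as.integer(nNoiseSets),
               seed = as.integer(seed))
}

# Background type counts: round miRNA/lncRNA, genes take the remainder.
.backgroundCounts <- function(spec) {
  b <- spec@backgroundVertices
  nMir <- round(b * spec@typeFractions[["miRNA"]])
  nLnc <- round(b * spec@typeFractions[["lncRNA"]])
  nGene <- b - nMir - nLnc
  if (nGene < 0) stop("type fractions leave no room for background genes")
  c(gene = nGene, miRNA = nMir, lncRNA = nLnc)
}

#' Generate a synthetic multi-stage study
#'
#' Per stage, each planted module wires internally with probability
#' \code{pIn}; all other admissible pairs (the four edge-kind whitelist is
#' respected by construction, so no inadmissible edge is ever proposed)
#' wire with probability \code{pOut}. Between adjacent stages each module
#' replaces \code{ceiling(driftRho * moduleSize)} members with background
#' genes currently outside every module; dropped members return to the
#' background, keeping the per-stage vertex universe fixed. The GMT
#' collection holds one gene set per module lineage (the union of its
#' members across stages) plus random decoy sets; truth tables map every
#' vertex to its planted module per stage.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir optional directory; when given, the exact pipeline input
#'   files are written there (per-stage \code{S<k>_edges.tsv}, a shared
#'   \code{molecule_types.tsv}, \code{gene_sets.gmt},
#'   \code{truth_modules.tsv}) byte-identically for a given spec and seed.
#' @return list with elements \code{networks} (list of
#'   [StageNetwork-class]), \code{truth} (data.frame stage/vertex/lineage,
#'   lineage 0 = background), \code{lineageMembers} (list: stage ->
#'   lineage -> member ids), \code{collection} (a [GmtCollection-class]),
#'   and \code{spec}.
#' @export
generateSyntheticStudy <- function(spec = syntheticSpec(), dir = NULL) {
  K <- spec@modulesPerStage
  m <- spec@moduleSize
  repl <- ceiling(spec@driftRho * m)
  bg <- .backgroundCounts(spec)
  if (repl * K > bg[["gene"]])
    stop("infeasible spec: drift needs ", repl * K,
         " spare background genes per transition but only ", bg[["gene"]],
         " exist")
  set.seed(spec@seed)
  gene_ids <- sprintf("g%03d", seq_len(K * m + bg[["gene"]]))
  mir_ids <- sprintf("mir%02d", seq_len(bg[["miRNA"]]))
  lnc_ids <- sprintf("lnc%02d", seq_len(bg[["lncRNA"]]))
  ids <- c(gene_ids, mir_ids, lnc_ids)
  types <- stats::setNames(c(rep("gene", length(gene_ids)),
                             rep("miRNA", length(mir_ids)),
                             rep("lncRNA", length(lnc_ids))), ids)
  ## drifting membership
  members <- vector("list", spec@nStages)
  members[[1L]] <- stats::setNames(
    split(gene_ids[seq_len(K * m)], rep(seq_len(K), each = m)),
    paste0("L", seq_len(K)))
  if (spec@nStages > 1L) for (s in 2L:spec@nStages) {
    prev <- members[[s - 1L]]
    free <- setdiff(gene_ids, unlist(prev))
    cur <- prev
    for (k in seq_len(K)) {
      if (repl == 0L) break
      drop <- sample(prev[[k]], repl)
      fresh <- sample(free, repl)
      free <- c(setdiff(free, fresh), drop)
      cur[[k]] <- sort(c(setdiff(prev[[k]], drop), fresh))
    }
    members[[s]] <- cur
  }
  ## per-stage edges over all admissible pairs
  n <- length(ids)
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  admissible <- !is.na(.edgeKind(types[ids[pair_i]], types[ids[pair_j]]))
  networks <- vector("list", spec@nStages)
  for (s in seq_len(spec@nStages)) {
    lin <- stats::setNames(rep(0L, n), ids)
    for (k in seq_len(K)) lin[members[[s]][[k]]] <- k
    same <- lin[ids[pair_i]] != 0L & lin[ids[pair_i]] == lin[ids[pair_j]]
    p <- ifelse(same, spec@pIn, spec@pOut)
    p[!admissible] <- 0
    keep <- stats::runif(length(p)) < p
    edges <- data.frame(a = ids[pair_i[keep]], b = ids[pair_j[keep]],
                        stringsAsFactors = FALSE)
    networks[[s]] <- suppressMessages(
      stageNetwork(edges, types, paste0("S", s)))
  }
  ## truth table
  truth <- do.call(rbind, lapply(seq_len(spec@nStages), function(s) {
    lin <- stats::setNames(rep(0L, n), ids)
    for (k in seq_len(K)) lin[members[[s]][[k]]] <- k
    data.frame(stage = paste0("S", s), vertex = ids, lineage = unname(lin),
               stringsAsFactors = FALSE)
  }))
  ## GMT: one set per lineage (union of members across stages) + decoys
  sets <- lapply(seq_len(K), function(k)
    sort(unique(unlist(lapply(members, `[[`, k)))))
  names(sets) <- paste0("L", seq_len(K))
  descs <- stats::setNames(paste("planted module lineage", seq_len(K)),
                           names(sets))
  for (d in seq_len(spec@nNoiseSets)) {
    nm <- sprintf("noise%02d", d)
    sets[[nm]] <- sort(sample(gene_ids, sample(5:15, 1L)))
    descs[nm] <- "random decoy set"
  }
  collection <- methods::new("GmtCollection", sets = sets,
                             descriptions = descs,
                             universe = sort(unique(unlist(sets))))
  out <- list(networks = networks, truth = truth,
              lineageMembers = members, collection = collection, spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (s in seq_len(spec@nStages))
      writeNetwork(networks[[s]],
                   file.path(dir, sprintf("S%d_edges.tsv", s)), "tsv")
    utils::write.table(data.frame(id = ids, kind = unname(types)),
                       file.path(dir, "molecule_types.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeGmt(collection, file.path(dir, "gene_sets.gmt"))
    utils::write.table(truth, file.path(dir, "truth_modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Evaluate recovered modules against the planted truth
#'
#' Per stage, the adjusted Rand index compares the recovered module label of
#' every assigned vertex with its planted lineage (background is its own
#' class); \code{scope = "all"} instead labels every vertex, unassigned ones
#' as an extra background-like class. Additionally, for every module lineage
#' and every adjacent stage pair, reports the best Jaccard coefficient
#' between recovered modules majority-assigned to that lineage in the two
#' stages (0 when a side has no majority module).
#'
#' @param moduleSets list of [ModuleSet-class] objects in stage order.
#' @param truth the truth data.frame from [generateSyntheticStudy()].
#' @param scope \code{"assigned"} (default) or \code{"all"}.
#' @return list with \code{ari} (named per stage) and
#'   \code{lineageJaccard} (data.frame from/to/lineage/jaccard).
#' @export
evaluateRecovery <- function(moduleSets, truth, scope = c("assigned", "all")) {
  scope <- match.arg(scope)
  stages <- vapply(moduleSets, stageId, "")
  ari <- stats::setNames(numeric(length(stages)), stages)
  for (i in seq_along(moduleSets)) {
    ms <- moduleSets[[i]]
    tt <- truth[truth$stage == ms@stage, ]
    lin <- stats::setNames(tt$lineage, tt$vertex)
    if (scope == "assigned") {
      verts <- unlist(ms@modules, use.names = FALSE)
      lab <- rep(names(ms@modules), lengths(ms@modules))
    } else {
      verts <- tt$vertex
      lab <- rep("unassigned", length(verts))
      for (mid in names(ms@modules))
        lab[verts %in% ms@modules[[mid]]] <- mid
    }
    ari[i] <- if (length(verts))
      mclust::adjustedRandIndex(lab, lin[verts]) else NA_real_
  }
  lineages <- sort(setdiff(unique(truth$lineage), 0L))
  lj <- data.frame(from = character(), to = character(), lineage = integer(),
                   jaccard = numeric(), stringsAsFactors = FALSE)
  majority <- function(ms, lin, k) {
    Filter(function(mem) mean(lin[mem] == k) > 0.5, ms@modules)
  }
  for (i in seq_len(length(moduleSets) - 1L)) {
    tA <- truth[truth$stage == stages[i], ]
    tB <- truth[truth$stage == stages[i + 1L], ]
    linA <- stats::setNames(tA$lineage, tA$vertex)
    linB <- stats::setNames(tB$lineage, tB$vertex)
    for (k in lineages) {
      ma <- majority(moduleSets[[i]], linA, k)
      mb <- majority(moduleSets[[i + 1L]], linB, k)
      best <- 0
      for (a in ma) for (b in mb)
        best <- max(best, jaccardCoefficient(a, b))
      lj[nrow(lj) + 1L, ] <- list(stages[i], stages[i + 1L], k, best)
    }
  }
  list(ari = ari, lineageJaccard = lj)
}
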