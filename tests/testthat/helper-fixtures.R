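# Fixtures and independent oracles shared across the suite.

# Build a StageNetwork from a vector of "a-b" edge strings and a type map;
# all-gene by default.
makeNet <- function(edges = character(), types = NULL, stage = "S1") {
  if (length(edges)) {
    parts <- strsplit(edges, "-", fixed = TRUE)
    edf <- data.frame(a = vapply(parts, `[`, "", 1L),
                      b = vapply(parts, `[`, "", 2L),
                      stringsAsFactors = FALSE)
  } else {
    edf <- data.frame(a = character(), b = character())
  }
  if (is.null(types)) {
    ids <- unique(c(edf$a, edf$b))
    types <- stats::setNames(rep("gene", length(ids)), ids)
  }
  suppressMessages(stageNetwork(edf, types, stage))
}

# A ModuleSet built directly from member lists (bypassing the walk), for
# tests of the downstream linking/enrichment steps.
makeModuleSet <- function(stage, members, kinds = NULL) {
  if (length(members)) names(members) <- paste0("M", seq_along(members))
  all_m <- as.character(unlist(members, use.names = FALSE))
  if (is.null(kinds))
    kinds <- stats::setNames(rep("gene", length(all_m)), all_m)
  methods::new("ModuleSet", stage = stage, modules = members, kinds = kinds,
               selected = all_m)
}

# Independent BH step-up, straight from the definition: q_(i) =
# min_{j >= i} min(1, m * p_(j) / j) mapped back to input order.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive hypergeometric upper tail: enumerate every size-m draw from a
# universe of n with K successes and count draws with overlap >= k.
enumHyperTail <- function(k, K, n, m) {
  if (m == 0L) return(if (k <= 0L) 1 else 0)
  draws <- utils::combn(n, m)
  hits <- colSums(draws <= K)  # successes are elements 1..K
  mean(hits >= k)
}

# Independent connectivity check by hand-rolled BFS over an edge string set.
bfsConnected <- function(members, net) {
  g <- networkGraph(net)
  if (length(members) <= 1L) return(TRUE)
  nms <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), function(x) nms[as.integer(x)])
  names(adj) <- nms
  seen <- members[1L]
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(intersect(unlist(adj[frontier]), members), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  setequal(seen, members)
}

# Small planted two-module network with a deterministic layout: two
# 6-cliques bridged by one edge.
twoCliqueNet <- function(stage = "S1") {
  cl <- function(v) {
    p <- utils::combn(v, 2L)
    paste(p[1L, ], p[2L, ], sep = "-")
  }
  makeNet(c(cl(paste0("a", 1:6)), cl(paste0("b", 1:6)), "a1-b1"),
          stage = stage)
}

# The default benchmark study and its recovered modules, computed once per
# test session (several acceptance properties share it).
.studyCache <- new.env(parent = emptyenv())
defaultStudyRun <- function() {
  if (is.null(.studyCache$run)) {
    study <- generateSyntheticStudy()
    moduleSets <- suppressMessages(lapply(study$networks, findModules))
    .studyCache$run <- list(study = study, moduleSets = moduleSets)
  }
  .studyCache$run
}
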