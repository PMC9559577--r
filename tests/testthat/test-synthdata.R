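smallSpec <- function(...) {
  syntheticSpec(nStages = 3L, modulesPerStage = 2L, moduleSize = 6L,
                backgroundVertices = 12L, pIn = 0.7, pOut = 0.05,
                nNoiseSets = 3L, seed = 5L, ...)
}

test_that("generated stages share a fixed typed vertex universe", {
  st <- generateSyntheticStudy(smallSpec())
  expect_length(st$networks, 3L)
  n_expected <- 2L * 6L + 12L
  for (net in st$networks) {
    mol <- molecules(net)
    expect_equal(nrow(mol), n_expected)
    # background split: 12 * 0.15 miRNA and lncRNA each, genes the rest
    expect_equal(sum(mol$kind == "miRNA"), 2L)
    expect_equal(sum(mol$kind == "lncRNA"), 2L)
    expect_equal(sum(mol$kind == "gene"), n_expected - 4L)
  }
  # the universe is literally identical across stages
  ids1 <- molecules(st$networks[[1]])$id
  for (net in st$networks[-1]) expect_equal(molecules(net)$id, ids1)
})

test_that("every generated edge respects the admissibility whitelist", {
  st <- generateSyntheticStudy(smallSpec())
  for (net in st$networks) {
    ek <- edgeTable(net)$edge_kind
    expect_true(all(ek %in% c("gene-gene", "gene-miRNA", "gene-lncRNA",
                              "miRNA-lncRNA")))
  }
})

test_that("planted modules are gene-only, sized m and drift by the ceiling rule", {
  spec <- smallSpec()
  st <- generateSyntheticStudy(spec)
  repl <- ceiling(spec@driftRho * spec@moduleSize)  # ceiling(1.5) = 2
  expect_equal(repl, 2L)
  for (s in seq_len(spec@nStages)) {
    mem <- st$lineageMembers[[s]]
    expect_length(mem, 2L)
    expect_true(all(lengths(mem) == 6L))
    expect_true(all(grepl("^g", unlist(mem))))
    # modules of one stage are disjoint
    expect_equal(anyDuplicated(unlist(mem)), 0L)
  }
  for (s in seq_len(spec@nStages - 1L)) {
    for (k in 1:2) {
      kept <- intersect(st$lineageMembers[[s]][[paste0("L", k)]],
                        st$lineageMembers[[s + 1L]][[paste0("L", k)]])
      expect_length(kept, 6L - repl)
    }
  }
})

test_that("the truth table matches the lineage membership lists", {
  st <- generateSyntheticStudy(smallSpec())
  expect_equal(nrow(st$truth), 3L * 24L)
  expect_true(all(st$truth$lineage %in% 0:2))
  for (s in 1:3) {
    tt <- st$truth[st$truth$stage == paste0("S", s), ]
    for (k in 1:2)
      expect_setequal(tt$vertex[tt$lineage == k],
                      st$lineageMembers[[s]][[paste0("L", k)]])
  }
})

test_that("the matched collection holds lineage unions plus decoys over a gene universe", {
  spec <- smallSpec()
  st <- generateSyntheticStudy(spec)
  sets <- geneSets(st$collection)
  expect_setequal(names(sets)[1:2], c("L1", "L2"))
  expect_equal(sum(grepl("^noise", names(sets))), 3L)
  for (k in 1:2)
    expect_setequal(sets[[paste0("L", k)]],
                    unique(unlist(lapply(st$lineageMembers, `[[`,
                                         paste0("L", k)))))
  expect_true(all(grepl("^g", setUniverse(st$collection))))
})

test_that("written study files are byte-identical across regeneration and re-readable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  st <- generateSyntheticStudy(smallSpec(), dir = d1)
  generateSyntheticStudy(smallSpec(), dir = d2)
  files <- c(sprintf("S%d_edges.tsv", 1:3), "molecule_types.tsv",
             "gene_sets.gmt", "truth_modules.tsv")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  net1 <- readStageNetwork(file.path(d1, "S1_edges.tsv"),
                           file.path(d1, "molecule_types.tsv"), "S1")
  expect_equal(edgeTable(net1), edgeTable(st$networks[[1]]))
  col <- readGmt(file.path(d1, "gene_sets.gmt"))
  expect_equal(geneSets(col), geneSets(st$collection))
})

test_that("a drift demand exceeding the spare background genes is rejected", {
  spec <- syntheticSpec(modulesPerStage = 4L, moduleSize = 12L,
                        backgroundVertices = 12L, driftRho = 0.25)
  expect_error(generateSyntheticStudy(spec), "infeasible")
})

test_that("specification validity rejects inconsistent parameters", {
  expect_error(syntheticSpec(pIn = 0.1, pOut = 0.5))
  expect_error(syntheticSpec(typeFractions = c(gene = 0.5, miRNA = 0.2,
                                               lncRNA = 0.2)))
})

test_that("perfect recovery scores ARI 1 and the drift-determined lineage Jaccard", {
  spec <- smallSpec()
  st <- generateSyntheticStudy(spec)
  perfect <- lapply(seq_len(spec@nStages), function(s)
    makeModuleSet(paste0("S", s), unname(st$lineageMembers[[s]])))
  ev <- evaluateRecovery(perfect, st$truth)
  expect_equal(unname(ev$ari), rep(1, 3))
  # drift 2 of 6: |intersection| = 4, |union| = 8
  expect_equal(ev$lineageJaccard$jaccard, rep(0.5, 4))
  expect_equal(ev$lineageJaccard$from, rep(c("S1", "S2"), each = 2))
})

test_that("degraded and empty recoveries score accordingly", {
  spec <- smallSpec()
  st <- generateSyntheticStudy(spec)
  # merging both planted modules into one cannot reach ARI 1
  merged <- lapply(seq_len(spec@nStages), function(s)
    makeModuleSet(paste0("S", s),
                  list(sort(unlist(st$lineageMembers[[s]], use.names = FALSE)))))
  ev <- evaluateRecovery(merged, st$truth)
  expect_true(all(ev$ari < 1))
  # an empty recovery has no assigned vertices to score
  empty <- lapply(1:3, function(s) makeModuleSet(paste0("S", s), list()))
  ev0 <- evaluateRecovery(empty, st$truth)
  expect_true(all(is.na(ev0$ari)))
  expect_equal(ev0$lineageJaccard$jaccard, rep(0, 4))
})

test_that("the all-vertex scope penalises unassigned planted members", {
  spec <- smallSpec()
  st <- generateSyntheticStudy(spec)
  # drop half of module L1 from the recovery in stage 1
  mem <- st$lineageMembers[[1]]
  partial <- list(makeModuleSet("S1", list(mem$L1[1:3], mem$L2)))
  a_assigned <- evaluateRecovery(partial, st$truth, scope = "assigned")$ari
  a_all <- evaluateRecovery(partial, st$truth, scope = "all")$ari
  expect_equal(unname(a_assigned[1]), 1)  # what was assigned is pure
  expect_lt(a_all[1], 1)                  # the omission now counts
})
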