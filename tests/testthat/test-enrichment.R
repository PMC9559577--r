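mkGmt <- function(lines) {
  p <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("GMT parsing handles descriptions, empty sets and duplicates", {
  p <- mkGmt(c("TA\tdesc A\tg1\tg2\tg3",
               "TB\t\tg3\tg4",
               "TEMPTY\tnothing"))
  expect_warning(col <- readGmt(p), "empty gene set")
  expect_setequal(names(geneSets(col)), c("TA", "TB"))
  expect_equal(geneSets(col)$TA, c("g1", "g2", "g3"))
  expect_equal(col@descriptions[["TA"]], "desc A")
  # default universe is the union of all members
  expect_setequal(setUniverse(col), paste0("g", 1:4))
  pd <- mkGmt(c("TA\td\tg1", "TA\td\tg2"))
  expect_error(readGmt(pd), "duplicate term")
})

test_that("an explicit universe restricts sets and drops emptied ones", {
  p <- mkGmt(c("TA\td\tg1\tg2\tg9", "TB\td\tg8"))
  expect_warning(col <- readGmt(p, universe = paste0("g", 1:5)),
                 "empty after universe restriction")
  expect_equal(names(geneSets(col)), "TA")
  expect_setequal(geneSets(col)$TA, c("g1", "g2"))
  expect_setequal(setUniverse(col), paste0("g", 1:5))
})

test_that("GMT collections survive a write/read round-trip", {
  p <- mkGmt(c("TA\tdesc A\tg1\tg2\tg3", "TB\tdesc B\tg3\tg4"))
  col <- readGmt(p)
  p2 <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(col, p2)
  col2 <- readGmt(p2)
  expect_equal(geneSets(col2), geneSets(col))
  expect_equal(col2@descriptions, col@descriptions)
  expect_equal(setUniverse(col2), setUniverse(col))
})

test_that("the hypergeometric upper tail matches closed-form and exhaustive enumeration", {
  # C(5,4)*C(15,1)/C(20,5) + C(5,5)/C(20,5), overlap >= 4 of term size 5
  uni <- sprintf("g%02d", 1:20)
  term <- uni[1:5]
  mod <- c(uni[c(1:4, 6)])
  expect_equal(hypergeomTest(mod, term, uni),
               (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5))
  # exhaustive-enumeration oracle on random small cases
  set.seed(17)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    K <- sample(1:(n - 1), 1)
    m <- sample(1:n, 1)
    u <- sprintf("u%02d", 1:n)
    tset <- u[1:K]
    mset <- sample(u, m)
    k <- length(intersect(mset, tset))
    expect_equal(hypergeomTest(mset, tset, u), enumHyperTail(k, K, n, m))
  }
  # overlap 0 is certain at the upper tail
  expect_equal(hypergeomTest("x", c("a", "b"), c("a", "b", "x", "y")), 1)
  expect_error(hypergeomTest("a", c("a", "z9"), c("a", "b")), "contained")
  expect_error(hypergeomTest("a", "a", character()), "empty universe")
})

test_that("BH adjustment reproduces the step-up definition on random inputs", {
  set.seed(8)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:12, 1))
    expect_equal(bhAdjust(p), bruteForceBH(p))
  }
  expect_equal(bhAdjust(numeric()), numeric())
  expect_error(bhAdjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bhAdjust(1.2), "\\(0, 1\\]")
  expect_error(bhAdjust(NA_real_), "\\(0, 1\\]")
})

test_that("module enrichment screens at q <= qMax with stage-scoped adjustment", {
  uni <- sprintf("g%02d", 1:20)
  p <- mkGmt(c(paste(c("TA", "d", uni[1:5]), collapse = "\t"),
               paste(c("TB", "d", uni[6:15]), collapse = "\t"),
               paste(c("TC", "d", uni[16:20]), collapse = "\t")))
  col <- readGmt(p)
  ms <- makeModuleSet("S1", list(c(uni[1:4], uni[6])))
  res <- enrichModules(ms, col, qMax = 0.05)
  expect_equal(res$term, "TA")  # the g06/TB overlap is never significant
  expect_equal(res$overlap, 4L)
  expect_equal(res$overlap_members[[1]], sort(uni[1:4]))
  # the q value equals independent BH over exactly the tested pairs
  p_ta <- enumHyperTail(4, 5, 20, 5)
  p_tb <- enumHyperTail(1, 10, 20, 5)
  expect_equal(res$q, bruteForceBH(c(p_ta, p_tb))[1])
  # with the screen disabled both tested pairs are reported
  res_all <- enrichModules(ms, col, qMax = 1)
  expect_setequal(res_all$term, c("TA", "TB"))
  expect_true(all(diff(res_all$q) >= 0))  # sorted by q within stage
})

test_that("stage-scoped and global adjustment differ as the definition demands", {
  uni <- sprintf("g%02d", 1:20)
  p <- mkGmt(c(paste(c("TA", "d", uni[1:5]), collapse = "\t"),
               paste(c("TB", "d", uni[6:15]), collapse = "\t")))
  col <- readGmt(p)
  ms1 <- makeModuleSet("S1", list(c(uni[1:4], uni[6])))
  ms2 <- makeModuleSet("S2", list(uni[c(6:9, 1)]))
  r_st <- enrichModules(list(ms1, ms2), col, qMax = 1, scope = "stage")
  r_gl <- enrichModules(list(ms1, ms2), col, qMax = 1, scope = "global")
  for (st in c("S1", "S2")) {
    i <- r_st$stage == st
    expect_equal(r_st$q[i], bruteForceBH(r_st$p[i]))
  }
  expect_equal(r_gl$q[order(r_gl$stage, r_gl$term)],
               bruteForceBH(r_gl$p[order(r_gl$stage, r_gl$term)]))
})

test_that("only gene-kind members are tested unless kinds is relaxed", {
  uni <- c(sprintf("g%02d", 1:10), "mir1")
  p <- mkGmt(paste(c("TA", "d", uni[1:5], "mir1"), collapse = "\t"))
  col <- readGmt(p, universe = uni)
  mem <- c(uni[1:4], "mir1")
  kinds <- stats::setNames(c(rep("gene", 4), "miRNA"), mem)
  ms <- methods::new("ModuleSet", stage = "S1",
                     modules = list(M1 = mem), kinds = kinds, selected = mem)
  r_gene <- enrichModules(ms, col, qMax = 1)
  r_all <- enrichModules(ms, col, qMax = 1, kinds = NULL)
  expect_equal(r_gene$overlap, 4L)
  expect_equal(r_all$overlap, 5L)
  expect_lt(r_all$p, r_gene$p)
})

test_that("the bundled core-function collection has the documented overlap structure", {
  path <- system.file("extdata", "core_functions.gmt", package = "moduleEvo")
  col <- readGmt(path)
  expect_length(geneSets(col), 4L)
  expect_equal(jaccardCoefficient(geneSets(col)$CXCR_chemokine_receptor_binding,
                                  geneSets(col)$chemokine_activity), 4 / 17)
  expect_equal(jaccardCoefficient(geneSets(col)$peptidoglycan_binding,
                                  geneSets(col)$oligosaccharide_binding), 1 / 2)
  # a CXCL-ligand module hits the receptor-binding term most strongly
  ms <- makeModuleSet("S2", list(c("CXCL1", "CXCL2", "CXCL5", "CXCL8", "REG3G")))
  res <- enrichModules(ms, col, qMax = 1)
  best <- res$term[which.min(res$q)]
  expect_equal(best, "CXCR_chemokine_receptor_binding")
})

test_that("the functional network links passing terms by set Jaccard", {
  path <- system.file("extdata", "core_functions.gmt", package = "moduleEvo")
  col <- readGmt(path)
  ms1 <- makeModuleSet("S1", list(c("CXCL1", "CXCL2", "CXCL5", "CXCL8", "CCL2")))
  ms2 <- makeModuleSet("S2", list(c("REG3G", "REG3A", "ZG16", "ITLN1", "PF4")))
  res <- enrichModules(list(ms1, ms2), col, qMax = 0.05)
  fn <- buildFunctionalNetwork(res, col)
  g <- networkGraph(fn)
  expect_true(all(igraph::V(g)$name %in% names(geneSets(col))))
  expect_setequal(unique(res$term), igraph::V(g)$name)
  et <- edgeTable(fn)
  if (nrow(et)) {
    expect_true(all(et$weight > 0))
    expect_true(all(et$edge_class == "function"))
    for (i in seq_len(nrow(et)))
      expect_equal(et$weight[i],
                   jaccardCoefficient(geneSets(col)[[et$src[i]]],
                                      geneSets(col)[[et$dst[i]]]))
  }
  # min_q matches the reported minimum per term
  for (tm in igraph::V(g)$name)
    expect_equal(igraph::V(g)$min_q[match(tm, igraph::V(g)$name)],
                 min(res$q[res$term == tm]))
  expect_error(buildFunctionalNetwork(data.frame(term = "nope", stage = "S1",
                                                 q = 0.01), col),
               "not in collection")
})

test_that("module-wise testing outscores pooled designs on a concentrated signal", {
  uni <- sprintf("g%02d", 1:20)
  gp <- mkGmt(c(paste(c("TA", "d", uni[1:5]), collapse = "\t"),
                paste(c("TB", "d", uni[6:15]), collapse = "\t"),
                paste(c("TC", "d", uni[16:20]), collapse = "\t")))
  col <- readGmt(gp)
  # stage network: TA's genes form a clique module, the rest are background
  cl <- utils::combn(uni[1:5], 2)
  bg <- paste(uni[6:19], uni[7:20], sep = "-")
  net <- makeNet(c(paste(cl[1, ], cl[2, ], sep = "-"), bg), stage = "S1")
  ms <- makeModuleSet("S1", list(uni[1:5]))
  cmp <- compareDesigns(list(net), list(ms), col)
  expect_equal(rownames(cmp), c("TA", "TB", "TC"))
  expect_setequal(colnames(cmp),
                  c("Design1.S1", "Design2.S1", "modulewise.S1"))
  # all 20 network genes pooled give overlap = term size for every term ->
  # p = 1 -> Q' = 0; the concentrated module is decisively positive
  expect_equal(unname(cmp["TA", "Design1.S1"]), 0)
  expect_gt(cmp["TA", "modulewise.S1"], cmp["TA", "Design1.S1"])
  # Design2 pools exactly the one module, so it matches modulewise here
  expect_equal(cmp["TA", "Design2.S1"], cmp["TA", "modulewise.S1"])
  # terms never overlapping the module score 0 under module-wise testing
  expect_equal(unname(cmp["TC", "modulewise.S1"]), 0)
})
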