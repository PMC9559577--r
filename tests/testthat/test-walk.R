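test_that("step weights decay linearly from N at the start to 1 at the last step", {
  cfg <- walkConfig(walkLength = 5)
  expect_equal(stepWeight(0, cfg), 5)
  expect_equal(stepWeight(4, cfg), 1)
  expect_equal(stepWeight(2, cfg), 3)
  expect_error(stepWeight(5, cfg), "0..N-1")
  expect_error(stepWeight(-1, cfg), "0..N-1")
})

test_that("a single-edge graph forces the walk to alternate endpoints", {
  net <- makeNet("a-b")
  rec <- runWalk(net, "a", walkConfig(walkLength = 3), seed = 1)
  expect_equal(rec@vertices, c("a", "b", "a"))
  expect_false(rec@truncated)
})

test_that("an isolated start vertex truncates immediately", {
  net <- makeNet("a-b", types = c(a = "gene", b = "gene", z = "gene"))
  rec <- runWalk(net, "z", walkConfig(walkLength = 3), seed = 1)
  expect_equal(rec@vertices, "z")
  expect_true(rec@truncated)
  expect_error(runWalk(net, "missing", walkConfig()), "not in network")
})

test_that("triangle walks realise exactly the enumerable neighbor-choice outcomes", {
  net <- makeNet(c("a-b", "b-c", "c-a"))
  cfg <- walkConfig(walkLength = 4)
  # oracle: all 2^3 choice sequences; from any vertex the two neighbors
  nbrs <- list(a = c("b", "c"), b = c("a", "c"), c = c("a", "b"))
  oracle <- character()
  for (c1 in 1:2) for (c2 in 1:2) for (c3 in 1:2) {
    p <- "a"
    for (ch in c(c1, c2, c3)) p <- c(p, nbrs[[p[length(p)]]][ch])
    oracle <- c(oracle, paste(p, collapse = ""))
  }
  oracle <- unique(oracle)  # 8 distinct outcomes
  expect_length(oracle, 8L)
  seen <- unique(vapply(1:200, function(s)
    paste(runWalk(net, "a", cfg, seed = s)@vertices, collapse = ""), ""))
  expect_true(all(seen %in% oracle))
  expect_setequal(seen, oracle)
})

test_that("penalty coefficients are relative-degree powers with isolates at 1", {
  # regular graph: every coefficient 1 for any beta
  ring <- makeNet(c("a-b", "b-c", "c-d", "d-a"))
  for (beta in c(-1, 0, 1, 2))
    expect_equal(unname(penaltyCoefficient(ring, walkConfig(penaltyExponent = beta))),
                 rep(1, 4))
  # star K1,4: center degree 4, mean degree 1.6
  star <- makeNet(c("c-l1", "c-l2", "c-l3", "c-l4"))
  expect_equal(penaltyCoefficient(star, walkConfig(penaltyExponent = 1))[["c"]],
               2.5)
  expect_equal(penaltyCoefficient(star, walkConfig(penaltyExponent = 1))[["l1"]],
               1 / 1.6)
  expect_equal(unname(penaltyCoefficient(star, walkConfig(penaltyExponent = 0))),
               rep(1, 5))
  # isolates always get 1
  iso <- makeNet("a-b", types = c(a = "gene", b = "gene", z = "gene"))
  expect_equal(penaltyCoefficient(iso, walkConfig(penaltyExponent = 2))[["z"]], 1)
})

test_that("accumulated weights on a forced two-vertex walk match hand enumeration", {
  net <- makeNet("a-b")
  cfg <- walkConfig(walkLength = 3, walksPerVertex = 1, penaltyExponent = 0,
                    seed = 5)
  wt <- accumulateWeights(net, cfg)
  # from a: a(3) b(2) a(1); from b: b(3) a(2) b(1) -> 6 each
  expect_equal(unname(vertexWeights(wt)[c("a", "b")]), c(6, 6))
})

test_that("a network of isolates accumulates only the start weight N", {
  net <- makeNet(types = c(a = "gene", b = "miRNA", z = "lncRNA"))
  wt <- accumulateWeights(net, walkConfig(walkLength = 7, walksPerVertex = 3))
  expect_equal(unname(vertexWeights(wt)), rep(7, 3))
})

test_that("identical configuration reproduces identical weight tables", {
  net <- twoCliqueNet()
  cfg <- walkConfig(walkLength = 8, walksPerVertex = 5, seed = 42)
  expect_identical(vertexWeights(accumulateWeights(net, cfg)),
                   vertexWeights(accumulateWeights(net, cfg)))
})

test_that("weights are normalised by the replicate count", {
  # deterministic forced walk: doubling R must not change the table
  net <- makeNet("a-b")
  w1 <- vertexWeights(accumulateWeights(net, walkConfig(walkLength = 3,
                                                        walksPerVertex = 2)))
  w2 <- vertexWeights(accumulateWeights(net, walkConfig(walkLength = 3,
                                                        walksPerVertex = 8)))
  expect_equal(w1, w2)
})

test_that("disabled penalty reproduces an independent plain decayed-visit simulation", {
  net <- twoCliqueNet()
  cfg <- walkConfig(walkLength = 6, walksPerVertex = 4, penaltyExponent = 0,
                    seed = 9)
  wt <- vertexWeights(accumulateWeights(net, cfg))
  # independent accumulation: replay each walk's substream and tally
  g <- networkGraph(net)
  nms <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), function(x) nms[as.integer(x)])
  names(adj) <- nms
  w <- stats::setNames(numeric(length(nms)), nms)
  N <- 6
  for (v in nms) for (r in 1:4) {
    set.seed(moduleEvo:::.hashSeed(9L, "S1", v, r))
    cur <- v
    w[cur] <- w[cur] + N
    for (t in 1:(N - 1)) {
      nb <- adj[[cur]]
      if (!length(nb)) break
      cur <- nb[sample.int(length(nb), 1)]
      w[cur] <- w[cur] + (N - t)
    }
  }
  expect_equal(wt, w / 4)
})

test_that("non-truncated walks conserve the triangular raw contribution", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    g <- igraph::sample_gnp(n, 0.4)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    igraph::V(g)$kind <- "gene"
    igraph::E(g)$edge_kind <- "gene-gene"
    net <- methods::new("StageNetwork", graph = g, stage = "S1")
    N <- sample(3:9, 1)
    cfg <- walkConfig(walkLength = N)
    rec <- runWalk(net, sample(igraph::V(g)$name, 1), cfg,
                   seed = sample.int(1e6, 1))
    if (!rec@truncated)
      expect_equal(walkContribution(rec, cfg), N * (N + 1) / 2)
    else
      expect_lt(walkContribution(rec, cfg), N * (N + 1) / 2)
  }
})

test_that("Monte-Carlo weight variance shrinks as replicates grow", {
  net <- twoCliqueNet()
  Rs <- c(5, 10, 20, 40)
  mean_var <- vapply(Rs, function(R) {
    tabs <- vapply(1:6, function(b) {
      cfg <- walkConfig(walkLength = 6, walksPerVertex = R, seed = 1000L + b)
      vertexWeights(accumulateWeights(net, cfg))
    }, numeric(12))
    mean(apply(tabs, 1, stats::var))
  }, numeric(1))
  fit <- stats::lm(log(mean_var) ~ log(Rs))
  expect_lt(unname(stats::coef(fit)[2]), 0)
})

test_that("vertex selection uses a strict empirical-quantile threshold", {
  mkTab <- function(w) methods::new("VertexWeightTable", stage = "S1",
                                    weights = w, config = walkConfig())
  w <- c(a = 10, b = 1, c = 1, d = 1, e = 1)
  expect_equal(selectVertices(mkTab(w), walkConfig(vertexQuantile = 0.8)), "a")
  expect_equal(selectVertices(mkTab(c(a = 2, b = 2, c = 2)),
                              walkConfig(vertexQuantile = 0.5)), character())
  expect_setequal(selectVertices(mkTab(w), walkConfig(vertexQuantile = 0)),
                  "a")
  w2 <- c(a = 5, b = 4, c = 1)
  expect_setequal(selectVertices(mkTab(w2), walkConfig(vertexQuantile = 0)),
                  c("a", "b"))
})
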