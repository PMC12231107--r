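stringEdges <- function(p1, p2, exp_, comb) {
  data.frame(protein1 = p1, protein2 = p2, experimental = exp_,
             combined_score = comb, stringsAsFactors = FALSE)
}

test_that("interactome loading applies the confidence/evidence filter", {
  edges <- stringEdges(c("a", "b", "c", "d", "e"),
                       c("b", "c", "d", "e", "a"),
                       exp_ = c(500, 0, 700, 0, 300),
                       comb = c(950, 920, 880, 990, 910))
  it <- makeInteractome(edges, minCombined = 900, requireExperimental = TRUE)
  g <- interactionGraph(it)
  expect_equal(igraph::ecount(g), 2)  # a-b (950/500) and e-a (910/300)
  ## no filtering: all edges survive after de-dup
  it2 <- makeInteractome(edges, minCombined = 0, requireExperimental = FALSE)
  expect_equal(igraph::ecount(interactionGraph(it2)), 5)
  ## both directions of the same edge are stored once
  dup <- stringEdges(c("x", "y"), c("y", "x"), c(500, 500), c(950, 960))
  expect_equal(igraph::ecount(interactionGraph(makeInteractome(dup))), 1)
  expect_warning(makeInteractome(edges, minCombined = 1000), "empty")
})

test_that("edge files round-trip and malformed rows are located", {
  edges <- stringEdges(c("A", "B"), c("B", "C"), c(400, 500), c(920, 930))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  it <- readInteractome(path, verbose = FALSE)
  expect_equal(igraph::ecount(interactionGraph(it)), 2)
  writeLines(c("protein1\tprotein2\texperimental\tcombined_score",
               "A\tB\t400\t920", "B\tC\toops\t930"), path)
  expect_error(readInteractome(path, verbose = FALSE), "line.*3")
})

test_that("first-order network takes seeds plus direct neighbors", {
  edges <- stringEdges(c("a", "b"), c("b", "c"), c(500, 500), c(950, 950))
  it <- makeInteractome(edges)
  sn <- firstOrderNetwork(it, "a")
  expect_setequal(nodeTable(sn)$node, c("A", "B"))
  expect_equal(igraph::ecount(interactionGraph(sn)), 1)
  ## seeds = all nodes: subnetwork equals the graph
  snAll <- firstOrderNetwork(it, c("a", "b", "c"))
  expect_equal(igraph::ecount(interactionGraph(snAll)), 2)
  ## unmapped seeds reported, isolated mapped seed retained
  sn2 <- firstOrderNetwork(it, c("a", "zzz"))
  expect_equal(unmappedSeeds(sn2), "ZZZ")
  expect_error(firstOrderNetwork(it, "nope"), "no seed maps")
})

test_that("minimum network: adjacent seeds, forced connector, leaf pruning", {
  ## two adjacent seeds: exactly that edge, no connectors
  edges <- stringEdges(c("a", "b", "c"), c("b", "c", "d"),
                       rep(500, 3), rep(950, 3))
  it <- makeInteractome(edges)
  sn <- minimumNetwork(it, c("a", "b"))
  expect_setequal(nodeTable(sn)$node, c("A", "B"))
  ## star: hub is the single connector for 3 leaf seeds
  star <- stringEdges(rep("h", 4), c("l1", "l2", "l3", "l4"),
                      rep(500, 4), rep(950, 4))
  snStar <- minimumNetwork(makeInteractome(star), c("l1", "l2", "l3"))
  expect_setequal(nodeTable(snStar)$node, c("H", "L1", "L2", "L3"))
  ## seeds in different components: one tree per component, none dropped
  two <- stringEdges(c("a", "c"), c("b", "d"), rep(500, 2), rep(950, 2))
  snTwo <- minimumNetwork(makeInteractome(two), c("a", "b", "c"))
  expect_setequal(nodeTable(snTwo)$node, c("A", "B", "C"))
})

test_that("minimum network is within 2x of the exhaustive Steiner optimum", {
  worst <- 0
  for (i in 1:30) {
    g <- randomTestGraph(sample(6:10, 1), 0.35, seed = 100 + i)
    if (igraph::ecount(g) == 0) next
    nm <- igraph::V(g)$name[igraph::degree(g) > 0]
    if (length(nm) < 2) next
    set.seed(i)
    seeds <- sample(nm, min(length(nm), sample(2:4, 1)))
    comp <- igraph::components(g)$membership
    names(comp) <- nm
    it <- makeInteractome(stringEdges(
      igraph::as_edgelist(g)[, 1], igraph::as_edgelist(g)[, 2],
      500, 950))
    sn <- minimumNetwork(it, seeds)
    got <- setdiff(nodeTable(sn)$node, toupper(seeds))
    ## oracle per seed component (the heuristic also works per component)
    opt <- 0
    for (cid in unique(comp[seeds])) {
      cs <- seeds[comp[seeds] == cid]
      if (length(cs) >= 2) opt <- opt + bruteSteinerConnectors(g, cs)
    }
    expect_lte(length(got), 2 * opt)
    worst <- max(worst, if (opt > 0) length(got) / opt else 1)
  }
  expect_lte(worst, 2)
})

test_that("minimum network is exactly optimal on trees", {
  for (i in 1:10) {
    set.seed(200 + i)
    g <- igraph::sample_tree(10)
    igraph::V(g)$name <- sprintf("V%02d", 1:10)
    seeds <- sample(igraph::V(g)$name, 3)
    el <- igraph::as_edgelist(g)
    it <- makeInteractome(stringEdges(el[, 1], el[, 2], 500, 950))
    sn <- minimumNetwork(it, seeds)
    got <- length(setdiff(nodeTable(sn)$node, toupper(seeds)))
    expect_equal(got, bruteSteinerConnectors(g, seeds))
  }
})

test_that("minimum network nodes stay within the first-order closure", {
  for (i in 1:10) {
    g <- randomTestGraph(12, 0.3, seed = 300 + i)
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) next
    it <- makeInteractome(stringEdges(el[, 1], el[, 2], 500, 950))
    set.seed(i)
    nm <- igraph::V(g)$name[igraph::degree(g) > 0]
    if (length(nm) < 3) next
    seeds <- sample(nm, 3)
    mini <- nodeTable(minimumNetwork(it, seeds))$node
    fo <- nodeTable(firstOrderNetwork(it, seeds))$node
    ## first-order closure grown once more covers any shortest connector set
    fo2 <- nodeTable(firstOrderNetwork(it, fo))$node
    expect_true(all(mini %in% fo2))
    reachableSeeds <- toupper(seeds)
    expect_true(all(reachableSeeds %in% mini))
  }
})

test_that("betweenness matches closed forms and the brute-force oracle", {
  path3 <- igraph::make_graph(~ a - b - c)
  cb <- nodeCentralities(path3)
  expect_equal(cb$betweenness[cb$node == "b"], 1)
  expect_equal(sort(cb$betweenness), c(0, 0, 1))
  star5 <- igraph::make_star(5, mode = "undirected")
  igraph::V(star5)$name <- c("hub", paste0("l", 1:4))
  cs <- nodeCentralities(star5)
  expect_equal(cs$betweenness[cs$node == "hub"], choose(4, 2))
  expect_true(all(cs$betweenness[cs$node != "hub"] == 0))
  for (i in 1:40) {
    g <- randomTestGraph(sample(4:8, 1), 0.4, seed = 400 + i)
    got <- nodeCentralities(g)
    want <- bruteBetweenness(g)
    expect_equal(stats::setNames(got$betweenness, got$node)[names(want)],
                 want, tolerance = 1e-9)
    ## total betweenness equals the oracle's total intermediate incidence
    expect_equal(sum(got$betweenness), sum(want), tolerance = 1e-9)
  }
})

test_that("map equation: single module is the node-rate entropy", {
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- letters[1:5]
  deg <- rep(4, 5) / 20
  expect_equal(mapEquation(g, rep(1, 5)), -sum(deg * log2(deg)))
})

test_that("community detection splits bridged cliques at the bridge", {
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  g <- igraph::add_edges(g, c(1, 7))
  igraph::V(g)$name <- sprintf("N%02d", 1:12)
  memb <- detectCommunities(g, seed = 1)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:6])), 1)
  expect_equal(length(unique(memb[7:12])), 1)
  ## exhaustive bipartition oracle agrees
  oracle <- bruteBestBipartition(g)
  expect_equal(nmi(memb, oracle), 1)
  expect_equal(mapEquation(g, memb), mapEquation(g, oracle), tolerance = 1e-9)
  ## complete graph: a single community
  k8 <- igraph::make_full_graph(8)
  igraph::V(k8)$name <- letters[1:8]
  expect_equal(length(unique(detectCommunities(k8, seed = 1))), 1)
})

test_that("map-equation descent is monotone and seed-deterministic", {
  sim <- simulateInteractome(80, "planted_partition", nBlocks = 4,
                             pIn = 0.35, pOut = 0.02, fracHighConf = 1,
                             fracExperimental = 1, seed = 9)
  it <- makeInteractome(sim$edges, minCombined = 0,
                        requireExperimental = FALSE)
  m1 <- detectCommunities(it, seed = 5)
  m2 <- detectCommunities(it, seed = 5)
  expect_identical(m1, m2)
  cl <- attr(m1, "codelengths")
  expect_true(all(diff(cl) <= 1e-12))
  ## reported codelength matches an independent evaluation of the partition
  expect_equal(cl[length(cl)], mapEquation(it, m1), tolerance = 1e-9)
  ## edgeless graph: singleton partition with a warning
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  expect_warning(m0 <- detectCommunities(g0), "edgeless")
  expect_equal(as.integer(m0), 1:3)
})

test_that("planted partition is recovered with high NMI", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulateInteractome(100, "planted_partition", nBlocks = 4,
                               pIn = 0.3, pOut = 0.02, fracHighConf = 1,
                               fracExperimental = 1, seed = 500 + s)
    it <- makeInteractome(sim$edges, minCombined = 0,
                          requireExperimental = FALSE)
    memb <- detectCommunities(it, seed = s)
    truth <- unlist(sim$truth$blocks)[names(memb)]
    if (nmi(memb, truth) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("community significance: whole graph p = 1, planted clique small p", {
  g <- randomTestGraph(40, 0.1, seed = 77)
  memb <- stats::setNames(rep(1L, 40), igraph::V(g)$name)
  sig <- communitySignificance(g, memb, nNull = 19, seed = 1)
  expect_equal(sig$p, 1)
  expect_error(communitySignificance(g, memb, nNull = 10), "19")
  ## planted 8-clique in a sparse background
  set.seed(8)
  bg <- igraph::sample_gnp(60, 0.04)
  igraph::V(bg)$name <- sprintf("V%02d", 1:60)
  cl <- utils::combn(1:8, 2)
  bg2 <- igraph::add_edges(bg, as.vector(cl))
  bg2 <- igraph::simplify(bg2)
  memb2 <- stats::setNames(c(rep(1L, 8), 2L + seq_len(52)),
                           igraph::V(bg2)$name)
  sig2 <- communitySignificance(bg2, memb2, nNull = 199, seed = 2)
  expect_lte(sig2$p[sig2$community == 1], 0.01)
})

test_that("subnetwork annotation fills the node table coherently", {
  sim <- simulateInteractome(60, "planted_partition", nBlocks = 3,
                             pIn = 0.4, pOut = 0.03, fracHighConf = 1,
                             fracExperimental = 1, seed = 13)
  it <- makeInteractome(sim$edges, minCombined = 0,
                        requireExperimental = FALSE)
  seeds <- sim$truth$nodes[c(1:4, 21:24)]
  sn <- annotateSubnetwork(firstOrderNetwork(it, seeds), seed = 1, nNull = 19)
  nt <- nodeTable(sn)
  expect_true(all(c("degree", "betweenness", "community", "community_p")
                  %in% names(nt)))
  expect_true(all(nt$betweenness >= 0))
  expect_true(all(nt$community >= 1))
  expect_true(all(seedGenes(sn) %in% nt$node[nt$is_seed]))
})
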