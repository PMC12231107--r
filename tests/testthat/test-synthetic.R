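test_that("noise-free growth screens equal the logistic closed form", {
  sim <- simulateGrowthScreen(nStrains = 8, nSensitive = 0, nResistant = 0,
                              noiseSd = 0, replicates = 2, times = 0:10,
                              seed = 3)
  expected <- logisticOD(0:10)
  for (s in unique(sim$records$strain)) {
    rs <- sim$records[sim$records$strain == s, ]
    for (cond in c("vehicle", "treated"))
      for (rp in 1:2)
        expect_equal(rs$od600[rs$condition == cond & rs$replicate == rp],
                     expected, tolerance = 1e-12)
  }
})

test_that("planted strains are exactly the ones below control at endpoint", {
  sim <- simulateGrowthScreen(nStrains = 50, nSensitive = 5, nResistant = 0,
                              sensitiveMultiplier = 0.5, noiseSd = 0,
                              seed = 7)
  finals <- sim$records[sim$records$time_h == max(sim$records$time_h) &
                        sim$records$condition == "treated" &
                        sim$records$replicate == 1, ]
  ctrl <- max(finals$od600)
  below <- finals$strain[finals$od600 < ctrl - 1e-9]
  expect_setequal(below, sim$truth$planted_sensitive)
})

test_that("generators are deterministic and substream-stable", {
  a <- simulateGrowthScreen(seed = 7)
  b <- simulateGrowthScreen(seed = 7)
  expect_identical(a$records, b$records)
  ## adding strains must not reshuffle existing strains' draws
  small <- simulateGrowthScreen(nStrains = 20, nSensitive = 2, nResistant = 2,
                                seed = 7)
  big <- simulateGrowthScreen(nStrains = 30, nSensitive = 2, nResistant = 2,
                              seed = 7)
  expect_identical(small$records,
                   big$records[big$records$strain %in% small$truth$strains, ])
  m1 <- simulateMicroscopy(nStrains = 5, nCells = 30, seed = 2)
  m2 <- simulateMicroscopy(nStrains = 5, nCells = 30, seed = 2)
  expect_identical(m1$cells, m2$cells)
})

test_that("erdos-renyi generator matches its binomial edge-count law", {
  e0 <- simulateInteractome(30, "erdos_renyi", p = 0, seed = 1)
  expect_equal(nrow(e0$edges), 0)
  counts <- vapply(1:40, function(s)
    nrow(simulateInteractome(40, "erdos_renyi", p = 0.1, seed = s)$edges),
    numeric(1))
  nPairs <- choose(40, 2)
  expect_true(length(unique(counts)) > 1)  # different seeds, different graphs
  se <- sqrt(nPairs * 0.1 * 0.9 / 40)
  expect_lt(abs(mean(counts) - nPairs * 0.1), 3 * se)
})

test_that("planted partition truth matches generation and scores are in range", {
  sim <- simulateInteractome(100, "planted_partition", nBlocks = 4,
                             pIn = 0.3, pOut = 0.02, seed = 1)
  blocks <- unlist(sim$truth$blocks)
  expect_equal(as.vector(table(blocks)), rep(25, 4))
  within <- blocks[sim$edges$protein1] == blocks[sim$edges$protein2]
  expect_gt(mean(within), 0.5)   # p_in >> p_out at these sizes
  expect_true(all(sim$edges$combined_score >= 150 &
                  sim$edges$combined_score <= 1000))
  expect_true(all(sim$edges$experimental >= 0 &
                  sim$edges$experimental <= 1000))
})

test_that("gene-set generator plants the stated overlap and round-trips GMT", {
  universe <- sprintf("G%04d", 1:500)
  query <- universe[1:40]
  gs <- simulateGeneSets(universe, query, nSets = 20, setSize = 40,
                         nPlanted = 2, plantedFraction = 1.0, seed = 5)
  expect_setequal(gs$sets[["SET001"]], query)   # fraction 1, size = |query|
  path <- tempfile(fileext = ".gmt")
  writeGMT(gs$sets, path)
  expect_identical(readGMT(path), gs$sets)
  expect_error(simulateGeneSets(universe, query, setSize = 501),
               "exceeds universe")
})

test_that("microscopy generator plants abundance shifts in its truth file", {
  shifts <- c(S0002 = 50, S0005 = 50, S0009 = 50)
  sim <- simulateMicroscopy(nStrains = 30, nCells = 50,
                            abundanceShifts = shifts, seed = 4)
  expect_setequal(names(sim$truth$abundance_shifts), names(shifts))
  expect_error(simulateMicroscopy(abundanceShifts = c(S0001 = -100)),
               "-100")
  expect_error(simulateMicroscopy(nCells = 5), "at least 10")
})

test_that("unplanted shift stays within the flagging threshold at n = 200", {
  ## with noise sd 0.1 and n = 200 cells, the s.e. of a log-median change is
  ## far below the 20% cutoff; no strain should be flagged
  sim <- simulateMicroscopy(nStrains = 10, nCells = 200, noiseSd = 0.1,
                            seed = 11)
  res <- scoreMicroscopy(sim$cells)
  expect_true(all(abs(res$pct_change) < 20))
  expect_false(any(res$flagged))
})

test_that("growth-model and strain-list preconditions are enforced", {
  expect_error(simulateGrowthScreen(nStrains = 0), "non-empty")
  expect_error(simulateGrowthScreen(r = -1), "positive")
  expect_error(simulateGrowthScreen(times = c(3, 2, 1)), "increasing")
  expect_error(simulateInteractome(1), "two nodes")
  expect_error(simulateInteractome(10, "planted_partition", pIn = 0.1,
                                   pOut = 0.5), "p_in|pOut|planted")
})
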