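test_that("plate normalization: uniform plates, gradients, idempotence", {
  uni <- matrix(100, 8, 12)
  expect_equal(normalizePlate(uni), matrix(1, 8, 12))
  ## doubling one interior row leaves all row medians equal after polishing
  gr <- matrix(100, 8, 12)
  gr[4, ] <- 200
  normed <- normalizePlate(gr)
  rowMeds <- apply(normed[2:7, 2:11], 1, median)
  expect_lt(max(abs(rowMeds - rowMeds[1])), 1e-9)
  ## idempotence
  set.seed(9)
  plate <- simulatePlateGrid(16, 24, rowGradient = c(0.7, 1.3),
                             colGradient = c(0.9, 1.1), seed = 2)$sizes
  once <- normalizePlate(plate)
  twice <- normalizePlate(once)
  expect_lt(max(abs(once - twice)), 1e-9)
  expect_error(normalizePlate(matrix(NA_real_, 4, 4)), "all-missing")
})

test_that("planted small colonies are the bottom-k after normalization", {
  planted <- cbind(c(5, 9, 12), c(7, 15, 20))
  sim <- simulatePlateGrid(16, 24, noiseSd = 0.03,
                           rowGradient = c(0.6, 1.4),
                           colGradient = c(0.8, 1.2),
                           planted = planted, plantedMultiplier = 0.5,
                           seed = 3)
  normed <- normalizePlate(sim$sizes)
  k <- nrow(planted)
  idx <- order(normed)[seq_len(k)]
  want <- sort((planted[, 2] - 1) * 16 + planted[, 1])
  expect_equal(sort(idx), want)
})

test_that("epistasis score: neutrality, reference forcing, zero double", {
  ## multiplicative neutrality: gDouble/gQuery == gArray/gWt
  expect_equal(epistasisScore(0.36, 0.6, 0.48, 0.8), 100)
  expect_equal(epistasisScore(0, 0.6, 0.48, 0.8), 0)
  expect_error(epistasisScore(0.3, 0, 0.5, 1), "> 0")
  ## the reference double is forced to exactly 100
  rawRef <- epistasisScore(0.5, 0.6, 0.7, 0.8)
  expect_equal(epistasisScore(0.5, 0.6, 0.7, 0.8, referenceScore = rawRef), 100)
  ## and other strains rescale by the same factor
  raw <- epistasisScore(0.3, 0.6, 0.7, 0.8)
  expect_equal(epistasisScore(0.3, 0.6, 0.7, 0.8, referenceScore = rawRef),
               raw * 100 / rawRef)
})

test_that("simulated epistasis screen recovers the planted score", {
  planted <- 50; noise <- 0.05; nrep <- 3
  set.seed(21)
  scores <- replicate(10, {
    reps <- vapply(seq_len(nrep), function(r) {
      gW <- 1 * exp(rnorm(1, 0, noise))
      gQ <- 0.7 * exp(rnorm(1, 0, noise))
      gA <- 0.8 * exp(rnorm(1, 0, noise))
      gD <- (planted / 100) * 0.7 * 0.8 / 1 * exp(rnorm(1, 0, noise))
      epistasisScore(gD, gQ, gA, gW)
    }, numeric(1))
    mean(reps)
  })
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - planted), 3 * max(se, 2))
})

test_that("chemgen scoring: identity, missing strains, planted effect", {
  sim <- simulateGrowthScreen(nStrains = 6, nSensitive = 0, nResistant = 0,
                              noiseSd = 0, seed = 1)
  cg <- chemgenScore(sim$records)
  expect_equal(cg$summary$mean_growth, rep(100, 6), tolerance = 1e-9)
  ## strain missing in vehicle is reported, not scored
  rec <- sim$records
  rec <- rec[!(rec$strain == "G0003" & rec$condition == "vehicle"), ]
  cg2 <- chemgenScore(rec)
  expect_false("G0003" %in% cg2$summary$strain)
  expect_true("G0003" %in% names(cg2$unscored))
  ## planted od-scale multiplier equals the score exactly when noise-free
  sim3 <- simulateGrowthScreen(nStrains = 10, nSensitive = 2, nResistant = 0,
                               sensitiveMultiplier = 0.5, noiseSd = 0,
                               effect = "od", seed = 2)
  cg3 <- chemgenScore(sim3$records)
  expect_equal(cg3$summary$mean_growth[cg3$summary$strain == "G0001"], 50,
               tolerance = 1e-9)
})

test_that("agar scoring averages normalized colony ratios per strain", {
  strains <- matrix(rep(c("A", "B"), each = 4), 2, 4)
  veh <- matrix(1, 2, 4)
  trt <- matrix(rep(c(0.5, 1.2), each = 4), 2, 4)  # A in cols 1-2, B in 3-4
  res <- chemgenScoreAgar(trt, veh, strains)
  expect_equal(res$mean_growth[res$strain == "A"], 50)
  expect_equal(res$mean_growth[res$strain == "B"], 120)
})

test_that("hit calling: k-of-n rule, zero variance, permutation invariance", {
  ## a strain crossing the threshold in only 1 of 3 screens is not called
  df <- data.frame(strain = "s1",
                   screen = rep(1:3, each = 3),
                   replicate = rep(1:3, 3),
                   percent_growth = c(60, 61, 59, 98, 102, 100, 99, 101, 100))
  calls <- callHits(df, stage = "screen", lower = 75, upper = 130,
                    minScreens = 2)
  expect_equal(calls$call, "none")
  ## zero-variance scores at exactly 100: no calls (t-test undefined -> NA p)
  df2 <- data.frame(strain = "s2", screen = rep(1:3, each = 3),
                    replicate = rep(1:3, 3), percent_growth = rep(100, 9))
  expect_equal(callHits(df2, stage = "screen")$call, "none")
  ## permutation invariance to strain order
  sim <- simulateGrowthScreen(seed = 11, effect = "od")
  sc <- chemgenScore(sim$records)$scores
  sc$screen <- 1L
  a <- callHits(sc, stage = "validation")
  b <- callHits(sc[rev(seq_len(nrow(sc))), ], stage = "validation")
  expect_identical(a, b)
})

test_that("planted screen is recovered with perfect precision and recall", {
  screens <- lapply(1:3, function(i)
    simulateGrowthScreen(nStrains = 50, nSensitive = 5, nResistant = 5,
                         sensitiveMultiplier = 0.5, resistantMultiplier = 1.5,
                         noiseSd = 0.05, replicates = 3, effect = "od",
                         seed = substreamSeed(11, "screen", i)))
  allScores <- do.call(rbind, lapply(seq_along(screens), function(i)
    cbind(screen = i, chemgenScore(screens[[i]]$records)$scores)))
  calls <- callHits(allScores, stage = "screen", lower = 75, upper = 130,
                    alpha = 0.05, minScreens = 2)
  truth <- screens[[1]]$truth
  sens <- calls$strain[calls$call == "sensitive"]
  res <- calls$strain[calls$call == "resistant"]
  expect_setequal(sens, truth$planted_sensitive)
  expect_setequal(res, truth$planted_resistant)
})

test_that("inviable strains are reported separately, thresholds validated", {
  df <- data.frame(strain = rep(c("ok", "dead"), each = 3),
                   replicate = rep(1:3, 2),
                   percent_growth = c(50, 52, 48, 30, 35, 40))
  veh <- c(ok = 1.0, dead = 0.02)
  calls <- callHits(df, stage = "validation", vehicleLevel = veh,
                    viabilityFloor = 0.1)
  expect_equal(calls$call[calls$strain == "dead"], "inviable")
  expect_equal(calls$call[calls$strain == "ok"], "sensitive")
  expect_error(callHits(df, stage = "validation", lower = 150, upper = 100),
               "lower")
})
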