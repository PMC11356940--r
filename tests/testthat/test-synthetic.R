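test_that("seeded fingerprint families hit their degenerate corners", {
  fam <- generateSeededFingerprints(64, 16, a = 1, b = 0, nVariants = 5,
                                    seed = 2)
  expect_equal(nFeatures(fam$seed), 16)
  for (v in fam$variants) {
    expect_identical(features(v), features(fam$seed))
    expect_equal(tanimoto(fam$seed, v), 1)
  }
  empty <- generateSeededFingerprints(64, 16, a = 0, b = 0, nVariants = 3,
                                      seed = 2)
  for (v in empty$variants) {
    expect_equal(nFeatures(v), 0)
    # empty-vs-nonempty is defined (0); the all-empty case raises
    expect_equal(tanimoto(empty$seed, v), 0)
  }
  expect_error(generateSeededFingerprints(8, 9, 0.5, 0.1, 2), "1 <= k <= L")
})

test_that("generators are pure functions of their seed", {
  f1 <- generateSeededFingerprints(128, 24, 0.5, 0.05, 10, seed = 33)
  f2 <- generateSeededFingerprints(128, 24, 0.5, 0.05, 10, seed = 33)
  expect_equal(f1, f2)
  s1 <- generateSmilesLike("c1ccccc1CCO", 3, 10, seed = 9)
  s2 <- generateSmilesLike("c1ccccc1CCO", 3, 10, seed = 9)
  expect_identical(s1, s2)
  spec <- SyntheticSpec(nTargets = 2L, nActives = 6L, nDecoys = 40L, seed = 8L)
  expect_equal(generateScoreBenchmark(spec), generateScoreBenchmark(spec))
  expect_equal(simulateBenchmark(spec)$molecules,
               simulateBenchmark(spec)$molecules)
})

test_that("family mean Tanimoto matches the closed-form expectation", {
  L <- 128; k <- 32; a <- 0.8; b <- 0.02
  fam <- generateSeededFingerprints(L, k, a, b, nVariants = 4000, seed = 13)
  mc <- mean(vapply(fam$variants, function(v) tanimoto(fam$seed, v),
                    numeric(1)))
  expect_equal(mc, expectedSeedTanimoto(L, k, a, b), tolerance = 0.02)
})

test_that("null score sets carry no label signal", {
  spec <- SyntheticSpec(nTargets = 40L, nActives = 40L, nDecoys = 400L,
                        activeShape = c(2, 2), decoyShape = c(2, 2),
                        seed = 19L)
  sets <- generateScoreBenchmark(spec)
  drfs <- vapply(sets, function(s) drfValue(drf(s, 0.1)), numeric(1))
  aucs <- vapply(sets, rocAuc, numeric(1))
  expect_equal(mean(drfs), 1, tolerance = 0.12)
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("fully shifted actives give DRF 0 and AUC 1", {
  spec <- SyntheticSpec(nTargets = 1L, nActives = 30L, nDecoys = 300L,
                        activeShape = c(60, 1), decoyShape = c(1, 60),
                        seed = 23L)
  set <- generateScoreBenchmark(spec)[[1]]
  expect_equal(drfValue(drf(set, 0.1)), 0)
  expect_equal(rocAuc(set), 1)
})

test_that("planted decoy contamination is recovered as DRF by construction", {
  f <- 0.4
  drfs <- vapply(1:40, function(s) {
    spec <- SyntheticSpec(nTargets = 1L, nActives = 50L, nDecoys = 1000L,
                          plantedFraction = f, seed = 100L + s)
    drfValue(drf(generateScoreBenchmark(spec)[[1]], 0.1))
  }, numeric(1))
  expect_lt(abs(mean(drfs) - f), 0.05)
})

test_that("SMILES-like strings degrade with edit count", {
  seedStr <- "c1ccc(CC(=O)NCCO)cc1"
  copies <- generateSmilesLike(seedStr, 0, 5, seed = 3)
  expect_true(all(copies == seedStr))
  expect_true(all(vapply(copies, function(s) lingoSim(seedStr, s), numeric(1)) == 1))
  meanSim <- vapply(c(0, 2, 8, 40), function(ne) {
    out <- generateSmilesLike(seedStr, ne, 30, seed = 5)
    mean(vapply(out, function(s) lingoSim(seedStr, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanSim) < 0))
  expect_lt(meanSim[4], 0.2)  # near-random strings barely overlap
})

test_that("planted potency correlation is recovered in the mean", {
  set.seed(29)
  taus <- vapply(1:60, function(i) {
    sims <- runif(120)
    ac <- generatePotency(sims, tauTarget = 0.5, seed = 2000L + i)
    kendallTau(sims, ac)
  }, numeric(1))
  expect_equal(mean(taus), 0.5, tolerance = 0.05)
  # tau_target 1: strictly monotone coupling
  sims <- runif(20)
  expect_equal(kendallTau(sims, generatePotency(sims, 1, seed = 4)), 1)
  expect_error(generatePotency(runif(10), 1.2), "unreachable tau")
  expect_error(generatePotency(runif(2), 0.5), "at least 3")
})

test_that("simulated benchmarks round-trip through the pipeline readers", {
  spec <- SyntheticSpec(nTargets = 2L, nActives = 6L, nDecoys = 50L,
                        seed = 37L)
  dir <- withr::local_tempdir()
  paths <- simulateBenchmarkFiles(spec, dir)
  sim <- simulateBenchmark(spec)
  mols <- readSmiles(paths[["smiles"]])
  expect_equal(mols, sim$molecules)
  bench <- readBenchmark(paths[["benchmark"]])
  expect_equal(lapply(bench, activeIds), lapply(sim$benchmarks, activeIds))
  expect_equal(lapply(bench, ac50), lapply(sim$benchmarks, ac50))
  fps <- readFingerprints(paths[["fingerprints"]])
  expect_equal(names(fps), names(sim$fingerprints))
  expect_equal(lapply(fps, features), lapply(sim$fingerprints, features))
  # benchmark structure: per-target disjoint actives/decoys, all with fps
  for (tb in bench) {
    expect_length(intersect(activeIds(tb), decoyIds(tb)), 0)
    expect_true(all(c(activeIds(tb), decoyIds(tb)) %in% names(fps)))
  }
})

test_that("simulated potencies make the planted query the most potent", {
  spec <- SyntheticSpec(nTargets = 1L, nActives = 10L, nDecoys = 30L,
                        tauTarget = -0.6, seed = 41L)
  sim <- simulateBenchmark(spec)
  tb <- sim$benchmarks[[1]]
  ac <- ac50(tb)
  expect_equal(names(which.min(ac)), activeIds(tb)[1])
  tab <- potencySimilarityTable(tb, sim$fingerprints)
  expect_equal(attr(tab, "queryId"), activeIds(tb)[1])
})
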