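test_that("DRF reproduces hand-computed worked cases", {
  # perfect separation: all actives above all decoys
  set <- ScoredSet(c(rep(1, 10), rep(0.5, 10)),
                   rep(c("active", "decoy"), each = 10))
  r <- drf(set, 0.1)
  expect_equal(r@x, 1L)
  expect_equal(r@sp, 1)
  expect_equal(r@dp, 0L)
  expect_equal(drfValue(r), 0)
  # 10 actives at 0.9, 0.8, ..., 0.0; 100 decoys, exactly 3 above 0.9
  act <- seq(0.9, 0, by = -0.1)
  dec <- c(0.95, 0.93, 0.91, runif(97, 0, 0.5))
  set2 <- ScoredSet(c(act, dec), rep(c("active", "decoy"), c(10, 100)))
  r2 <- drf(set2, 0.1)
  expect_equal(r2@x, 1L)
  expect_equal(r2@sp, 0.9)
  expect_equal(r2@dp, 3L)
  expect_equal(drfValue(r2), 0.3)
})

test_that("DRF tie handling is strict on decoys and positional on actives", {
  # decoys scoring exactly sp do not count toward dp
  set <- ScoredSet(c(0.9, 0.9, 0.9, 0.2, 0.1),
                   c("active", "active", "decoy", "decoy", "decoy"))
  r <- drf(set, 0.5)  # x = 1, sp = 0.9; the tied decoy does not exceed it
  expect_equal(r@dp, 0L)
  expect_equal(drfValue(r), 0)
})

test_that("DRF rejects degenerate inputs", {
  set <- ScoredSet(c(0.9, 0.1), c("active", "decoy"))
  expect_error(drf(set, 0.1), "too few decoys")
  expect_error(drf(set, 0), "fraction in \\(0, 1\\)")
  expect_error(drf(set, 1), "fraction in \\(0, 1\\)")
  onlyAct <- ScoredSet(0.5, "active")
  expect_error(drf(onlyAct, 0.5), "at least one")
})

test_that("ROC AUC equals the pairwise concordance probability", {
  s <- ScoredSet(c(0.9, 0.4, 0.5, 0.3),
                 c("active", "active", "decoy", "decoy"))
  expect_equal(rocAuc(s), 0.75)
  perfect <- ScoredSet(c(1, 1, 0, 0), rep(c("active", "decoy"), each = 2))
  expect_equal(rocAuc(perfect), 1)
  allTied <- ScoredSet(rep(0.5, 6), rep(c("active", "decoy"), 3))
  expect_equal(rocAuc(allTied), 0.5)
})

test_that("drf and rocAuc agree with brute-force oracles on random sets", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:50, 1); d <- sample(10:50, 1)
    set <- randomScoredSet(n, d)
    expect_equal(rocAuc(set), aucOracle(set))
    p <- 0.25  # floor(p*d) >= 2 for every d in range
    expect_equal(drfValue(drf(set, p)), drfOracle(set, p))
  }
})

test_that("rocAuc agrees with pROC on tied and untied data", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:20) {
    set <- randomScoredSet(sample(5:40, 1), sample(5:40, 1), tied = (i %% 2 == 0))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = scoreLabels(set), predictor = scores(set),
      levels = c("decoy", "active"), direction = "<", quiet = TRUE)))
    expect_equal(rocAuc(set), ref)
  }
})

test_that("DRF, AUC and recovery curves are invariant to monotone rescoring", {
  set.seed(41)
  for (trans in list(function(x) x^3, function(x) exp(5 * x),
                     function(x) 2 * x - 7)) {
    set <- randomScoredSet(20, 80)
    set2 <- ScoredSet(trans(scores(set)), scoreLabels(set))
    expect_equal(drfValue(drf(set, 0.1)), drfValue(drf(set2, 0.1)))
    expect_equal(rocAuc(set), rocAuc(set2))
    expect_equal(cumulativeRecoveryCurve(set)[, -1],
                 cumulativeRecoveryCurve(set2)[, -1])
  }
})

test_that("DRF above one (decoy enrichment) is representable", {
  # actives at the bottom, decoys on top: decoys are enriched
  set <- ScoredSet(c(runif(10, 0, 0.2), runif(100, 0.5, 1)),
                   rep(c("active", "decoy"), c(10, 100)))
  v <- drfValue(drf(set, 0.1))
  expect_gt(v, 1)
  expect_lte(v, 100 / floor(0.1 * 100))
})

test_that("survival fractions match direct counts and are monotone", {
  set <- ScoredSet(c(0.15, 0.25, 0.35, 0.95, 0.1, 0.2),
                   c(rep("active", 4), rep("decoy", 2)))
  tab <- fractionAboveCutoffs(set, c(0, 0.3, 2 / 3))
  expect_equal(tab$activeFraction[1], 1)
  expect_equal(tab$decoyFraction[1], 1)
  expect_equal(tab$activeFraction[2], 0.5)  # 2 of 4 actives >= 0.3
  expect_equal(tab$decoyFraction[3], 0)
  over <- fractionAboveCutoffs(set, 1)  # above the max score
  expect_equal(over$activeFraction, 0)
  expect_equal(over$decoyFraction, 0)
  big <- fractionAboveCutoffs(randomScoredSet(30, 70), seq(0, 1, 0.1))
  expect_true(all(diff(big$activeFraction) <= 0))
  expect_true(all(diff(big$decoyFraction) <= 0))
  expect_error(fractionAboveCutoffs(set, c(0.5, 0.1)), "ascending")
})

test_that("cumulative recovery curve matches hand enumeration", {
  set <- ScoredSet(c(0.9, 0.1), c("active", "decoy"))
  curve <- cumulativeRecoveryCurve(set)
  expect_equal(nrow(curve), 2)
  expect_equal(curve$activeRecovered, c(1, 1))
  expect_equal(curve$decoyRecovered, c(0, 1))
  # 6-record hand-built set with a tie across labels
  set6 <- ScoredSet(c(0.8, 0.5, 0.2, 0.5, 0.4, 0.1),
                    c(rep("active", 3), rep("decoy", 3)))
  c6 <- cumulativeRecoveryCurve(set6)
  expect_equal(c6$threshold, c(0.8, 0.5, 0.4, 0.2, 0.1))
  expect_equal(c6$activeRecovered, c(1, 2, 2, 3, 3) / 3)
  expect_equal(c6$decoyRecovered, c(0, 1, 2, 2, 3) / 3)
  # last point recovers everything; consistency with fractionAboveCutoffs
  expect_equal(unlist(c6[nrow(c6), 2:3], use.names = FALSE), c(1, 1))
  at <- fractionAboveCutoffs(set6, 0.4)
  expect_equal(c6$activeRecovered[c6$threshold == 0.4], at$activeFraction)
  expect_equal(c6$decoyRecovered[c6$threshold == 0.4], at$decoyFraction)
})

test_that("BEDROC attains its extremes and its random expectation", {
  perfect <- ScoredSet(c(10:6, 5:1), rep(c("active", "decoy"), each = 5))
  expect_gt(bedroc(perfect), 0.99)
  worst <- ScoredSet(c(5:1, 10:6), rep(c("active", "decoy"), each = 5))
  expect_lt(bedroc(worst), 0.05)
  expect_error(bedroc(perfect, alpha = 0), "positive")
  # Monte-Carlo over label permutations versus the analytic RIE = 1 value
  alpha <- 20; n <- 10; d <- 90; N <- n + d; ra <- n / N
  randConst <- ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
  set.seed(61)
  sims <- replicate(4000, {
    lab <- sample(rep(c("active", "decoy"), c(n, d)))
    bedroc(ScoredSet(seq_len(N), lab), alpha)
  })
  # per-draw sd is ~0.106, so 4000 draws give se ~0.0017; 0.015 is ~9 se
  expect_lt(abs(mean(sims) - randConst), 0.015)
})

test_that("sum of log ranks rewards early recognition and averages ties", {
  early <- ScoredSet(c(4, 3, 2, 1), c("active", "active", "decoy", "decoy"))
  late <- ScoredSet(c(4, 3, 2, 1), c("decoy", "decoy", "active", "active"))
  expect_lt(sumLogRank(early), sumLogRank(late))
  expect_equal(sumLogRank(early), log(1 / 4) + log(2 / 4))
  # a fully tied set: every record has expected rank spread over 1..N
  tied <- ScoredSet(rep(1, 4), c("active", "decoy", "active", "decoy"))
  expect_equal(sumLogRank(tied), 2 * mean(log((1:4) / 4)))
})
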