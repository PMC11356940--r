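test_that("LINGO fragmentation normalizes ring digits and deduplicates", {
  # "c1ccccc1" -> "c0ccccc0": 4-grams c0cc, 0ccc, cccc (x2), ccc0
  expect_setequal(lingoFeatures("c1ccccc1", q = 4),
                  c("c0cc", "0ccc", "cccc", "ccc0"))
  # strings shorter than q collapse to the whole (normalized) string
  expect_identical(lingoFeatures("CCO", q = 4), "CCO")
  expect_identical(lingoFeatures("C1O", q = 4), "C0O")
  # deterministic: identical input, identical set
  expect_identical(lingoFeatures("c1ccncc1CC(=O)", 4),
                   lingoFeatures("c1ccncc1CC(=O)", 4))
  # ring-closure normalization makes renumbered rings identical
  expect_identical(lingoFeatures("c1ccccc1", 4), lingoFeatures("c2ccccc2", 4))
  expect_error(lingoFeatures("", 4), "non-empty")
  expect_error(lingoFeatures("CCO", 0), "positive")
})

test_that("LINGO feature-set size respects the q-gram bound", {
  set.seed(101)
  for (i in 1:25) {
    s <- paste(sample(c("C", "c", "N", "O", "(", ")", "1", "="),
                      sample(1:30, 1), replace = TRUE), collapse = "")
    q <- sample(1:6, 1)
    expect_lte(length(lingoFeatures(s, q)), max(1, nchar(s) - q + 1))
  }
})

test_that("Tanimoto matches set arithmetic and its boundary values", {
  expect_equal(tanimoto(Fingerprint(c(1, 2, 3)), Fingerprint(c(2, 3, 4))), 0.5)
  a <- Fingerprint(c("ab", "cd", "ef"))
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(Fingerprint(1:4), Fingerprint(5:8)), 0)
  expect_error(tanimoto(Fingerprint(character()), Fingerprint(character())),
               "undefined")
  # one empty set is defined: similarity 0
  expect_equal(tanimoto(Fingerprint(character()), Fingerprint(1:3)), 0)
})

test_that("Tanimoto is symmetric and bounded on random sets", {
  set.seed(7)
  for (i in 1:50) {
    a <- Fingerprint(sample(0:30, sample(1:12, 1)))
    b <- Fingerprint(sample(0:30, sample(1:12, 1)))
    t1 <- tanimoto(a, b)
    expect_identical(t1, tanimoto(b, a))
    expect_gte(t1, 0); expect_lte(t1, 1)
  }
})

test_that("incompatible fingerprint conventions are rejected", {
  folded <- Fingerprint(c(1, 2), length = 64)
  other <- Fingerprint(c(1, 2), length = 128)
  unfolded <- Fingerprint(c(1, 2))
  expect_error(tanimoto(folded, other), "different lengths")
  expect_error(tanimoto(folded, unfolded), "folded")
  expect_warning(
    tanimoto(Fingerprint(1:3, source = "lingo"),
             Fingerprint(1:3, source = "external:ecfp2")),
    "different sources")
})

test_that("folding maps by modulo / stable hash and never grows the set", {
  expect_identical(features(foldFingerprint(Fingerprint(c(0, 1024)), 1024)),
                   "0")
  # length above every position: identity on integer features
  fp <- Fingerprint(c(3, 17, 40))
  expect_setequal(features(foldFingerprint(fp, 1024)), c("3", "17", "40"))
  expect_equal(fpLength(foldFingerprint(fp, 1024)), 1024)
  expect_error(foldFingerprint(fp, 0), "positive")
  set.seed(11)
  for (i in 1:30) {
    feats <- unique(replicate(sample(1:15, 1),
      paste(sample(letters, 4, replace = TRUE), collapse = "")))
    orig <- Fingerprint(feats)
    len <- sample(c(4, 16, 64), 1)
    folded <- foldFingerprint(orig, len)
    expect_lte(nFeatures(folded), nFeatures(orig))
    expect_true(all(as.integer(features(folded)) < len))
  }
  # string hashing is stable across calls
  expect_identical(features(foldFingerprint(Fingerprint(c("ccO", "c1c")), 256)),
                   features(foldFingerprint(Fingerprint(c("ccO", "c1c")), 256)))
})

test_that("Tanimoto after folding equals the Jaccard of the folded sets", {
  set.seed(23)
  for (i in 1:40) {
    a <- Fingerprint(sample(0:99, sample(2:20, 1)))
    b <- Fingerprint(sample(0:99, sample(2:20, 1)))
    len <- sample(c(8, 16, 32), 1)
    fa <- features(foldFingerprint(a, len))
    fb <- features(foldFingerprint(b, len))
    jaccard <- length(intersect(fa, fb)) / length(union(fa, fb))
    expect_equal(tanimoto(foldFingerprint(a, len), foldFingerprint(b, len)),
                 jaccard)
  }
})

test_that("multiset LINGO similarity counts repeated q-grams", {
  # "CCCCC" has 4-grams {CCCC x2}; vs "CCCC" {CCCC x1}: min/max = 1/2
  expect_equal(lingoSim("CCCCC", "CCCC", q = 4, multiset = TRUE), 0.5)
  # set semantics collapses the repeat: identical sets
  expect_equal(lingoSim("CCCCC", "CCCC", q = 4), 1)
  expect_equal(lingoSim("CCO", "CCO", multiset = TRUE), 1)
})
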