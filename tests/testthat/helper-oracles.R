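# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive: O(n*d) pair enumeration, full pooled sorts, O(m^2)
# pair counting, so that the fast implementations are checked against
# straightforward definitions.

# AUC as the exact Mann-Whitney probability: enumerate every active-decoy
# pair, ties count one half.
aucOracle <- function(set) {
  act <- scores(set)[scoreLabels(set) == "active"]
  dec <- scores(set)[scoreLabels(set) == "decoy"]
  total <- 0
  for (a in act) total <- total + sum(a > dec) + 0.5 * sum(a == dec)
  total / (length(act) * length(dec))
}

# DRF by fully sorting the pooled set: walk the merged descending list to
# the x-th active, then count decoys strictly above that score.
drfOracle <- function(set, p) {
  sc <- scores(set); lab <- scoreLabels(set)
  ord <- order(sc, decreasing = TRUE)
  sc <- sc[ord]; lab <- lab[ord]
  n <- sum(lab == "active"); d <- sum(lab == "decoy")
  x <- ceiling(p * n)
  sp <- sc[which(lab == "active")[x]]
  sum(sc[lab == "decoy"] > sp) / floor(p * d)
}

# Kendall tau-b by explicit pair enumeration with tie corrections.
kendallOracle <- function(x, y) {
  m <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) nc <- nc + 1
      else nd <- nd + 1
    }
  }
  n0 <- m * (m - 1) / 2
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

# Random ScoredSet with integer-ish scores so ties occur.
randomScoredSet <- function(n, d, tied = TRUE) {
  pool <- if (tied) sample(1:20, n + d, replace = TRUE) / 20
          else runif(n + d)
  ScoredSet(pool, rep(c("active", "decoy"), c(n, d)))
}

# Tiny two-target benchmark with deterministic fingerprints, for pipeline
# tests that need hand-checkable numbers.
tinyBenchmark <- function() {
  fps <- list(
    a1 = Fingerprint(c(1, 2, 3, 4), length = 16, source = "synthetic"),
    a2 = Fingerprint(c(1, 2, 3, 5), length = 16, source = "synthetic"),
    a3 = Fingerprint(c(1, 2, 6, 7), length = 16, source = "synthetic"),
    d1 = Fingerprint(c(8, 9, 10, 11), length = 16, source = "synthetic"),
    d2 = Fingerprint(c(1, 8, 9, 10), length = 16, source = "synthetic"))
  tb <- TargetBenchmark("TGT", activeIds = c("a1", "a2", "a3"),
                        decoyIds = c("d1", "d2"),
                        ac50 = c(10, 2, 7))
  list(benchmark = tb, fingerprints = fps)
}
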