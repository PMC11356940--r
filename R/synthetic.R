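#' @include AllClasses.R
NULL

.smilesAlphabet <- c("C", "c", "N", "n", "O", "o", "S", "s", "P", "F",
                     "I", "l", "r", "B", "1", "2", "3", "(", ")", "=",
                     "#", "[", "]", "@", "+", "-")

#' Closed-form expected Tanimoto of the seeded fingerprint family
#'
#' Under the seeded-variant model — a seed with `k` on-bits among `L`,
#' each variant keeping every seed bit with probability `a` and turning
#' on every off-bit with probability `b`, independently — the expected
#' intersection with the seed is `k a` and the expected union is
#' `k + (L - k) b` (every seed bit stays in the union whether or not the
#' variant keeps it). The ratio-of-expectations approximation
#' \deqn{E[T] \approx \frac{k a}{k + (L - k) b}}
#' is the calibration target for [generateSeededFingerprints()]; its bias
#' relative to the true mean Tanimoto is small for the universe sizes
#' used here and is bounded empirically in the package's tests.
#'
#' @param L,k Universe size and seed on-bit count.
#' @param a,b Retention and activation probabilities.
#' @return The approximate expected seed-variant Tanimoto.
#' @export
expectedSeedTanimoto <- function(L, k, a, b) {
  stopifnot(k >= 1, k <= L, a >= 0, a <= 1, b >= 0, b <= 1)
  (k * a) / (k + (L - k) * b)
}

#' Generate a seed fingerprint and a family of noisy variants
#'
#' Draws a seed fingerprint with exactly `k` on-bits among a universe of
#' `L` bit positions, then `nVariants` variants: each keeps every seed
#' on-bit with probability `a` and activates every off-bit with
#' probability `b`, all independently. The family's expected Tanimoto to
#' the seed is controlled by [expectedSeedTanimoto()]; with `a = 1, b = 0`
#' every variant equals the seed, and with `a = b = 0` variants are empty.
#' Reproducible: identical `(L, k, a, b, nVariants, seed)` give identical
#' output.
#'
#' @param L Universe size (number of bit positions).
#' @param k Seed on-bit count, `1 <= k <= L`.
#' @param a,b Retention / activation probabilities in \[0, 1\].
#' @param nVariants Number of variants to draw.
#' @param seed Integer RNG seed.
#' @return A list with `seed` (a [Fingerprint-class]) and `variants` (a
#'   list of [Fingerprint-class]), all tagged `source = "synthetic"` and
#'   folded to length `L`.
#' @export
generateSeededFingerprints <- function(L, k, a, b, nVariants, seed = 1L) {
  L <- as.integer(L); k <- as.integer(k)
  if (is.na(k) || is.na(L) || k < 1L || k > L)
    stop("'k' must satisfy 1 <= k <= L")
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1, nVariants >= 1)
  .withSeed(seed, {
    bits <- sort(sample.int(L, k) - 1L)
    offBits <- setdiff(seq_len(L) - 1L, bits)
    variants <- lapply(seq_len(nVariants), function(i) {
      kept <- bits[stats::runif(k) < a]
      extra <- offBits[stats::runif(L - k) < b]
      Fingerprint(c(kept, extra), length = L, source = "synthetic")
    })
    list(seed = Fingerprint(bits, length = L, source = "synthetic"),
         variants = variants)
  })
}

#' Generate labeled score sets with planted enrichment
#'
#' Draws, for each of `nTargets` targets, a [ScoredSet-class] of
#' `nActives` active scores from `Beta(activeShape)` and `nDecoys` decoy
#' scores of which a planted fraction `f` comes from the active
#' distribution and the remainder from `Beta(decoyShape)`. With identical
#' shapes for both labels (or `f = 1`) this is the null regime — scores
#' carry no label information, so DRF concentrates near 1 and AUC near
#' 0.5. With well-separated shapes and planted fraction `f`, the score
#' threshold of the top-`p` actives passes about `f * p * d` decoys, so
#' the measured DRF concentrates near `f`: the generator plants a known
#' enrichment for parameter-recovery testing.
#'
#' @param spec A [SyntheticSpec-class]; the fields used are `nTargets`,
#'   `nActives`, `nDecoys`, `activeShape`, `decoyShape`,
#'   `plantedFraction`, and `seed`.
#' @return A list of `nTargets` [ScoredSet-class] objects.
#' @examples
#' spec <- SyntheticSpec(nTargets = 1L, nActives = 50L, nDecoys = 500L,
#'                       plantedFraction = 0.3, seed = 11L)
#' drf(generateScoreBenchmark(spec)[[1]], 0.1)
#' @export
generateScoreBenchmark <- function(spec) {
  stopifnot(methods::is(spec, "SyntheticSpec"))
  methods::validObject(spec)
  .withSeed(spec@seed, {
    lapply(seq_len(spec@nTargets), function(i) {
      nPlanted <- round(spec@plantedFraction * spec@nDecoys)
      act <- stats::rbeta(spec@nActives, spec@activeShape[1L],
                          spec@activeShape[2L])
      decPlanted <- stats::rbeta(nPlanted, spec@activeShape[1L],
                                 spec@activeShape[2L])
      decRest <- stats::rbeta(spec@nDecoys - nPlanted, spec@decoyShape[1L],
                              spec@decoyShape[2L])
      ScoredSet(c(act, decPlanted, decRest),
                rep(c("active", "decoy"),
                    c(spec@nActives, spec@nDecoys)))
    })
  })
}

#' Generate SMILES-like strings by random edits
#'
#' Produces `count` strings, each obtained from `seedString` by `nEdits`
#' random single-character edits (substitution, insertion, or deletion,
#' chosen uniformly) over a SMILES-style alphabet. The strings are text
#' for exercising the LINGO fingerprint end-to-end, not chemically valid
#' molecules. Mean LINGO similarity to the seed decays as `nEdits` grows.
#' Strings never shrink below one character.
#'
#' @param seedString Non-empty starting string.
#' @param nEdits Number of edits per output string (>= 0).
#' @param count Number of strings.
#' @param seed Integer RNG seed.
#' @return Character vector of length `count`.
#' @export
generateSmilesLike <- function(seedString, nEdits, count, seed = 1L) {
  stopifnot(is.character(seedString), nzchar(seedString), nEdits >= 0,
            count >= 1)
  .withSeed(seed, {
    vapply(seq_len(count), function(i) {
      chars <- strsplit(seedString, "")[[1L]]
      for (e in seq_len(nEdits)) {
        op <- sample(c("sub", "ins", "del"), 1L)
        pos <- sample.int(length(chars), 1L)
        newChar <- sample(.smilesAlphabet, 1L)
        chars <- switch(op,
          sub = { chars[pos] <- newChar; chars },
          ins = append(chars, newChar, after = pos - 1L),
          del = if (length(chars) > 1L) chars[-pos] else chars)
      }
      paste(chars, collapse = "")
    }, character(1))
  })
}

#' Generate AC50 potencies with a target rank correlation to similarity
#'
#' Couples a potency value to each similarity via a Gaussian copula: the
#' normal scores of the similarity ranks are mixed with independent
#' Gaussian noise at correlation `rho = sin(pi * tauTarget / 2)` — the
#' bivariate-normal relation between Pearson's rho and Kendall's tau — and
#' exponentiated to positive AC50 values. The expected Kendall tau
#' between similarity and the generated AC50 then equals `tauTarget`:
#' `tauTarget = 1` gives AC50 strictly monotone in similarity,
#' `tauTarget = 0` gives independent potencies, and intermediate values
#' are recovered in the mean over seeds.
#'
#' Note the sign: `tauTarget` is the correlation between similarity and
#' raw AC50, so a *negative* target plants "more similar compounds are
#' more potent" (lower AC50).
#'
#' @param similarities Numeric vector of at least 3 similarity values.
#' @param tauTarget Desired Kendall tau in \[-1, 1\].
#' @param seed Integer RNG seed.
#' @return Numeric vector of positive AC50 values, parallel to
#'   `similarities`.
#' @export
generatePotency <- function(similarities, tauTarget, seed = 1L) {
  m <- length(similarities)
  if (m < 3L) stop("at least 3 similarities are required")
  if (!is.numeric(tauTarget) || is.na(tauTarget) || abs(tauTarget) > 1)
    stop("unreachable tau: 'tauTarget' must lie in [-1, 1]")
  .withSeed(seed, {
    rho <- sin(pi * tauTarget / 2)
    zx <- stats::qnorm(rank(similarities, ties.method = "average") / (m + 1))
    z <- rho * zx + sqrt(1 - rho^2) * stats::rnorm(m)
    exp(z)
  })
}

#' Simulate a complete multi-target screening benchmark
#'
#' Builds an in-memory benchmark with the structure of a per-target
#' active/decoy screening set: for each target, a seed fingerprint is
#' drawn and actives are generated as high-retention variants
#' (`aActive`, `bActive`) while decoys are low-retention variants
#' (`aDecoy`, `bDecoy`) of the same seed, giving overlapping but shifted
#' active-active versus active-decoy similarity distributions. Every
#' molecule also receives a SMILES-like string (edits of a per-target
#' seed string). Actives receive AC50 potencies planted at Kendall
#' correlation `tauTarget` against their similarity to the designated
#' query active, which itself receives the lowest AC50 so that
#' most-potent query selection recovers it.
#'
#' @param spec A [SyntheticSpec-class]; `nActives` must be at least 4 so
#'   potencies can be planted.
#' @return A list with `benchmarks` (named list of
#'   [TargetBenchmark-class]), `fingerprints` (named list of
#'   [Fingerprint-class] covering every molecule), and `molecules`
#'   (data.frame of `id`, `smiles`).
#' @seealso [simulateBenchmarkFiles()] to write the same material in the
#'   pipeline's input formats.
#' @export
simulateBenchmark <- function(spec) {
  stopifnot(methods::is(spec, "SyntheticSpec"))
  methods::validObject(spec)
  if (spec@nActives < 4L)
    stop("'nActives' must be at least 4 to plant potencies")
  .withSeed(spec@seed, {
    benchmarks <- list()
    fingerprints <- list()
    mols <- list()
    for (t in seq_len(spec@nTargets)) {
      tid <- sprintf("T%02d", t)
      subSeeds <- sample.int(2^30, 4L)
      fam <- generateSeededFingerprints(spec@L, spec@k, spec@aActive,
                                        spec@bActive, spec@nActives,
                                        seed = subSeeds[1L])
      # decoys: low-retention variants of the same target seed
      decFam <- .withSeed(subSeeds[2L], {
        bits <- as.integer(features(fam$seed))
        offBits <- setdiff(seq_len(spec@L) - 1L, bits)
        lapply(seq_len(spec@nDecoys), function(i) {
          kept <- bits[stats::runif(spec@k) < spec@aDecoy]
          extra <- offBits[stats::runif(spec@L - spec@k) < spec@bDecoy]
          Fingerprint(c(kept, extra), length = spec@L, source = "synthetic")
        })
      })
      actIds <- sprintf("%s_A%03d", tid, seq_len(spec@nActives))
      decIds <- sprintf("%s_D%05d", tid, seq_len(spec@nDecoys))
      names(fam$variants) <- actIds
      names(decFam) <- decIds
      # potencies: query = first active, planted tau against similarity to it
      query <- actIds[1L]
      others <- actIds[-1L]
      sims <- vapply(others, function(id)
        tanimoto(fam$variants[[query]], fam$variants[[id]]), numeric(1))
      acOthers <- generatePotency(sims, spec@tauTarget, seed = subSeeds[3L])
      acAll <- c(min(acOthers) / 2, acOthers)
      seedSmiles <- paste(sample(.smilesAlphabet, 30L, replace = TRUE),
                          collapse = "")
      smi <- generateSmilesLike(seedSmiles, nEdits = 6L,
                                count = spec@nActives + spec@nDecoys,
                                seed = subSeeds[4L])
      # a leading '#' would read back as a comment line in the .smi format
      smi <- sub("^#", "C", smi)
      benchmarks[[tid]] <- TargetBenchmark(tid, activeIds = actIds,
                                           decoyIds = decIds, ac50 = acAll)
      fingerprints <- c(fingerprints, fam$variants, decFam)
      mols[[tid]] <- data.frame(id = c(actIds, decIds), smiles = smi)
    }
    molecules <- do.call(rbind, mols)
    rownames(molecules) <- NULL
    list(benchmarks = benchmarks, fingerprints = fingerprints,
         molecules = molecules)
  })
}

#' Write a simulated benchmark in the pipeline's input formats
#'
#' Runs [simulateBenchmark()] and writes its output to `dir` as
#' `library.smi` (SMILES library), `benchmark.tsv` (target / molecule /
#' label / AC50 table) and `fingerprints.tsv` (fingerprint TSV), the
#' three files the screening pipeline reads. Generated files round-trip
#' through [readSmiles()], [readBenchmark()] and [readFingerprints()]
#' without modification.
#'
#' @param spec A [SyntheticSpec-class].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
simulateBenchmarkFiles <- function(spec, dir) {
  sim <- simulateBenchmark(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(smiles = file.path(dir, "library.smi"),
             benchmark = file.path(dir, "benchmark.tsv"),
             fingerprints = file.path(dir, "fingerprints.tsv"))
  writeSmiles(sim$molecules, paths[["smiles"]])
  writeBenchmark(sim$benchmarks, paths[["benchmark"]])
  writeFingerprints(sim$fingerprints, paths[["fingerprints"]])
  invisible(paths)
}
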