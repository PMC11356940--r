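#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# Fingerprint
# ---------------------------------------------------------------------------

#' Fingerprint: a finite feature set for one molecule
#'
#' A `Fingerprint` holds the feature set of one molecule: character q-grams
#' for the text-based LINGO fingerprint, or non-negative integer bit
#' positions for hashed bit-vector fingerprints. Features have set
#' semantics (no duplicates; order is irrelevant). A folded fingerprint
#' additionally carries the bit-vector length, and every position must lie
#' in `[0, length)`.
#'
#' Features are stored internally as a sorted character vector; integer
#' positions are stored in decimal form. The `source` tag records where the
#' fingerprint came from (`"lingo"`, `"external:<name>"`, or
#' `"synthetic"`), and [tanimoto()] warns when sources are mixed.
#'
#' @slot features Character vector of unique feature keys.
#' @slot length Integer bit-vector length, or `NA` for unfolded
#'   fingerprints.
#' @slot source Character scalar tag.
#'
#' @param features Character vector or non-negative numeric vector of
#'   feature keys; duplicates are removed.
#' @param length Optional positive integer; supply it when `features` are
#'   bit positions of a fixed-length vector.
#' @param source Character scalar tag, default `"external:unknown"`.
#'
#' @return `Fingerprint()` returns a `Fingerprint` object; `features()`
#'   returns the sorted character vector of feature keys; `fpLength()`
#'   returns the bit-vector length (`NA` if unfolded); `fpSource()` the
#'   source tag; `nFeatures()` the feature count.
#' @examples
#' fp <- Fingerprint(c(3, 17, 40), length = 64, source = "external:demo")
#' nFeatures(fp)
#' lingoFingerprint("c1ccccc1")
#' @aliases features fpLength fpSource nFeatures
#' @export
setClass("Fingerprint",
  representation(features = "character", length = "integer",
                 source = "character"),
  prototype(features = character(), length = NA_integer_,
            source = "external:unknown"))

setValidity("Fingerprint", function(object) {
  msg <- character()
  if (anyDuplicated(object@features))
    msg <- c(msg, "duplicate feature keys (features must be a set)")
  if (length(object@source) != 1L || is.na(object@source))
    msg <- c(msg, "'source' must be a single string")
  if (length(object@length) != 1L)
    msg <- c(msg, "'length' must be a single integer or NA")
  if (length(object@length) == 1L && !is.na(object@length)) {
    if (object@length < 1L)
      msg <- c(msg, "'length' must be positive")
    pos <- suppressWarnings(as.numeric(object@features))
    if (anyNA(pos) || any(pos != floor(pos)))
      msg <- c(msg, "folded fingerprints must have integer bit positions")
    else if (length(pos) && (any(pos < 0) || any(pos >= object@length)))
      msg <- c(msg, "bit positions must lie in [0, length)")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Fingerprint-class
#' @export
Fingerprint <- function(features = character(), length = NA,
                        source = "external:unknown") {
  if (is.numeric(features)) {
    if (length(features) && (anyNA(features) || any(features != floor(features)) ||
                             any(features < 0)))
      stop("numeric features must be non-negative integers (bit positions)")
    features <- format(features, scientific = FALSE, trim = TRUE)
  }
  features <- sort(unique(as.character(features)), method = "radix")
  new("Fingerprint", features = features, length = as.integer(length),
      source = source)
}

#' @rdname Fingerprint-class
#' @export
setMethod("features", "Fingerprint", function(x) x@features)

#' @rdname Fingerprint-class
#' @export
fpLength <- function(x) x@length

#' @rdname Fingerprint-class
#' @export
fpSource <- function(x) x@source

#' @rdname Fingerprint-class
#' @export
nFeatures <- function(x) length(x@features)

setMethod("show", "Fingerprint", function(object) {
  kind <- if (is.na(object@length)) "unfolded" else
    paste0("folded, length ", object@length)
  cat("Fingerprint (", object@source, ", ", kind, "): ",
      length(object@features), " features\n", sep = "")
  if (length(object@features)) {
    shown <- utils::head(object@features, 8L)
    cat("  ", paste(shown, collapse = " "),
        if (length(object@features) > 8L) " ..." else "", "\n", sep = "")
  }
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# ScoredSet
# ---------------------------------------------------------------------------

#' ScoredSet: labeled similarity scores for one target
#'
#' A `ScoredSet` holds the pooled (score, label) records of one screening
#' experiment: each record is the similarity of some candidate molecule to
#' a query, labeled `"active"` or `"decoy"` according to the candidate's
#' benchmark annotation. It is the input to all enrichment metrics
#' ([drf()], [rocAuc()], [bedroc()], [fractionAboveCutoffs()],
#' [cumulativeRecoveryCurve()]).
#'
#' @slot score Numeric vector of finite similarity scores.
#' @slot label Character vector, `"active"` or `"decoy"`, parallel to
#'   `score`.
#'
#' @param score Numeric vector of finite scores.
#' @param label Character vector of labels (`"active"`/`"decoy"`).
#' @param x A `ScoredSet`.
#'
#' @return `ScoredSet()` returns a `ScoredSet`; `nActives()`/`nDecoys()`
#'   the class counts; `scores()` and `scoreLabels()` the parallel record
#'   vectors.
#' @examples
#' s <- ScoredSet(score = c(.9, .8, .4, .2), label = c("active", "decoy",
#'                "active", "decoy"))
#' nActives(s)
#' rocAuc(s)
#' @aliases nActives nDecoys scores scoreLabels
#' @export
setClass("ScoredSet",
  representation(score = "numeric", label = "character"))

setValidity("ScoredSet", function(object) {
  msg <- character()
  if (length(object@score) != length(object@label))
    msg <- c(msg, "'score' and 'label' must have equal length")
  if (length(object@score) && !all(is.finite(object@score)))
    msg <- c(msg, "all scores must be finite")
  if (!all(object@label %in% c("active", "decoy")))
    msg <- c(msg, "labels must be 'active' or 'decoy'")
  if (length(msg)) msg else TRUE
})

#' @rdname ScoredSet-class
#' @export
ScoredSet <- function(score, label) {
  new("ScoredSet", score = as.numeric(score), label = as.character(label))
}

#' @rdname ScoredSet-class
#' @export
setMethod("nActives", "ScoredSet", function(x) sum(x@label == "active"))

#' @rdname ScoredSet-class
#' @export
setMethod("nDecoys", "ScoredSet", function(x) sum(x@label == "decoy"))

#' @rdname ScoredSet-class
#' @export
setMethod("scores", "ScoredSet", function(x) x@score)

#' @rdname ScoredSet-class
#' @export
setMethod("scoreLabels", "ScoredSet", function(x) x@label)

setMethod("show", "ScoredSet", function(object) {
  cat("ScoredSet: ", nActives(object), " actives, ", nDecoys(object),
      " decoys\n", sep = "")
  if (length(object@score))
    cat("  score range: [", format(min(object@score)), ", ",
        format(max(object@score)), "]\n", sep = "")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# DRFResult
# ---------------------------------------------------------------------------

#' DRFResult: one decoy retention factor computation
#'
#' Records the intermediate quantities of a decoy retention factor
#' computation on a [ScoredSet-class]: the active fraction `p`, the rank
#' `x = ceiling(p * n)`, the score threshold `sp` of the x-th highest
#' active, the count `dp` of decoys scoring strictly above `sp`, and the
#' DRF value `dp / floor(p * d)`. A value of 1 is the random-scorer
#' expectation, 0 means no decoy outscores the threshold, and values above
#' 1 indicate enrichment for decoys.
#'
#' @slot p Active-recovery fraction in (0, 1).
#' @slot x Integer rank of the threshold active.
#' @slot sp Score of the x-th highest active.
#' @slot dp Integer count of decoys with score strictly greater than `sp`.
#' @slot n,d Integer class sizes.
#' @slot value The DRF value, `dp / floor(p * d)`.
#' @seealso [drf()]
#' @export
setClass("DRFResult",
  representation(p = "numeric", x = "integer", sp = "numeric",
                 dp = "integer", n = "integer", d = "integer",
                 value = "numeric"))

setValidity("DRFResult", function(object) {
  msg <- character()
  if (object@dp < 0L || object@dp > object@d)
    msg <- c(msg, "'dp' must lie in [0, d]")
  if (object@value < 0)
    msg <- c(msg, "DRF value must be non-negative")
  if ((object@value == 0) != (object@dp == 0L))
    msg <- c(msg, "value == 0 exactly when dp == 0")
  if (length(msg)) msg else TRUE
})

#' @rdname DRFResult-class
#' @param object A `DRFResult`.
#' @export
setMethod("show", "DRFResult", function(object) {
  cat("DRF_", format(object@p), " = ", format(object@value),
      "  (x = ", object@x, ", sp = ", format(object@sp),
      ", dp = ", object@dp, " of d = ", object@d, ")\n", sep = "")
  invisible(NULL)
})

#' @rdname DRFResult-class
#' @param x A `DRFResult`.
#' @export
drfValue <- function(x) x@value

# ---------------------------------------------------------------------------
# TargetBenchmark
# ---------------------------------------------------------------------------

#' TargetBenchmark: actives and decoys for one protein target
#'
#' One protein target's benchmark material: the identifiers of its
#' confirmed active ligands (with optional AC50 potencies, in
#' concentration units where lower means more potent) and of its decoys.
#' Molecules themselves (SMILES, fingerprints) are kept in separate
#' libraries keyed by identifier, mirroring the file layout of screening
#' benchmarks where one compound library serves many targets.
#'
#' @slot targetId Character scalar.
#' @slot activeIds Character vector of active molecule ids (at least one).
#' @slot ac50 Numeric vector parallel to `activeIds`; `NA` where no
#'   potency is recorded; positive elsewhere.
#' @slot decoyIds Character vector of decoy molecule ids, disjoint from
#'   `activeIds`.
#'
#' @param targetId,activeIds,decoyIds,ac50 See slots; `ac50` defaults to
#'   all-`NA`.
#' @return `TargetBenchmark()` returns a `TargetBenchmark`; the accessors
#'   return the corresponding slot (`ac50()` as a named numeric vector).
#' @examples
#' tb <- TargetBenchmark("T1", activeIds = c("a1", "a2"),
#'                       decoyIds = c("d1", "d2", "d3"),
#'                       ac50 = c(0.4, 7.1))
#' activeIds(tb)
#' ac50(tb)
#' @aliases targetId activeIds decoyIds ac50
#' @export
setClass("TargetBenchmark",
  representation(targetId = "character", activeIds = "character",
                 ac50 = "numeric", decoyIds = "character"))

setValidity("TargetBenchmark", function(object) {
  msg <- character()
  if (length(object@targetId) != 1L || is.na(object@targetId) ||
      !nzchar(object@targetId))
    msg <- c(msg, "'targetId' must be a non-empty string")
  if (length(object@activeIds) < 1L)
    msg <- c(msg, "at least one active is required")
  if (length(object@ac50) != length(object@activeIds))
    msg <- c(msg, "'ac50' must be parallel to 'activeIds'")
  if (any(!is.na(object@ac50) & object@ac50 <= 0))
    msg <- c(msg, "AC50 values must be positive")
  if (anyDuplicated(c(object@activeIds, object@decoyIds)))
    msg <- c(msg, "active and decoy ids must be unique and disjoint")
  if (length(msg)) msg else TRUE
})

#' @rdname TargetBenchmark-class
#' @export
TargetBenchmark <- function(targetId, activeIds, decoyIds = character(),
                            ac50 = rep(NA_real_, length(activeIds))) {
  new("TargetBenchmark", targetId = as.character(targetId),
      activeIds = as.character(activeIds), ac50 = as.numeric(ac50),
      decoyIds = as.character(decoyIds))
}

#' @rdname TargetBenchmark-class
#' @export
setMethod("targetId", "TargetBenchmark", function(x) x@targetId)

#' @rdname TargetBenchmark-class
#' @export
setMethod("activeIds", "TargetBenchmark", function(x) x@activeIds)

#' @rdname TargetBenchmark-class
#' @export
setMethod("decoyIds", "TargetBenchmark", function(x) x@decoyIds)

#' @rdname TargetBenchmark-class
#' @export
setMethod("ac50", "TargetBenchmark",
          function(x) stats::setNames(x@ac50, x@activeIds))

setMethod("show", "TargetBenchmark", function(object) {
  cat("TargetBenchmark '", object@targetId, "': ",
      length(object@activeIds), " actives (",
      sum(!is.na(object@ac50)), " with AC50), ",
      length(object@decoyIds), " decoys\n", sep = "")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# SyntheticSpec
# ---------------------------------------------------------------------------

#' SyntheticSpec: parameters of the synthetic benchmark generator
#'
#' Bundles the knobs of the synthetic benchmark generator: the fingerprint
#' universe size `L` and seed on-bit count `k`; the per-bit retention
#' probability `a` and off-bit activation probability `b` that control the
#' expected Tanimoto similarity of generated variants to their seed; the
#' benchmark shape (`nTargets`, `nActives`, `nDecoys`); Beta-distribution
#' shape parameters for active-class and decoy-class similarity scores;
#' the planted fraction `f` of decoys drawn from the active score
#' distribution (0 gives the null regime when the two Beta laws coincide);
#' the target Kendall correlation `tauTarget` between similarity and AC50;
#' and the RNG `seed`.
#'
#' Separate retention/activation pairs are used for active (`aActive`,
#' `bActive`) and decoy (`aDecoy`, `bDecoy`) variants when a full
#' benchmark is simulated, so that active-active similarities are drawn
#' from a higher — but overlapping — regime than active-decoy
#' similarities, emulating the heavily overlapping score distributions
#' seen in real active/decoy sets.
#'
#' @slot L,k Integer universe size and seed on-bit count, `1 <= k <= L`.
#' @slot aActive,bActive,aDecoy,bDecoy Probabilities in \[0, 1\].
#' @slot nTargets,nActives,nDecoys Positive integer counts.
#' @slot activeShape,decoyShape Numeric length-2 Beta shape parameters for
#'   the score-only generator.
#' @slot plantedFraction Fraction of decoys drawn from the active score
#'   distribution.
#' @slot tauTarget Target Kendall tau in \[-1, 1\].
#' @slot seed Integer RNG seed.
#'
#' @param L,k,aActive,bActive,aDecoy,bDecoy,nTargets,nActives,nDecoys,activeShape,decoyShape,plantedFraction,tauTarget,seed
#'   See slots.
#' @return A `SyntheticSpec`.
#' @seealso [generateSeededFingerprints()], [generateScoreBenchmark()],
#'   [simulateBenchmark()]
#' @export
setClass("SyntheticSpec",
  representation(L = "integer", k = "integer",
                 aActive = "numeric", bActive = "numeric",
                 aDecoy = "numeric", bDecoy = "numeric",
                 nTargets = "integer", nActives = "integer",
                 nDecoys = "integer",
                 activeShape = "numeric", decoyShape = "numeric",
                 plantedFraction = "numeric", tauTarget = "numeric",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  probs <- c(object@aActive, object@bActive, object@aDecoy, object@bDecoy,
             object@plantedFraction)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@k < 1L || object@k > object@L)
    msg <- c(msg, "'k' must satisfy 1 <= k <= L")
  if (any(c(object@nTargets, object@nActives, object@nDecoys) < 1L))
    msg <- c(msg, "counts must be >= 1")
  if (any(c(object@activeShape, object@decoyShape) <= 0) ||
      length(object@activeShape) != 2L || length(object@decoyShape) != 2L)
    msg <- c(msg, "Beta shape parameters must be two positive numbers")
  if (abs(object@tauTarget) > 1)
    msg <- c(msg, "'tauTarget' must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticSpec-class
#' @export
SyntheticSpec <- function(L = 512L, k = 48L,
                          aActive = 0.30, bActive = 0.03,
                          aDecoy = 0.18, bDecoy = 0.035,
                          nTargets = 5L, nActives = 30L, nDecoys = 1500L,
                          activeShape = c(8, 2), decoyShape = c(2, 8),
                          plantedFraction = 0, tauTarget = 0,
                          seed = 1L) {
  new("SyntheticSpec", L = as.integer(L), k = as.integer(k),
      aActive = aActive, bActive = bActive, aDecoy = aDecoy,
      bDecoy = bDecoy, nTargets = as.integer(nTargets),
      nActives = as.integer(nActives), nDecoys = as.integer(nDecoys),
      activeShape = as.numeric(activeShape),
      decoyShape = as.numeric(decoyShape),
      plantedFraction = plantedFraction, tauTarget = tauTarget,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec: ", object@nTargets, " targets x (",
      object@nActives, " actives + ", object@nDecoys, " decoys), ",
      "universe L = ", object@L, ", k = ", object@k, ", seed = ",
      object@seed, "\n", sep = "")
  invisible(NULL)
})
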