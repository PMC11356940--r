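#' Tanimoto similarity between two fingerprints
#'
#' Computes the Tanimoto coefficient \eqn{T_{ab} = |F_a \cap F_b| / |F_a \cup
#' F_b|} between the feature sets of two fingerprints. This is the Jaccard
#' index over fingerprint bits and the standard similarity measure in
#' ligand-based virtual screening: 1 means identical fingerprints (not
#' necessarily identical compounds), 0 means disjoint fingerprints.
#'
#' Both fingerprints must follow the same convention: comparing a folded
#' fingerprint against one folded to a different length is an error, and
#' comparing fingerprints from different sources triggers a warning (scores
#' across featurizations are not comparable). The Tanimoto coefficient of two
#' empty feature sets is undefined; an error is raised rather than silently
#' returning a conventional value, since empty fingerprints almost always
#' indicate an upstream featurization bug.
#'
#' @param fpA,fpB [Fingerprint-class] objects.
#' @return A similarity value in \[0, 1\]; symmetric in its arguments.
#' @seealso [lingoFingerprint()], [foldFingerprint()]
#' @examples
#' a <- Fingerprint(c(1, 2, 3))
#' b <- Fingerprint(c(2, 3, 4))
#' tanimoto(a, b)  # 2 shared / 4 total = 0.5
#' @export
setGeneric("tanimoto", function(fpA, fpB) standardGeneric("tanimoto"))

#' Fold a fingerprint to a fixed bit-vector length
#'
#' Maps every feature to a bit position in `[0, length)` and returns the
#' folded fingerprint. Integer features map by value modulo `length`;
#' string features are first hashed with a fixed, platform-independent
#' polynomial hash (djb2 accumulated modulo 2^31) so folded results are
#' reproducible across sessions and machines. Folding can only merge
#' features, never create them, so the folded set is never larger than the
#' original.
#'
#' @param fp A [Fingerprint-class].
#' @param length Positive integer, the folded bit-vector length.
#' @return A [Fingerprint-class] with integer-position features and its
#'   `length` slot set.
#' @examples
#' fp <- Fingerprint(c(0, 1024), length = 2048)
#' foldFingerprint(fp, 1024)  # positions collapse to {0}
#' @export
setGeneric("foldFingerprint", function(fp, length) standardGeneric("foldFingerprint"))

#' @rdname Fingerprint-class
#' @param x,object A `Fingerprint`.
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname ScoredSet-class
#' @export
setGeneric("nActives", function(x) standardGeneric("nActives"))

#' @rdname ScoredSet-class
#' @export
setGeneric("nDecoys", function(x) standardGeneric("nDecoys"))

#' @rdname ScoredSet-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname ScoredSet-class
#' @export
setGeneric("scoreLabels", function(x) standardGeneric("scoreLabels"))

#' @rdname TargetBenchmark-class
#' @export
setGeneric("targetId", function(x) standardGeneric("targetId"))

#' @rdname TargetBenchmark-class
#' @export
setGeneric("activeIds", function(x) standardGeneric("activeIds"))

#' @rdname TargetBenchmark-class
#' @export
setGeneric("decoyIds", function(x) standardGeneric("decoyIds"))

#' @rdname TargetBenchmark-class
#' @export
setGeneric("ac50", function(x) standardGeneric("ac50"))
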