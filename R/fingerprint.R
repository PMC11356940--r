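#' @include AllClasses.R
NULL

# djb2 polynomial hash, accumulated modulo 2^31 so every intermediate stays
# exactly representable in a double. Fixed constants -> identical folds on
# every platform and session (unlike R's internal randomized hashing).
.stringHash <- function(s) {
  m <- 2147483648  # 2^31
  vapply(s, function(one) {
    h <- 5381
    for (code in utf8ToInt(one)) h <- (h * 33 + code) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' LINGO features of a SMILES string
#'
#' Fragments a SMILES string into its set of overlapping substrings
#' (q-grams), the text-based LINGO fingerprint. The string is treated
#' purely as text — no molecular graph is built. Before fragmentation,
#' every ring-closure digit `0`-`9` is normalized to `0`, so that e.g.
#' `c1ccccc1` and `c2ccccc2` yield identical features; no other
#' canonicalization is attempted. If the normalized string is shorter than
#' `q`, the single-element set containing the whole string is returned.
#'
#' @param smiles Non-empty SMILES string.
#' @param q Substring length, a positive integer (default 4, the choice of
#'   the original LINGO method).
#' @return Character vector of distinct q-grams (set semantics, sorted).
#' @examples
#' lingoFeatures("c1ccccc1")        # 4-grams of "c0ccccc0"
#' lingoFeatures("CCO")             # shorter than q: the whole string
#' @export
lingoFeatures <- function(smiles, q = 4L) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("'smiles' must be a single non-empty string")
  q <- as.integer(q)
  if (is.na(q) || q < 1L) stop("'q' must be a positive integer")
  s <- gsub("[0-9]", "0", smiles)
  n <- nchar(s)
  if (n <= q) return(s)
  grams <- substring(s, seq_len(n - q + 1L), seq_len(n - q + 1L) + q - 1L)
  sort(unique(grams), method = "radix")
}

#' @rdname lingoFeatures
#' @return `lingoFingerprint()` wraps the feature set in a
#'   [Fingerprint-class] tagged `source = "lingo"`.
#' @export
lingoFingerprint <- function(smiles, q = 4L) {
  Fingerprint(lingoFeatures(smiles, q), source = "lingo")
}

#' LINGO similarity of two SMILES strings
#'
#' Convenience wrapper computing the Tanimoto coefficient between the
#' LINGO feature sets of two SMILES strings. With `multiset = TRUE` the
#' q-grams are counted rather than collected into a set, and the
#' generalized Tanimoto \eqn{\sum_g \min(c_a(g), c_b(g)) / \sum_g
#' \max(c_a(g), c_b(g))} over q-gram counts is returned; the default is
#' set semantics, uniform with binary bit-vector fingerprints.
#'
#' @inheritParams lingoFeatures
#' @param smilesA,smilesB SMILES strings.
#' @param multiset Logical; count q-gram multiplicities?
#' @return Similarity in \[0, 1\].
#' @export
lingoSim <- function(smilesA, smilesB, q = 4L, multiset = FALSE) {
  if (!multiset)
    return(tanimoto(lingoFingerprint(smilesA, q), lingoFingerprint(smilesB, q)))
  gramCounts <- function(smiles) {
    s <- gsub("[0-9]", "0", smiles)
    n <- nchar(s)
    g <- if (n <= q) s else
      substring(s, seq_len(n - q + 1L), seq_len(n - q + 1L) + q - 1L)
    table(g)
  }
  ca <- gramCounts(smilesA); cb <- gramCounts(smilesB)
  keys <- union(names(ca), names(cb))
  a <- ifelse(keys %in% names(ca), ca[keys], 0)
  b <- ifelse(keys %in% names(cb), cb[keys], 0)
  sum(pmin(a, b)) / sum(pmax(a, b))
}

#' @rdname tanimoto
#' @export
setMethod("tanimoto", signature("Fingerprint", "Fingerprint"),
  function(fpA, fpB) {
    la <- fpA@length; lb <- fpB@length
    if (!is.na(la) && !is.na(lb) && la != lb)
      stop("cannot compare fingerprints folded to different lengths (",
           la, " vs ", lb, ")")
    if (xor(is.na(la), is.na(lb)))
      stop("cannot compare a folded fingerprint with an unfolded one")
    if (fpA@source != fpB@source)
      warning("comparing fingerprints from different sources ('",
              fpA@source, "' vs '", fpB@source, "')")
    a <- fpA@features; b <- fpB@features
    if (length(a) == 0L && length(b) == 0L)
      stop("Tanimoto of two empty fingerprints is undefined")
    inter <- sum(a %in% b)
    inter / (length(a) + length(b) - inter)
  })

#' @rdname foldFingerprint
#' @export
setMethod("foldFingerprint", signature("Fingerprint", "numeric"),
  function(fp, length) {
    len <- as.integer(length)
    if (is.na(len) || len < 1L) stop("'length' must be a positive integer")
    f <- fp@features
    isInt <- grepl("^[0-9]+$", f)
    vals <- numeric(base::length(f))
    vals[isInt] <- as.numeric(f[isInt]) %% len
    if (any(!isInt)) vals[!isInt] <- .stringHash(f[!isInt]) %% len
    Fingerprint(vals, length = len, source = fp@source)
  })
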