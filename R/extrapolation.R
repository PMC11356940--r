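#' @include AllClasses.R
NULL

.checkNonNeg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop("'", name, "' must be a single non-negative number")
  invisible(x)
}

#' Expected decoy load of a score-filtered screen, from a measured DRF
#'
#' For a screening library of `librarySize` molecules (taken as almost
#' entirely inactive), thresholding at the score that recovers a fraction
#' `p` of actives leaves about `librarySize * p * drf` decoys mixed with
#' the surviving actives. A random scorer (DRF = 1) leaves `p` of the
#' library; enrichment (DRF < 1) shrinks this proportionally. The
#' arithmetic is what makes DRF useful for planning: apparently strong
#' 10- or 100-fold enrichment can still leave millions of false matches
#' when the library holds billions of candidates.
#'
#' @param librarySize Number of molecules screened (N >= 1).
#' @param p Active-recovery fraction in (0, 1\].
#' @param drf Measured decoy retention factor (non-negative).
#' @return Expected decoy count, real-valued (not rounded).
#' @examples
#' expectedDecoysGivenDrf(1e6, 0.1, 0.05)   # 5000
#' expectedDecoysGivenDrf(1e9, 0.1, 0.09)   # 9 million
#' @export
expectedDecoysGivenDrf <- function(librarySize, p, drf) {
  .checkNonNeg(librarySize, "librarySize")
  if (librarySize < 1) stop("'librarySize' must be >= 1")
  .checkNonNeg(drf, "drf")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop("'p' must lie in (0, 1]")
  librarySize * p * drf
}

#' Expected decoy load from a decoy pass fraction
#'
#' When a fraction of benchmark decoys survives a similarity cutoff,
#' scaling that fraction to a large library gives the expected number of
#' surviving inactives: `librarySize * decoyPassFraction`.
#'
#' @param librarySize Number of molecules screened.
#' @param decoyPassFraction Fraction of decoys at or above the cutoff, in
#'   \[0, 1\].
#' @return Expected decoy count.
#' @examples
#' expectedDecoysAtThreshold(3.7e9, 0.0064)  # ~23.7 million
#' @export
expectedDecoysAtThreshold <- function(librarySize, decoyPassFraction) {
  .checkNonNeg(librarySize, "librarySize")
  .checkNonNeg(decoyPassFraction, "decoyPassFraction")
  if (decoyPassFraction > 1) stop("'decoyPassFraction' must lie in [0, 1]")
  librarySize * decoyPassFraction
}

#' Active-to-decoy ratio of a filtered result set
#'
#' Expresses a filtered screen's composition as `1:k`, with
#' `k = expectedDecoys / nActivesPassing`. The raw ratio is kept exactly;
#' `kRounded` rounds to the nearest thousand for display (the precision at
#' which such ratios are usually quoted) and `label` formats it.
#'
#' @param nActivesPassing Count of actives surviving the cutoff (>= 1).
#' @param expectedDecoys Expected decoy count at the same cutoff.
#' @return A list with elements `k` (exact), `kRounded`, and `label`
#'   (e.g. `"1:56,000"`).
#' @examples
#' activeDecoyRatio(423, 23680000)$label  # "1:56,000"
#' @export
activeDecoyRatio <- function(nActivesPassing, expectedDecoys) {
  .checkNonNeg(expectedDecoys, "expectedDecoys")
  if (!is.numeric(nActivesPassing) || length(nActivesPassing) != 1L ||
      is.na(nActivesPassing) || nActivesPassing < 1)
    stop("ratio undefined: 'nActivesPassing' must be >= 1")
  k <- expectedDecoys / nActivesPassing
  kRounded <- round(k / 1000) * 1000
  list(k = k, kRounded = kRounded,
       label = paste0("1:", formatC(kRounded, format = "d", big.mark = ",")))
}

#' Fold enrichment implied by a DRF
#'
#' A decoy retention factor of `drf` corresponds to a `1/drf`-fold
#' reduction in decoys relative to random retention: DRF 0.2 is a 5-fold
#' reduction, DRF 0.09 about 11-fold. A DRF of exactly 0 means unbounded
#' enrichment; `Inf` is returned as the distinguished value.
#'
#' @param drf Measured decoy retention factor (non-negative).
#' @return `1/drf`, or `Inf` when `drf` is 0.
#' @examples
#' foldEnrichment(0.2)   # 5
#' foldEnrichment(0.09)  # ~11.1
#' @export
foldEnrichment <- function(drf) {
  .checkNonNeg(drf, "drf")
  if (drf == 0) return(Inf)
  1 / drf
}

#' Library-scale extrapolation report
#'
#' Combines the extrapolation arithmetic into one record: expected decoy
#' count (from a DRF or from a decoy pass fraction), the implied
#' active-to-decoy ratio when an active count is supplied, and the fold
#' enrichment when a DRF is supplied. Counts are additionally reported
#' rounded to three significant figures for display; raw values are
#' always retained.
#'
#' @param librarySize Number of molecules screened.
#' @param p,drf Supply both to extrapolate from a measured DRF.
#' @param passFraction Supply instead of `p`/`drf` to extrapolate from a
#'   decoy pass fraction at a similarity cutoff.
#' @param activesPassing Optional count of actives surviving the cutoff.
#' @return A list with `expectedDecoys`, `expectedDecoysRounded` (3
#'   significant figures), and, when computable, `foldEnrichment` and
#'   `ratio` (see [activeDecoyRatio()]).
#' @examples
#' extrapolate(3.7e9, passFraction = 0.0064, activesPassing = 423)
#' extrapolate(1e6, p = 0.1, drf = 0.05)
#' @export
extrapolate <- function(librarySize, p = NULL, drf = NULL,
                        passFraction = NULL, activesPassing = NULL) {
  fromDrf <- !is.null(p) && !is.null(drf)
  if (!fromDrf && is.null(passFraction))
    stop("supply either (p, drf) or passFraction")
  expected <- if (fromDrf) expectedDecoysGivenDrf(librarySize, p, drf)
              else expectedDecoysAtThreshold(librarySize, passFraction)
  out <- list(expectedDecoys = expected,
              expectedDecoysRounded = signif(expected, 3))
  if (fromDrf) out$foldEnrichment <- foldEnrichment(drf)
  if (!is.null(activesPassing))
    out$ratio <- activeDecoyRatio(activesPassing, expected)
  out
}
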