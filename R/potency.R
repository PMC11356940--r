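#' @include AllClasses.R
NULL

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall rank correlation between two equal-length
#' vectors: the difference between concordant and discordant pair counts,
#' normalized by the geometric mean of the tie-adjusted pair counts.
#' Delegates to `stats::cor(..., method = "kendall")`, which implements
#' exactly this tau-b statistic; the wrapper adds the input validation the
#' screening context needs — a constant vector leaves the correlation
#' undefined and is reported as an error rather than `NA`, since it
#' usually means a degenerate similarity column or a single repeated
#' potency.
#'
#' @param x,y Numeric vectors of equal length (>= 2), each with at least
#'   two distinct values.
#' @return Tau in \[-1, 1\].
#' @examples
#' kendallTau(c(1, 2, 3), c(3, 1, 2))  # -1/3
#' @export
kendallTau <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("at least two observations are required")
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite and free of NA")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: input vector is constant")
  unname(stats::cor(x, y, method = "kendall"))
}

#' Similarity-to-most-potent versus potency, for one target
#'
#' Builds the record table behind a similarity-potency correlation: the
#' most potent active (minimal AC50, ties broken by id) serves as the
#' query, and every *other* active with a recorded AC50 contributes one
#' record holding its Tanimoto similarity to the query and its AC50.
#' Decoys carry no potency and are excluded. At least two
#' potency-bearing actives are required (a query plus one record).
#'
#' @param benchmark A [TargetBenchmark-class] with AC50 data.
#' @param fingerprints Named list of [Fingerprint-class] covering the
#'   potency-bearing actives.
#' @return A data.frame with columns `moleculeId`, `similarity`, `ac50`,
#'   plus attribute `queryId`.
#' @export
potencySimilarityTable <- function(benchmark, fingerprints) {
  stopifnot(methods::is(benchmark, "TargetBenchmark"))
  ac <- benchmark@ac50
  has <- !is.na(ac)
  if (sum(has) < 2L)
    stop("target '", benchmark@targetId,
         "' has fewer than 2 potency-bearing actives")
  ids <- benchmark@activeIds[has]
  acv <- ac[has]
  query <- ids[order(acv, ids)][1L]
  others <- setdiff(ids, query)
  missing <- setdiff(c(query, others), names(fingerprints))
  if (length(missing))
    stop("missing fingerprints for: ", paste(missing, collapse = ", "))
  qfp <- fingerprints[[query]]
  out <- data.frame(
    moleculeId = others,
    similarity = vapply(others, function(id) tanimoto(qfp, fingerprints[[id]]),
                        numeric(1), USE.NAMES = FALSE),
    ac50 = acv[match(others, ids)])
  attr(out, "queryId") <- query
  out
}

#' Kendall correlation heatmap over fingerprints and targets
#'
#' Computes, for every (fingerprint set, target) cell, the Kendall tau
#' between similarity-to-the-most-potent-active and AC50, together with
#' the number of actives entering each cell (small cells are prone to
#' stochastic correlation estimates, so the sample size is always
#' reported alongside tau). Cells where tau is undefined — constant
#' similarities or potencies, or too few potency-bearing actives — are
#' `NA`, never silently zero.
#'
#' Sign convention: similarity is correlated with raw AC50, so a
#' *negative* tau means higher similarity goes with lower AC50, i.e. with
#' more potent compounds. Rank correlation is invariant to monotone
#' transforms of either variable, so using log-AC50 would only flip
#' nothing and change nothing.
#'
#' @param benchmarks Named list of [TargetBenchmark-class].
#' @param fingerprintSets Named list of fingerprint libraries (each a
#'   named list of [Fingerprint-class]), one per fingerprint type; a
#'   single library is accepted and labelled `"fp"`.
#' @return A list with `tau` and `nActives` matrices (fingerprint rows,
#'   target columns).
#' @export
correlationHeatmap <- function(benchmarks, fingerprintSets) {
  if (length(fingerprintSets) && methods::is(fingerprintSets[[1L]], "Fingerprint"))
    fingerprintSets <- list(fp = fingerprintSets)
  tnames <- vapply(benchmarks, targetId, character(1))
  fnames <- names(fingerprintSets)
  tau <- matrix(NA_real_, nrow = length(fnames), ncol = length(tnames),
                dimnames = list(fnames, tnames))
  nAct <- tau
  for (f in fnames) {
    for (i in seq_along(benchmarks)) {
      cell <- tryCatch({
        tab <- potencySimilarityTable(benchmarks[[i]], fingerprintSets[[f]])
        list(tau = kendallTau(tab$similarity, tab$ac50), n = nrow(tab) + 1L)
      }, error = function(e) NULL)
      if (!is.null(cell)) {
        tau[f, tnames[i]] <- cell$tau
        nAct[f, tnames[i]] <- cell$n
      }
    }
  }
  list(tau = tau, nActives = nAct)
}
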