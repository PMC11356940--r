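#' @include AllClasses.R
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards; with seed = NULL the global stream is used.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.queryModes <- c("all_actives", "random_active", "best_affinity", "most_potent")

# Query actives for a benchmark under the given mode. best_affinity and
# most_potent both resolve to minimal AC50 (lower concentration = stronger
# activity), ties broken by lexicographic id for reproducibility.
.selectQueries <- function(benchmark, mode, seed = NULL) {
  mode <- match.arg(mode, .queryModes)
  acts <- benchmark@activeIds
  switch(mode,
    all_actives = acts,
    random_active = .withSeed(seed, acts[sample.int(length(acts), 1L)]),
    best_affinity = ,
    most_potent = {
      ac <- benchmark@ac50
      if (all(is.na(ac)))
        stop("query mode '", mode, "' requires AC50 potencies, but target '",
             benchmark@targetId, "' has none")
      pool <- acts[!is.na(ac)]
      pool[order(ac[!is.na(ac)], pool)][1L]
    })
}

#' Query-versus-library similarity scores for one target
#'
#' Runs the core similarity-screening step for one protein target: selects
#' query active(s) according to `queryMode`, and scores each query against
#' every *other* molecule of the target (all remaining actives plus all
#' decoys) with [tanimoto()]. Self-pairs are always excluded — scoring a
#' query against itself would inject a guaranteed similarity of 1 for an
#' active and bias every enrichment metric. In `all_actives` mode both
#' directions of each active-active pair are retained (a scored against b,
#' and b against a), since each query contributes its full candidate
#' block.
#'
#' @param benchmark A [TargetBenchmark-class].
#' @param fingerprints Named list of [Fingerprint-class] covering every
#'   molecule id in the benchmark (missing ids are an error, all listed).
#' @param queryMode One of `"all_actives"` (every active queries in turn),
#'   `"random_active"` (one active chosen under `seed`),
#'   `"best_affinity"`/`"most_potent"` (the active with minimal AC50; the
#'   two names are synonyms for the same selection).
#' @param seed Integer seed for `random_active` mode; ignored otherwise.
#' @return A pair-table data.frame with columns `targetId`, `queryId`,
#'   `candidateId`, `score`, `label`; one row per (query, candidate) pair.
#' @export
computePairScores <- function(benchmark, fingerprints,
                              queryMode = "all_actives", seed = NULL) {
  stopifnot(methods::is(benchmark, "TargetBenchmark"))
  allIds <- c(benchmark@activeIds, benchmark@decoyIds)
  missing <- setdiff(allIds, names(fingerprints))
  if (length(missing))
    stop("missing fingerprints for ", length(missing), " molecule(s): ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  queries <- .selectQueries(benchmark, queryMode, seed)
  lab <- stats::setNames(rep(c("active", "decoy"),
                             c(length(benchmark@activeIds),
                               length(benchmark@decoyIds))), allIds)
  blocks <- lapply(queries, function(q) {
    cand <- setdiff(allIds, q)
    qfp <- fingerprints[[q]]
    data.frame(targetId = benchmark@targetId, queryId = q,
               candidateId = cand,
               score = vapply(cand, function(cid)
                 tanimoto(qfp, fingerprints[[cid]]), numeric(1),
                 USE.NAMES = FALSE),
               label = unname(lab[cand]))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Pooled enrichment metrics for one target
#'
#' Pools all rows of a pair table (the union over queries) into a single
#' [ScoredSet-class] and computes ROC AUC and the decoy retention factor
#' at the stated `p`. Pooling before scoring — rather than averaging
#' per-query metrics — treats the merged, similarity-sorted list as the
#' screening result, the operational view of a similarity screen.
#'
#' @param pairs A pair-table data.frame (see [computePairScores()]); must
#'   contain both labels.
#' @param p Active-recovery fraction passed to [drf()].
#' @return A list with elements `auc` (numeric) and `drf`
#'   ([DRFResult-class]).
#' @export
evaluateTarget <- function(pairs, p = 0.1) {
  if (!nrow(pairs)) stop("empty pair table")
  set <- ScoredSet(pairs$score, pairs$label)
  if (nActives(set) < 1L || nDecoys(set) < 1L)
    stop("pair table must contain both active and decoy rows")
  list(auc = rocAuc(set), drf = drf(set, p))
}

#' Aggregate per-target metrics across a benchmark
#'
#' Computes, for each fingerprint, the unweighted arithmetic mean of the
#' per-target AUC and DRF values — the summary row of a benchmark report
#' table. Per-target rows are retained; mean rows carry `target = "MEAN"`.
#'
#' @param perTarget A data.frame with columns `fingerprint`, `target`,
#'   `auc`, `drf` (one row per fingerprint-target pair).
#' @return A data.frame of the same shape with one `MEAN` row appended
#'   per fingerprint, rows sorted by fingerprint name then target, mean
#'   rows last within each fingerprint.
#' @export
summarizeBenchmark <- function(perTarget) {
  stopifnot(is.data.frame(perTarget),
            all(c("fingerprint", "target", "auc", "drf") %in% names(perTarget)))
  if (!nrow(perTarget)) stop("no per-target rows to summarize")
  out <- do.call(rbind, lapply(sort(unique(perTarget$fingerprint)), function(f) {
    rows <- perTarget[perTarget$fingerprint == f, , drop = FALSE]
    rows <- rows[order(rows$target), , drop = FALSE]
    rbind(rows, data.frame(fingerprint = f, target = "MEAN",
                           auc = mean(rows$auc), drf = mean(rows$drf)))
  }))
  rownames(out) <- NULL
  out
}

#' Per-label histogram of similarity scores
#'
#' Bins the scores of a pair table into `bins` equal-width bins on
#' \[0, 1\], separately for actives and decoys — the tabular form of the
#' overlapping active/decoy similarity distributions. The last bin is
#' closed on the right, so counts sum to the per-label totals.
#'
#' @param pairs A pair-table data.frame with scores in \[0, 1\].
#' @param bins Positive integer number of bins.
#' @return A data.frame with columns `binStart`, `binEnd`, `activeCount`,
#'   `decoyCount`.
#' @export
similarityDistribution <- function(pairs, bins = 20L) {
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1L) stop("'bins' must be a positive integer")
  if (any(pairs$score < 0 | pairs$score > 1))
    stop("similarity scores must lie in [0, 1]")
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(pairs$score, edges, rightmost.closed = TRUE), 1L),
              bins)
  act <- tabulate(idx[pairs$label == "active"], nbins = bins)
  dec <- tabulate(idx[pairs$label == "decoy"], nbins = bins)
  data.frame(binStart = edges[-length(edges)], binEnd = edges[-1L],
             activeCount = act, decoyCount = dec)
}

#' Run the full screening evaluation over a benchmark
#'
#' The end-to-end evaluation: for each target, compute query-candidate
#' similarities under the chosen query mode, pool, and score with
#' [evaluateTarget()]; then aggregate the per-target metrics into mean
#' rows with [summarizeBenchmark()]. Provenance (query mode, `p`, seed,
#' pooling convention) is recorded in the report header so a report is
#' interpretable on its own.
#'
#' @param benchmarks Named list of [TargetBenchmark-class].
#' @param fingerprints Named list of [Fingerprint-class] covering all
#'   molecules, or a named list of such lists (one per fingerprint type,
#'   names used as the `fingerprint` column).
#' @param queryMode,seed,p See [computePairScores()] and [drf()].
#' @param fingerprintName Label for the single-fingerprint case, default
#'   `"fp"`.
#' @return A report list with elements `provenance`, `perTarget` (list of
#'   per-target records with n, d, x, sp, dp, auc, drf), and `summary`
#'   (per-fingerprint means). Serialize with [writeReport()].
#' @examples
#' spec <- SyntheticSpec(nTargets = 2L, nActives = 8L, nDecoys = 60L)
#' sim <- simulateBenchmark(spec)
#' rep <- runBenchmark(sim$benchmarks, sim$fingerprints, p = 0.1, seed = 7)
#' rep$summary
#' @export
runBenchmark <- function(benchmarks, fingerprints, queryMode = "all_actives",
                         p = 0.1, seed = NULL, fingerprintName = "fp") {
  single <- length(fingerprints) && methods::is(fingerprints[[1L]], "Fingerprint")
  fpSets <- if (single) stats::setNames(list(fingerprints), fingerprintName)
            else fingerprints
  perTarget <- list()
  for (fpName in names(fpSets)) {
    for (tb in benchmarks) {
      pairs <- computePairScores(tb, fpSets[[fpName]], queryMode, seed)
      m <- evaluateTarget(pairs, p)
      r <- m$drf
      perTarget[[length(perTarget) + 1L]] <- list(
        fingerprint = fpName, target = tb@targetId,
        n = r@n, d = r@d, x = r@x, sp = r@sp, dp = r@dp,
        auc = m$auc, drf = r@value)
    }
  }
  flat <- data.frame(
    fingerprint = vapply(perTarget, `[[`, character(1), "fingerprint"),
    target = vapply(perTarget, `[[`, character(1), "target"),
    auc = vapply(perTarget, `[[`, numeric(1), "auc"),
    drf = vapply(perTarget, `[[`, numeric(1), "drf"))
  summ <- summarizeBenchmark(flat)
  summ <- summ[summ$target == "MEAN", c("fingerprint", "auc", "drf")]
  rownames(summ) <- NULL
  list(
    provenance = list(
      package = "fpscreen", queryMode = queryMode, p = p,
      seed = if (is.null(seed)) NA else as.integer(seed),
      pooling = "per-target pooled over queries; symmetric active-active pairs retained; self-pairs excluded"),
    perTarget = perTarget,
    summary = summ)
}
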