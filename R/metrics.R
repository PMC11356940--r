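#' @include AllClasses.R
NULL

.checkScoredSet <- function(x, needBoth = TRUE) {
  if (!methods::is(x, "ScoredSet")) stop("expected a ScoredSet")
  if (needBoth && (nActives(x) < 1L || nDecoys(x) < 1L))
    stop("metric requires at least one active and one decoy")
  invisible(x)
}

#' Decoy retention factor
#'
#' The decoy retention factor DRF_p measures how effectively decoys are
#' filtered out of the score range containing the top fraction `p` of
#' active molecules. With `n` actives and `d` decoys, let
#' `x = ceiling(p * n)` and let `sp` be the score of the x-th highest
#' active — the threshold that recovers the fraction `p` of actives. With
#' `dp` the number of decoys scoring strictly above `sp`,
#' \deqn{DRF_p = d_p / \lfloor p \, d \rfloor .}
#'
#' A random scorer retains about `p * d` decoys above `sp`, giving
#' DRF close to 1; an ideal scorer gives 0; values above 1 mean the
#' scorer enriches for decoys. Unlike many early-enrichment metrics, the
#' value generalizes across set sizes, which also makes it usable for
#' library-scale planning (see [expectedDecoysGivenDrf()]).
#'
#' Ties: `sp` is the score of the x-th element of the descending active
#' score list, duplicates included; decoys scoring exactly `sp` do not
#' count toward `dp` ("exceed" is read strictly).
#'
#' @param scoredSet A [ScoredSet-class] with at least one record of each
#'   label.
#' @param p Active-recovery fraction in (0, 1), default 0.1. Must satisfy
#'   `floor(p * d) >= 1`, otherwise there are too few decoys for this `p`.
#' @return A [DRFResult-class].
#' @examples
#' set <- ScoredSet(score = c(rep(1, 10), rep(0.5, 10)),
#'                  label = rep(c("active", "decoy"), each = 10))
#' drf(set, p = 0.1)  # perfect separation: DRF = 0
#' @export
drf <- function(scoredSet, p = 0.1) {
  .checkScoredSet(scoredSet)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("'p' must be a single fraction in (0, 1)")
  act <- scoredSet@score[scoredSet@label == "active"]
  dec <- scoredSet@score[scoredSet@label == "decoy"]
  n <- length(act); d <- length(dec)
  x <- as.integer(ceiling(p * n))
  denom <- floor(p * d)
  if (denom < 1) stop("too few decoys for this p (floor(p * d) == 0)")
  sp <- sort(act, decreasing = TRUE)[x]
  dp <- sum(dec > sp)
  new("DRFResult", p = p, x = x, sp = sp, dp = as.integer(dp),
      n = as.integer(n), d = as.integer(d), value = dp / denom)
}

#' ROC AUC via Mann-Whitney rank sums
#'
#' The area under the ROC curve equals the probability that a uniformly
#' chosen active outscores a uniformly chosen decoy, with ties counted
#' one half. It is computed exactly from midranks:
#' \deqn{AUC = (R_a - n(n+1)/2) / (n d)}
#' where \eqn{R_a} is the rank sum of the actives. A perfect separator
#' gives 1, a random scorer 0.5.
#'
#' @inheritParams drf
#' @return AUC in \[0, 1\].
#' @examples
#' s <- ScoredSet(score = c(.9, .4, .5, .3),
#'                label = c("active", "active", "decoy", "decoy"))
#' rocAuc(s)  # 3 of 4 active-decoy pairs concordant: 0.75
#' @export
rocAuc <- function(scoredSet) {
  .checkScoredSet(scoredSet)
  act <- scoredSet@label == "active"
  n <- sum(act); d <- sum(!act)
  r <- rank(scoredSet@score, ties.method = "average")
  (sum(r[act]) - n * (n + 1) / 2) / (n * d)
}

#' Per-label survival fractions at similarity cutoffs
#'
#' For each cutoff `c`, the fraction of actives and of decoys with score
#' `>= c` — the quantity plotted as cutoff-survival bars when asking how
#' many molecules of each class remain above increasingly strict
#' similarity thresholds. Fractions are non-increasing in the cutoff.
#'
#' @inheritParams drf
#' @param cutoffs Numeric vector of cutoffs in \[0, 1\], sorted ascending.
#'   Default: 0.1, 0.2, ..., 0.9 and 0.99.
#' @return A data.frame with columns `cutoff`, `activeFraction`,
#'   `decoyFraction`.
#' @export
fractionAboveCutoffs <- function(scoredSet, cutoffs = c(seq(0.1, 0.9, 0.1), 0.99)) {
  .checkScoredSet(scoredSet)
  if (any(is.na(cutoffs)) || any(cutoffs < 0 | cutoffs > 1))
    stop("cutoffs must lie in [0, 1]")
  if (is.unsorted(cutoffs)) stop("cutoffs must be sorted ascending")
  act <- scoredSet@score[scoredSet@label == "active"]
  dec <- scoredSet@score[scoredSet@label == "decoy"]
  data.frame(
    cutoff = cutoffs,
    activeFraction = vapply(cutoffs, function(c) mean(act >= c), numeric(1)),
    decoyFraction = vapply(cutoffs, function(c) mean(dec >= c), numeric(1)))
}

#' Cumulative recovery curve over decreasing score thresholds
#'
#' The stepwise curve giving, at every distinct observed score threshold
#' `t` (in decreasing order), the fraction of actives and of decoys with
#' score `>= t`. Both fractions are non-decreasing along the curve and the
#' final point (at the minimum observed score) recovers everything. The
#' curve value at a threshold equals [fractionAboveCutoffs()] at that
#' cutoff.
#'
#' @inheritParams drf
#' @return A data.frame with columns `threshold`, `activeRecovered`,
#'   `decoyRecovered`.
#' @export
cumulativeRecoveryCurve <- function(scoredSet) {
  .checkScoredSet(scoredSet)
  thr <- sort(unique(scoredSet@score), decreasing = TRUE)
  act <- sort(scoredSet@score[scoredSet@label == "active"], decreasing = TRUE)
  dec <- sort(scoredSet@score[scoredSet@label == "decoy"], decreasing = TRUE)
  n <- length(act); d <- length(dec)
  data.frame(
    threshold = thr,
    activeRecovered = vapply(thr, function(t) sum(act >= t), numeric(1)) / n,
    decoyRecovered = vapply(thr, function(t) sum(dec >= t), numeric(1)) / d)
}

#' BEDROC early-recognition score
#'
#' The Boltzmann-enhanced discrimination of ROC: actives are weighted by
#' an exponential in their rank so that early recognition dominates.
#' With `N = n + d` records, active ranks `r_i` on the descending-score
#' ordering, and `Ra = n / N`:
#' \deqn{RIE = \frac{\frac{1}{n}\sum_i e^{-\alpha r_i / N}}
#'   {\frac{1}{N} \frac{1 - e^{-\alpha}}{e^{\alpha/N} - 1}}}
#' \deqn{BEDROC = RIE \cdot \frac{R_a \sinh(\alpha/2)}
#'   {\cosh(\alpha/2) - \cosh(\alpha/2 - \alpha R_a)}
#'   + \frac{1}{1 - e^{\alpha (1 - R_a)}}.}
#' Values lie in \[0, 1\]; `alpha` sets how sharply the weight
#' concentrates at the top (with the default 20, 80 percent of the weight
#' sits in the top ~8 percent of the list). Tied scores are handled
#' exactly: within a tied block the expected exponential weight under a
#' uniform random ordering of the block is used.
#'
#' BEDROC and [sumLogRank()] are auxiliary metrics here; the primary
#' early-enrichment statistic of this package is [drf()].
#'
#' @inheritParams drf
#' @param alpha Positive weighting parameter, default 20.
#' @return BEDROC value in \[0, 1\].
#' @export
bedroc <- function(scoredSet, alpha = 20) {
  .checkScoredSet(scoredSet)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number")
  n <- nActives(scoredSet); N <- length(scoredSet@score)
  w <- .tieAveragedActiveSum(scoredSet, function(r) exp(-alpha * r / N))
  rie <- (w / n) / ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  ra <- n / N
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Sum of log ranks of the actives
#'
#' The sum over actives of `log(rank / N)` on the descending-score
#' ranking (`N = n + d`). More negative values mean earlier recognition.
#' Ties are averaged exactly over permutations of each tied block.
#'
#' @inheritParams drf
#' @return A real number (<= 0).
#' @export
sumLogRank <- function(scoredSet) {
  .checkScoredSet(scoredSet)
  N <- length(scoredSet@score)
  .tieAveragedActiveSum(scoredSet, function(r) log(r / N))
}

# Sum over actives of f(rank) on the descending-score ordering, with exact
# expectation under uniform permutation of tied blocks: a block spanning
# ranks r1..r2 holding t actives contributes t * mean(f(r1:r2)).
.tieAveragedActiveSum <- function(scoredSet, f) {
  ord <- order(scoredSet@score, decreasing = TRUE)
  sc <- scoredSet@score[ord]
  isAct <- scoredSet@label[ord] == "active"
  total <- 0
  i <- 1L
  N <- length(sc)
  while (i <= N) {
    j <- i
    while (j < N && sc[j + 1L] == sc[i]) j <- j + 1L
    t <- sum(isAct[i:j])
    if (t > 0) total <- total + t * mean(f(i:j))
    i <- j + 1L
  }
  total
}
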