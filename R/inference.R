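# Sample-level inference over per-participant correlation coefficients.

#' Sign counts of per-participant coefficients
#'
#' Exact zeros are counted separately and excluded from the binomial n;
#' undefined (`NA`) coefficients are excluded entirely.
#'
#' @param rhos numeric vector of per-participant coefficients (may contain
#'   `NA` for undefined values).
#' @return list with `nPos`, `nNeg`, `nZero`.
#' @export
signCounts <- function(rhos) {
  r <- rhos[!is.na(rhos)]
  list(nPos = sum(r > 0), nNeg = sum(r < 0), nZero = sum(r == 0))
}

#' Exact binomial point probability of a sign split
#'
#' The probability of obtaining exactly `k` positive and `m` negative signs
#' under a fair coin: `choose(k + m, k) * 0.5^(k + m)`, evaluated in log
#' space through the log-gamma function. Symmetric in `(k, m)`.
#'
#' @param k,m non-negative counts with `k + m >= 1`.
#' @return the point probability.
#' @export
binomialPointProbability <- function(k, m) {
  if (k < 0 || m < 0) stop("counts must be non-negative")
  if (k + m < 1) stop("need k + m >= 1")
  exp(lgamma(k + m + 1) - lgamma(k + 1) - lgamma(m + 1) - (k + m) * log(2))
}

#' Beta-binomial Bayesian sign test
#'
#' Directional sign test with a conjugate Beta prior on the proportion `phi`
#' of cases favouring the stated direction. With `k` cases in the direction
#' and `m` against (ties removed by the caller), the posterior is
#' `Beta(a0 + k, b0 + m)` and the Bayes factor is the posterior odds that
#' `phi > 0.5`, divided by the prior odds (1 under the default uniform
#' `Beta(1, 1)` prior). Tail probabilities are evaluated with the
#' regularized incomplete beta function (`stats::pbeta`).
#'
#' @param k,m non-negative counts, not both zero.
#' @param a0,b0 Beta prior parameters (default uniform).
#' @return the Bayes factor BF10 (possibly `Inf` when `m = 0` under a prior
#'   with no mass guard).
#' @export
signTestBF <- function(k, m, a0 = 1, b0 = 1) {
  if (k < 0 || m < 0) stop("counts must be non-negative")
  if (k + m < 1) stop("no information: k = m = 0")
  postUp <- pbeta(0.5, a0 + k, b0 + m, lower.tail = FALSE)
  postLo <- pbeta(0.5, a0 + k, b0 + m)
  priorUp <- pbeta(0.5, a0, b0, lower.tail = FALSE)
  priorLo <- pbeta(0.5, a0, b0)
  (postUp / postLo) / (priorUp / priorLo)
}

#' Bootstrap percentile confidence interval for a mean
#'
#' Arithmetic mean with a percentile interval over `reps` resamples with
#' replacement of size n, drawn from a seeded generator (deterministic for a
#' fixed seed).
#'
#' @param values numeric vector, n >= 2.
#' @param reps number of bootstrap resamples (>= 1).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `low`, `high`.
#' @export
bootstrapMeanCI <- function(values, reps = 10000L, seed = NULL, level = 0.95) {
  if (!length(values)) stop("empty input")
  if (length(values) < 2L) stop("need n >= 2")
  if (reps < 1L) stop("need reps >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  means <- colMeans(matrix(sample(values, n * reps, replace = TRUE), nrow = n))
  qs <- quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(mean = mean(values), low = qs[1], high = qs[2])
}

#' Gaussian kernel density estimate
#'
#' Plain Gaussian-kernel density, bandwidth by Silverman's rule of thumb
#' (`stats::bw.nrd0`); a reporting aid for visualizing the distribution of
#' per-participant coefficients.
#'
#' @param values numeric vector, n >= 2, non-constant.
#' @param grid evaluation grid; default covers the data plus 4 bandwidths on
#'   each side at 512 points.
#' @param bw bandwidth override.
#' @return list with `x` (grid), `y` (density values), `bw`.
#' @export
gaussianKde <- function(values, grid = NULL, bw = NULL) {
  if (length(values) < 2L) stop("need n >= 2")
  if (sd(values) == 0) stop("constant input: bandwidth rule degenerates")
  if (is.null(bw)) bw <- stats::bw.nrd0(values)
  if (is.null(grid))
    grid <- seq(min(values) - 4 * bw, max(values) + 4 * bw, length.out = 512L)
  y <- vapply(grid, function(g) mean(dnorm(g, mean = values, sd = bw)),
              numeric(1))
  list(x = grid, y = y, bw = bw)
}

#' Sample-level summary of per-participant associations
#'
#' For each measure-by-method-by-window cell of the association table:
#' the (bootstrapped) mean coefficient with percentile 95% limits, the sign
#' counts with the exact binomial point probability of the positive/negative
#' split, and — for adjusted methods — the beta-binomial sign-test Bayes
#' factor contrasting each participant's adjusted coefficient with their
#' unadjusted one (counting participants whose adjusted rho is lower versus
#' higher, ties excluded; `NA` when all pairs tie).
#'
#' Undefined coefficients (zero rank variance, non-converged ordinal fits)
#' are excluded from means, sign counts and paired comparisons.
#'
#' @param assoc association table from [computeAssociations()] (optionally
#'   row-bound with [computeBackgroundAssociations()]).
#' @param cfg an [AnalysisConfig-class]; supplies `bootstrapReps` and `seed`.
#' @param level confidence level for the bootstrap interval.
#' @return a `data.frame` with one row per summary cell: `measure`, `method`,
#'   `window`, `n`, `mean_rho`, `ci_low`, `ci_high`, `n_pos`, `n_neg`,
#'   `n_zero`, `p_binomial`, `n_lower`, `n_higher`, `n_ties`, `bf10`.
#' @export
summarizeSample <- function(assoc, cfg = analysisConfig(), level = 0.95) {
  set.seed(cfg@seed)
  cells <- unique(assoc[, c("measure", "method", "window")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    ms <- cells$measure[i]; md <- cells$method[i]; w <- cells$window[i]
    sel <- assoc$measure == ms & assoc$method == md &
      (if (is.na(w)) is.na(assoc$window) else !is.na(assoc$window) & assoc$window == w)
    a <- assoc[sel, ]
    rhos <- a$rho
    rhos[!a$converged] <- NA
    def <- rhos[!is.na(rhos)]
    if (length(def) < 2L) next
    ci <- bootstrapMeanCI(def, reps = cfg@bootstrapReps)
    sc <- signCounts(def)
    pb <- if (sc$nPos + sc$nNeg >= 1)
      binomialPointProbability(sc$nPos, sc$nNeg) else NA_real_
    nLower <- nHigher <- nTies <- NA_integer_
    bf <- NA_real_
    if (md != "unadjusted") {
      un <- assoc[assoc$measure == ms & assoc$method == "unadjusted", ]
      uMap <- stats::setNames(un$rho, un$participant)
      adj <- rhos
      base <- uMap[a$participant]
      ok <- !is.na(adj) & !is.na(base)
      nLower <- sum(adj[ok] < base[ok])
      nHigher <- sum(adj[ok] > base[ok])
      nTies <- sum(adj[ok] == base[ok])
      bf <- if (nLower + nHigher >= 1) signTestBF(nLower, nHigher) else NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      measure = ms, method = md, window = w, n = length(def),
      mean_rho = ci$mean, ci_low = ci$low, ci_high = ci$high,
      n_pos = sc$nPos, n_neg = sc$nNeg, n_zero = sc$nZero,
      p_binomial = pb, n_lower = nLower, n_higher = nHigher, n_ties = nTies,
      bf10 = bf, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
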