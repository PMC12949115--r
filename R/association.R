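# Per-participant association estimators: Spearman rho and its two
# covariate-adjusted (semi-partial) variants.

#' Mid-ranks
#'
#' Ranks with tied values receiving the mean of their rank positions, so that
#' the rank sum is always n(n+1)/2.
#'
#' @param v numeric vector, non-empty and finite.
#' @return numeric vector of mid-ranks in 1..n.
#' @export
averageRanks <- function(v) {
  if (!length(v)) stop("empty input")
  if (!all(is.finite(v))) stop("ranks require finite values")
  rank(v, ties.method = "average")
}

#' Spearman rank correlation
#'
#' Pearson product-moment correlation of mid-ranks. When either variable has
#' zero rank variance the coefficient is undefined and `NA` is returned
#' (callers treat `NA` as a flagged undefined value, never as silent
#' propagation).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return a value in `[-1, 1]`, or `NA` when undefined.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need n >= 3")
  rx <- averageRanks(x)
  ry <- averageRanks(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Yeo-Johnson power transformation
#'
#' The monotone power-family transform defined for all reals:
#' for `x >= 0`, `((x + 1)^lambda - 1) / lambda` (`log(x + 1)` at
#' `lambda = 0`); for `x < 0`, `-((1 - x)^(2 - lambda) - 1) / (2 - lambda)`
#' (`-log(1 - x)` at `lambda = 2`). Evaluated through `expm1()`/`log1p()`
#' so it is numerically continuous in `lambda` across both special points.
#'
#' @param x numeric vector.
#' @param lambda transform exponent.
#' @return transformed values, strictly increasing in `x`.
#' @export
yeoJohnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (any(pos)) {
    lx <- log1p(x[pos])
    out[pos] <- if (abs(lambda) < 1e-12) lx else expm1(lambda * lx) / lambda
  }
  if (any(!pos)) {
    lx <- log1p(-x[!pos])
    l2 <- 2 - lambda
    out[!pos] <- if (abs(l2) < 1e-12) -lx else -expm1(l2 * lx) / l2
  }
  out
}

#' Fit the Yeo-Johnson exponent by profile maximum likelihood
#'
#' Maximizes the Gaussian profile log-likelihood of the transformed data,
#' including the log-Jacobian term
#' `(lambda - 1) * sum(sign(x) * log(|x| + 1))`, over a fixed bracket using
#' one-dimensional golden-section/parabolic search (`stats::optimize`) with
#' tolerance 1e-6. Deterministic.
#'
#' @param x numeric vector, n >= 3, non-constant.
#' @param bracket search interval for the exponent (default `c(-5, 5)`).
#' @return list with `lambda` (the fitted exponent) and `loglik` (the profile
#'   log-likelihood at `lambda`).
#' @export
fitYeoJohnson <- function(x, bracket = c(-5, 5)) {
  if (length(x) < 3L) stop("need n >= 3")
  if (!all(is.finite(x))) stop("finite values required")
  if (sd(x) == 0) stop("constant input: Yeo-Johnson exponent is unidentified")
  n <- length(x)
  jac <- sum(sign(x) * log1p(abs(x)))
  prof <- function(lambda) {
    z <- yeoJohnson(x, lambda)
    s2 <- mean((z - mean(z))^2)
    if (!is.finite(s2) || s2 <= 0) return(-Inf)
    -n / 2 * log(s2) + (lambda - 1) * jac
  }
  opt <- optimize(prof, bracket, maximum = TRUE, tol = 1e-6)
  list(lambda = opt$maximum, loglik = opt$objective)
}

#' Ordinary least-squares residuals
#'
#' Residuals of `y` regressed on `c` with an intercept. Residuals sum to zero
#' and are orthogonal to `c`. Degenerate contract: when `c` is constant the
#' model collapses to the intercept and the centred `y` is returned.
#'
#' @param y response vector.
#' @param c covariate vector of the same length, n >= 3.
#' @return numeric residual vector.
#' @export
linearResiduals <- function(y, c) {
  if (length(y) != length(c)) stop("length mismatch")
  if (length(y) < 3L) stop("need n >= 3")
  if (sd(c) == 0) return(y - mean(y))
  lm.fit(cbind(1, c), y)$residuals
}

#' Parametric semi-partial Spearman correlation
#'
#' Each of the four variables is separately Yeo-Johnson transformed at its
#' own profile-ML exponent (intended to normalize the skewed sample
#' distributions); each transformed response is regressed on its own
#' transformed covariate by ordinary least squares; the two residual series
#' are then correlated with Spearman's method.
#'
#' @param x,y response series (e.g. MEP amplitudes per muscle), one value per
#'   trial.
#' @param cx,cy covariate series (e.g. background r.m.s. EMG per muscle).
#' @return Spearman correlation of the two residual series (`NA` when
#'   undefined).
#' @export
parametricSemipartial <- function(x, y, cx, cy) {
  tx <- yeoJohnson(x, fitYeoJohnson(x)$lambda)
  ty <- yeoJohnson(y, fitYeoJohnson(y)$lambda)
  tcx <- if (sd(cx) == 0) cx else yeoJohnson(cx, fitYeoJohnson(cx)$lambda)
  tcy <- if (sd(cy) == 0) cy else yeoJohnson(cy, fitYeoJohnson(cy)$lambda)
  spearmanRho(linearResiduals(tx, tcx), linearResiduals(ty, tcy))
}

# Negative log-likelihood machinery for the cumulative-logit model
# P(Y <= level j | x) = plogis(alpha_j - beta * x).

.clmLoglik <- function(theta, yIdx, x, J) {
  alpha <- theta[seq_len(J - 1L)]
  if (is.unsorted(alpha, strictly = TRUE)) return(-Inf)
  beta <- if (is.null(x)) 0 else theta[J]
  eta <- if (is.null(x)) 0 else beta * x
  up <- c(alpha, Inf)[yIdx] - eta
  lo <- c(-Inf, alpha)[yIdx] - eta
  p <- plogis(up) - plogis(lo)
  if (any(p <= 0)) return(-Inf)
  sum(log(p))
}

.clmGradient <- function(theta, yIdx, x, J) {
  alpha <- theta[seq_len(J - 1L)]
  beta <- if (is.null(x)) 0 else theta[J]
  eta <- if (is.null(x)) 0 else beta * x
  up <- c(alpha, Inf)[yIdx] - eta
  lo <- c(-Inf, alpha)[yIdx] - eta
  p <- plogis(up) - plogis(lo)
  fu <- dlogis(up)     # 0 at +Inf
  fl <- dlogis(lo)     # 0 at -Inf
  g <- numeric(length(theta))
  wu <- fu / p
  wl <- fl / p
  for (j in seq_len(J - 1L)) {
    g[j] <- sum(wu[yIdx == j]) - sum(wl[yIdx == j + 1L])
  }
  if (!is.null(x)) g[J] <- -sum(x * (fu - fl) / p)
  g
}

.clmHessian <- function(theta, yIdx, x, J) {
  # central finite differences of the analytic gradient
  k <- length(theta)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    h <- 1e-5 * (1 + abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    H[, i] <- (.clmGradient(tp, yIdx, x, J) - .clmGradient(tm, yIdx, x, J)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a cumulative-logit ordinal regression by maximum likelihood
#'
#' Cumulative-link model with logit link,
#' `P(Y <= level j | x) = plogis(alpha_j - beta * x)`, fitted by a Newton
#' ascent with step-halving: each proposed step is halved until the
#' log-likelihood increases and the intercepts remain strictly increasing.
#' With `J` distinct outcome levels there are `J - 1` ordered intercepts and
#' one slope; with all-distinct outcomes (`J = n`) the model is the fully
#' saturated rank parameterization. Starting values are the empirical
#' cumulative logits with zero slope.
#'
#' Convergence is declared when the gradient max-norm falls below `tol`
#' (default 1e-6). Parameter divergence beyond `bound` (default 30) — as
#' under complete separation, where the likelihood increases without bound —
#' terminates the ascent with `converged = FALSE` and `separation = TRUE`.
#'
#' @param y outcome vector (typically mid-ranks); tied values collapse to a
#'   single ordinal level; J >= 2 levels required.
#' @param x predictor vector (typically mid-ranks of the covariate), or
#'   `NULL` for the intercept-only (null) model. A constant predictor is
#'   rejected.
#' @param tol gradient max-norm convergence tolerance.
#' @param maxIter maximum Newton iterations.
#' @param bound parameter magnitude at which separation is declared.
#' @return list with `alpha` (ordered intercepts), `beta` (slope; 0 for the
#'   null model), `levels` (sorted distinct outcome values), `logLik`,
#'   `logLikPath` (log-likelihood after each accepted step), `converged`,
#'   `separation`, `iterations`.
#' @export
fitCumulativeLogit <- function(y, x = NULL, tol = 1e-6, maxIter = 100L,
                               bound = 30) {
  if (length(y) < 3L) stop("need n >= 3")
  if (!is.null(x)) {
    if (length(x) != length(y)) stop("length mismatch")
    if (sd(x) == 0) stop("constant predictor: slope is unidentified")
  }
  levels <- sort(unique(y))
  J <- length(levels)
  if (J < 2L) stop("outcome must have at least 2 distinct levels")
  yIdx <- match(y, levels)
  cumprop <- cumsum(tabulate(yIdx, J) / length(y))[seq_len(J - 1L)]
  theta <- c(qlogis(cumprop), if (!is.null(x)) 0)
  ll <- .clmLoglik(theta, yIdx, x, J)
  llPath <- ll
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    g <- .clmGradient(theta, yIdx, x, J)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- .clmHessian(theta, yIdx, x, J)
    dir <- tryCatch(solve(-H, g), error = function(e) g)  # fall back to ascent
    step <- 1
    repeat {
      cand <- theta + step * dir
      llc <- .clmLoglik(cand, yIdx, x, J)
      if (is.finite(llc) && llc > ll) {
        theta <- cand; ll <- llc; llPath <- c(llPath, ll); break
      }
      step <- step / 2
      if (step < 1e-12) break
    }
    if (step < 1e-12) {
      # no ascent possible along the Newton direction
      converged <- max(abs(g)) < sqrt(tol)
      break
    }
    if (max(abs(theta)) > bound) { separation <- TRUE; break }
  }
  if (!converged && iter >= maxIter && max(abs(theta)) > bound / 2)
    separation <- TRUE
  list(alpha = theta[seq_len(J - 1L)],
       beta = if (is.null(x)) 0 else theta[J],
       levels = levels, logLik = ll, logLikPath = llPath,
       converged = converged, separation = separation, iterations = iter)
}

#' Probability-scale residuals for an ordinal fit
#'
#' For an observation `y` under the fitted conditional distribution,
#' `r(y | x) = P(Y* < y | x) - P(Y* > y | x)`, which lies in `[-1, 1]` and is
#' strictly increasing in the rank of `y` at fixed `x`. Under the null
#' (intercept-only) model with all-distinct outcomes, the residual of the
#' observation with rank `r` is `(2r - n - 1) / n`.
#'
#' @param fit a fit returned by [fitCumulativeLogit()].
#' @param y outcome values; each must be one of `fit$levels`.
#' @param x predictor values (omit for a null-model fit).
#' @return numeric residuals in `[-1, 1]`.
#' @export
probabilityScaleResiduals <- function(fit, y, x = NULL) {
  j <- match(y, fit$levels)
  if (anyNA(j)) stop("outcome value not among the fitted levels")
  eta <- if (is.null(x)) 0 else fit$beta * x
  J <- length(fit$levels)
  lo <- c(-Inf, fit$alpha)[j] - eta     # P(Y* < y) = F(alpha_{j-1} - beta x)
  up <- c(fit$alpha, Inf)[j] - eta      # P(Y* > y) = 1 - F(alpha_j - beta x)
  plogis(lo) + plogis(up) - 1
}

#' Non-parametric (probability-scale residual) semi-partial correlation
#'
#' Entirely rank-based pipeline: all four variables are replaced by their
#' mid-ranks; per muscle, the ranked response is regressed on the ranked
#' covariate with a cumulative-logit ordinal model; probability-scale
#' residuals are extracted from each fit; and the two residual series are
#' correlated with Spearman's method. Invariant to any strictly monotone
#' transform of any input.
#'
#' @inheritParams parametricSemipartial
#' @return Spearman correlation of the two residual series; `NA` (with
#'   attribute `converged = FALSE`) when either ordinal fit fails to
#'   converge.
#' @export
psrSemipartial <- function(x, y, cx, cy) {
  rx <- averageRanks(x);  ry <- averageRanks(y)
  rcx <- averageRanks(cx); rcy <- averageRanks(cy)
  fx <- fitCumulativeLogit(rx, rcx)
  fy <- fitCumulativeLogit(ry, rcy)
  if (!fx$converged || !fy$converged) {
    out <- NA_real_
    attr(out, "converged") <- FALSE
    return(out)
  }
  ex <- probabilityScaleResiduals(fx, rx, rcx)
  ey <- probabilityScaleResiduals(fy, ry, rcy)
  out <- spearmanRho(ex, ey)
  attr(out, "converged") <- TRUE
  out
}

#' Per-participant association table
#'
#' For each participant, correlates the conditioned-trial (CS_TS) MEP
#' measures of the two muscles: unadjusted Spearman rho, plus the parametric
#' and/or probability-scale-residual semi-partial variants per background
#' window. Participants contribute only complete conditioned trials;
#' participants with fewer than 3 such trials are skipped.
#'
#' @param features a feature table from [extractFeatures()] (or
#'   [simulateFeatures()]).
#' @param cfg an [AnalysisConfig-class].
#' @param measure `"amplitude"` (peak-to-peak) or `"area"`.
#' @return a long `data.frame`: `participant`, `measure`, `window` (`NA` for
#'   the unadjusted rows), `method` (`unadjusted`, `parametric`, `psr`),
#'   `rho`, `n`, `converged`.
#' @export
computeAssociations <- function(features, cfg = analysisConfig(),
                                measure = c("amplitude", "area")) {
  measure <- match.arg(measure)
  stem <- if (measure == "amplitude") "mep_amp" else "mep_area"
  xcol <- paste0(stem, "_rFCR")
  ycol <- paste0(stem, "_lFCR")
  rows <- list()
  for (p in unique(features$participant)) {
    f <- features[features$participant == p & features$condition == "CS_TS", ]
    keep <- is.finite(f[[xcol]]) & is.finite(f[[ycol]])
    f <- f[keep, ]
    n <- nrow(f)
    if (n < 3L) next
    x <- f[[xcol]]
    y <- f[[ycol]]
    rows[[length(rows) + 1L]] <- data.frame(
      participant = p, measure = measure, window = NA_real_,
      method = "unadjusted", rho = spearmanRho(x, y), n = n, converged = TRUE,
      stringsAsFactors = FALSE)
    for (w in cfg@backgroundWindows) {
      cx <- f[[sprintf("rms_rFCR_%g", w)]]
      cy <- f[[sprintf("rms_lFCR_%g", w)]]
      if ("parametric" %in% cfg@methods) {
        rho <- parametricSemipartial(x, y, cx, cy)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, measure = measure, window = w,
          method = "parametric", rho = rho, n = n, converged = TRUE,
          stringsAsFactors = FALSE)
      }
      if ("psr" %in% cfg@methods) {
        rho <- psrSemipartial(x, y, cx, cy)
        conv <- isTRUE(attr(rho, "converged"))
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, measure = measure, window = w,
          method = "psr", rho = as.numeric(rho), n = n, converged = conv,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-participant background-EMG associations
#'
#' Unadjusted Spearman correlation, per background window, between the
#' r.m.s. EMG of the two muscles across a participant's conditioned trials.
#'
#' @inheritParams computeAssociations
#' @return a `data.frame` in the layout of [computeAssociations()] with
#'   `measure = "background"` and `method = "unadjusted"`.
#' @export
computeBackgroundAssociations <- function(features, cfg = analysisConfig()) {
  rows <- list()
  for (p in unique(features$participant)) {
    f <- features[features$participant == p & features$condition == "CS_TS", ]
    for (w in cfg@backgroundWindows) {
      cx <- f[[sprintf("rms_rFCR_%g", w)]]
      cy <- f[[sprintf("rms_lFCR_%g", w)]]
      keep <- is.finite(cx) & is.finite(cy)
      if (sum(keep) < 3L) next
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, measure = "background", window = w,
        method = "unadjusted", rho = spearmanRho(cx[keep], cy[keep]),
        n = sum(keep), converged = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
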