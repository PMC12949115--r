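test_that("mid-ranks handle ties and always sum to n(n+1)/2", {
  expect_equal(averageRanks(c(1.2, 3.4, 3.4, 5)), c(1, 2.5, 2.5, 4))
  expect_equal(averageRanks(rep(7, 4)), rep(2.5, 4))
  expect_error(averageRanks(numeric()), "empty")
  set.seed(11)
  for (n in c(3, 10, 57)) {
    v <- sample(rnorm(n - 1), n, replace = TRUE)  # guaranteed ties sometimes
    expect_equal(sum(averageRanks(v)), n * (n + 1) / 2)
  }
})

test_that("Spearman rho matches hand values and flags zero-variance input", {
  x <- c(0.3, 1.7, 2.2, 9.1)
  expect_equal(spearmanRho(x, x), 1)
  expect_equal(spearmanRho(x, rev(x)), -1)
  expect_equal(spearmanRho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_true(is.na(spearmanRho(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearmanRho(1:4, 1:5), "mismatch")
})

test_that("Spearman rho is invariant under strictly increasing transforms", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- 0.5 * x + rnorm(15)
    rho <- spearmanRho(x, y)
    expect_equal(spearmanRho(exp(x), y), rho)
    expect_equal(spearmanRho(x, y^3 + 2 * y), rho)
    expect_equal(spearmanRho(qlogis(plogis(x)), exp(y)), rho, tolerance = 1e-12)
  }
})

test_that("Yeo-Johnson transform matches its closed forms and is monotone", {
  x <- c(0, 0.5, 2, 10)
  expect_equal(yeoJohnson(x, 1), x)                       # identity for x >= 0
  expect_equal(yeoJohnson(0, -3.7), 0)
  expect_equal(yeoJohnson(exp(1) - 1, 0), 1)
  expect_equal(yeoJohnson(-(exp(1) - 1), 2), -1)
  # continuity in lambda at the special points
  expect_equal(yeoJohnson(c(-2, 3), 1e-9), yeoJohnson(c(-2, 3), 0),
               tolerance = 1e-6)
  expect_equal(yeoJohnson(c(-2, 3), 2 - 1e-9), yeoJohnson(c(-2, 3), 2),
               tolerance = 1e-6)
  # strictly increasing in x for assorted lambdas
  xs <- sort(rnorm(50, sd = 3))
  for (l in c(-2, 0, 0.5, 1, 2, 3.5))
    expect_true(all(diff(yeoJohnson(xs, l)) > 0))
})

test_that("the fitted Yeo-Johnson exponent maximizes the profile likelihood", {
  profile <- function(x, lambda) {
    z <- yeoJohnson(x, lambda)
    -length(x) / 2 * log(mean((z - mean(z))^2)) +
      (lambda - 1) * sum(sign(x) * log1p(abs(x)))
  }
  set.seed(13)
  # Gaussian data: lambda near 1 (averaged over replicates)
  lams <- replicate(20, fitYeoJohnson(rnorm(200, mean = 5))$lambda)
  expect_equal(mean(lams), 1, tolerance = 0.1)
  # large-scale log-normal data: log1p ~ log, so lambda near 0
  lams0 <- replicate(20, fitYeoJohnson(exp(rnorm(200, mean = 5)))$lambda)
  expect_equal(mean(lams0), 0, tolerance = 0.1)
  # grid oracle: the returned optimum beats a 1000-point grid
  for (i in 1:5) {
    x <- exp(rnorm(30)) - 0.5
    fit <- fitYeoJohnson(x)
    grid <- vapply(seq(-5, 5, length.out = 1000), function(l) profile(x, l),
                   numeric(1))
    expect_gte(fit$loglik, max(grid) - 1e-4)
  }
  expect_error(fitYeoJohnson(rep(2, 10)), "constant")
})

test_that("least-squares residuals satisfy the normal equations", {
  c1 <- c(1, 2, 3, 4, 5)
  expect_equal(linearResiduals(3 - 2 * c1, c1), rep(0, 5))
  y <- c(4, 7, 1, 9, 2)
  expect_equal(linearResiduals(y, rep(3, 5)), y - mean(y))
  set.seed(14)
  for (i in 1:10) {
    y <- rnorm(25); cc <- rnorm(25)
    r <- linearResiduals(y, cc)
    expect_equal(sum(r), 0, tolerance = 1e-10)
    expect_equal(sum(r * cc), 0, tolerance = 1e-10)
  }
})

test_that("parametric semi-partial reduces to plain Spearman for constant covariates", {
  set.seed(15)
  x <- exp(rnorm(18)); y <- exp(0.4 * log(x) + rnorm(18))
  expect_equal(parametricSemipartial(x, y, rep(1, 18), rep(2, 18)),
               spearmanRho(x, y))
})

test_that("cumulative-logit MLE agrees with the empirical null and a grid oracle", {
  # saturated null: fitted cumulative probabilities = empirical proportions
  f0 <- fitCumulativeLogit(rep(1:4, each = 5))
  expect_equal(f0$alpha, qlogis(c(1, 2, 3) / 4), tolerance = 1e-5)
  expect_equal(f0$alpha[1], -log(3), tolerance = 1e-5)
  expect_error(fitCumulativeLogit(rep(1:4, each = 2), rep(1, 8)), "constant")

  # n = 8 toy, two outcome levels: exhaustive 2-d grid at 0.01 resolution
  y <- c(1, 1, 1, 2, 1, 2, 2, 2)
  x <- c(-1.5, -0.8, 0.3, -0.4, 0.9, 0.2, 1.3, 0.6)
  fit <- fitCumulativeLogit(y, x)
  grid <- expand.grid(a = seq(-3, 3, by = 0.01), b = seq(-2, 4, by = 0.01))
  eta <- outer(grid$a, rep(1, 8)) - outer(grid$b, x)
  p <- plogis(eta)
  lls <- rowSums(log(p[, y == 1, drop = FALSE])) +
    rowSums(log(1 - p[, y == 2, drop = FALSE]))
  best <- grid[which.max(lls), ]
  expect_lt(abs(fit$alpha - best$a), 0.01)   # agreement to two decimals
  expect_lt(abs(fit$beta - best$b), 0.01)
  expect_gte(fit$logLik, max(lls) - 1e-6)
})

test_that("cumulative-logit MLE matches an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(16)
  x <- rnorm(80)
  latent <- 1.3 * x + rlogis(80)
  y <- as.integer(cut(latent, c(-Inf, -1, 0.5, 2, Inf)))
  fit <- fitCumulativeLogit(y, x)
  ref <- MASS::polr(factor(y) ~ x, method = "logistic")
  expect_true(fit$converged)
  expect_equal(fit$alpha, unname(ref$zeta), tolerance = 1e-4)
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-4)
})

test_that("the Newton ascent never decreases the log-likelihood and flags separation", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    x <- averageRanks(rnorm(n))
    y <- averageRanks(0.5 * x + rnorm(n, sd = 4))
    fit <- fitCumulativeLogit(y, x)
    expect_true(all(diff(fit$logLikPath) > 0))
    expect_true(!is.unsorted(fit$alpha, strictly = TRUE))
  }
  sep <- fitCumulativeLogit(1:8, 1:8)   # perfectly monotone: no finite MLE
  expect_true(sep$separation)
  expect_false(sep$converged)
})

test_that("probability-scale residuals match the closed-form null and an
           enumeration oracle", {
  # null model, n distinct values: residual of rank r is (2r - n - 1) / n
  n <- 9
  f0 <- fitCumulativeLogit(1:n)
  expect_equal(probabilityScaleResiduals(f0, 1:n), (2 * (1:n) - n - 1) / n,
               tolerance = 1e-6)
  # middle of 3 distinct values sits at 0 by symmetry
  f3 <- fitCumulativeLogit(c(10, 20, 30))
  expect_equal(probabilityScaleResiduals(f3, 20), 0, tolerance = 1e-6)
  expect_error(probabilityScaleResiduals(f3, 15), "levels")

  # enumeration oracle: sum fitted category probabilities below/above y
  set.seed(18)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    x <- rnorm(n)
    y <- as.integer(cut(x + rnorm(n), breaks = c(-Inf, -0.5, 0.5, Inf)))
    if (length(unique(y)) < 2) next
    fit <- fitCumulativeLogit(y, x)
    J <- length(fit$levels)
    catProb <- function(xi) {
      cum <- c(plogis(fit$alpha - fit$beta * xi), 1)
      c(cum[1], diff(cum))
    }
    oracle <- vapply(seq_len(n), function(i) {
      p <- catProb(x[i])
      j <- match(y[i], fit$levels)
      sum(p[seq_len(J) < j]) - sum(p[seq_len(J) > j])
    }, numeric(1))
    got <- probabilityScaleResiduals(fit, y, x)
    expect_equal(got, oracle, tolerance = 1e-10)
    expect_true(all(got >= -1 & got <= 1))
  }
})

test_that("PSR under the null sums to zero when all outcomes are distinct", {
  set.seed(19)
  for (n in c(5, 12, 18)) {
    f <- fitCumulativeLogit(sample(n))
    expect_equal(sum(probabilityScaleResiduals(f, 1:n)), 0, tolerance = 1e-6)
  }
})

test_that("the PSR semi-partial is rank-based: monotone transforms leave it
           bit-identical", {
  set.seed(20)
  s <- simulateSeries(18, shared = 0.3, coupling = 1.2, rhoBg = 0.3)
  base <- psrSemipartial(s$x, s$y, s$cx, s$cy)
  expect_identical(as.numeric(psrSemipartial(exp(s$x), s$y, s$cx, s$cy)),
                   as.numeric(base))
  expect_identical(as.numeric(psrSemipartial(s$x, log(s$y), s$cx^3, s$cy)),
                   as.numeric(base))
  expect_true(abs(as.numeric(base)) <= 1)
})

test_that("both semi-partial estimators stay in [-1, 1] and shrink shared-covariate
           association", {
  set.seed(21)
  nPart <- 120
  un <- par <- psr <- numeric(nPart)
  for (p in seq_len(nPart)) {
    s <- simulateSeries(18, shared = 0.32, coupling = 1.2, rhoBg = 0.6)
    un[p] <- spearmanRho(s$x, s$y)
    par[p] <- parametricSemipartial(s$x, s$y, s$cx, s$cy)
    psr[p] <- as.numeric(psrSemipartial(s$x, s$y, s$cx, s$cy))
  }
  expect_true(all(abs(c(par, psr)) <= 1, na.rm = TRUE))
  expect_lt(mean(par, na.rm = TRUE), mean(un))
  expect_lt(mean(psr, na.rm = TRUE), mean(un))
  expect_gt(mean(un), 0)
})

test_that("the association table carries every method per window with trial counts", {
  set.seed(22)
  sf <- simulateFeatures(syntheticConfig(nParticipants = 4L, seed = 23L))
  cfg <- analysisConfig(backgroundWindows = c(100, 10), bootstrapReps = 50L)
  assoc <- computeAssociations(sf$features, cfg)
  expect_setequal(unique(assoc$method), c("unadjusted", "parametric", "psr"))
  expect_equal(sum(assoc$method == "unadjusted"), 4L)
  expect_equal(sum(assoc$method == "parametric"), 8L)   # 4 participants x 2 windows
  expect_true(all(assoc$n == 18L))
  expect_true(all(abs(assoc$rho[assoc$converged]) <= 1, na.rm = TRUE))
  bg <- computeBackgroundAssociations(sf$features, cfg)
  expect_equal(nrow(bg), 8L)
  expect_true(all(bg$measure == "background"))
})
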