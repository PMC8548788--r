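# Chemometrics: HCA, adequacy tests, factor extraction, varimax, scores,
# composite score and ranking.

test_that("average-linkage HCA on squared distances matches a hand trace", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  tr <- hca(x, "squared-euclidean")
  h <- tr$hclust
  expect_equal(h$height, c(1, 90.5))  # {0,1} at 1; then mean(81, 100)
  expect_equal(length(h$height), nrow(x) - 1)
  expect_true(all(diff(h$height) >= 0))

  dup <- matrix(c(1, 2, 1, 2, 5, 9), nrow = 3, byrow = TRUE)
  expect_equal(hca(dup, "squared-euclidean")$hclust$height[1], 0)
})

test_that("heatmap-mode HCA standardizes features and uses 1 - correlation", {
  m <- matrix(rnorm(40, sd = 2), 8, 5)
  tr <- hca(m, "similarity-heatmap")
  z <- scale(m)
  expect_equal(sort(tr$hclust$height[1]),
               sort(stats::hclust(stats::as.dist(1 - cor(t(z))),
                                  "average")$height[1]))
  const <- m; const[, 2] <- 3
  expect_error(hca(const, "similarity-heatmap"), "constant")
})

test_that("cutting the cluster-structured study recovers the planted groups", {
  d <- default_design()
  contents <- sample_contents(d, 15, seed = 9, structure = "clusters")
  tr <- hca(unclass(contents), "squared-euclidean")
  got <- stats::cutree(tr$hclust, k = 3)
  truth <- attr(contents, "cluster")
  # same partition up to label permutation
  expect_equal(length(unique(paste(got, truth))), 3)
})

test_that("KMO agrees with an explicit partial-correlation oracle", {
  set.seed(11)
  n <- 200
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(f1 + rnorm(n, sd = 0.4), f1 + rnorm(n, sd = 0.4),
             f2 + rnorm(n, sd = 0.4), f2 + rnorm(n, sd = 0.4))
  # oracle: partial correlation of i, j given the rest via regression residuals
  pcor <- function(i, j) {
    rest <- X[, -c(i, j), drop = FALSE]
    cor(lm.fit(cbind(1, rest), X[, i])$residuals,
        lm.fit(cbind(1, rest), X[, j])$residuals)
  }
  R <- cor(X)
  r2 <- q2 <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    r2 <- r2 + R[i, j]^2
    q2 <- q2 + pcor(i, j)^2
  }
  expect_equal(kmo(X)$kmo, r2 / (r2 + q2), tolerance = 1e-10)
})

test_that("KMO of two variables is one half and singular input errors", {
  set.seed(3)
  X <- cbind(rnorm(50), rnorm(50), rnorm(50))
  # p = 2 gives exactly 1/2 (partial equals marginal); check via a 3rd
  # variable that is pure noise: drop it and verify with the formula directly
  R <- cor(X[, 1:2])
  S <- solve(R)
  q <- -S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  expect_equal(R[1, 2]^2 / (R[1, 2]^2 + q^2), 0.5, tolerance = 1e-12)
  sing <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(kmo(sing), "singular|undefined")
})

test_that("Bartlett sphericity matches the determinant formula", {
  set.seed(5)
  X <- matrix(rnorm(120), 20, 6)
  b <- bartlett_sphericity(X)
  expect_equal(b$df, 15)
  expect_equal(b$chi2,
               -(20 - 1 - (2 * 6 + 5) / 6) * log(det(cor(X))),
               tolerance = 1e-12)
  # centered orthogonal columns -> identity correlation -> chi2 = 0
  C <- scale(matrix(rnorm(80), 10, 8), scale = FALSE)
  I4 <- qr.Q(qr(C))[, 1:4]
  expect_lt(bartlett_sphericity(I4)$chi2, 1e-8)
  expect_error(bartlett_sphericity(matrix(rnorm(30), 5, 6)), "n > p")
})

test_that("variance table reproduces the published eigenvalue arithmetic", {
  ev <- c(2.717, 1.836, 0.804, 0.414, 0.168, 0.061)
  vt <- variance_table(ev)
  expect_equal(round(vt$cum_pct[3], 3), 89.283)
  expect_equal(vt$cum_pct[6], 100)
  expect_equal(sum(ev > 0.8), 3)  # retention rule keeps three factors
})

test_that("factor extraction conserves eigenvalues and scales loadings", {
  d <- default_design()
  contents <- sample_contents(d, 15, seed = 12, structure = "factors")
  fm <- extract_factors(unclass(contents))
  expect_equal(sum(fm$eigenvalues), 6, tolerance = 1e-8)
  expect_equal(fm$n_retained, 3)
  # communality = row sums of squared loadings, preserved by rotation
  expect_equal(rowSums(fm$loadings^2), rowSums(fm$rotated^2),
               tolerance = 1e-8)
  # regression scores on principal components have unit variance
  expect_equal(apply(fm$scores, 2, var), rep(1, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  # isotropic data: all eigenvalues near 1
  set.seed(1)
  iso <- matrix(rnorm(6 * 4000), ncol = 4)
  expect_equal(eigen(cor(iso))$values, rep(1, 4), tolerance = 0.1)
})

test_that("varimax is a fixed point on simple structure and invertible", {
  L <- rbind(c(0.9, 0), c(0.85, 0), c(0, 0.9), c(0, 0.8))
  expect_equal(varimax_rotate(L), L, tolerance = 1e-6, ignore_attr = TRUE)
  # random orthogonal pre-rotation is undone up to order/sign
  set.seed(7)
  Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  back <- varimax_rotate(L %*% Q)
  cong <- abs(crossprod(back, L)) /
    sqrt(outer(colSums(back^2), colSums(L^2)))
  expect_true(all(apply(cong, 2, max) > 0.999))
  expect_equal(rowSums(back^2), rowSums(L^2), tolerance = 1e-8)
  expect_message(varimax_rotate(L[, 1, drop = FALSE]), "single factor")
})

test_that("planted three-factor structure is recovered from the study", {
  d <- default_design()
  hits <- vapply(c(12, 25, 77), function(s) {
    contents <- sample_contents(d, 15, seed = s, structure = "factors")
    fm <- extract_factors(unclass(contents))
    planted <- attr(contents, "planted_loadings")
    cong <- abs(crossprod(fm$rotated, planted)) /
      sqrt(outer(colSums(fm$rotated^2), colSums(planted^2)))
    fm$n_retained == 3 && all(apply(cong, 2, max) > 0.95)
  }, logical(1))
  expect_true(all(hits))
})

test_that("factor scores and the composite score follow their formulas", {
  set.seed(2)
  X <- matrix(rnorm(60), 10, 6)
  cf <- matrix(0, 6, 2); cf[3, 1] <- 1  # one-hot: score = standardized feature
  sc <- factor_scores(X, cf)
  expect_equal(sc[, 1], scale(X)[, 3], ignore_attr = TRUE)
  expect_equal(sc[, 2], rep(0, 10), ignore_attr = TRUE)
  expect_error(factor_scores(X, matrix(0, 5, 2)), "match")
  # all-mean sample scores 0
  X2 <- rbind(X, colMeans(X))
  expect_equal(factor_scores(X2, cf)[11, 1], 0, tolerance = 1e-9)

  w <- c(38.006, 27.720, 23.556)
  expect_equal(composite_score(c(0, 0, 0), w), 0)
  expect_equal(composite_score(c(1, 0, 0), w), 38.006 / 89.282,
               tolerance = 1e-4)
  expect_equal(composite_score(c(0.3, -1, 2), c(1, 1, 1)),
               mean(c(0.3, -1, 2)))
  # ranking invariant under weight rescaling
  sc3 <- matrix(rnorm(30), 10, 3)
  expect_equal(rank_samples(composite_score(sc3, w)),
               rank_samples(composite_score(sc3, 10 * w)))
})

test_that("ranking is competition-style descending", {
  t1 <- load_fixture("table1_batches")
  rk <- rank_samples(t1$score)
  expect_equal(t1$batch[rk == 1], "S14")
  expect_equal(rk, t1$ranking)
  expect_equal(rank_samples(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(rank_samples(c(5, 5, 1)), c(1, 1, 3))
})
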