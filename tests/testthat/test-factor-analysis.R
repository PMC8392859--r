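test_that("percent variance reproduces the printed accounting", {
  expect_equal(percent_variance(4.76, 11), 43.27, tolerance = 0.005)
  expect_equal(percent_variance(1.87, 11), 17.00, tolerance = 0.005)
  expect_equal(43.27 + 25.31 + 17.00, 85.58, tolerance = 1e-9)
})

test_that("correlation-matrix PCA has unit eigenvalue mean and right loadings", {
  set.seed(30)
  n <- 300
  z <- matrix(rnorm(n * 2), n, 2)
  X <- cbind(a = z[, 1], b = z[, 1] * 0.8 + z[, 2] * 0.6,
             c = rnorm(n), d = rnorm(n), e = rnorm(n))
  fl <- pca_fa(X, retain = 2)
  expect_equal(sum(fl$eigenvalues), 5, tolerance = 1e-8)
  # loadings are eigvec * sqrt(lambda): communalities bounded by 1
  expect_true(all(fl$communalities <= 1 + 1e-8))
  expect_true(all(diff(fl$cumulative_percent) >= 0))
  # spherical case: all eigenvalues near 1
  Xs <- matrix(rnorm(4000 * 4), ncol = 4)
  fls <- pca_fa(Xs, retain = 1)
  expect_true(all(abs(fls$eigenvalues - 1) < 0.15))
  # zero-variance column named in error
  Xz <- cbind(X, f = rep(1, n))
  expect_error(pca_fa(Xz), "f")
})

test_that("varimax preserves communalities and row sums of squares", {
  set.seed(31)
  X <- matrix(rnorm(200 * 6), 200, 6) %*% matrix(runif(36, -1, 1), 6, 6)
  colnames(X) <- letters[1:6]
  fl <- pca_fa(X, retain = 2)
  rot <- varimax_rotate(fl)
  expect_equal(rowSums(rot$loadings^2), fl$communalities, tolerance = 1e-8)
  expect_true(rot$rotated)
  # a perfect simple structure is a fixed point up to sign/permutation
  L <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.7), c(0, 0.6))
  Lr <- varimax_rotate(L)
  expect_equal(abs(Lr[Lr > 1e-6]), c(0.9, 0.8, 0.7, 0.6), tolerance = 1e-6)
})

test_that("varimax matches an exhaustive angle grid search on 2-factor toys", {
  set.seed(32)
  for (i in 1:5) {
    L <- matrix(rnorm(8, sd = 0.5), 4, 2)
    Lr <- varimax_rotate(L, kaiser_normalize = TRUE)
    crit_fit <- varimax_criterion(Lr)
    # oracle: rotate by every angle on a fine grid, keep the best criterion
    angles <- seq(0, pi / 2, length.out = 20001)
    crit_grid <- max(vapply(angles, function(a) {
      R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
      varimax_criterion(L %*% R)
    }, numeric(1)))
    expect_equal(crit_fit, crit_grid, tolerance = 1e-4)
  }
})

test_that("KMO matches the equicorrelation closed form and stays in (0,1]", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  # partials of an equicorrelated trio are r/(1+r) = 1/3 each
  expect_equal(kmo(R), 1.5 / (1.5 + 6 * (1 / 3)^2), tolerance = 1e-9) # 0.6923
  expect_equal(kmo(R), 0.6923, tolerance = 1e-4)
  set.seed(33)
  for (i in 1:20) {
    X <- matrix(rnorm(60 * 4), 60, 4)
    v <- kmo(cor(X))
    expect_gt(v, 0); expect_lte(v, 1)
  }
  near_I <- diag(4); near_I[1, 2] <- near_I[2, 1] <- 1e-9
  expect_warning(kmo(near_I), "ill-conditioned")
})

test_that("Bartlett sphericity matches the closed form", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  b <- bartlett_sphericity(R, n = 100)
  # det = 0.5; multiplier = 99 - 11/6
  expect_equal(b$chi2, -(100 - 1 - 11 / 6) * log(0.5), tolerance = 1e-9)
  expect_equal(b$chi2, 67.35, tolerance = 0.01)
  expect_equal(b$df, 3)
  expect_lt(b$p, 1e-10)
  # identity: chi2 = 0, p = 1
  b0 <- bartlett_sphericity(diag(4), n = 50)
  expect_equal(b0$chi2, 0)
  expect_equal(b0$p, 1)
  # chi2 increases with n for fixed R != I
  expect_gt(bartlett_sphericity(R, 200)$chi2, bartlett_sphericity(R, 100)$chi2)
  expect_error(bartlett_sphericity(R, 3))
})

test_that("KMO and Bartlett match brute-force oracles on random matrices", {
  set.seed(34)
  for (i in 1:10) {
    p <- sample(3:5, 1)
    X <- matrix(rnorm(80 * p), 80, p)
    X[, 1] <- X[, 1] + 0.5 * X[, p]
    R <- cor(X)
    # brute-force KMO from explicit partial correlations
    S <- solve(R)
    part <- -S / sqrt(outer(diag(S), diag(S)))
    num <- sum(R[upper.tri(R)]^2)
    den <- num + sum(part[upper.tri(part)]^2)
    expect_equal(kmo(R), num / den, tolerance = 1e-12)
    b <- bartlett_sphericity(R, 80)
    expect_equal(b$chi2, -(80 - 1 - (2 * p + 5) / 6) * log(det(R)),
                 tolerance = 1e-12)
  }
})

test_that("loading labels use absolute strong/moderate bands", {
  expect_equal(classify_loadings(0.85), "strong")
  expect_equal(classify_loadings(-0.76), "strong")
  expect_equal(classify_loadings(0.42), "none")
  expect_equal(classify_loadings(0.5), "moderate")
  expect_equal(classify_loadings(0.7), "moderate")
  expect_equal(classify_loadings(0.701), "strong")
  m <- classify_loadings(matrix(c(0.9, -0.6, 0.1, 0.2), 2))
  expect_equal(dim(m), c(2L, 2L))
})

test_that("loadings table carries the eigenvalue footer", {
  set.seed(35)
  X <- matrix(rnorm(100 * 5), 100, 5); colnames(X) <- letters[1:5]
  fl <- pca_fa(X, retain = 2)
  tab <- loadings_table(fl)
  expect_equal(nrow(tab), 5 + 3)
  expect_equal(tab$variable[6:8],
               c("Eigenvalues", "% of Variance", "Cumulative %"))
})
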