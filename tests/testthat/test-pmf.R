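test_that("uncertainty follows the EPA convention above and below the MDL", {
  expect_equal(build_uncertainty(10, mdl = 1, ef = 0.1), sqrt(1 + 0.25),
               tolerance = 1e-9)                         # 1.11803
  expect_equal(build_uncertainty(0.5, mdl = 1, ef = 0.1), 5 / 6,
               tolerance = 1e-9)
  expect_error(build_uncertainty(2, mdl = 0, ef = 0))
  expect_error(build_uncertainty(2, mdl = -1, ef = 0.1))
  # matrix wrapper: defaults MDL to 1% of median
  X <- matrix(c(10, 20, 30, 1, 2, 3), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  U <- uncertainty_matrix(X, ef = 0.1)
  expect_equal(attr(U, "mdl")[["A"]], 0.2)
  expect_equal(unname(U[1, 1]), sqrt((0.1 * 10)^2 + (0.5 * 0.2)^2))
})

test_that("row-wise NNLS matches a reference solver", {
  skip_if_not_installed("pracma")
  set.seed(3)
  for (rep in 1:50) {
    p <- sample(1:4, 1); m <- p + sample(1:5, 1)
    M <- matrix(runif(m * p), m, p)
    w <- runif(m, 0.1, 2)
    y <- runif(m, -0.5, 1)
    A <- array(0, c(1, p, p)); A[1, , ] <- t(M) %*% diag(w) %*% M
    b <- matrix(colSums(M * (w * y)), 1)
    x1 <- riverwq:::nnls_rows(A, b)[1, ]
    x2 <- pracma::lsqnonneg(diag(sqrt(w)) %*% M, sqrt(w) * y)$x
    expect_equal(x1, x2, tolerance = 1e-6)
  }
})

test_that("exact low-rank matrices are factorized to Q ~ 0", {
  # rank-1 outer product
  set.seed(2)
  a <- runif(20, 1, 3); b <- runif(6, 1, 5)
  f1 <- fit_pmf(outer(a, b), p = 1, n_starts = 2, seed = 1)
  expect_lt(f1$Q, 1e-10)
  expect_equal(unname(outer(f1$G[, 1], f1$F[1, ])), unname(outer(a, b)),
               tolerance = 1e-6)
  # rank-3 noiseless fixture
  fx <- fixtures()
  X <- fx$rank3_noiseless$matrix$values[, setdiff(wq_parameters(), "pH")]
  fit <- fit_pmf(X, p = 3, n_starts = 2, seed = 1)
  expect_lt(fit$Q, 1e-6 * length(X))
  expect_true(all(fit$G >= 0))
  expect_true(all(fit$F >= 0))
})

test_that("Q is non-increasing over iterations and recomputable", {
  fx <- fixtures()
  X <- fx$rank3_noiseless$matrix$values[, setdiff(wq_parameters(), "pH")]
  U <- uncertainty_matrix(X)
  fit <- fit_pmf(X, U, p = 2, n_starts = 2, seed = 4, max_iter = 300)
  dq <- diff(fit$q_trace)
  expect_true(all(dq <= 1e-9 * pmax(fit$q_trace[-length(fit$q_trace)], 1e-12)))
  q_re <- sum(((X - fit$G %*% fit$F) / U)^2)
  expect_equal(q_re, fit$Q, tolerance = 1e-6)
})

test_that("fit is reproducible and normalized with ordered factors", {
  fx <- fixtures()
  X <- fx$rank3_noiseless$matrix$values[, setdiff(wq_parameters(), "pH")]
  f1 <- fit_pmf(X, p = 3, n_starts = 2, seed = 10)
  f2 <- fit_pmf(X, p = 3, n_starts = 2, seed = 10)
  expect_identical(f1$F, f2$F)
  expect_equal(unname(colMeans(f1$G)), rep(1, 3), tolerance = 1e-8)
  expect_true(all(diff(rowSums(f1$F)) <= 1e-8))   # descending order
})

test_that("input validation rejects ill-posed problems", {
  X <- matrix(runif(40, 1, 5), 10, 4)
  expect_error(fit_pmf(-X, p = 2), "non-negative")
  expect_error(fit_pmf(X, p = 4), "p <")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_pmf(Xna, p = 2), "missing")
  expect_error(fit_pmf(X, U = matrix(0, 10, 4), p = 2), "positive")
})

test_that("apportionment percentages are row-normalized concentrations", {
  # printed-table normalization oracle (exact arithmetic)
  conc <- rbind(EC = c(149.17, 0.06, 275.33),
                TCB = c(2.83, 13239.00, 1415.80))
  pct <- contribution_percentages(conc)
  expect_equal(unname(pct["EC", 3]), 64.85, tolerance = 0.005)
  expect_equal(unname(pct["TCB", 2]), 90.32, tolerance = 0.005)
  expect_equal(unname(rowSums(pct)), c(100, 100), tolerance = 1e-9)
  # degenerate zero row flagged as NA
  expect_true(all(is.na(contribution_percentages(rbind(c(0, 0))))))

  # from a fitted model: percentages per parameter sum to 100
  fx <- fixtures()
  X <- fx$rank3_noiseless$matrix$values[, setdiff(wq_parameters(), "pH")]
  fit <- fit_pmf(X, p = 3, n_starts = 2, seed = 1)
  tab <- apportion(fit, X)
  pct_cols <- grep("^pct_", names(tab))
  expect_equal(rowSums(tab[, pct_cols]), rep(100, nrow(tab)),
               tolerance = 0.1, ignore_attr = TRUE)
  # p = 1: single factor takes 100% of every parameter
  f1 <- fit_pmf(X, p = 1, n_starts = 1, seed = 1, max_iter = 50)
  t1 <- apportion(f1, X)
  expect_equal(t1$pct_f1, rep(100, nrow(t1)))
})

test_that("per-variable R2 matches the correlation formula", {
  x <- c(1, 3, 2, 5, 4)
  y <- c(1.2, 2.9, 2.2, 4.8, 3.9)
  # brute-force Pearson formula
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r2_per_variable(x, y), r^2, tolerance = 1e-12)
  expect_equal(r2_per_variable(x, x), 1)
  expect_warning(out <- r2_per_variable(x, rep(2, 5)), "constant")
  expect_true(is.na(out))
  expect_error(r2_per_variable(1:2, 1:2))
})

test_that("source profiles and contributions are recovered on synthetic data", {
  # single-seed recovery here; the multi-seed experiment runs in the
  # acceptance suite
  d <- generate_dataset(seed = 11L)
  keep <- setdiff(wq_parameters(), c("pH", "DO"))
  X <- d$matrix$values[, keep]
  fit <- fit_pmf(X, uncertainty_matrix(X), p = 3, n_starts = 3, seed = 2)
  mm <- match_profiles(fit$F, d$truth$F_true[, keep])
  expect_true(all(mm$cosine >= 0.9))
  g_cor <- vapply(1:3, function(k) {
    cor(fit$G[, mm$perm[k]], d$truth$G_true[, k])
  }, numeric(1))
  expect_true(all(g_cor >= 0.8))
})

test_that("profile matching is exact on a permuted copy", {
  F_true <- default_profiles()[, -1]   # drop pH column
  mm <- match_profiles(F_true[c(3, 1, 2), ], F_true)
  expect_equal(mm$perm, c(2L, 3L, 1L))
  expect_equal(mm$cosine, rep(1, 3), tolerance = 1e-12)
})
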