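test_that("Bray-Curtis similarity matches direct arithmetic and its bounds", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 0)
  expect_equal(bray_curtis(c(6, 2), c(2, 2)), 1 - 4 / 12, tolerance = 1e-12)
  expect_error(bray_curtis(c(0, 0), c(0, 0)))
  expect_error(bray_curtis(c(-1, 2), c(1, 2)))
  set.seed(40)
  for (i in 1:30) {
    a <- runif(5, 0, 10); b <- runif(5, 0, 10)
    s <- bray_curtis(a, b)
    expect_equal(s, bray_curtis(b, a))             # symmetry
    expect_gte(s, 0); expect_lte(s, 1)
    # agreement with vegan's dissimilarity
    expect_equal(s, 1 - as.numeric(vegan::vegdist(rbind(a, b), "bray")),
                 tolerance = 1e-12)
  }
})

test_that("site clustering separates constructed groups at the 60% cut", {
  # two identical sites + one distant site -> 2 groups
  m <- rbind(s1 = c(10, 5, 2), s2 = c(10, 5, 2), s3 = c(200, 80, 40))
  ct <- cluster_sites(m, cut_similarity = 0.60)
  expect_equal(length(unique(ct$groups)), 2L)
  expect_equal(ct$groups[["s1"]], ct$groups[["s2"]])
  # cut at similarity 1.0: all (distinct) sites become singletons
  m2 <- rbind(s1 = c(10, 5, 2), s2 = c(11, 5, 2), s3 = c(200, 80, 40))
  ct1 <- cluster_sites(m2, cut_similarity = 1.0)
  expect_equal(length(unique(ct1$groups)), 3L)
})

test_that("separated-tiers fixture recovers the three pollution tiers", {
  fx <- fixtures()
  d <- fx$separated_tiers
  ct <- cluster_sites(d$matrix)
  expect_equal(length(unique(ct$groups)), 3L)
  # group labels must be a relabelling of the tiers
  tier <- d$truth$tiers[names(ct$groups)]
  expect_equal(length(unique(paste(ct$groups, tier))), 3L)
})

test_that("newick export writes a tree over all sites", {
  fx <- fixtures()
  ct <- cluster_sites(fx$separated_tiers$matrix)
  path <- tempfile(fileext = ".nwk")
  write_newick(ct, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, names(ct$groups))
})

test_that("stepwise DA separates two obvious 1-D groups perfectly", {
  set.seed(41)
  X <- cbind(v = c(rnorm(20, 0), rnorm(20, 100)), noise = rnorm(40))
  g <- rep(c("a", "b"), each = 20)
  m <- stepwise_da(X, g)
  expect_equal(m$selected, "v")
  expect_equal(m$classification$percent_correct, 100)
})

test_that("Wilks' lambda and classification match a brute-force SSCP oracle", {
  # fixed 2-group, 2-variable toy (n = 12)
  X <- cbind(x1 = c(2.1, 1.8, 2.5, 3.0, 2.2, 1.9, 4.1, 4.5, 3.8, 4.9, 4.2, 4.6),
             x2 = c(1.0, 1.4, 0.8, 1.2, 1.1, 0.9, 2.0, 2.4, 1.7, 2.2, 2.1, 1.9))
  g <- rep(c("low", "high"), each = 6)
  # brute-force Wilks over both variables
  grand <- colMeans(X)
  Tm <- crossprod(sweep(X, 2, grand))
  W <- matrix(0, 2, 2)
  for (lev in unique(g)) {
    sub <- X[g == lev, ]
    W <- W + crossprod(sweep(sub, 2, colMeans(sub)))
  }
  lambda_both <- det(W) / det(Tm)
  m <- stepwise_da(X, g, f_enter = 3.84, f_remove = 2.71)
  if (setequal(m$selected, c("x1", "x2"))) {
    expect_equal(m$wilks_lambda, lambda_both, tolerance = 1e-9)
  } else {
    expect_equal(m$wilks_lambda,
                 riverwq:::wilks_lambda(X[, m$selected, drop = FALSE], g),
                 tolerance = 1e-9)
  }
  # classification counts equal a hand count from the linear rule
  pred <- predict(m, X)
  expect_equal(sum(pred == g), sum(diag(m$classification$counts)))
  # cross-check assignments against MASS::lda with equal priors
  skip_if_not_installed("MASS")
  ld <- MASS::lda(X[, m$selected, drop = FALSE], grouping = g,
                  prior = c(0.5, 0.5))
  expect_equal(as.character(predict(ld)$class), pred)
})

test_that("null-label DA accuracy is near chance", {
  set.seed(42)
  acc <- replicate(30, {
    X <- matrix(rnorm(300 * 3), 300, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    g <- sample(rep(1:3, each = 100))
    m <- suppressWarnings(stepwise_da(X, g, f_enter = 0, f_remove = -1))
    m$classification$percent_correct
  })
  expect_lt(abs(mean(acc) / 100 - 1 / 3), 0.06)
})

test_that("DA on the separated-tiers fixture is at least 95% correct", {
  fx <- fixtures()
  d <- fx$separated_tiers
  m <- stepwise_da(d$matrix$values, d$matrix$meta$tier)
  expect_gte(m$classification$percent_correct, 95)
  # classification-matrix row sums equal group sizes
  expect_equal(unname(rowSums(m$classification$counts)),
               unname(as.vector(table(d$matrix$meta$tier))))
})

test_that("no variable enters when f_enter is unattainably high", {
  set.seed(43)
  X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  g <- rep(1:2, each = 30)
  expect_warning(m <- stepwise_da(X, g, f_enter = 1e6), "no variable")
  expect_equal(length(m$selected), 0L)
})
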