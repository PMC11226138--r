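test_that("weighted_graph computes degrees and validates its input", {
  g <- weighted_graph(matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(g$degrees), c(1, 1))

  g0 <- weighted_graph(matrix(0, 3, 3))
  expect_equal(unname(g0$degrees), c(0, 0, 0))
  expect_true(all(g0$weights == 0))

  # path a-b-c with weights 2 and 3: degrees are the row sums
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 2
  W[2, 3] <- W[3, 2] <- 3
  expect_equal(unname(weighted_graph(W)$degrees), c(2, 5, 3))

  A <- matrix(c(0, 1, 2, 0), 2)
  expect_error(weighted_graph(A), "asymmetric.*\\(1, 2\\)|asymmetric.*\\(2, 1\\)")
  expect_error(weighted_graph(matrix(c(0, -1, -1, 0), 2)), "negative")
  expect_error(weighted_graph(matrix(c(0, NaN, NaN, 0), 2)), "NA")
  expect_warning(weighted_graph(matrix(c(2, 1, 1, 0), 2)), "diagonal")
  expect_equal(diag(suppressWarnings(weighted_graph(matrix(c(2, 1, 1, 0), 2)))$weights),
               c(g1 = 0, g2 = 0))
})

test_that("normalized Laplacian matches its defining branches", {
  # single unit edge
  L <- normalized_laplacian(weighted_graph(matrix(c(0, 1, 1, 0), 2)))
  expect_equal(unname(L$matrix), matrix(c(1, -1, -1, 1), 2))
  expect_equal(eigen(L$matrix, symmetric = TRUE)$values, c(2, 0))

  # isolated vertex: all-zero row and column
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  Li <- normalized_laplacian(weighted_graph(W))$matrix
  expect_equal(unname(Li[3, ]), c(0, 0, 0))
  expect_equal(unname(Li[, 3]), c(0, 0, 0))
  expect_equal(unname(diag(Li)), c(1, 1, 0))

  # unweighted 3-path: diag 1, edge entries -1/sqrt(2), spectrum {0,1,2}
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  Lp <- normalized_laplacian(weighted_graph(W))$matrix
  expect_equal(unname(diag(Lp)), c(1, 1, 1))
  expect_equal(Lp[1, 2], -1 / sqrt(2))
  expect_equal(sort(eigen(Lp, symmetric = TRUE)$values), c(0, 1, 2),
               tolerance = 1e-12)
})

test_that("normalized Laplacian spectra stay in [0, 2] with 0 attained", {
  set.seed(41)
  for (i in 1:30) {
    g <- random_weighted_graph(sample(2:15, 1), density = runif(1, 0.2, 1))
    ev <- eigen(normalized_laplacian(g)$matrix, symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev >= -1e-9) && all(ev <= 2 + 1e-9))
    if (any(g$weights > 0)) expect_lte(min(abs(ev)), 1e-9)
  }
})

test_that("entrywise Laplacian equals the matrix-product form when all degrees are positive", {
  set.seed(42)
  for (i in 1:10) {
    p <- sample(3:12, 1)
    W <- matrix(runif(p * p, 0.1, 1), p); W <- (W + t(W)) / 2; diag(W) <- 0
    g <- weighted_graph(W)
    L <- normalized_laplacian(g)$matrix
    Dm <- diag(1 / sqrt(g$degrees))
    expect_equal(max(abs(L - Dm %*% (diag(g$degrees) - W) %*% Dm)), 0,
                 tolerance = 1e-10)
  }
})

test_that("self-loop weights rescale the diagonal but keep the spectrum in [0, 2]", {
  set.seed(43)
  g <- random_weighted_graph(8)
  s <- rep(1, 8)
  L <- normalized_laplacian(g, self_weights = s)$matrix
  expect_equal(unname(diag(L)), unname(g$degrees / (g$degrees + 1)))
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-9) && all(ev <= 2 + 1e-9))
  # no self-loops recovers the plain convention
  expect_equal(normalized_laplacian(g, self_weights = rep(0, 8))$matrix,
               normalized_laplacian(g)$matrix)
})

test_that("correlation networks use absolute Pearson weights", {
  x1 <- c(1, 2, 3, 4)
  cn <- correlation_network(cbind(a = x1, b = 2 * x1))
  expect_equal(cn$graph$weights["a", "b"], 1)

  cn2 <- correlation_network(cbind(a = x1, b = c(1, 3, 2, 4)))
  expect_equal(cn2$graph$weights["a", "b"], 0.8)
  expect_equal(cn2$correlations["a", "b"], 0.8)

  # single gene: 1 x 1 zero weight matrix
  cn3 <- correlation_network(matrix(rnorm(5), ncol = 1))
  expect_equal(unname(cn3$graph$weights), matrix(0, 1, 1))

  expect_error(correlation_network(matrix(rnorm(4), 2)), "3 samples")
})

test_that("zero-variance genes get zero correlations, not NA", {
  X <- cbind(a = rnorm(10), b = rep(1, 10), c = rnorm(10))
  expect_warning(cn <- correlation_network(X), "zero-variance")
  expect_true(all(cn$graph$weights[, "b"] == 0))
  expect_false(anyNA(cn$graph$weights))
})

test_that("correlation networks are invariant to per-gene affine rescaling", {
  set.seed(44)
  X <- matrix(rnorm(60), 12)
  Y <- sweep(sweep(X, 2, c(2, -3, 0.5, 10, 1), "*"), 2, c(1, 0, -5, 2, 0), "+")
  w1 <- correlation_network(X)$graph$weights
  w2 <- correlation_network(Y)$graph$weights
  expect_equal(max(abs(w1 - w2)), 0, tolerance = 1e-10)
})
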