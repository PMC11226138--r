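test_that("the unpenalized fit reduces to the ordinary eigendecomposition", {
  set.seed(51)
  for (i in 1:10) {
    g <- random_weighted_graph(sample(3:12, 1), density = runif(1, 0.3, 1))
    L <- normalized_laplacian(g)
    fit <- suppressWarnings(net_sevd(L, penalty = penalty_config(kind = "dense")))
    expect_lt(max(abs(fit$eigenvalues -
                        sort(eigen(L$matrix, symmetric = TRUE)$values,
                             decreasing = TRUE))), 1e-6)
  }
})

test_that("a dominating L1 penalty zeroes every loading and eigenvalue", {
  set.seed(52)
  L <- normalized_laplacian(random_weighted_graph(6))$matrix
  g1 <- 10 * max(abs(crossprod(L)))
  fit <- suppressWarnings(net_sevd(L, penalty = penalty_config(g1, 0, "none")))
  expect_true(all(fit$loadings == 0))
  expect_true(all(fit$eigenvalues == 0))
})

test_that("the inner solve matches the lattice oracle on the 3-node path", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  L <- normalized_laplacian(weighted_graph(W))$matrix
  prob <- inner_problem(L, g1 = 0.1, g2 = 0.1)
  sol <- penalized_loading_solve(L, prob$target,
                                 penalty_config(0.1, 0.1, "network"))
  f_solver <- gram_objective(sol$beta, prob$Q, prob$cvec, 0.1)
  f_lattice <- lattice_min_objective(prob$Q, prob$cvec, 0.1)
  expect_lt(abs(f_solver - f_lattice), 1e-3)
  expect_lte(f_solver, f_lattice + 1e-9)  # solver attains the convex minimum
})

test_that("with an identity design the solve is coordinatewise soft-thresholding", {
  z <- c(2, -0.4, 0.04, 1, -3)
  g1 <- 0.5
  sol <- penalized_loading_solve(diag(5), z, penalty_config(g1, 0, "none"))
  soft <- sign(z) * pmax(abs(z) - g1 / 2, 0)
  expect_equal(sol$beta, soft, tolerance = 1e-9)
})

test_that("full shrinkage returns the zero vector", {
  set.seed(53)
  L <- normalized_laplacian(random_weighted_graph(5))$matrix
  z <- rnorm(5)
  sol <- penalized_loading_solve(L, z, penalty_config(1e6, 0.1, "network"))
  expect_equal(sol$beta, rep(0, 5))
})

test_that("the convex solve beats the threshold-after-least-squares heuristic", {
  set.seed(54)
  for (i in 1:5) {
    L <- normalized_laplacian(random_weighted_graph(6))$matrix
    z <- rnorm(6)
    g1 <- 0.3; g2 <- 0.2
    Q <- crossprod(L) + g2 * L
    cvec <- crossprod(L) %*% z
    sol <- penalized_loading_solve(L, z, penalty_config(g1, g2, "network"))
    ev <- eigen(L, symmetric = TRUE)          # minimum-norm least squares
    keep <- abs(ev$values) > 1e-10
    ls <- drop(ev$vectors[, keep] %*%
                 (crossprod(ev$vectors[, keep], z) / ev$values[keep]))
    heur <- sign(ls) * pmax(abs(ls) - g1 / 2, 0)
    expect_lte(gram_objective(sol$beta, Q, cvec, g1),
               gram_objective(heur, Q, cvec, g1) + 1e-9)
  }
})

test_that("nonzero count of the inner solve is non-increasing in gamma1", {
  set.seed(55)
  L <- normalized_laplacian(random_weighted_graph(8))$matrix
  z <- rnorm(8)
  nnz <- vapply(c(0.001, 0.01, 0.05, 0.1, 0.3, 1, 3), function(g1) {
    sum(penalized_loading_solve(L, z, penalty_config(g1, 0.1, "network"))$beta != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("the alternating objective is non-increasing", {
  set.seed(56)
  for (kind in c("network", "ridge", "none")) {
    L <- normalized_laplacian(random_weighted_graph(8))
    fit <- suppressWarnings(net_sevd(L, penalty = penalty_config(0.1, 0.1, kind)))
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
  }
})

test_that("inner solve matches exact enumeration on every graph with p <= 4", {
  for (p in 3:4) {
    for (W in all_simple_graphs(p)) {
      L <- normalized_laplacian(weighted_graph(W))$matrix
      prob <- inner_problem(L, g1 = 0.1, g2 = 0.1)
      sol <- penalized_loading_solve(L, prob$target,
                                     penalty_config(0.1, 0.1, "network"))
      oracle <- enum_l1_quadratic(prob$Q, drop(prob$cvec), 0.1)
      expect_lt(abs(gram_objective(sol$beta, prob$Q, prob$cvec, 0.1) -
                      oracle$objective), 1e-3)
    }
  }
})

test_that("sign adjustment preserves the spectrum and flips off-diagonal signs", {
  L2 <- matrix(c(1, -1, -1, 1), 2)
  expect_equal(sign_adjusted_laplacian(L2, c(1, -1)),
               matrix(c(1, 1, 1, 1), 2))
  expect_equal(sign_adjusted_laplacian(L2, c(2, 3)), L2)  # S = I
  set.seed(57)
  for (i in 1:10) {
    L <- normalized_laplacian(random_weighted_graph(7))$matrix
    s <- sample(c(-1, 1, 0), 7, replace = TRUE)
    Ls <- sign_adjusted_laplacian(L, s)
    expect_equal(Ls, t(Ls))
    expect_lt(max(abs(sort(eigen(Ls, symmetric = TRUE)$values) -
                        sort(eigen(L, symmetric = TRUE)$values))), 1e-10)
  }
})

test_that("regularization selection minimizes the reconstruction criterion", {
  set.seed(58)
  L <- normalized_laplacian(random_weighted_graph(5))
  sel <- select_regularization(L, grid = rbind(c(0, 0), c(0.1, 0.1), c(1, 0.1)))
  expect_equal(unname(sel$selected), c(0, 0))
  expect_lt(sel$criterion_values[sel$selected_index], 1e-12)

  sel1 <- select_regularization(L, grid = rbind(c(0.2, 0.3)))
  expect_equal(unname(sel1$selected), c(0.2, 0.3))

  # criterion recomputed independently from the stored fits
  sel2 <- select_regularization(L, grid = rbind(c(0.05, 0.1), c(0.5, 0.1)))
  crit <- vapply(sel2$fits, function(f) {
    sum((L$matrix - L$matrix %*% f$loadings %*% t(f$rotation))^2)
  }, numeric(1))
  expect_equal(sel2$criterion_values, crit, tolerance = 1e-10)
  expect_equal(sel2$selected_index, which.min(crit))
})

test_that("fit contracts: orthonormal rotation, unit or zero vectors, sorted eigenvalues", {
  set.seed(59)
  L <- normalized_laplacian(random_weighted_graph(9))
  fit <- suppressWarnings(net_sevd(L, penalty = penalty_config(0.05, 0.1, "network")))
  expect_lt(max(abs(crossprod(fit$rotation) - diag(9))), 1e-8)
  norms <- sqrt(colSums(fit$vectors^2))
  expect_true(all(abs(norms - 1) < 1e-10 | norms == 0))
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_error(net_sevd(L, q = 10), "q")
  expect_warning(net_sevd(L, penalty = penalty_config(0.05, 0.1, "network"),
                          max_iter = 1), "converge")
})

test_that("fit reports serialize with eigenvalues and per-component gene lists", {
  set.seed(60)
  L <- normalized_laplacian(random_weighted_graph(4))
  fit <- suppressWarnings(net_sevd(L, penalty = penalty_config(0.1, 0.1, "network")))
  lines <- report_sparse_fit(fit)
  expect_true(any(grepl("^eigenvalues\t", lines)))
  expect_length(grep("^component_", lines), 4)
})
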