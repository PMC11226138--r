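test_that("lasso network estimation honors the closed-form single-predictor solution", {
  set.seed(81)
  n <- 200
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + 0.1 * rnorm(n)
  X <- cbind(a = x1, b = x2)
  lam <- 4   # residual-sum-of-squares scale
  fit <- fit_regulatory_network(X, lambda_rule = "fixed", lambda = lam)
  # standardized single-predictor lasso: delta = soft(x'y/n, lam/(2n)) / (x'x/n)
  Xs <- scale(X)
  oracle <- vapply(1:2, function(j) {
    xy <- sum(Xs[, j] * Xs[, -j]) / n
    xx <- sum(Xs[, -j]^2) / n
    sign(xy) * max(abs(xy) - lam / (2 * n), 0) / xx
  }, numeric(1))
  expect_equal(fit$coefficients["a", "b"], oracle[1], tolerance = 1e-6)
  expect_equal(fit$coefficients["b", "a"], oracle[2], tolerance = 1e-6)
  expect_equal(fit$weights["a", "b"], mean(abs(oracle)), tolerance = 1e-6)
  expect_gt(fit$weights["a", "b"], 0.7)

  # full shrinkage: empty network
  empty <- fit_regulatory_network(X, lambda_rule = "fixed", lambda = 1e6)
  expect_true(all(empty$weights == 0))
})

test_that("edge weights are the symmetrized coefficient magnitudes", {
  set.seed(82)
  X <- matrix(rnorm(30 * 6), 30, dimnames = list(NULL, paste0("g", 1:6)))
  fit <- fit_regulatory_network(X, lambda_rule = "fixed", lambda = 1)
  D <- fit$coefficients
  expect_equal(fit$weights, (abs(D) + t(abs(D))) / 2)
  expect_true(all(diag(D) == 0))
  # arithmetic of the rule itself
  expect_equal((abs(0.4) + abs(0)) / 2, 0.2)
})

test_that("fitted lasso coefficients satisfy the subgradient conditions", {
  set.seed(83)
  n <- 60
  X <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("g", 1:8)))
  X[, 2] <- 0.7 * X[, 1] + 0.5 * rnorm(n)
  for (rule in list(c("fixed", 5), c("cv", NA))) {
    fit <- fit_regulatory_network(X, lambda_rule = rule[1],
                                  lambda = as.numeric(rule[2]), seed = 3)
    Xs <- scale(X)
    for (j in 1:8) {
      lam_g <- fit$lambda[j] / (2 * n)
      beta <- fit$coefficients[j, -j]
      r <- Xs[, j] - Xs[, -j, drop = FALSE] %*% beta
      grad <- drop(crossprod(Xs[, -j, drop = FALSE], r)) / n
      active <- beta != 0
      if (any(active))
        expect_lt(max(abs(grad[active] - lam_g * sign(beta[active]))), 1e-5)
      if (any(!active))
        expect_lt(max(abs(grad[!active])) - lam_g, 1e-5)
    }
  }
})

test_that("constant target genes yield a zero coefficient row with a message", {
  set.seed(84)
  X <- cbind(a = rnorm(20), b = rep(3, 20), c = rnorm(20))
  expect_message(
    fit <- suppressWarnings(fit_regulatory_network(X, "fixed", lambda = 1)),
    "constant target")
  expect_true(all(fit$coefficients["b", ] == 0))
})

test_that("quartile splits use interpolated quartiles with strict tails", {
  sp <- split_by_quartiles(setNames(1:8, letters[1:8]))
  expect_equal(unname(sp$q1), 2.75)
  expect_equal(unname(sp$q3), 6.25)
  expect_equal(sp$sensitive_ids, c("a", "b"))
  expect_equal(sp$resistant_ids, c("g", "h"))
  expect_error(split_by_quartiles(rep(1, 10)), "too few")
  # order invariance
  shuffled <- setNames(c(5, 1, 8, 3, 7, 2, 6, 4),
                       c("e", "a", "h", "c", "g", "b", "f", "d"))
  sp2 <- split_by_quartiles(shuffled)
  expect_setequal(sp2$sensitive_ids, c("a", "b"))
  expect_setequal(sp2$resistant_ids, c("g", "h"))
  # data-frame input
  sp3 <- split_by_quartiles(data.frame(id = letters[1:8], ic50 = 1:8))
  expect_equal(sp3$sensitive_ids, c("a", "b"))
})

test_that("variance filtering keeps the top fraction with label tie-breaks", {
  X <- sapply(1:10, function(j) seq(-1, 1, length.out = 30) * j)
  colnames(X) <- sprintf("g%02d", 1:10)
  out <- filter_top_variance(X, 0.2)
  expect_equal(out$genes, c("g09", "g10"))
  expect_identical(filter_top_variance(X, 1)$expression, X)
  # constant genes never outrank varying ones
  X2 <- cbind(const = rep(1, 30), vary = rnorm(30))
  expect_equal(filter_top_variance(X2, 0.5)$genes, "vary")
})

test_that("top-edge sub-network extraction returns components above the node bound", {
  star <- matrix(0, 7, 7, dimnames = list(paste0("g", 1:7), paste0("g", 1:7)))
  star[1, 2:7] <- star[2:7, 1] <- runif(6, 0.5, 1)
  subs <- extract_top_edge_subnetworks(weighted_graph(star), 1, 5)
  expect_length(subs, 1)
  expect_setequal(subs[[1]], paste0("g", 1:7))

  tri2 <- matrix(0, 6, 6, dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    tri2[e[1], e[2]] <- tri2[e[2], e[1]] <- 1
  expect_length(extract_top_edge_subnetworks(weighted_graph(tri2), 1, 5), 0)

  # path with weights 10..1, keep top ceiling(0.2 * 10) = 2 edges
  path <- matrix(0, 11, 11,
                 dimnames = list(sprintf("n%02d", 1:11), sprintf("n%02d", 1:11)))
  for (i in 1:10) path[i, i + 1] <- path[i + 1, i] <- 11 - i
  subs <- extract_top_edge_subnetworks(weighted_graph(path), 0.2, 1)
  kept <- attr(subs, "kept_edges")
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$weight, c(10, 9))
  expect_length(subs, 1)                       # edges 1-2, 2-3 share node 2
  expect_setequal(subs[[1]], c("n01", "n02", "n03"))
})

test_that("the pipeline is deterministic and alpha = 0 flags nothing", {
  fx <- simulate_drug_response_dataset(n_cell_lines = 400, seed = 86)
  base <- pipeline_config(edge_fraction = 1, min_nodes = 5,
                          top_variance_fraction = 0.35, T = 30,
                          lambda_rule = "fixed", lambda = 50, seed = 5)
  r1 <- run_differential_pipeline(fx$expression, fx$sensitivity, base)
  r2 <- run_differential_pipeline(fx$expression, fx$sensitivity, base)
  expect_identical(r1$tests$table, r2$tests$table)
  expect_identical(r1$markers, r2$markers)
  expect_identical(r1$flagged_subnetworks, r2$flagged_subnetworks)

  zero <- base; zero$alpha <- 0
  r0 <- run_differential_pipeline(fx$expression, fx$sensitivity, zero)
  expect_length(r0$flagged_subnetworks, 0)
  expect_equal(nrow(r0$markers), 0)

  expect_error(
    run_differential_pipeline(fx$expression,
                              setNames(rnorm(8), paste0("Z", 1:8)), base),
    "no matched sample IDs")
})
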