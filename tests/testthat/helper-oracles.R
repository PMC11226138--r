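# Shared helpers: small random graphs and two independent oracles for
# the penalized inner solve,
#   min_beta ||z - L beta||^2 + g1 ||beta||_1 + g2 beta' P beta ,
# written in Gram form f(beta) = beta' Q beta - 2 c' beta + g1 ||beta||_1
# with Q = L'L + g2 P and c = L'z (the constant z'z is dropped from both
# sides of every comparison).

random_weighted_graph <- function(p, density = 0.5) {
  W <- matrix(runif(p * p), p)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W[W < stats::quantile(W[upper.tri(W)], 1 - density)] <- 0
  weighted_graph(W)
}

gram_objective <- function(beta, Q, cvec, g1) {
  drop(beta %*% Q %*% beta) - 2 * sum(cvec * beta) + g1 * sum(abs(beta))
}

# Exact oracle: enumerate all 3^p sign patterns of the solution, solve
# the stationarity system on each active set, and keep the KKT-consistent
# candidate with the smallest objective.  Convexity guarantees the true
# minimizer's pattern is among them.
enum_l1_quadratic <- function(Q, cvec, g1) {
  p <- length(cvec)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  best_f <- Inf
  best_beta <- numeric(p)
  for (i in seq_len(nrow(patterns))) {
    s <- patterns[i, ]
    act <- which(s != 0)
    beta <- numeric(p)
    if (length(act) > 0) {
      sol <- tryCatch(
        solve(Q[act, act, drop = FALSE], cvec[act] - g1 * s[act] / 2),
        error = function(e) NULL)
      if (is.null(sol) || any(sign(sol) != s[act])) next
      beta[act] <- sol
    }
    grad <- 2 * (Q %*% beta - cvec)
    zero <- which(s == 0)
    if (length(zero) > 0 && any(abs(grad[zero]) > g1 + 1e-9)) next
    f <- gram_objective(beta, Q, cvec, g1)
    if (f < best_f) { best_f <- f; best_beta <- beta }
  }
  list(beta = best_beta, objective = best_f)
}

# Brute-force lattice oracle: evaluates the objective on a regular grid
# over [-lim, lim]^3 (vectorized over the last two coordinates).
lattice_min_objective <- function(Q, cvec, g1, step = 0.02, lim = 2) {
  g <- seq(-lim, lim, by = step)
  grid23 <- as.matrix(expand.grid(g, g))
  best <- Inf
  for (b1 in g) {
    B <- cbind(b1, grid23)
    f <- rowSums((B %*% Q) * B) - 2 * drop(B %*% cvec) +
      g1 * rowSums(abs(B))
    best <- min(best, f)
  }
  best
}

# All labeled simple graphs on p vertices, as weight matrices.
all_simple_graphs <- function(p) {
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    W <- matrix(0, p, p)
    W[pairs[bits == 1L, , drop = FALSE]] <- 1
    W + t(W)
  })
}

# Gram form of the inner problem for a Laplacian with the network
# penalty, using the leading dense eigenvector as the working target.
inner_problem <- function(L, g1 = 0.1, g2 = 0.1) {
  a <- eigen(L, symmetric = TRUE)$vectors[, 1]
  list(Q = crossprod(L) + g2 * L, cvec = drop(crossprod(L) %*% a),
       target = drop(L %*% a))
}
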