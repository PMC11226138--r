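#' Spectral distance between two network spectra
#'
#' The dissimilarity of two graphs over the same gene set is the sum of
#' squared differences between their rank-matched normalized-Laplacian
#' eigenvalues, `d = sum_r (lambda_Y[r] - lambda_N[r])^2`.  It is zero
#' exactly when the (sorted) spectra coincide, so isospectral graphs are
#' indistinguishable.  A square-root variant is available for comparison.
#'
#' @param eigs_Y,eigs_N numeric spectra of equal length, sorted
#'   descending.
#' @param squared if `FALSE`, return the square root of the sum.
#' @return A `spectral_distance` list: `value`, `q`, `eigenvalues_Y`,
#'   `eigenvalues_N`.
#' @examples
#' spectral_distance(c(2, 1, 0), c(2, 0, 0))$value  # 1
#' @export
spectral_distance <- function(eigs_Y, eigs_N, squared = TRUE) {
  if (length(eigs_Y) != length(eigs_N))
    stop("spectra have different lengths (", length(eigs_Y), " vs ",
         length(eigs_N), "); phenotype networks must share gene set and q",
         call. = FALSE)
  if (length(eigs_Y) < 1) stop("empty spectra", call. = FALSE)
  v <- sum((eigs_Y - eigs_N)^2)
  if (!squared) v <- sqrt(v)
  structure(list(value = v, q = length(eigs_Y),
                 eigenvalues_Y = eigs_Y, eigenvalues_N = eigs_N),
            class = "spectral_distance")
}

#' @export
print.spectral_distance <- function(x, ...) {
  cat("Spectral distance:", x$value, "over", x$q, "eigenvalue pairs\n")
  invisible(x)
}

#' Correlation-network Laplacian builder
#'
#' The default network builder for the differential test: maps an
#' expression matrix to the normalized Laplacian of its
#' absolute-correlation network.  Since the weight matrix `W = |rho|`
#' has `w_ii = 1`, each gene carries a unit self-loop that enters the
#' degree used for normalization (see [normalized_laplacian()]); the
#' Laplacian diagonal is therefore `d_i / (1 + d_i)` and the spectrum
#' remains sensitive to the overall co-expression strength of the
#' group, which is what separates a co-regulated module from
#' uncorrelated noise.  Set `self_loop = FALSE` for the plain
#' zero-diagonal convention, under which only the relative edge
#' pattern matters.
#'
#' @param expression numeric matrix, samples in rows, genes in columns.
#' @param self_loop include the unit self-correlation in the degrees
#'   (default `TRUE`).
#' @return A [normalized_laplacian()].
#' @export
correlation_laplacian <- function(expression, self_loop = TRUE) {
  graph <- correlation_network(expression, warn_constant = FALSE)$graph
  normalized_laplacian(
    graph,
    self_weights = if (self_loop) rep(1, graph$n_vertices))
}

# Eigenvalues of one expression group under a given builder + solver config.
group_eigenvalues <- function(expression, network_builder, penalty, q,
                              tol, max_iter) {
  L <- network_builder(expression)
  fit <- suppressWarnings(net_sevd(L, q = q, penalty = penalty,
                                   tol = tol, max_iter = max_iter))
  fit$eigenvalues
}

#' Permutation test for differential network structure
#'
#' Tests whether the networks estimated from two phenotype groups differ
#' more than expected under exchangeable labels.  The observed statistic
#' is the spectral distance between the sparse eigenvalue spectra of the
#' two group networks.  For each of `T` permutations the group labels
#' are reshuffled over the pooled samples (group sizes preserved), both
#' networks are re-estimated from scratch (builder and sparse
#' eigen-solve), and the permutation distance recorded.  The p-value is
#' the fraction of permutations whose distance is at least the observed
#' one, `p = #\{d_obs <= d_perm\} / T`, with no continuity correction:
#' `p = 0` therefore means `p < 1/T`.
#'
#' Samples are pooled in the order `rbind(expr_Y, expr_N)`; the
#' permutation stream is drawn from `seed` against that canonical
#' ordering.
#'
#' @param expr_Y,expr_N expression matrices (samples x genes) for the
#'   two phenotypes, with the same genes in the same column order.
#' @param network_builder function mapping an expression matrix to a
#'   [normalized_laplacian()]; default [correlation_laplacian()].
#' @param penalty a [penalty_config()] for the eigen-solver.
#' @param q number of eigenvalue pairs compared (default: all `p`).
#' @param T number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param alpha significance level stored alongside the result.
#' @param tol,max_iter solver controls, see [net_sevd()].
#' @param squared use the squared-distance form (default) or its square
#'   root; the p-value is identical under any monotone transform.
#' @return A `permutation_result` list: `observed` (a
#'   [spectral_distance()]), `null_distances`, `T`, `p_value`, `seed`,
#'   `alpha`.
#' @export
permutation_test <- function(expr_Y, expr_N,
                             network_builder = correlation_laplacian,
                             penalty = penalty_config(), q = NULL,
                             T = 500, seed = NULL, alpha = 0.05,
                             tol = 1e-6, max_iter = 200, squared = TRUE) {
  expr_Y <- as.matrix(expr_Y); expr_N <- as.matrix(expr_N)
  if (ncol(expr_Y) != ncol(expr_N))
    stop("phenotype matrices must share the same genes", call. = FALSE)
  if (T < 1) stop("`T` must be at least 1", call. = FALSE)
  p <- ncol(expr_Y)
  if (is.null(q)) q <- p

  eigs_Y <- group_eigenvalues(expr_Y, network_builder, penalty, q, tol, max_iter)
  eigs_N <- group_eigenvalues(expr_N, network_builder, penalty, q, tol, max_iter)
  observed <- spectral_distance(eigs_Y, eigs_N, squared = squared)

  pooled <- rbind(expr_Y, expr_N)
  n_Y <- nrow(expr_Y); n <- nrow(pooled)
  if (!is.null(seed)) set.seed(seed)
  null_distances <- vapply(seq_len(T), function(pm) {
    idx <- sample.int(n)
    e1 <- group_eigenvalues(pooled[idx[seq_len(n_Y)], , drop = FALSE],
                            network_builder, penalty, q, tol, max_iter)
    e2 <- group_eigenvalues(pooled[idx[-seq_len(n_Y)], , drop = FALSE],
                            network_builder, penalty, q, tol, max_iter)
    spectral_distance(e1, e2, squared = squared)$value
  }, numeric(1))

  structure(list(
    observed       = observed,
    null_distances = null_distances,
    T              = T,
    p_value        = sum(observed$value <= null_distances) / T,
    seed           = seed,
    alpha          = alpha
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test: observed distance", signif(x$observed$value, 6),
      "p =", x$p_value, "(T =", x$T, ")\n")
  if (x$p_value == 0) cat("  (p = 0 means p < 1/T =", 1 / x$T, ")\n")
  invisible(x)
}

#' Identify differentially regulated sub-networks
#'
#' Runs the permutation test independently on each candidate
#' sub-network, restricted to that sub-network's gene columns, and flags
#' those with `p_value < alpha` (strict).  Per-sub-network seeds are
#' derived deterministically from the master seed, so the same inputs
#' and seed always give the same flag set.  No multiple-testing
#' correction is applied across sub-networks.
#'
#' @inheritParams permutation_test
#' @param subnetworks list of gene index vectors (or column-name
#'   vectors), each with at least 2 genes.
#' @param alpha significance level for flagging.
#' @return A `subnetwork_tests` list: `results` (one
#'   [permutation_test()] result per sub-network), `flagged` (logical),
#'   `table` (data frame: subnetwork_id, n_genes, distance, p_value,
#'   flagged), `alpha`.
#' @export
identify_differential_subnetworks <- function(subnetworks, expr_Y, expr_N,
                                              network_builder = correlation_laplacian,
                                              penalty = penalty_config(),
                                              q = NULL, T = 500, alpha = 0.05,
                                              seed = 1L, tol = 1e-6,
                                              max_iter = 200) {
  expr_Y <- as.matrix(expr_Y); expr_N <- as.matrix(expr_N)
  if (!is.list(subnetworks) || length(subnetworks) == 0)
    stop("`subnetworks` must be a non-empty list of gene sets", call. = FALSE)
  sizes <- lengths(subnetworks)
  if (any(sizes < 2))
    stop("sub-network(s) ", paste(which(sizes < 2), collapse = ", "),
         " have fewer than 2 genes", call. = FALSE)

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(subnetworks))

  results <- vector("list", length(subnetworks))
  for (i in seq_along(subnetworks)) {
    genes <- subnetworks[[i]]
    results[[i]] <- permutation_test(
      expr_Y[, genes, drop = FALSE], expr_N[, genes, drop = FALSE],
      network_builder = network_builder, penalty = penalty, q = q,
      T = T, seed = sub_seeds[i], alpha = alpha, tol = tol,
      max_iter = max_iter)
  }
  p_values <- vapply(results, `[[`, numeric(1), "p_value")
  flagged <- p_values < alpha
  ids <- names(subnetworks)
  if (is.null(ids)) ids <- paste0("subnetwork_", seq_along(subnetworks))
  names(flagged) <- names(results) <- ids
  structure(list(
    results = results,
    flagged = flagged,
    table = data.frame(
      subnetwork_id = ids,
      n_genes  = as.integer(sizes),
      distance = vapply(results, function(r) r$observed$value, numeric(1)),
      p_value  = p_values,
      flagged  = flagged,
      stringsAsFactors = FALSE),
    alpha = alpha
  ), class = "subnetwork_tests")
}

#' @export
print.subnetwork_tests <- function(x, ...) {
  cat("Differential sub-network tests (alpha =", x$alpha, "):",
      sum(x$flagged), "of", length(x$flagged), "flagged\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a differential sub-network test table
#'
#' Tab-separated: subnetwork_id, n_genes, distance, p_value, flagged.
#'
#' @param tests a [identify_differential_subnetworks()] result.
#' @param path output file.
#' @export
write_subnetwork_tests <- function(tests, path) {
  stopifnot(inherits(tests, "subnetwork_tests"))
  utils::write.table(tests$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
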