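#' Build a weighted gene network
#'
#' Constructs a weighted undirected graph from a symmetric non-negative
#' weight matrix.  Genes are vertices, `weights[i, j]` is the strength of
#' the edge between genes `i` and `j`; the degree of a vertex is the sum
#' of the weights of its incident edges.  Graphs are simple: a nonzero
#' diagonal is zeroed with a warning, and inputs that are symmetric only
#' up to numerical noise (relative tolerance `tol`) are symmetrized as
#' `(W + t(W)) / 2`.
#'
#' @param weights square numeric matrix of non-negative edge weights.
#' @param labels character vector of gene identifiers; defaults to the
#'   matrix dimnames or `g1, g2, ...`.
#' @param tol relative symmetry tolerance.
#' @return An object of class `weighted_graph` with elements `n_vertices`,
#'   `vertex_labels`, `weights` (zero-diagonal symmetric matrix),
#'   `adjacency` and `degrees`.
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 0), 2))
#' g$degrees
#' @export
weighted_graph <- function(weights, labels = NULL, tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  p <- nrow(weights)
  if (ncol(weights) != p)
    stop("`weights` must be square, got ", p, " x ", ncol(weights), call. = FALSE)
  if (anyNA(weights))
    stop("`weights` contains NA/NaN entries", call. = FALSE)
  asym <- abs(weights - t(weights))
  scale <- max(abs(weights), 1)
  if (max(asym) > tol * scale) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "`weights` is asymmetric beyond tolerance: entry (%d, %d) differs from (%d, %d) by %g",
      ij[1], ij[2], ij[2], ij[1], max(asym)), call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  if (min(weights) < 0)
    stop("negative edge weight found: w = ", min(weights), call. = FALSE)
  if (p > 0 && any(diag(weights) != 0)) {
    warning("nonzero diagonal (self-loops) zeroed", call. = FALSE)
  }
  diag(weights) <- 0

  if (is.null(labels)) labels <- rownames(weights)
  if (is.null(labels)) labels <- paste0("g", seq_len(p))
  labels <- as.character(labels)
  if (length(labels) != p)
    stop("`labels` must have length ", p, call. = FALSE)
  dimnames(weights) <- list(labels, labels)

  structure(list(
    n_vertices    = p,
    vertex_labels = labels,
    weights       = weights,
    adjacency     = weights,
    degrees       = rowSums(weights)
  ), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  n_edges <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("Weighted graph:", x$n_vertices, "vertices,", n_edges, "edges\n")
  invisible(x)
}

#' Degree matrix of a weighted graph
#'
#' @param graph a [weighted_graph()].
#' @return Diagonal matrix `D` with `D[i, i] = d_i`.
#' @export
degree_matrix <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  diag(graph$degrees, nrow = graph$n_vertices)
}

#' Normalized Laplacian of a weighted graph
#'
#' Computes `L = D^{-1/2} (D - A) D^{-1/2}`: diagonal entries are 1 for
#' vertices with nonzero degree, off-diagonal entries are
#' `-w_ij / sqrt(d_i d_j)` for edges, and 0 otherwise.  Isolated vertices
#' (degree 0) keep an all-zero row and column, contributing eigenvalue 0,
#' so Laplacians of two phenotype networks over the same gene set stay
#' size-aligned.  The spectrum of a normalized Laplacian lies in [0, 2].
#'
#' The `self_weights` argument supports graphs whose vertices carry a
#' self-loop (as correlation networks do, where `w_ii = |rho_ii| = 1`):
#' self-loop weight enters the degree used for normalization, so the
#' diagonal entry becomes `1 - s_i / d_i < 1` and the spectrum keeps
#' track of each vertex's total connectivity strength instead of
#' cancelling it.  A self-loop contributes nothing to `D - A`, so the
#' matrix stays positive semidefinite with spectrum in [0, 2].
#'
#' @param graph a [weighted_graph()].
#' @param self_weights optional length-p non-negative vector of
#'   self-loop weights added to the degrees (default none).
#' @return An object of class `normalized_laplacian` with elements
#'   `matrix` (the p x p Laplacian), `unnormalized` (`D - A`) and
#'   `source_graph`.
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 0), 2))
#' normalized_laplacian(g)$matrix
#' @export
normalized_laplacian <- function(graph, self_weights = NULL) {
  stopifnot(inherits(graph, "weighted_graph"))
  W <- graph$weights
  d_off <- graph$degrees
  L0 <- diag(d_off, nrow = graph$n_vertices) - W
  if (is.null(self_weights)) {
    d <- d_off
  } else {
    stopifnot(length(self_weights) == graph$n_vertices,
              all(self_weights >= 0))
    d <- d_off + self_weights
  }
  inv_sqrt_d <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- L0 * outer(inv_sqrt_d, inv_sqrt_d)
  # exact branch values on the diagonal: (d_i - w_ii) / d_i, 0 for
  # isolated vertices
  diag(L) <- ifelse(d > 0, d_off / d, 0)
  L <- (L + t(L)) / 2
  dimnames(L) <- dimnames(W)
  structure(list(
    matrix       = L,
    unnormalized = L0,
    source_graph = graph
  ), class = "normalized_laplacian")
}

#' @export
print.normalized_laplacian <- function(x, ...) {
  cat("Normalized Laplacian:", nrow(x$matrix), "x", ncol(x$matrix), "\n")
  invisible(x)
}

# Accept either a normalized_laplacian or a bare symmetric matrix.
as_laplacian_matrix <- function(laplacian) {
  if (inherits(laplacian, "normalized_laplacian")) return(laplacian$matrix)
  if (is.matrix(laplacian) && is.numeric(laplacian) &&
      nrow(laplacian) == ncol(laplacian)) return(laplacian)
  stop("expected a `normalized_laplacian` or a square numeric matrix",
       call. = FALSE)
}

#' Absolute-correlation gene network
#'
#' Builds a co-expression network from an expression matrix: edge weights
#' are the absolute Pearson correlations `|rho_ij|` between gene columns,
#' with the diagonal zeroed.  Genes with zero sample variance get all
#' correlations set to 0 (with a warning) rather than NA, so that
#' permutation resampling never produces an invalid graph.
#'
#' @param expression numeric matrix, samples in rows, genes in columns.
#' @param warn_constant warn when zero-variance genes are encountered.
#' @return An object of class `correlation_network` with elements
#'   `correlations` (signed Pearson matrix) and `graph` (a
#'   [weighted_graph()] with `W = |rho|`).
#' @export
correlation_network <- function(expression, warn_constant = TRUE) {
  expression <- as.matrix(expression)
  if (!is.numeric(expression)) stop("`expression` must be numeric", call. = FALSE)
  n <- nrow(expression)
  p <- ncol(expression)
  if (n < 3) stop("need at least 3 samples to estimate correlations", call. = FALSE)
  labels <- colnames(expression)
  if (is.null(labels)) labels <- paste0("g", seq_len(p))

  sds <- apply(expression, 2, stats::sd)
  constant <- !is.finite(sds) | sds == 0
  rho <- matrix(0, p, p, dimnames = list(labels, labels))
  if (any(!constant)) {
    rho[!constant, !constant] <- stats::cor(expression[, !constant, drop = FALSE])
  }
  if (any(constant) && warn_constant) {
    warning("zero-variance gene(s) ", paste(labels[constant], collapse = ", "),
            ": correlations set to 0", call. = FALSE)
  }
  diag(rho) <- 1
  W <- abs(rho)
  diag(W) <- 0
  structure(list(
    correlations = rho,
    graph        = weighted_graph(W, labels = labels)
  ), class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Correlation network over", x$graph$n_vertices, "genes\n")
  invisible(x)
}
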