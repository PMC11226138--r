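#' Scenario configuration for the Monte Carlo study
#'
#' The study design: two phenotype groups A and B of `n_A = n_B = 100`
#' samples over 10-gene sub-networks, five of which share a common
#' precision matrix between the groups while five are A-specific — group
#' A follows a structured Gaussian graphical model and group B is pure
#' independent noise of variance `sigma2`.  The four scenarios differ in
#' the precision structure: 1 = random, 2 = cluster, 3 = scale-free,
#' 4 = hub.
#'
#' @param structure `"random"`, `"cluster"`, `"scale_free"` or `"hub"`;
#'   a scenario number 1-4 is also accepted.
#' @param n_A,n_B group sample sizes.
#' @param genes_per_subnetwork genes per sub-network.
#' @param n_common,n_specific number of common / A-specific
#'   sub-networks.
#' @param sigma2 noise variance of group B on the A-specific genes.
#' @param T permutations per sub-network test.
#' @param n_reps replications of the whole experiment.
#' @param alpha significance level for flagging.
#' @param prob,within_prob,v,u precision-generator parameters, see
#'   [generate_precision_matrix()].
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(structure = "random", n_A = 100, n_B = 100,
                            genes_per_subnetwork = 10, n_common = 5,
                            n_specific = 5, sigma2 = 1, T = 500,
                            n_reps = 50, alpha = 0.05, prob = 0.3,
                            within_prob = 0.6, v = 0.3, u = 0.1) {
  structures <- c("random", "cluster", "scale_free", "hub")
  if (is.numeric(structure)) structure <- structures[structure]
  structure <- match.arg(structure, structures)
  stopifnot(n_A >= 3, n_B >= 3, genes_per_subnetwork >= 2,
            n_common >= 0, n_specific >= 0, n_common + n_specific >= 1,
            sigma2 > 0, T >= 1, n_reps >= 1, alpha >= 0, alpha <= 1)
  structure(list(structure = structure, n_A = n_A, n_B = n_B,
                 genes_per_subnetwork = genes_per_subnetwork,
                 n_common = n_common, n_specific = n_specific,
                 sigma2 = sigma2, T = T, n_reps = n_reps, alpha = alpha,
                 prob = prob, within_prob = within_prob, v = v, u = u),
            class = "scenario_config")
}

#' Generate a positive-definite precision matrix with graph structure
#'
#' Draws a binary edge structure of the requested kind, places the
#' off-diagonal value `v` on the structural edges (symmetrically), and
#' inflates the diagonal to `|lambda_min| + u` so the matrix is positive
#' definite with smallest eigenvalue at least `u`:
#' * `"random"` — each pair included independently with probability
#'   `prob`;
#' * `"cluster"` — two blocks of `p/2` genes with within-block edge
#'   probability `within_prob` and no between-block edges;
#' * `"scale_free"` — a preferential-attachment tree;
#' * `"hub"` — one center connected to all other vertices.
#'
#' @param structure structure kind (see above).
#' @param p number of genes.
#' @param prob edge-inclusion probability for `"random"`.
#' @param within_prob within-block edge probability for `"cluster"`.
#' @param n_blocks number of blocks for `"cluster"`.
#' @param v off-diagonal magnitude on structural edges.
#' @param u diagonal inflation margin (lower bound on the smallest
#'   eigenvalue).
#' @param seed optional integer seed.
#' @return A symmetric positive-definite p x p matrix.
#' @export
generate_precision_matrix <- function(structure = c("random", "cluster",
                                                    "scale_free", "hub"),
                                      p, prob = 0.3, within_prob = 0.6,
                                      n_blocks = 2, v = 0.3, u = 0.1,
                                      seed = NULL) {
  structure <- match.arg(structure)
  stopifnot(p >= 2)
  if (!is.null(seed)) set.seed(seed)

  theta <- matrix(0, p, p)
  if (structure == "random") {
    up <- upper.tri(theta)
    theta[up] <- stats::rbinom(sum(up), 1, prob)
  } else if (structure == "cluster") {
    blocks <- sort(rep_len(seq_len(n_blocks), p))
    up <- which(upper.tri(theta), arr.ind = TRUE)
    same <- blocks[up[, 1]] == blocks[up[, 2]]
    theta[up[same, , drop = FALSE]] <-
      stats::rbinom(sum(same), 1, within_prob)
  } else if (structure == "scale_free") {
    g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    theta[el] <- 1
    theta[el[, c(2, 1), drop = FALSE]] <- 1
    theta[lower.tri(theta)] <- 0
  } else {                                   # hub: star on vertex 1
    theta[1, 2:p] <- 1
  }
  theta <- theta + t(theta)
  theta[theta > 0] <- 1

  omega <- theta * v
  lam_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  diag(omega) <- abs(lam_min) + u
  omega
}

# n draws from N(0, Sigma) via the Cholesky factor.
rmvnorm_chol <- function(n, Sigma) {
  R <- chol(Sigma)
  matrix(stats::rnorm(n * ncol(Sigma)), n) %*% R
}

#' Generate one Monte Carlo scenario dataset
#'
#' Common sub-networks: all `n_A + n_B` samples are drawn jointly from
#' `N(0, Omega_c^{-1})` and then split into the two groups (for
#' Gaussians this is distributionally identical to drawing the groups
#' separately from the same precision; set `joint_common = FALSE` for
#' the per-group stream).  A-specific sub-networks: group A is drawn
#' from `N(0, Omega_A^{-1})` while group B is i.i.d. `N(0, sigma2)`
#' noise.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @param joint_common draw common-gene samples jointly then split
#'   (default) or per group.
#' @return A `scenario_dataset` list: `expr_A`, `expr_B` (matrices with
#'   one column block per sub-network), `subnetworks` (named list of
#'   column indices), `truth` (`"common"` / `"A_specific"` per
#'   sub-network), `precisions`, `config`.
#' @export
generate_scenario <- function(config, seed = NULL, joint_common = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  k <- config$genes_per_subnetwork
  n_sub <- config$n_common + config$n_specific
  n_A <- config$n_A; n_B <- config$n_B
  expr_A <- matrix(NA_real_, n_A, n_sub * k)
  expr_B <- matrix(NA_real_, n_B, n_sub * k)
  precisions <- vector("list", n_sub)
  truth <- character(n_sub)
  subnetworks <- vector("list", n_sub)
  ids <- character(n_sub)

  for (nw in seq_len(n_sub)) {
    cols <- (nw - 1L) * k + seq_len(k)
    subnetworks[[nw]] <- cols
    omega <- generate_precision_matrix(config$structure, k,
                                       prob = config$prob,
                                       within_prob = config$within_prob,
                                       v = config$v, u = config$u)
    precisions[[nw]] <- omega
    Sigma <- solve(omega)
    if (nw <= config$n_common) {
      truth[nw] <- "common"
      ids[nw] <- paste0("common_", nw)
      if (joint_common) {
        X <- rmvnorm_chol(n_A + n_B, Sigma)
        expr_A[, cols] <- X[seq_len(n_A), ]
        expr_B[, cols] <- X[n_A + seq_len(n_B), ]
      } else {
        expr_A[, cols] <- rmvnorm_chol(n_A, Sigma)
        expr_B[, cols] <- rmvnorm_chol(n_B, Sigma)
      }
    } else {
      truth[nw] <- "A_specific"
      ids[nw] <- paste0("specific_", nw - config$n_common)
      expr_A[, cols] <- rmvnorm_chol(n_A, Sigma)
      expr_B[, cols] <- matrix(stats::rnorm(n_B * k, sd = sqrt(config$sigma2)),
                               n_B)
    }
  }
  gene_names <- unlist(lapply(seq_len(n_sub), function(nw)
    paste0(ids[nw], "_g", seq_len(k))))
  colnames(expr_A) <- colnames(expr_B) <- gene_names
  names(subnetworks) <- names(precisions) <- names(truth) <- ids

  structure(list(expr_A = expr_A, expr_B = expr_B,
                 subnetworks = subnetworks, truth = truth,
                 precisions = precisions, config = config),
            class = "scenario_dataset")
}

# Map a method label to its eigen-solver penalty configuration.
method_penalty <- function(method, gamma1 = 0.1, gamma2 = 0.1) {
  switch(method,
    ssDGN    = penalty_config(gamma1, gamma2, kind = "network"),
    ssDGNs   = penalty_config(gamma1, gamma2, kind = "sign_adjusted_network"),
    sPCA     = penalty_config(gamma1, gamma2, kind = "ridge"),
    sPCAwoL2 = penalty_config(gamma1, 0, kind = "none"),
    oEVD     = penalty_config(0, 0, kind = "dense"),
    stop("unknown method: ", method, call. = FALSE))
}

# Confusion counts -> the five identification metrics.  With no flags at
# all, precision is 1 if nothing was missed and 0 otherwise (never hit in
# the study design); an empty precision+recall sum gives F = 0.
classification_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  f <- if (!is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  c(accuracy = (tp + tn) / total, f_measure = f, tnr = tnr,
    recall = recall, precision = precision)
}

#' Run the differential-network identification experiment
#'
#' For each replication: generate a scenario dataset, build per-phenotype
#' absolute-correlation networks and normalized Laplacians per
#' sub-network, compute the method's sparse eigenvalues, permutation
#' p-values and flags at `p < alpha`; count flagged A-specific
#' sub-networks as true positives and unflagged common ones as true
#' negatives; report accuracy, F-measure, TNR, recall and precision
#' averaged over replications with standard deviations.
#'
#' @param config a [scenario_config()].
#' @param method `"ssDGN"` (network penalty), `"ssDGNs"` (sign-adjusted
#'   network penalty), `"sPCA"` (ridge), `"sPCAwoL2"` (L1 only) or
#'   `"oEVD"` (dense, unpenalized).
#' @param seed master seed; all replication and permutation seeds derive
#'   from it.
#' @param gamma1,gamma2 regularization weights for the penalized
#'   methods.
#' @return An `identification_metrics` list: `mean`, `sd` (named
#'   vectors over the five metrics), `per_replication` (data frame with
#'   confusion counts and metrics), `method`, `config`.
#' @export
run_experiment <- function(config, method = "ssDGN", seed = 1L,
                           gamma1 = 0.1, gamma2 = 0.1) {
  stopifnot(inherits(config, "scenario_config"))
  method <- match.arg(method, c("ssDGN", "ssDGNs", "sPCA", "sPCAwoL2", "oEVD"))
  penalty <- method_penalty(method, gamma1, gamma2)

  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 2L * config$n_reps), ncol = 2)
  per_rep <- vector("list", config$n_reps)
  for (rep in seq_len(config$n_reps)) {
    dat <- generate_scenario(config, seed = rep_seeds[rep, 1])
    tests <- identify_differential_subnetworks(
      dat$subnetworks, dat$expr_A, dat$expr_B,
      penalty = penalty, T = config$T, alpha = config$alpha,
      seed = rep_seeds[rep, 2])
    specific <- dat$truth == "A_specific"
    tp <- sum(tests$flagged & specific)
    fn <- sum(!tests$flagged & specific)
    fp <- sum(tests$flagged & !specific)
    tn <- sum(!tests$flagged & !specific)
    per_rep[[rep]] <- c(tp = tp, tn = tn, fp = fp, fn = fn,
                        classification_metrics(tp, tn, fp, fn))
  }
  per_rep <- as.data.frame(do.call(rbind, per_rep))
  metric_names <- c("accuracy", "f_measure", "tnr", "recall", "precision")
  structure(list(
    mean = colMeans(per_rep[metric_names], na.rm = TRUE),
    sd = vapply(per_rep[metric_names], stats::sd, numeric(1), na.rm = TRUE),
    per_replication = per_rep,
    method = method, config = config, seed = seed,
    gamma1 = gamma1, gamma2 = gamma2
  ), class = "identification_metrics")
}

#' @export
print.identification_metrics <- function(x, ...) {
  cat("Identification metrics:", x$method, "| structure",
      x$config$structure, "| sigma2", x$config$sigma2, "|",
      x$config$n_reps, "replications, T =", x$config$T, "\n")
  out <- rbind(mean = round(x$mean, 3), sd = round(x$sd, 3))
  print(out)
  invisible(x)
}

#' Write an experiment report table
#'
#' One row per (method, metric): mean and standard deviation over
#' replications, tab-separated.
#'
#' @param results a list of [run_experiment()] results (or a single
#'   one).
#' @param path output file.
#' @export
write_experiment_report <- function(results, path) {
  if (inherits(results, "identification_metrics")) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, structure = r$config$structure,
               sigma2 = r$config$sigma2, metric = names(r$mean),
               mean = unname(r$mean), sd = unname(r$sd),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
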