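#' Lasso neighborhood-selection estimate of a gene regulatory network
#'
#' Regresses each target gene on all remaining genes with an L1 penalty
#' (one lasso per target, coordinate descent via glmnet), then
#' symmetrizes the coefficient magnitudes into undirected edge weights
#' `w_ij = (|delta_ij| + |delta_ji|) / 2`.  Expression columns are
#' standardized (mean 0, variance 1) before fitting, so that magnitudes
#' are comparable across regressions with different targets; the
#' coefficients are reported on that standardized scale.
#'
#' @param expression numeric matrix, samples in rows, genes in columns
#'   (`n >= 10`, `p >= 2`).
#' @param lambda_rule `"cv"` (per-target 5-fold cross-validation with
#'   the one-standard-error rule), `"fixed"` (a shared `lambda`), or
#'   `"bic"` (per-target BIC over the glmnet path).
#' @param lambda penalty weight for `lambda_rule = "fixed"`, on the
#'   residual-sum-of-squares scale
#'   `sum_i (x_ij - delta' x_i)^2 + lambda * sum |delta_k|`.
#' @param nfolds folds for `"cv"`.
#' @param seed seed for the cross-validation fold assignment.
#' @return A `regulatory_network_estimate` list: `coefficients` (p x p,
#'   entry `(j, k)` is the effect of regulator `k` on target `j`,
#'   structural zero diagonal), `lambda` (per target, RSS scale),
#'   `weights`, `graph` (a [weighted_graph()]), `lambda_rule`.
#' @export
fit_regulatory_network <- function(expression, lambda_rule = c("cv", "fixed", "bic"),
                                   lambda = NULL, nfolds = 5, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  expression <- as.matrix(expression)
  n <- nrow(expression); p <- ncol(expression)
  if (n < 10) stop("need at least 10 samples, got ", n, call. = FALSE)
  if (p < 2) stop("need at least 2 genes, got ", p, call. = FALSE)
  if (lambda_rule == "fixed" && (is.null(lambda) || lambda < 0))
    stop("`lambda_rule = \"fixed\"` requires a non-negative `lambda`",
         call. = FALSE)
  labels <- colnames(expression)
  if (is.null(labels)) labels <- paste0("g", seq_len(p))

  sds <- apply(expression, 2, stats::sd)
  constant <- !is.finite(sds) | sds == 0
  Xs <- scale(expression)
  Xs[, constant] <- 0

  delta <- matrix(0, p, p, dimnames = list(labels, labels))
  lambdas <- rep(NA_real_, p)
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_len(p)) {
    if (constant[j]) {
      message("constant target gene ", labels[j], ": zero coefficient row")
      next
    }
    y <- Xs[, j]
    X <- Xs[, -j, drop = FALSE]
    # glmnet needs two or more predictors; pad a structural zero column
    padded <- ncol(X) == 1
    if (padded) X <- cbind(X, 0)
    # glmnet minimizes RSS/(2n) + lambda_g*||.||_1, so lambda_g = lambda/(2n)
    if (lambda_rule == "fixed") {
      fit <- glmnet::glmnet(X, y, standardize = FALSE, intercept = FALSE,
                            thresh = 1e-10)
      lam_g <- lambda / (2 * n)
      co <- as.numeric(stats::coef(fit, s = lam_g, exact = TRUE, x = X, y = y,
                                   standardize = FALSE,
                                   intercept = FALSE))[-1]
      lambdas[j] <- lambda
    } else if (lambda_rule == "cv") {
      foldid <- sample(rep_len(seq_len(nfolds), n))
      cv <- glmnet::cv.glmnet(X, y, standardize = FALSE, intercept = FALSE,
                              foldid = foldid, thresh = 1e-10)
      co <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1]
      lambdas[j] <- cv$lambda.1se * 2 * n
    } else {                               # bic over the glmnet path
      fit <- glmnet::glmnet(X, y, standardize = FALSE, intercept = FALSE,
                            thresh = 1e-10)
      pred <- stats::predict(fit, X)
      rss <- colSums((y - pred)^2)
      bic <- n * log(pmax(rss, 1e-12) / n) + fit$df * log(n)
      best <- which.min(bic)
      co <- as.numeric(fit$beta[, best])
      lambdas[j] <- fit$lambda[best] * 2 * n
    }
    if (padded) co <- co[1]
    delta[j, -j] <- co
  }
  weights <- (abs(delta) + t(abs(delta))) / 2
  structure(list(
    coefficients = delta,
    lambda       = stats::setNames(lambdas, labels),
    weights      = weights,
    graph        = weighted_graph(weights, labels = labels),
    lambda_rule  = lambda_rule
  ), class = "regulatory_network_estimate")
}

#' @export
print.regulatory_network_estimate <- function(x, ...) {
  cat("Lasso regulatory network:", nrow(x$weights), "genes,",
      sum(x$weights[upper.tri(x$weights)] > 0), "edges (rule:",
      x$lambda_rule, ")\n")
  invisible(x)
}

#' Split samples into sensitive and resistant groups by quartiles
#'
#' Drug-sensitive samples have sensitivity (log IC50) strictly below the
#' first quartile, resistant samples strictly above the third; the
#' middle half is excluded.  Quartiles use the linear-interpolation
#' convention (`stats::quantile` type 7).
#'
#' @param sensitivity named numeric vector of per-sample drug
#'   sensitivity values (names are sample IDs), or a two-column data
#'   frame `(sample_id, value)`.
#' @param min_group minimum size of each tail group.
#' @return A `phenotype_split` list: `sensitivity`, `q1`, `q3`,
#'   `sensitive_ids`, `resistant_ids`.
#' @export
split_by_quartiles <- function(sensitivity, min_group = 2) {
  if (is.data.frame(sensitivity)) {
    stopifnot(ncol(sensitivity) >= 2)
    sensitivity <- stats::setNames(as.numeric(sensitivity[[2]]),
                                   as.character(sensitivity[[1]]))
  }
  if (length(sensitivity) < 8)
    stop("need at least 8 samples to split by quartiles", call. = FALSE)
  if (anyNA(sensitivity)) stop("NA sensitivity values", call. = FALSE)
  ids <- names(sensitivity)
  if (is.null(ids)) ids <- as.character(seq_along(sensitivity))
  q <- stats::quantile(sensitivity, c(0.25, 0.75), names = FALSE, type = 7)
  sensitive <- ids[sensitivity < q[1]]
  resistant <- ids[sensitivity > q[2]]
  if (length(sensitive) < min_group || length(resistant) < min_group)
    stop("too few samples in a tail group (sensitive: ", length(sensitive),
         ", resistant: ", length(resistant), ")", call. = FALSE)
  structure(list(sensitivity = stats::setNames(sensitivity, ids),
                 q1 = q[1], q3 = q[2],
                 sensitive_ids = sensitive, resistant_ids = resistant),
            class = "phenotype_split")
}

#' Keep the highest-variance genes
#'
#' Keeps `ceiling(fraction * p)` genes ranked by sample variance, ties
#' broken by gene-label order.
#'
#' @param expression numeric matrix, samples in rows, genes in columns.
#' @param fraction proportion of genes to keep, in (0, 1].
#' @return List with `expression` (reduced matrix) and `genes` (kept
#'   labels, in original column order).
#' @export
filter_top_variance <- function(expression, fraction = 0.1) {
  expression <- as.matrix(expression)
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  p <- ncol(expression)
  labels <- colnames(expression)
  if (is.null(labels)) labels <- paste0("g", seq_len(p))
  vars <- apply(expression, 2, stats::var)
  keep_n <- ceiling(fraction * p)
  ranked <- order(-vars, labels)
  keep <- sort(ranked[seq_len(keep_n)])
  list(expression = expression[, keep, drop = FALSE], genes = labels[keep])
}

# Nonzero undirected edges of a network, as a data frame sorted by
# decreasing weight with lexicographic (gene_i, gene_j) tie-break.
network_edges <- function(network) {
  graph <- if (inherits(network, "regulatory_network_estimate")) network$graph
           else if (inherits(network, "weighted_graph")) network
           else stop("expected a regulatory network estimate or weighted graph",
                     call. = FALSE)
  W <- graph$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(
    gene_i = graph$vertex_labels[idx[, 1]],
    gene_j = graph$vertex_labels[idx[, 2]],
    weight = W[idx],
    stringsAsFactors = FALSE)
  edges[order(-edges$weight, edges$gene_i, edges$gene_j), , drop = FALSE]
}

#' Extract sub-networks from the strongest edges
#'
#' Keeps the top `ceiling(edge_fraction * #nonzero edges)` edges by
#' weight (ties by lexicographic gene pair) and returns the connected
#' components of the kept-edge graph whose node count is strictly
#' greater than `min_nodes`.
#'
#' @param network a `regulatory_network_estimate` or
#'   [weighted_graph()].
#' @param edge_fraction proportion of nonzero edges to keep.
#' @param min_nodes strict lower bound on component size (a component
#'   must have more than `min_nodes` nodes).
#' @return List of gene-label vectors, one per qualifying component
#'   (possibly empty), with the kept edges attached as attribute
#'   `"kept_edges"`.
#' @export
extract_top_edge_subnetworks <- function(network, edge_fraction = 0.01,
                                         min_nodes = 5) {
  edges <- network_edges(network)
  if (nrow(edges) == 0) {
    out <- list()
    attr(out, "kept_edges") <- edges
    return(out)
  }
  keep_n <- ceiling(edge_fraction * nrow(edges))
  kept <- edges[seq_len(keep_n), , drop = FALSE]
  comps <- edge_components(kept)
  out <- comps[vapply(comps, length, integer(1)) > min_nodes]
  attr(out, "kept_edges") <- kept
  out
}

# Connected components of an edge list, each sorted, ordered by size
# (desc) then first gene label for determinism.
edge_components <- function(edges) {
  if (nrow(edges) == 0) return(list())
  g <- igraph::graph_from_data_frame(edges[, c("gene_i", "gene_j")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(comps, function(x) sort(unname(x)))
  ord <- order(-vapply(comps, length, integer(1)),
               vapply(comps, `[`, character(1), 1))
  unname(comps[ord])
}

#' Pipeline configuration
#'
#' @param alpha significance level for flagging sub-networks.
#' @param edge_fraction proportion of strongest edges kept per
#'   phenotype network.
#' @param min_nodes strict lower bound on candidate sub-network size.
#' @param min_marker_edges minimum degree in the resistance-specific
#'   flagged networks for a gene to be listed as a marker.
#' @param top_variance_fraction proportion of genes kept by the
#'   variance filter.
#' @param T number of permutations per sub-network test.
#' @param lambda_rule,lambda,nfolds lasso controls, see
#'   [fit_regulatory_network()].
#' @param gamma1,gamma2,penalty_kind eigen-solver controls, see
#'   [penalty_config()].
#' @param candidate_rule form candidate sub-networks from the components
#'   of the union of both phenotypes' kept edges (`"union"`, default) or
#'   from each phenotype's own kept-edge graph (`"per_phenotype"`).
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, edge_fraction = 0.01, min_nodes = 5,
                            min_marker_edges = 3, top_variance_fraction = 0.1,
                            T = 500, lambda_rule = "cv", lambda = NULL,
                            nfolds = 5, gamma1 = 0.1, gamma2 = 0.1,
                            penalty_kind = "network",
                            candidate_rule = c("union", "per_phenotype"),
                            seed = 1L) {
  structure(list(alpha = alpha, edge_fraction = edge_fraction,
                 min_nodes = min_nodes, min_marker_edges = min_marker_edges,
                 top_variance_fraction = top_variance_fraction, T = T,
                 lambda_rule = lambda_rule, lambda = lambda, nfolds = nfolds,
                 gamma1 = gamma1, gamma2 = gamma2,
                 penalty_kind = penalty_kind,
                 candidate_rule = match.arg(candidate_rule),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Differential gene-network pipeline for drug-response data
#'
#' End-to-end workflow: split cell lines into drug-sensitive and
#' -resistant groups by sensitivity quartiles; keep the top-variance
#' genes; estimate a lasso regulatory network per phenotype; keep each
#' phenotype's strongest edges and form candidate sub-networks from the
#' connected components of their union; test each candidate with the
#' spectral-distance permutation test (re-estimating lasso networks for
#' every permutation); match flagged sub-networks back to the resistant
#' phenotype's kept edges and list marker genes with at least
#' `min_marker_edges` incident edges there.
#'
#' @param expression numeric matrix, cell lines in rows (rownames are
#'   sample IDs), genes in columns.
#' @param sensitivity named numeric vector (or two-column data frame)
#'   of per-sample log IC50 values.
#' @param config a [pipeline_config()].
#' @return A `pipeline_report` list: `split`, `kept_genes`,
#'   `network_sensitive`, `network_resistant`, `edges_sensitive`,
#'   `edges_resistant` (kept top edges), `candidates`, `tests`,
#'   `flagged_subnetworks`, `markers` (data frame gene / edge_count),
#'   `manifest`, `config`.
#' @export
run_differential_pipeline <- function(expression, sensitivity,
                                      config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  expression <- as.matrix(expression)
  if (is.data.frame(sensitivity)) {
    sensitivity <- stats::setNames(as.numeric(sensitivity[[2]]),
                                   as.character(sensitivity[[1]]))
  }
  ids <- intersect(rownames(expression), names(sensitivity))
  if (length(ids) == 0)
    stop("phenotype split stage: no matched sample IDs between expression ",
         "and sensitivity", call. = FALSE)
  expression <- expression[ids, , drop = FALSE]
  sensitivity <- sensitivity[ids]

  split <- split_by_quartiles(sensitivity)
  filt <- filter_top_variance(expression, config$top_variance_fraction)
  expr_st <- filt$expression[split$sensitive_ids, , drop = FALSE]
  expr_rs <- filt$expression[split$resistant_ids, , drop = FALSE]

  fit_net <- function(X, seed) fit_regulatory_network(
    X, lambda_rule = config$lambda_rule, lambda = config$lambda,
    nfolds = config$nfolds, seed = seed)
  nw_st <- fit_net(expr_st, config$seed)
  nw_rs <- fit_net(expr_rs, config$seed)

  sub_st <- extract_top_edge_subnetworks(nw_st, config$edge_fraction,
                                         config$min_nodes)
  sub_rs <- extract_top_edge_subnetworks(nw_rs, config$edge_fraction,
                                         config$min_nodes)
  edges_st <- attr(sub_st, "kept_edges")
  edges_rs <- attr(sub_rs, "kept_edges")

  if (config$candidate_rule == "union") {
    candidates <- edge_components(rbind(edges_st, edges_rs))
    candidates <- candidates[vapply(candidates, length, integer(1)) >
                               config$min_nodes]
  } else {
    candidates <- unique(c(sub_st, sub_rs))
  }

  builder <- function(X) normalized_laplacian(
    fit_regulatory_network(X, lambda_rule = config$lambda_rule,
                           lambda = config$lambda, nfolds = config$nfolds,
                           seed = config$seed)$graph)
  penalty <- penalty_config(config$gamma1, config$gamma2,
                            kind = config$penalty_kind)

  if (length(candidates) > 0) {
    names(candidates) <- paste0("subnetwork_", seq_along(candidates))
    tests <- identify_differential_subnetworks(
      candidates, expr_st, expr_rs, network_builder = builder,
      penalty = penalty, T = config$T, alpha = config$alpha,
      seed = config$seed)
    flagged <- candidates[tests$flagged]
  } else {
    tests <- NULL
    flagged <- list()
  }

  # markers: degree in the resistant phenotype's kept edges restricted
  # to flagged sub-networks
  markers <- data.frame(gene = character(0), edge_count = integer(0),
                        stringsAsFactors = FALSE)
  if (length(flagged) > 0 && nrow(edges_rs) > 0) {
    genes <- unlist(flagged, use.names = FALSE)
    in_flagged <- edges_rs$gene_i %in% genes & edges_rs$gene_j %in% genes
    deg <- table(c(edges_rs$gene_i[in_flagged], edges_rs$gene_j[in_flagged]))
    deg <- deg[deg >= config$min_marker_edges]
    if (length(deg) > 0) {
      ord <- order(-as.integer(deg), names(deg))
      markers <- data.frame(gene = names(deg)[ord],
                            edge_count = as.integer(deg)[ord],
                            stringsAsFactors = FALSE)
    }
  }

  manifest <- run_manifest("pipeline", config, config$seed,
                           timings = c(total = proc.time()[["elapsed"]] - t0))
  structure(list(
    split = split, kept_genes = filt$genes,
    network_sensitive = nw_st, network_resistant = nw_rs,
    edges_sensitive = edges_st, edges_resistant = edges_rs,
    candidates = candidates, tests = tests,
    flagged_subnetworks = flagged, markers = markers,
    manifest = manifest, config = config
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Differential network pipeline\n")
  cat("  sensitive / resistant cell lines:",
      length(x$split$sensitive_ids), "/", length(x$split$resistant_ids), "\n")
  cat("  genes after variance filter:", length(x$kept_genes), "\n")
  cat("  candidate sub-networks:", length(x$candidates),
      "| flagged:", length(x$flagged_subnetworks), "\n")
  if (nrow(x$markers) > 0) {
    cat("  markers (gene: edges):",
        paste0(x$markers$gene, " (", x$markers$edge_count, ")",
               collapse = ", "), "\n")
  } else cat("  markers: none\n")
  invisible(x)
}

#' Synthetic drug-response dataset with a planted resistance module
#'
#' Generates a synthetic stand-in for a drug-sensitivity study: cell
#' lines with log IC50 values and an expression matrix in which one
#' hub-structured gene module is co-regulated only in the resistant
#' (top-quartile) cell lines, one module is co-regulated in all cell
#' lines, and the remaining genes are low-variance background noise.
#' Ground truth (module memberships, hub gene and its true degree) is
#' returned alongside, for end-to-end validation of
#' [run_differential_pipeline()].
#'
#' @param n_cell_lines number of cell lines.
#' @param module_size genes per module (one hub + `module_size - 1`
#'   partners).
#' @param n_background number of background noise genes.
#' @param hub_coef coupling of module partners to their hub.
#' @param background_sd standard deviation of background genes (below 1
#'   so the variance filter removes them).
#' @param seed integer seed.
#' @return List with `expression`, `sensitivity` (named vector) and
#'   `truth` (list: `resistance_module`, `common_module`, `hub`,
#'   `hub_edges`, `resistant_ids`, `sensitive_ids`).
#' @export
simulate_drug_response_dataset <- function(n_cell_lines = 800, module_size = 7,
                                           n_background = 26, hub_coef = 0.8,
                                           background_sd = 0.5, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("CL%03d", seq_len(n_cell_lines))
  sensitivity <- stats::setNames(stats::rnorm(n_cell_lines), ids)
  q3 <- stats::quantile(sensitivity, 0.75, names = FALSE, type = 7)
  q1 <- stats::quantile(sensitivity, 0.25, names = FALSE, type = 7)
  resistant <- ids[sensitivity > q3]
  sensitive <- ids[sensitivity < q1]

  res_genes <- c("RESHUB1", sprintf("RESG%02d", seq_len(module_size - 1)))
  com_genes <- c("COMHUB1", sprintf("COMG%02d", seq_len(module_size - 1)))
  bg_genes <- sprintf("BG%03d", seq_len(n_background))
  genes <- c(res_genes, com_genes, bg_genes)

  n <- n_cell_lines
  expr <- matrix(stats::rnorm(n * length(genes)), n,
                 dimnames = list(ids, genes))
  partner_sd <- sqrt(1 - hub_coef^2)       # partners keep unit variance

  # resistance module: hub-driven only in resistant lines
  in_rs <- ids %in% resistant
  hub <- expr[, "RESHUB1"]
  for (g in res_genes[-1]) {
    expr[in_rs, g] <- hub_coef * hub[in_rs] +
      partner_sd * stats::rnorm(sum(in_rs))
  }
  # common module: hub-driven in every cell line
  hub <- expr[, "COMHUB1"]
  for (g in com_genes[-1]) {
    expr[, g] <- hub_coef * hub + partner_sd * stats::rnorm(n)
  }
  expr[, bg_genes] <- background_sd * expr[, bg_genes]

  list(expression = expr, sensitivity = sensitivity,
       truth = list(resistance_module = sort(res_genes),
                    common_module = sort(com_genes),
                    hub = "RESHUB1", hub_edges = module_size - 1L,
                    resistant_ids = resistant, sensitive_ids = sensitive))
}
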