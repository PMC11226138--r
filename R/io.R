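#' Load an expression matrix from delimited text
#'
#' Expects one header row of labels and one leading ID column; every
#' remaining cell must be numeric.  By the package's file convention
#' samples are in rows and genes in columns; files stored the other way
#' around are read with `orientation = "genes_in_rows"`.
#'
#' @param path file path.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"genes_in_rows"` (the matrix is transposed after reading).
#' @param sep field separator (default tab).
#' @return Numeric matrix with sample IDs as rownames and gene labels
#'   as colnames.
#' @export
load_expression <- function(path, orientation = c("samples_in_rows",
                                                  "genes_in_rows"),
                            sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  m <- matrix(NA_real_, nrow(raw), ncol(raw),
              dimnames = list(rownames(raw), colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric cell \"%s\" at row \"%s\", column \"%s\"",
                   raw[[j]][bad[1]], rownames(raw)[bad[1]],
                   colnames(raw)[j]), call. = FALSE)
    m[, j] <- v
  }
  if (orientation == "genes_in_rows") m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicate gene labels: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  m
}

#' Write an expression matrix as delimited text
#'
#' @param expression numeric matrix, samples in rows.
#' @param path output file.
#' @param sep field separator.
#' @export
write_expression <- function(expression, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(expression),
                   expression, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a weighted network to file
#'
#' Two formats: `"edge_list"` (tab-separated `gene_i`, `gene_j`,
#' `weight`; one line per unordered pair with nonzero weight; an empty
#' graph yields a header-only file) and `"matrix"` (full weight matrix
#' with gene labels as first row and column).  Both round-trip through
#' [read_network()] to at least 12 significant digits.
#'
#' @param graph a [weighted_graph()].
#' @param path output file.
#' @param format `"edge_list"` or `"matrix"`.
#' @export
write_network <- function(graph, path, format = c("edge_list", "matrix")) {
  stopifnot(inherits(graph, "weighted_graph"))
  format <- match.arg(format)
  if (format == "edge_list") {
    W <- graph$weights
    idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    df <- data.frame(gene_i = graph$vertex_labels[idx[, 1]],
                     gene_j = graph$vertex_labels[idx[, 2]],
                     weight = sprintf("%.15g", W[idx]),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    df <- data.frame(gene = graph$vertex_labels,
                     apply(graph$weights, 2, sprintf, fmt = "%.15g"),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene", graph$vertex_labels)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a weighted network from file
#'
#' @param path file written by [write_network()] (or any file in one of
#'   its two formats; an edge-list header is optional).
#' @param format `"edge_list"` or `"matrix"`.
#' @param labels full vertex label set for edge-list files, so isolated
#'   vertices survive the round trip; defaults to the genes present in
#'   the file.
#' @return A [weighted_graph()].
#' @export
read_network <- function(path, format = c("edge_list", "matrix"),
                         labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edge_list") {
    first <- readLines(path, n = 1)
    has_header <- grepl("gene_i", first, fixed = TRUE)
    df <- utils::read.table(path, header = has_header, sep = "\t",
                            colClasses = c("character", "character",
                                           "numeric"))
    colnames(df) <- c("gene_i", "gene_j", "weight")
    if (is.null(labels)) labels <- sort(unique(c(df$gene_i, df$gene_j)))
    p <- length(labels)
    W <- matrix(0, p, p, dimnames = list(labels, labels))
    for (i in seq_len(nrow(df))) {
      W[df$gene_i[i], df$gene_j[i]] <- df$weight[i]
      W[df$gene_j[i], df$gene_i[i]] <- df$weight[i]
    }
    weighted_graph(W, labels = labels)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, row.names = 1)
    W <- as.matrix(df)
    weighted_graph(W, labels = rownames(df))
  }
}

#' Run manifest
#'
#' Provenance record attached to every pipeline output: the subcommand,
#' an MD5 digest of the resolved configuration, the master seed, the
#' package version and informational per-stage timings.
#'
#' @param command subcommand or entry-point name.
#' @param config configuration object (any R value; digested after
#'   deparsing).
#' @param seed master seed.
#' @param timings named numeric vector of wall-clock seconds.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(command, config, seed, timings = numeric(0)) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  structure(list(
    command = command,
    config_hash = unname(tools::md5sum(tf)),
    seed = seed,
    version = as.character(utils::packageVersion("netsevd")),
    timings = timings
  ), class = "run_manifest")
}

#' Write a run manifest as key-value text
#'
#' @param manifest a [run_manifest()].
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  lines <- c(paste0("command\t", manifest$command),
             paste0("config_hash\t", manifest$config_hash),
             paste0("seed\t", manifest$seed),
             paste0("version\t", manifest$version))
  if (length(manifest$timings) > 0)
    lines <- c(lines, sprintf("timing_%s\t%.3f", names(manifest$timings),
                              manifest$timings))
  writeLines(lines, path)
  invisible(path)
}
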