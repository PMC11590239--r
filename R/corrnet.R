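#' Spearman rank correlation of two vectors
#'
#' Computed as the Pearson product-moment correlation of average-ranked
#' values (ties receive their average rank). Binary, ordinal and count
#' variables enter as numeric ranks, matching the construction of a single
#' mixed correlation matrix.
#'
#' @param x,y numeric vectors of equal length (at least 3), no missing
#'   values.
#' @return the coefficient in `[-1, 1]`, or `NA` if either vector has zero
#'   variance (the matrix builder maps that to 0 with a warning).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, !anyNA(x), !anyNA(y))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sx * sy)
}

#' Full pairwise Spearman matrix of a cohort table
#'
#' Requires a complete (post-imputation) table. Zero-variance columns cannot
#' carry rank information; their rows and columns are set to 0 and a warning
#' names them. This degradation (rather than an error) matters during
#' bootstrap resampling, where a low-prevalence binary variable can easily be
#' constant in a resample.
#'
#' @param table a complete [cohort_table()].
#' @return a `correlation_matrix` in variable order.
#' @export
correlation_matrix_of <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (anyNA(as.matrix(table$data))) {
    stop("table has missing values; impute first")
  }
  m <- as.matrix(table$data)
  spearman_matrix(m)
}

# shared fast path: ranks once per column, then Pearson on ranks
spearman_matrix <- function(m, warn = TRUE) {
  ranks <- apply(m, 2, rank, ties.method = "average")
  sds <- apply(ranks, 2, stats::sd)
  degenerate <- sds == 0
  out <- matrix(0, ncol(m), ncol(m), dimnames = list(colnames(m), colnames(m)))
  ok <- !degenerate
  if (sum(ok) >= 2) {
    out[ok, ok] <- stats::cor(ranks[, ok, drop = FALSE])
  }
  diag(out) <- 1
  if (any(degenerate)) {
    if (warn) {
      warning("zero-variance column(s) degraded to r = 0: ",
              paste(colnames(m)[degenerate], collapse = ", "))
    }
  }
  as_correlation_matrix(out)
}

#' Build a weighted network from a correlation matrix
#'
#' Every unordered variable pair whose coefficient satisfies
#' `|r| >= threshold` becomes an edge with the signed coefficient as its
#' weight. The retention rule is inclusive: at the conventional weak-effect
#' cutoff 0.2, an edge with `|r| = 0.2` exactly is kept.
#'
#' @param corr a `correlation_matrix`.
#' @param threshold absolute-value cutoff in `[0, 1]`; 0 keeps the complete
#'   graph.
#' @return an object of class `weighted_network` with elements `nodes`
#'   (variable names in matrix order), `edges` (data.frame `i`, `j`,
#'   `node_i`, `node_j`, `weight` with `i < j`), and `threshold`.
#' @export
build_network <- function(corr, threshold = 0) {
  stopifnot(is.matrix(corr))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  nodes <- rownames(corr)
  idx <- which(upper.tri(corr) & abs(corr) >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    i = idx[, 1], j = idx[, 2],
    node_i = nodes[idx[, 1]], node_j = nodes[idx[, 2]],
    weight = corr[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (threshold |r| >= ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Re-filter an existing network at a higher threshold
#'
#' @param net a `weighted_network`.
#' @param threshold new absolute-value cutoff; must be at least the
#'   network's current threshold.
#' @return a `weighted_network`.
#' @export
filter_network <- function(net, threshold) {
  stopifnot(inherits(net, "weighted_network"))
  if (threshold < net$threshold) {
    stop("cannot lower a threshold; rebuild from the correlation matrix")
  }
  edges <- net$edges[abs(net$edges$weight) >= threshold, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = net$nodes, edges = edges, threshold = threshold),
            class = "weighted_network")
}

# absolute-weight adjacency matrix (0 = no edge)
adjacency_of <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    a[cbind(net$edges$i, net$edges$j)] <- abs(net$edges$weight)
    a[cbind(net$edges$j, net$edges$i)] <- abs(net$edges$weight)
  }
  a
}

#' Export a network's edge list to CSV
#'
#' @param net a `weighted_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges
  out <- data.frame(node_i = e$node_i, node_j = e$node_j,
                    weight = e$weight,
                    sign = ifelse(e$weight >= 0, "positive", "negative"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
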