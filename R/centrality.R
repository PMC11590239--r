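#' Strength centrality
#'
#' Sum of the absolute weights of a node's incident edges. Isolated nodes
#' score 0.
#'
#' @param net a `weighted_network`.
#' @return named numeric vector in node order.
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  rowSums(adjacency_of(net))
}

# length matrix: 1/|w| per edge, Inf where no edge (or w == 0)
length_matrix <- function(net) {
  a <- adjacency_of(net)
  l <- ifelse(a > 0, 1 / a, Inf)
  diag(l) <- 0
  l
}

# single-source Dijkstra on a length matrix; returns list(dist, sigma, preds,
# order) -- sigma counts geodesics, preds holds predecessor lists. Distances
# tying within `tol` are treated as equal geodesics.
dijkstra_source <- function(l, s, tol = 1e-12) {
  n <- nrow(l)
  dist <- rep(Inf, n)
  dist[s] <- 0
  sigma <- numeric(n)
  sigma[s] <- 1
  preds <- vector("list", n)
  visited <- logical(n)
  ord <- integer(0)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    v <- cand[which.min(dist[cand])]
    visited[v] <- TRUE
    ord <- c(ord, v)
    nbrs <- which(is.finite(l[v, ]) & !visited & seq_len(n) != v)
    for (w in nbrs) {
      alt <- dist[v] + l[v, w]
      if (alt < dist[w] - tol) {
        dist[w] <- alt
        sigma[w] <- sigma[v]
        preds[[w]] <- v
      } else if (is.finite(dist[w]) && abs(alt - dist[w]) <= tol) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = ord)
}

#' All-pairs geodesic distances
#'
#' Edge lengths are the reciprocal of the absolute edge weight, so strongly
#' correlated nodes are close. Pairs in different connected components are
#' `Inf`; zero-weight edges carry no path.
#'
#' @param net a `weighted_network`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
geodesic_distances <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  l <- length_matrix(net)
  n <- nrow(l)
  d <- matrix(Inf, n, n, dimnames = dimnames(l))
  for (s in seq_len(n)) d[s, ] <- dijkstra_source(l, s)$dist
  d
}

#' Closeness centrality
#'
#' The inverse of the sum of a node's geodesic distances to all other nodes.
#' On a disconnected network the sum runs over the node's own connected
#' component only (unreachable nodes would contribute infinite distance);
#' isolated nodes score 0. Raw (unnormalised) values are returned: the
#' reported quantities downstream — ranks and percentile ranks — are
#' invariant to any common rescaling.
#'
#' @param net a `weighted_network`.
#' @param distances optional precomputed [geodesic_distances()] matrix.
#' @return named numeric vector in node order.
#' @export
closeness_centrality <- function(net, distances = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  d <- if (is.null(distances)) geodesic_distances(net) else distances
  n <- nrow(d)
  out <- vapply(seq_len(n), function(i) {
    x <- d[i, -i]
    s <- sum(x[is.finite(x)])
    if (s > 0) 1 / s else 0
  }, numeric(1))
  names(out) <- rownames(d)
  out
}

#' Betweenness centrality
#'
#' For every unordered pair of other nodes, a node accumulates the fraction
#' of geodesics between the pair that pass through it (accumulated with the
#' standard single-source dependency recursion). With continuous weights
#' tied geodesics are rare; when they occur the count is split fractionally.
#'
#' @param net a `weighted_network`.
#' @return named numeric vector in node order.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  l <- length_matrix(net)
  n <- nrow(l)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sp <- dijkstra_source(l, s)
    delta <- numeric(n)
    for (w in rev(sp$order)) {
      for (v in sp$preds[[w]]) {
        delta[v] <- delta[v] + sp$sigma[v] / sp$sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2
  names(bc) <- rownames(l)
  bc
}

#' Integer percentile rank of one node's centrality value
#'
#' `floor(100 * (number of nodes with strictly smaller value) / N)`, so the
#' maximum of 34 distinct values sits at the 97th percentile and the minimum
#' at the 0th.
#'
#' @param values named numeric vector of a centrality measure.
#' @param node node name (or index).
#' @return integer percentile in `[0, 100]`.
#' @export
percentile_rank <- function(values, node) {
  if (is.character(node) && !node %in% names(values)) {
    stop("unknown node: ", node)
  }
  v <- values[node]
  as.integer(floor(100 * sum(values < v) / length(values)))
}

# descending competition rank (1 = highest; ties share smallest position)
descending_rank <- function(values) {
  as.integer(rank(-values, ties.method = "min"))
}

#' Full centrality table of a network
#'
#' Computes strength, closeness and betweenness for every node, plus the
#' descending competition rank and the integer percentile rank of each
#' measure. Rows are ordered by descending strength, the ordering used in
#' the study's centrality profiles.
#'
#' @param net a `weighted_network`.
#' @param meta optional variable metadata; adds a `group` column.
#' @return data.frame with columns `node`, (`group`,) `strength`,
#'   `closeness`, `betweenness`, `rank_*` and `pct_*` per measure.
#' @export
centrality_table <- function(net, meta = NULL) {
  str <- node_strength(net)
  clo <- closeness_centrality(net)
  btw <- betweenness_centrality(net)
  tab <- data.frame(
    node = net$nodes,
    strength = unname(str),
    closeness = unname(clo),
    betweenness = unname(btw),
    rank_strength = descending_rank(str),
    rank_closeness = descending_rank(clo),
    rank_betweenness = descending_rank(btw),
    pct_strength = vapply(net$nodes, function(v) percentile_rank(str, v),
                          integer(1)),
    pct_closeness = vapply(net$nodes, function(v) percentile_rank(clo, v),
                           integer(1)),
    pct_betweenness = vapply(net$nodes, function(v) percentile_rank(btw, v),
                             integer(1)),
    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    tab$group <- meta$group[match(tab$node, meta$name)]
    tab <- tab[, c("node", "group", setdiff(names(tab), c("node", "group")))]
  }
  tab <- tab[order(-tab$strength, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
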