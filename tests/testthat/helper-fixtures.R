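# random weighted network over n nodes; edge weights uniform on
# [-0.9, -0.1] U [0.1, 0.9] so no near-zero weights blow up path lengths
random_network <- function(n, seed, p_edge = 0.6) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p_edge) {
          w <- stats::runif(1, 0.1, 0.9) * sample(c(-1, 1), 1)
          m[i, j] <- m[j, i] <- w
        }
      }
    }
    diag(m) <- 1
    dimnames(m) <- list(paste0("v", 1:n), paste0("v", 1:n))
    build_network(as_correlation_matrix(m), 0.05)
  })
}

# tiny cohort builder
small_cohort <- function(cols, kinds = NULL) {
  df <- as.data.frame(cols)
  if (is.null(kinds)) kinds <- rep("numeric", length(cols))
  cohort_table(df, variable_meta(names(df), kinds))
}

# --- exhaustive shortest-path oracles (simple-path enumeration, n <= 7) ---

bf_all_simple_paths <- function(lmat, s, t) {
  n <- nrow(lmat)
  paths <- list()
  walk <- function(v, visited, len, path) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- list(len = len, path = path)
      return()
    }
    for (w in seq_len(n)) {
      if (!visited[w] && is.finite(lmat[v, w]) && v != w) {
        visited[w] <- TRUE
        walk(w, visited, len + lmat[v, w], c(path, w))
        visited[w] <- FALSE
      }
    }
  }
  vis <- logical(n)
  vis[s] <- TRUE
  walk(s, vis, 0, s)
  paths
}

# oracle distances + betweenness by enumerating every simple path per pair
bf_distance_betweenness <- function(net, tol = 1e-9) {
  lmat <- ifelse(risknet:::adjacency_of(net) > 0,
                 1 / risknet:::adjacency_of(net), Inf)
  diag(lmat) <- 0
  n <- nrow(lmat)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- bf_all_simple_paths(lmat, s, t)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      dmin <- min(lens)
      d[s, t] <- d[t, s] <- dmin
      geo <- ps[lens <= dmin + tol]
      for (g in geo) {
        inner <- setdiff(g$path, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(geo)
      }
    }
  }
  dimnames(d) <- list(net$nodes, net$nodes)
  names(btw) <- net$nodes
  list(distances = d, betweenness = btw)
}
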