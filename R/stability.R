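#' Non-parametric bootstrap of edge weights
#'
#' Resamples participant rows with replacement `B` times, recomputes the
#' full Spearman matrix on every resample, and summarises each edge of the
#' full-sample network by its bootstrap mean and an empirical percentile
#' confidence interval (nearest-rank quantiles). Imputation is expected to
#' have been applied before resampling — the original analysis imputed once
#' on the full data. Columns that come out constant in a resample degrade to
#' r = 0, as in [correlation_matrix_of()].
#'
#' @param table a complete [cohort_table()].
#' @param threshold absolute-value cutoff defining which edges are
#'   summarised (the bootstrap itself always recomputes the full matrix).
#' @param B number of resamples (the original analysis used 1000).
#' @param ci_level nominal coverage of the percentile interval.
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @return list with `edges` (data.frame `node_i`, `node_j`, `estimate`,
#'   `boot_mean`, `ci_low`, `ci_high`), `B`, `ci_level`, `seed`, `threshold`,
#'   and `samples` (edge-by-resample matrix of weights).
#' @export
bootstrap_edge_weights <- function(table, threshold = 0, B = 1000,
                                   ci_level = 0.95, seed = 1) {
  stopifnot(inherits(table, "cohort_table"), B >= 1,
            ci_level > 0, ci_level < 1)
  m <- as.matrix(table$data)
  if (anyNA(m)) stop("table has missing values; impute first")
  full <- suppressWarnings(spearman_matrix(m, warn = FALSE))
  net <- build_network(full, threshold)
  e <- net$edges
  n <- nrow(m)
  samples <- matrix(NA_real_, nrow(e), B)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      rows <- sample.int(n, n, replace = TRUE)
      rb <- suppressWarnings(spearman_matrix(m[rows, , drop = FALSE],
                                             warn = FALSE))
      samples[, b] <- rb[cbind(e$i, e$j)]
    }
  })
  alpha <- (1 - ci_level) / 2
  qs <- apply(samples, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              type = 1, names = FALSE)
  edges <- data.frame(node_i = e$node_i, node_j = e$node_j,
                      estimate = e$weight,
                      boot_mean = rowMeans(samples),
                      ci_low = if (nrow(e)) qs[1, ] else numeric(0),
                      ci_high = if (nrow(e)) qs[2, ] else numeric(0),
                      stringsAsFactors = FALSE)
  list(edges = edges, samples = samples, B = B, ci_level = ci_level,
       seed = seed, threshold = threshold)
}

#' Case-dropping bootstrap of a centrality measure
#'
#' Computes the full-sample centrality vector once, then for each drop
#' proportion `p` draws `m` simple random subsamples without replacement of
#' size `round((1 - p) * n)`, recomputes the measure on each subsample's
#' thresholded network, and records the Pearson correlation between the
#' subsample and full-sample centrality vectors. Nodes isolated in a
#' subsample network contribute centrality 0, keeping vectors aligned. A
#' correlation is `NA` when either vector is constant; such replicates count
#' as failing the stability criterion in [cs_coefficient()].
#'
#' @param table a complete [cohort_table()].
#' @param measure `"strength"`, `"closeness"` or `"betweenness"`.
#' @param threshold network cutoff applied to every recomputed matrix.
#' @param grid drop proportions in `[0, 1)`, increasing. Default
#'   `0.1, ..., 0.9`.
#' @param m subsamples per level.
#' @param seed integer seed.
#' @return object of class `case_drop_result`: list with `measure`, `grid`,
#'   `correlations` (level-by-replicate matrix), `m`, `seed`, `threshold`,
#'   `n`.
#' @export
case_dropping_bootstrap <- function(table, measure = c("strength",
                                                       "closeness",
                                                       "betweenness"),
                                    threshold = 0,
                                    grid = seq(0.1, 0.9, by = 0.1),
                                    m = 100, seed = 1) {
  stopifnot(inherits(table, "cohort_table"), m >= 1)
  measure <- match.arg(measure)
  if (any(grid < 0 | grid >= 1) || is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing within [0, 1)")
  }
  dat <- as.matrix(table$data)
  if (anyNA(dat)) stop("table has missing values; impute first")
  n <- nrow(dat)
  sizes <- round((1 - grid) * n)
  if (any(sizes < 3)) stop("subsample size below 3 for the largest drop")
  fun <- switch(measure, strength = node_strength,
                closeness = closeness_centrality,
                betweenness = betweenness_centrality)
  measure_of <- function(rows) {
    cm <- suppressWarnings(spearman_matrix(dat[rows, , drop = FALSE],
                                           warn = FALSE))
    fun(build_network(cm, threshold))
  }
  full_vec <- measure_of(seq_len(n))
  cors <- matrix(NA_real_, length(grid), m,
                 dimnames = list(paste0("p", grid), NULL))
  withr::with_seed(seed, {
    for (g in seq_along(grid)) {
      for (r in seq_len(m)) {
        rows <- sample.int(n, sizes[g], replace = FALSE)
        sub <- measure_of(rows)
        cors[g, r] <- suppressWarnings(stats::cor(full_vec, sub))
      }
    }
  })
  structure(list(measure = measure, grid = grid, correlations = cors,
                 m = m, seed = seed, threshold = threshold, n = n),
            class = "case_drop_result")
}

#' @export
print.case_drop_result <- function(x, ...) {
  cat("<case_drop_result> ", x$measure, ", ", length(x$grid),
      " drop levels x ", x$m, " replicates (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion `p` in the grid such that, at every level up
#' to and including `p`, at least `confidence` of the recorded correlations
#' are at or above `r_min`; 0 when no level qualifies. Requiring all smaller
#' levels to pass as well keeps the coefficient monotone in the face of
#' sampling noise. `NA` correlations (constant centrality vectors) count as
#' failures.
#'
#' @param result a [case_dropping_bootstrap()] result.
#' @param r_min correlation threshold (the original analysis used 0.5).
#' @param confidence required proportion of passing replicates (0.95).
#' @return a single drop proportion, an element of `{0} U grid`.
#' @export
cs_coefficient <- function(result, r_min = 0.5, confidence = 0.95) {
  stopifnot(inherits(result, "case_drop_result"))
  pass <- apply(result$correlations, 1, function(r) {
    mean(!is.na(r) & r >= r_min) >= confidence
  })
  ok <- cumprod(pass) == 1  # all levels up to p must pass
  if (!any(ok)) return(0)
  result$grid[max(which(ok))]
}

#' Export an edge-bootstrap summary to CSV
#'
#' @param boot result of [bootstrap_edge_weights()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_bootstrap <- function(boot, path) {
  utils::write.csv(boot$edges, path, row.names = FALSE)
  invisible(path)
}

#' Export case-dropping correlations (long format) to CSV
#'
#' One row per (drop level, replicate) plus the CS value as an attribute
#' column.
#'
#' @param result a [case_dropping_bootstrap()] result.
#' @param path output path.
#' @param r_min,confidence passed to [cs_coefficient()] for the summary
#'   column.
#' @return `path`, invisibly.
#' @export
write_case_drop <- function(result, path, r_min = 0.5, confidence = 0.95) {
  long <- data.frame(
    measure = result$measure,
    drop_proportion = rep(result$grid, times = result$m),
    replicate = rep(seq_len(result$m), each = length(result$grid)),
    correlation = as.vector(result$correlations),
    stringsAsFactors = FALSE)
  long$cs <- cs_coefficient(result, r_min, confidence)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
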