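#' Fruchterman-Reingold force-directed layout
#'
#' Classical force-directed iteration: with optimal spacing
#' `k = sqrt(area / N)`, every node pair repels with force `k^2 / d` and
#' every edge attracts with force `(d^2 / k) * |w|` — attraction is scaled
#' by the absolute edge weight so strongly correlated nodes end up close,
#' regardless of sign (signs affect colour in rendering, not forces).
#' Displacements are capped by a temperature cooled linearly from
#' `0.1 * sqrt(area)` to 0. Initial positions are uniform in the unit
#' square, drawn from the seed, so the layout is fully reproducible.
#'
#' @param net a `weighted_network`.
#' @param seed integer seed for the initial placement.
#' @param iterations number of cooling steps (default 500).
#' @param area layout area; defaults to the node count.
#' @return data.frame `node`, `x`, `y` in node order, with attributes
#'   `seed` and `iterations`.
#' @export
fruchterman_reingold_layout <- function(net, seed = 1, iterations = 500,
                                        area = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (iterations < 1) stop("iterations must be at least 1")
  n <- length(net$nodes)
  if (is.null(area)) area <- n
  stopifnot(area > 0)
  w <- adjacency_of(net)  # absolute weights
  k <- sqrt(area / n)
  pos <- withr::with_seed(seed, matrix(stats::runif(2 * n), n, 2))
  if (n > 1) {
    t0 <- 0.1 * sqrt(area)
    eps <- 1e-9
    for (it in seq_len(iterations)) {
      temp <- t0 * (1 - (it - 1) / iterations)
      dx <- outer(pos[, 1], pos[, 1], "-")
      dy <- outer(pos[, 2], pos[, 2], "-")
      d <- sqrt(dx^2 + dy^2)
      d[d < eps] <- eps
      # repulsion k^2/d between all pairs, attraction d^2/k * |w| along edges
      coef <- k^2 / d^2 - d * w / k
      diag(coef) <- 0
      disp_x <- rowSums(coef * dx)
      disp_y <- rowSums(coef * dy)
      len <- sqrt(disp_x^2 + disp_y^2)
      len[len < eps] <- eps
      step <- pmin(len, temp) / len
      pos[, 1] <- pos[, 1] + disp_x * step
      pos[, 2] <- pos[, 2] + disp_y * step
    }
  }
  out <- data.frame(node = net$nodes, x = pos[, 1], y = pos[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "iterations") <- iterations
  out
}

#' Circular layout
#'
#' Nodes equally spaced on the unit circle in input order, starting at the
#' top (angle 90 degrees) and proceeding clockwise.
#'
#' @param net a `weighted_network`.
#' @return data.frame `node`, `x`, `y`.
#' @export
circular_layout <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  n <- length(net$nodes)
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  data.frame(node = net$nodes, x = cos(theta), y = sin(theta),
             stringsAsFactors = FALSE)
}

#' Export layout coordinates to CSV
#'
#' @param layout a layout data.frame (`node`, `x`, `y`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout[, c("node", "x", "y")], path, row.names = FALSE)
  invisible(path)
}
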