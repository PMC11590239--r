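# default instrument-group palette; unknown groups cycle through hues
GROUP_PALETTE <- c(
  demographics = "#999999", BIS = "#56B4E9", `CTA-substances` = "#009E73",
  CTQ = "#F0E442", SDQ = "#0072B2", `MINI-KID` = "#D55E00",
  PHQ = "#CC79A7", `suicide-outcome` = "#E41A1C", migration = "#A65628")

EDGE_POSITIVE <- "#3366CCCC"  # blue, direct relationship
EDGE_NEGATIVE <- "#E69F00CC"  # orange, inverse relationship

open_device <- function(path, width = 8, height = 8) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(path, width = width, height = height),
    pdf = grDevices::pdf(path, width = width, height = height),
    stop("unsupported image extension: .", ext))
}

#' Render a network at given layout coordinates
#'
#' Edge width is proportional to the absolute weight; positive correlations
#' are drawn blue, negative ones orange. Nodes are filled by instrument
#' group and labelled. Rendering is a pure output operation — the network is
#' never modified.
#'
#' @param net a `weighted_network`.
#' @param layout data.frame `node`, `x`, `y` covering all nodes.
#' @param out output path (`.png`, `.svg` or `.pdf`).
#' @param meta optional variable metadata supplying node groups.
#' @param max_lwd line width of the strongest edge.
#' @return invisibly, a list with `path`, `n_edges_drawn` and `n_nodes`.
#' @export
render_network <- function(net, layout, out, meta = NULL, max_lwd = 6) {
  stopifnot(inherits(net, "weighted_network"))
  if (!all(net$nodes %in% layout$node)) {
    stop("layout does not cover all nodes")
  }
  xy <- layout[match(net$nodes, layout$node), c("x", "y")]
  e <- net$edges[abs(net$edges$weight) > 0, , drop = FALSE]
  groups <- if (!is.null(meta)) meta$group[match(net$nodes, meta$name)]
            else rep("", length(net$nodes))
  pal <- GROUP_PALETTE
  extra <- setdiff(unique(groups), names(pal))
  if (length(extra)) {
    pal <- c(pal, stats::setNames(
      grDevices::hcl.colors(max(3, length(extra)), "Dark 3")[seq_along(extra)],
      extra))
  }
  open_device(out)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  graphics::plot(xy$x, xy$y, type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = 1,
                 xlim = range(xy$x) + c(-0.12, 0.12) * diff(range(xy$x) + 1e-9),
                 ylim = range(xy$y) + c(-0.12, 0.12) * diff(range(xy$y) + 1e-9))
  if (nrow(e)) {
    wmax <- max(abs(e$weight))
    graphics::segments(xy$x[e$i], xy$y[e$i], xy$x[e$j], xy$y[e$j],
                       lwd = 0.4 + (max_lwd - 0.4) * abs(e$weight) / wmax,
                       col = ifelse(e$weight >= 0, EDGE_POSITIVE,
                                    EDGE_NEGATIVE))
  }
  graphics::points(xy$x, xy$y, pch = 21, cex = 3.2,
                   bg = pal[groups], col = "grey25")
  graphics::text(xy$x, xy$y, labels = net$nodes, cex = 0.55)
  invisible(list(path = out, n_edges_drawn = nrow(e),
                 n_nodes = length(net$nodes)))
}

#' Render a three-panel centrality profile
#'
#' Strength, closeness and betweenness for every variable, one panel per
#' measure, variables ordered top-to-bottom by descending strength of the
#' first configuration. Several configurations (e.g. full vs thresholded
#' network) are overlaid as separate lines.
#'
#' @param tables a single [centrality_table()] or a named list of them.
#' @param out output path (`.png`, `.svg` or `.pdf`).
#' @return invisibly, a list with `path`, `node_order` (top to bottom) and
#'   the ggplot object.
#' @export
render_centrality_profile <- function(tables, out) {
  if (is.data.frame(tables)) tables <- list(network = tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("config", seq_along(tables))
  }
  first <- tables[[1]]
  stopifnot(nrow(first) >= 1)
  node_order <- first$node  # already strength-descending
  long <- do.call(rbind, lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    do.call(rbind, lapply(c("strength", "closeness", "betweenness"),
      function(ms) data.frame(configuration = nm, node = tb$node,
                              measure = ms, value = tb[[ms]],
                              stringsAsFactors = FALSE)))
  }))
  long$node <- factor(long$node, levels = rev(node_order))
  long$measure <- factor(long$measure,
                         levels = c("strength", "closeness", "betweenness"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$node,
                                          group = .data$configuration,
                                          colour = .data$configuration)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_point(size = 1.3) +
    ggplot2::facet_wrap(~measure, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw(base_size = 9) +
    ggplot2::theme(legend.position = if (length(tables) > 1) "bottom"
                   else "none")
  open_device(out, width = 7, height = max(3, 0.18 * length(node_order) + 1))
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(list(path = out, node_order = node_order, plot = p))
}
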