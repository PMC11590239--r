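#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end pipeline with the study's
#' defaults: weak-correlation cutoff 0.2, 1000 edge-bootstrap resamples,
#' 95% percentile intervals, CS criterion r >= 0.5 at 95% confidence, drop
#' grid 0.1-0.9, 100 subsamples per level.
#'
#' @param threshold absolute-correlation cutoff for the thresholded network.
#' @param n_boots edge-bootstrap resamples.
#' @param ci_level percentile-interval coverage.
#' @param cs_corr CS correlation threshold.
#' @param cs_confidence CS confidence level.
#' @param drop_grid case-dropping proportions.
#' @param samples_per_level case-dropping subsamples per level.
#' @param seed master seed for all stochastic stages.
#' @param layout_iterations,layout_area Fruchterman-Reingold parameters.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(threshold = 0.2, n_boots = 1000,
                            ci_level = 0.95, cs_corr = 0.5,
                            cs_confidence = 0.95,
                            drop_grid = seq(0.1, 0.9, by = 0.1),
                            samples_per_level = 100, seed = 1,
                            layout_iterations = 500, layout_area = NULL) {
  stopifnot(threshold >= 0, threshold <= 1, n_boots >= 1,
            ci_level > 0, ci_level < 1, cs_corr > 0, cs_corr < 1,
            cs_confidence > 0, cs_confidence < 1)
  structure(list(threshold = threshold, n_boots = n_boots,
                 ci_level = ci_level, cs_corr = cs_corr,
                 cs_confidence = cs_confidence, drop_grid = drop_grid,
                 samples_per_level = samples_per_level, seed = seed,
                 layout_iterations = layout_iterations,
                 layout_area = layout_area),
            class = "analysis_config")
}

#' Run the end-to-end network analysis
#'
#' Orchestrates the full pipeline: missingness profiling and imputation,
#' Spearman matrix, full and thresholded networks, centrality tables,
#' layouts, and — for cohort input — edge bootstrap and the case-dropping
#' CS-coefficient for all three centrality measures. A precomputed
#' correlation matrix may be supplied instead of a cohort (this is how the
#' published centrality results are reproduced from the printed matrix);
#' resampling stages are then skipped and flagged in the report.
#'
#' @param cohort a [cohort_table()], or `NULL` when `corr` is given.
#' @param corr a `correlation_matrix`, or `NULL` when `cohort` is given.
#' @param config an [analysis_config()].
#' @param meta optional variable metadata for grouping (defaults to the
#'   cohort's).
#' @param stability compute bootstrap/CS stages (cohort input only).
#' @return a list of class `analysis_report`.
#' @export
run_analysis <- function(cohort = NULL, corr = NULL,
                         config = analysis_config(), meta = NULL,
                         stability = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(cohort) == is.null(corr)) {
    stop("supply exactly one of `cohort` or `corr`")
  }
  report <- list(config = config, mode = if (is.null(cohort)) "matrix"
                 else "cohort")
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_table"))
    meta <- meta %||% cohort$meta
    report$missingness <- missingness_profile(cohort)
    cohort <- impute_table(cohort)
    corr <- correlation_matrix_of(cohort)
  } else {
    corr <- as_correlation_matrix(unclass(corr))
    report$missingness <- NULL
  }
  report$correlation <- corr
  net_full <- build_network(corr, 0)
  net_thr <- filter_network(net_full, config$threshold)
  report$network_full <- net_full
  report$network_thresholded <- net_thr
  report$centrality_full <- centrality_table(net_full, meta)
  report$centrality_thresholded <- centrality_table(net_thr, meta)
  report$layout_fr <- fruchterman_reingold_layout(
    net_thr, seed = config$seed, iterations = config$layout_iterations,
    area = config$layout_area)
  report$layout_circle <- circular_layout(net_full)
  report$meta <- meta
  if (!is.null(cohort) && stability) {
    report$edge_bootstrap <- bootstrap_edge_weights(
      cohort, threshold = config$threshold, B = config$n_boots,
      ci_level = config$ci_level, seed = config$seed)
    report$case_drop <- lapply(
      stats::setNames(nm = c("strength", "closeness", "betweenness")),
      function(ms) case_dropping_bootstrap(
        cohort, measure = ms, threshold = config$threshold,
        grid = config$drop_grid, m = config$samples_per_level,
        seed = config$seed))
    report$cs <- vapply(report$case_drop, cs_coefficient,
                        r_min = config$cs_corr,
                        confidence = config$cs_confidence, numeric(1))
  }
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> mode:", x$mode, "\n")
  cat("nodes:", length(x$network_full$nodes),
      "| edges full:", nrow(x$network_full$edges),
      "| edges |r| >=", x$config$threshold, ":",
      nrow(x$network_thresholded$edges), "\n")
  cat("top strength:", x$centrality_full$node[1], "\n")
  if (!is.null(x$cs)) {
    cat("CS(r =", x$config$cs_corr, "):",
        paste(names(x$cs), round(x$cs, 2), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Emits the edge lists, centrality tables, layouts, bootstrap summaries,
#' figures, and a machine-readable `report.json` echoing the configuration
#' and carrying an MD5-checksummed file manifest.
#'
#' @param report an [run_analysis()] result.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (`file`, `md5`), invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  write_correlation_matrix(report$correlation, fp("correlation_matrix.csv"))
  add("correlation_matrix.csv")
  write_edge_list(report$network_full, fp("edges_full.csv"))
  add("edges_full.csv")
  write_edge_list(report$network_thresholded, fp("edges_thresholded.csv"))
  add("edges_thresholded.csv")
  utils::write.csv(report$centrality_full, fp("centrality_full.csv"),
                   row.names = FALSE)
  add("centrality_full.csv")
  utils::write.csv(report$centrality_thresholded,
                   fp("centrality_thresholded.csv"), row.names = FALSE)
  add("centrality_thresholded.csv")
  write_layout(report$layout_fr, fp("layout_fr.csv"))
  add("layout_fr.csv")
  if (!is.null(report$missingness)) {
    utils::write.csv(
      data.frame(variable = names(report$missingness$per_variable),
                 proportion_missing = report$missingness$per_variable),
      fp("missingness.csv"), row.names = FALSE)
    add("missingness.csv")
  }
  if (!is.null(report$edge_bootstrap)) {
    write_edge_bootstrap(report$edge_bootstrap, fp("edge_bootstrap.csv"))
    add("edge_bootstrap.csv")
    for (ms in names(report$case_drop)) {
      f <- paste0("case_drop_", ms, ".csv")
      write_case_drop(report$case_drop[[ms]], fp(f),
                      r_min = report$config$cs_corr,
                      confidence = report$config$cs_confidence)
      add(f)
    }
    utils::write.csv(
      data.frame(measure = names(report$cs), cs = unname(report$cs)),
      fp("cs_coefficients.csv"), row.names = FALSE)
    add("cs_coefficients.csv")
  }
  render_network(report$network_thresholded, report$layout_fr,
                 fp("network_fr.png"), meta = report$meta)
  add("network_fr.png")
  render_network(report$network_thresholded, report$layout_circle,
                 fp("network_circle.png"), meta = report$meta)
  add("network_circle.png")
  render_centrality_profile(
    list(full = report$centrality_full,
         thresholded = report$centrality_thresholded),
    fp("centrality_profile.png"))
  add("centrality_profile.png")

  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  json <- list(
    mode = report$mode,
    config = unclass(report$config),
    missingness_average = if (!is.null(report$missingness))
      report$missingness$average else NA,
    n_nodes = length(report$network_full$nodes),
    n_edges_full = nrow(report$network_full$edges),
    n_edges_thresholded = nrow(report$network_thresholded$edges),
    top_strength = report$centrality_full$node[1],
    cs = as.list(report$cs %||% NULL),
    manifest = manifest)
  jsonlite::write_json(json, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}
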