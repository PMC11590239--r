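#' Missingness profile of a cohort table
#'
#' @param table a [cohort_table()].
#' @return a list with `per_variable` (named proportions missing, in variable
#'   order) and `average` (their arithmetic mean).
#' @export
missingness_profile <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  per <- vapply(table$data, function(x) mean(is.na(x)), numeric(1))
  list(per_variable = per, average = mean(per))
}

#' Single-shot unconditional imputation
#'
#' Numeric variables receive the observed-value mean; binary and ordinal
#' variables the observed mode (ties broken by the smallest value, so the
#' result is deterministic and order-independent); count variables the
#' observed mean rounded half-up to an integer (configurable to mode).
#' A complete table is returned unchanged. This is the single-pass scheme
#' used on the original cohort; no multiple imputation is attempted.
#'
#' @param table a [cohort_table()].
#' @param count_method `"mean"` (rounded half-up, default) or `"mode"` for
#'   count variables.
#' @return a complete [cohort_table()].
#' @export
impute_table <- function(table, count_method = c("mean", "mode")) {
  stopifnot(inherits(table, "cohort_table"))
  count_method <- match.arg(count_method)
  data <- table$data
  for (k in seq_len(nrow(table$meta))) {
    v <- table$meta$name[k]
    x <- data[[v]]
    miss <- is.na(x)
    if (!any(miss)) next
    obs <- x[!miss]
    if (length(obs) == 0) stop("variable '", v, "' is entirely missing")
    kind <- table$meta$kind[k]
    fill <- switch(kind,
      numeric = mean(obs),
      count = if (count_method == "mean") floor(mean(obs) + 0.5)
              else observed_mode(obs),
      binary = observed_mode(obs),
      ordinal = observed_mode(obs))
    x[miss] <- fill
    data[[v]] <- x
  }
  cohort_table(data, table$meta)
}

# smallest most-frequent observed value
observed_mode <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}
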