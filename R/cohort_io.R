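#' @keywords internal
"_PACKAGE"

VAR_KINDS <- c("numeric", "binary", "ordinal", "count")

#' Construct a variable-metadata table
#'
#' Variable metadata declares, for every column of a cohort table, its
#' measurement kind (`numeric`, `binary`, `ordinal`, `count`), the instrument
#' family it belongs to (used for node colouring), and a human-readable label.
#'
#' @param name character vector of short unique variable identifiers.
#' @param kind character vector, each one of `"numeric"`, `"binary"`,
#'   `"ordinal"`, `"count"`.
#' @param group instrument-family label per variable (recycled if length 1).
#' @param label human-readable description per variable; defaults to `name`.
#' @return a `data.frame` with columns `name`, `kind`, `group`, `label`.
#' @export
variable_meta <- function(name, kind, group = "", label = name) {
  if (length(name) == 0 || anyNA(name) || any(!nzchar(name))) {
    stop("variable names must be non-empty")
  }
  if (anyDuplicated(name)) {
    stop("duplicate variable name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  bad <- setdiff(unique(kind), VAR_KINDS)
  if (length(bad)) {
    stop("unknown variable kind(s): ", paste(bad, collapse = ", "))
  }
  data.frame(name = as.character(name),
             kind = rep_len(as.character(kind), length(name)),
             group = rep_len(as.character(group), length(name)),
             label = rep_len(as.character(label), length(name)),
             stringsAsFactors = FALSE)
}

#' Construct a cohort table
#'
#' A cohort table couples a participant-by-variable data frame (missing
#' entries as `NA`) with its variable metadata. Values are validated against
#' each variable's declared kind: binary values must be 0/1, ordinal and
#' count values must be integers.
#'
#' @param data data.frame of numeric columns, one per metadata row, in
#'   metadata order; `NA` marks a missing entry.
#' @param meta variable metadata as returned by [variable_meta()].
#' @return an object of class `cohort_table` with elements `data`, `meta`
#'   and `n` (participant count).
#' @export
cohort_table <- function(data, meta) {
  stopifnot(is.data.frame(data), is.data.frame(meta))
  if (!setequal(names(data), meta$name) ||
      !identical(sort(names(data)), sort(meta$name))) {
    missing_meta <- setdiff(names(data), meta$name)
    missing_data <- setdiff(meta$name, names(data))
    stop("column/metadata mismatch",
         if (length(missing_meta)) paste0("; not in metadata: ",
                                          paste(missing_meta, collapse = ", ")),
         if (length(missing_data)) paste0("; not in data: ",
                                          paste(missing_data, collapse = ", ")))
  }
  data <- data[, meta$name, drop = FALSE]
  if (nrow(data) < 1) stop("cohort table needs at least one row")
  for (k in seq_len(nrow(meta))) {
    v <- meta$name[k]
    x <- data[[v]]
    if (!is.numeric(x)) stop("non-numeric values in column '", v, "'")
    obs <- x[!is.na(x)]
    if (meta$kind[k] == "binary" && length(obs) && !all(obs %in% c(0, 1))) {
      stop("binary variable '", v, "' has values outside {0,1}")
    }
    if (meta$kind[k] %in% c("ordinal", "count") && length(obs) &&
        any(obs != round(obs))) {
      stop(meta$kind[k], " variable '", v, "' has non-integer values")
    }
  }
  structure(list(data = data, meta = meta, n = nrow(data)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", x$n, " participants x ", nrow(x$meta),
      " variables\n", sep = "")
  cat("kinds:", paste(sprintf("%s=%d", names(table(x$meta$kind)),
                              table(x$meta$kind)), collapse = " "), "\n")
  invisible(x)
}

#' Read a cohort table and its variable metadata from CSV
#'
#' The cohort file is comma-separated with a mandatory header row whose names
#' must match the metadata's variable roster exactly (order is taken from the
#' metadata). Blank cells and the `na` sentinel become missing values.
#'
#' @param path_table path to the cohort CSV.
#' @param path_meta path to the metadata CSV with columns
#'   `name,kind,group,label`.
#' @param na missing-value sentinel in addition to empty cells.
#' @return a [cohort_table()].
#' @export
read_cohort_table <- function(path_table, path_meta, na = "NA") {
  meta <- utils::read.csv(path_meta, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  req <- c("name", "kind")
  if (!all(req %in% names(meta))) {
    stop("metadata file must have at least columns: ",
         paste(req, collapse = ", "))
  }
  if (is.null(meta$group)) meta$group <- ""
  if (is.null(meta$label)) meta$label <- meta$name
  meta <- variable_meta(meta$name, meta$kind, meta$group, meta$label)
  raw <- utils::read.csv(path_table, stringsAsFactors = FALSE,
                         na.strings = c("", na), check.names = FALSE)
  extra <- setdiff(names(raw), meta$name)
  if (length(extra)) {
    stop("column(s) in table but not in metadata: ",
         paste(extra, collapse = ", "))
  }
  absent <- setdiff(meta$name, names(raw))
  if (length(absent)) {
    stop("variable(s) declared in metadata but absent from table: ",
         paste(absent, collapse = ", "))
  }
  for (v in names(raw)) {
    if (!is.numeric(raw[[v]])) {
      xs <- suppressWarnings(as.numeric(raw[[v]]))
      if (any(is.na(xs) & !is.na(raw[[v]]))) {
        stop("non-numeric cell in column '", v, "'")
      }
      raw[[v]] <- xs
    }
    raw[[v]] <- as.double(raw[[v]])
  }
  cohort_table(raw, meta)
}

#' Write a cohort table (and optionally its metadata) to CSV
#'
#' @param table a [cohort_table()].
#' @param path_table output path for the cohort CSV.
#' @param path_meta optional output path for the metadata CSV.
#' @param na sentinel written for missing cells.
#' @return the cohort path, invisibly.
#' @export
write_cohort_table <- function(table, path_table, path_meta = NULL,
                               na = "NA") {
  stopifnot(inherits(table, "cohort_table"))
  utils::write.csv(table$data, path_table, row.names = FALSE, na = na)
  if (!is.null(path_meta)) {
    utils::write.csv(table$meta, path_meta, row.names = FALSE)
  }
  invisible(path_table)
}

#' Validate and class a square matrix as a correlation matrix
#'
#' Checks symmetry (asymmetries up to `tol` are averaged out, larger ones are
#' errors), a unit diagonal, and that all entries lie in `[-1, 1]`.
#'
#' @param m square numeric matrix with identical row and column names.
#' @param tol symmetrisation tolerance.
#' @return the matrix with class `correlation_matrix`.
#' @export
as_correlation_matrix <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) != ncol(m)) stop("correlation matrix must be square")
  if (is.null(rownames(m)) && is.null(colnames(m))) {
    rownames(m) <- colnames(m) <- paste0("V", seq_len(nrow(m)))
  } else if (is.null(rownames(m))) {
    rownames(m) <- colnames(m)
  } else if (is.null(colnames(m))) {
    colnames(m) <- rownames(m)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column names must agree")
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) stop("matrix is asymmetric beyond tolerance: ", asym)
  m <- (m + t(m)) / 2
  if (max(abs(diag(m) - 1)) > tol) stop("diagonal entries must equal 1")
  diag(m) <- 1
  if (any(abs(m) > 1 + tol)) stop("entries must lie in [-1, 1]")
  m[m > 1] <- 1
  m[m < -1] <- -1
  class(m) <- c("correlation_matrix", class(m))
  m
}

#' Read a correlation matrix from CSV
#'
#' First column and header row carry variable names; the body must be a
#' square numeric matrix.
#'
#' @param path path to the CSV.
#' @param tol symmetrisation tolerance passed to [as_correlation_matrix()].
#' @return a `correlation_matrix`.
#' @export
read_correlation_matrix <- function(path, tol = 1e-9) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("correlation matrix body must be numeric")
  if (is.null(colnames(m)) || nrow(m) != ncol(m)) {
    stop("correlation matrix body must be square with named rows/columns")
  }
  as_correlation_matrix(m, tol = tol)
}

#' Write a correlation matrix to CSV
#'
#' @param m a `correlation_matrix` (or plain symmetric matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(m, path) {
  df <- data.frame(variable = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' The packaged 34-variable Spearman matrix
#'
#' Returns the transcribed full Spearman correlation matrix of the adolescent
#' suicide-attempter cohort (34 already-scored questionnaire variables,
#' n = 267). See `inst/extdata/table3_notes.md` for the transcription audit,
#' including the single printed cell pair whose signs disagree.
#'
#' @return a `correlation_matrix` of dimension 34, symmetric with unit
#'   diagonal.
#' @seealso [fixture_variables()] for the variable roster with kinds and
#'   instrument groups.
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3_spearman.csv", package = "risknet",
                      mustWork = TRUE)
  read_correlation_matrix(path)
}

#' Variable roster of the packaged correlation matrix
#'
#' @return variable metadata (`name`, `kind`, `group`, `label`) for the 34
#'   variables of [table3_fixture()], in matrix order.
#' @export
fixture_variables <- function() {
  path <- system.file("extdata", "table3_variables.csv", package = "risknet",
                      mustWork = TRUE)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  variable_meta(meta$name, meta$kind, meta$group, meta$label)
}
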