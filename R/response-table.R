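#' Typed participant-by-variable response table
#'
#' The central data container: an `n x p` numeric matrix of response codes
#' with a logical missingness mask and a [var_schema()] describing each
#' column. Ordinal codes are 0-based consecutive integers in
#' `[0, levels - 1]`.
#'
#' @param values numeric `n x p` matrix (or data frame); `NA` marks missing.
#' @param schema a [var_schema()] whose names match `colnames(values)`.
#'
#' @return An object of class `response_table` with elements `values`
#'   (matrix, `NA` where missing), `missing` (logical mask), `schema`, `n`,
#'   `p`.
#' @examples
#' sch <- var_schema(c("a", "b"), "ordinal", levels = 3)
#' response_table(cbind(a = c(0, 1, NA), b = c(2, 2, 0)), sch)
#' @export
response_table <- function(values, schema) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("a response table needs n >= 2 and p >= 2")
  if (is.null(colnames(values))) colnames(values) <- schema$name
  if (!identical(colnames(values), schema$name)) {
    unknown <- setdiff(colnames(values), schema$name)
    if (length(unknown))
      stop("columns absent from schema: ", paste(unknown, collapse = ", "))
    missing_cols <- setdiff(schema$name, colnames(values))
    if (length(missing_cols))
      stop("schema variables absent from data: ",
           paste(missing_cols, collapse = ", "))
    values <- values[, schema$name, drop = FALSE]
  }
  validate_codes(values, schema)
  out <- list(values = values, missing = is.na(values), schema = schema,
              n = nrow(values), p = ncol(values))
  class(out) <- "response_table"
  out
}

validate_codes <- function(values, schema) {
  ord <- which(schema_is_ordinal(schema))
  lv <- schema_levels(schema)
  for (j in ord) {
    x <- values[, j]
    obs <- which(!is.na(x))
    bad <- obs[x[obs] != round(x[obs]) | x[obs] < 0 | x[obs] > lv[j] - 1L]
    if (length(bad))
      stop(sprintf(
        "invalid ordinal code(s) in column '%s' (levels %d): rows %s",
        schema$name[j], lv[j],
        paste(utils::head(bad, 5L), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("Response table: %d participants x %d variables (%s missing)\n",
              x$n, x$p, format(100 * mean(x$missing), digits = 3)))
  cat("Kinds:", paste(sprintf("%s=%d", names(table(x$schema$kind)),
                              table(x$schema$kind)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.response_table <- function(x, ...) {
  as.data.frame(x$values, ...)
}

#' @export
dim.response_table <- function(x) c(x$n, x$p)

#' Read and write response tables as CSV plus a JSON schema
#'
#' The CSV dialect is fixed: comma separator, UTF-8, `.` decimal point, the
#' empty string for a missing cell. Header names must match the schema
#' exactly; ordinal codes outside `[0, levels - 1]` are rejected with the
#' offending rows named.
#'
#' @param path_csv path to the response CSV.
#' @param path_schema path to the JSON schema (see [write_schema()]).
#' @return a [response_table()].
#' @export
read_responses <- function(path_csv, path_schema) {
  schema <- read_schema(path_schema)
  df <- utils::read.csv(path_csv, check.names = FALSE, na.strings = "",
                        colClasses = "numeric", fileEncoding = "UTF-8")
  response_table(as.matrix(df), schema)
}

#' @param table a [response_table()].
#' @rdname read_responses
#' @export
write_responses <- function(table, path_csv, path_schema) {
  df <- as.data.frame(table$values)
  utils::write.csv(df, path_csv, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  write_schema(table$schema, path_schema)
  invisible(path_csv)
}

# complete-case subset of columns, as a plain matrix
table_matrix <- function(table, cols = NULL) {
  v <- table$values
  if (!is.null(cols)) v <- v[, cols, drop = FALSE]
  v
}

# subset participants, keeping schema
table_rows <- function(table, rows) {
  out <- table
  out$values <- table$values[rows, , drop = FALSE]
  out$missing <- is.na(out$values)
  out$n <- nrow(out$values)
  out
}

# subset variables
table_cols <- function(table, cols) {
  idx <- if (is.character(cols)) match(cols, table$schema$name) else cols
  if (anyNA(idx)) stop("unknown variable(s): ",
                       paste(cols[is.na(idx)], collapse = ", "))
  sch <- table$schema[idx, , drop = FALSE]
  class(sch) <- c("panet_schema", "data.frame")
  out <- list(values = table$values[, idx, drop = FALSE],
              missing = table$missing[, idx, drop = FALSE],
              schema = sch, n = table$n, p = length(idx))
  class(out) <- "response_table"
  out
}
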