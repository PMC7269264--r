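#' Variable schema for typed questionnaire data
#'
#' A schema declares, for every column of a response table, whether it is
#' ordinal (with a fixed number of ordered categories coded `0 .. levels-1`),
#' binary (treated as ordinal with 2 levels for correlation dispatch) or
#' continuous, plus a free role tag (`"item"`, `"covariate"` or
#' `"grouping"`).
#'
#' @param name character vector of unique column names.
#' @param kind character vector, each one of `"ordinal"`, `"continuous"`,
#'   `"binary"`.
#' @param levels integer vector of category counts; required (>= 2) for
#'   ordinal variables, forced to 2 for binary, `NA` for continuous.
#' @param role character vector of role tags; defaults to `"item"`.
#'
#' @return A data frame of class `panet_schema` with columns `name`, `kind`,
#'   `levels`, `role`.
#' @examples
#' var_schema(c("q1", "q2", "age"), c("ordinal", "ordinal", "continuous"),
#'            levels = c(5, 5, NA))
#' @export
var_schema <- function(name, kind, levels = NULL, role = "item") {
  name <- as.character(name)
  kind <- match.arg(as.character(kind), c("ordinal", "continuous", "binary"),
                    several.ok = TRUE)
  kind <- rep_len(kind, length(name))
  if (anyDuplicated(name))
    stop("schema names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  if (is.null(levels)) levels <- rep(NA_integer_, length(name))
  levels <- rep_len(as.integer(levels), length(name))
  levels[kind == "binary"] <- 2L
  levels[kind == "continuous"] <- NA_integer_
  bad <- kind == "ordinal" & (is.na(levels) | levels < 2L)
  if (any(bad))
    stop("ordinal variables need levels >= 2: ",
         paste(name[bad], collapse = ", "))
  out <- data.frame(name = name, kind = kind, levels = levels,
                    role = rep_len(as.character(role), length(name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("panet_schema", "data.frame")
  out
}

#' @export
print.panet_schema <- function(x, ...) {
  cat("Variable schema:", nrow(x), "variables\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# number of ordered levels used for correlation dispatch (binary -> 2)
schema_levels <- function(schema) {
  lv <- schema$levels
  lv[schema$kind == "binary"] <- 2L
  lv
}

# "ordinal-like" for dispatch purposes
schema_is_ordinal <- function(schema) schema$kind %in% c("ordinal", "binary")

#' Read or write a variable schema as JSON
#'
#' @param path file path.
#' @return `read_schema()` returns a [var_schema()] object; `write_schema()`
#'   returns `path` invisibly.
#' @seealso [read_responses()]
#' @export
read_schema <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  vars <- if (is.data.frame(doc)) doc else doc$variables
  if (is.null(vars)) stop("schema JSON must hold a 'variables' array")
  var_schema(vars$name, vars$kind,
             levels = if ("levels" %in% names(vars)) vars$levels else NULL,
             role = if ("role" %in% names(vars)) vars$role else "item")
}

#' @param schema a [var_schema()] object.
#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(list(variables = schema), path, auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows")
  invisible(path)
}

#' Automatic ordinal/continuous classification of a column
#'
#' A column is classified as ordinal when every observed value is an integer
#' and there are at most 7 distinct observed values, mirroring the cutoff of
#' the automatic mixed-correlation convention; otherwise continuous. An
#' explicit schema declaration always overrides this heuristic.
#'
#' @param x numeric vector (may contain `NA`).
#' @return `"ordinal"` or `"continuous"`.
#' @examples
#' auto_kind(c(0, 1, 2, 3, 4))    # "ordinal"
#' auto_kind(rnorm(100))          # "continuous"
#' @export
auto_kind <- function(x) {
  obs <- x[!is.na(x)]
  ux <- unique(obs)
  if (length(ux) < 2L)
    stop("constant column: no correlation defined")
  if (all(obs == round(obs)) && length(ux) <= 7L) "ordinal" else "continuous"
}
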