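#' Nonparametric imputation of a response table
#'
#' Fills missing cells before correlation estimation. Three methods:
#'
#' * `"forest"` (default): an iterative random-forest scheme. Cells are
#'   initialized by column mode (ordinal/binary) or median (continuous);
#'   columns are then revisited in order of increasing missingness, each
#'   regressed (continuous) or classified (ordinal) on all other columns
#'   with a random forest, and the missing cells replaced by predictions.
#'   Iteration stops when the change criterion — scaled sum of squared
#'   changes for continuous columns plus disagreement fraction for ordinal
#'   ones — rises, returning the previous iteration's values, or after
#'   `max_iter` passes.
#' * `"knn"`: k-nearest neighbours on standardized shared observed columns;
#'   neighbour mode for ordinal cells, mean for continuous.
#' * `"mode_median"`: column mode / median, the initialization alone.
#'
#' Observed cells are never modified; ordinal imputations are always valid
#' codes.
#'
#' @param table a [response_table()]; no column may be fully missing.
#' @param method imputation method.
#' @param max_iter forest iterations cap (default 10).
#' @param k neighbour count for `"knn"` (default 5).
#' @param num_trees forest size per column (default 100).
#' @param seed integer; the procedure is deterministic given it.
#' @return A complete [response_table()] (all-false mask).
#' @export
impute <- function(table, method = c("forest", "knn", "mode_median"),
                   max_iter = 10, k = 5, num_trees = 100, seed = 1) {
  method <- match.arg(method)
  X <- table$values
  miss <- table$missing
  if (!any(miss)) return(table)
  full <- which(colSums(!miss) == 0)
  if (length(full))
    stop("fully missing column(s): ",
         paste(table$schema$name[full], collapse = ", "))
  if (method %in% c("forest", "knn") && table$n < 10)
    stop("forest/knn imputation needs n >= 10")
  ordinal <- schema_is_ordinal(table$schema)
  filled <- switch(method,
    mode_median = fill_mode_median(X, miss, ordinal),
    knn = fill_knn(X, miss, ordinal, k),
    forest = fill_forest(X, miss, ordinal, max_iter, num_trees, seed))
  stopifnot(!anyNA(filled))
  out <- table
  out$values <- filled
  out$missing <- matrix(FALSE, table$n, table$p,
                        dimnames = dimnames(table$missing))
  validate_codes(filled, table$schema)
  out
}

col_mode <- function(x) {
  tab <- table(x[!is.na(x)])
  as.numeric(names(tab)[which.max(tab)])
}

fill_mode_median <- function(X, miss, ordinal) {
  for (j in which(colSums(miss) > 0)) {
    fill <- if (ordinal[j]) col_mode(X[, j]) else
      stats::median(X[, j], na.rm = TRUE)
    X[miss[, j], j] <- fill
  }
  X
}

fill_knn <- function(X, miss, ordinal, k) {
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  sds[sds == 0] <- 1
  Z <- sweep(X, 2, colMeans(X, na.rm = TRUE))
  Z <- sweep(Z, 2, sds, "/")
  out <- fill_mode_median(X, miss, ordinal)
  rows <- which(rowSums(miss) > 0)
  for (i in rows) {
    shared <- !miss[i, ]
    d <- sqrt(rowMeans((Z[, shared, drop = FALSE] -
                          rep(Z[i, shared], each = nrow(Z)))^2,
                       na.rm = TRUE))
    d[i] <- Inf
    for (j in which(miss[i, ])) {
      cand <- which(!miss[, j] & is.finite(d))
      if (!length(cand)) next
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      out[i, j] <- if (ordinal[j]) col_mode(X[nb, j]) else mean(X[nb, j])
    }
  }
  out
}

fill_forest <- function(X, miss, ordinal, max_iter, num_trees, seed) {
  set.seed(seed)
  cur <- fill_mode_median(X, miss, ordinal)
  cols <- which(colSums(miss) > 0)
  cols <- cols[order(colSums(miss)[cols])]
  prev_crit <- Inf
  for (iter in seq_len(max_iter)) {
    new <- cur
    for (j in cols) {
      df <- as.data.frame(new[, -j, drop = FALSE])
      names(df) <- paste0("x", seq_len(ncol(df)))
      y <- new[, j]
      df$.y <- if (ordinal[j]) factor(y) else y
      obs <- !miss[, j]
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df[obs, , drop = FALSE],
        num.trees = num_trees, num.threads = 1,
        seed = seed + iter * 1000L + j,
        respect.unordered.factors = "order")
      pred <- stats::predict(fit, df[!obs, , drop = FALSE],
                             num.threads = 1)$predictions
      new[!obs, j] <- if (ordinal[j])
        as.numeric(as.character(pred)) else as.numeric(pred)
    }
    # change criterion between successive imputations
    crit <- 0
    for (j in cols) {
      a <- new[miss[, j], j]; b <- cur[miss[, j], j]
      crit <- crit + if (ordinal[j]) mean(a != b) else
        sum((a - b)^2) / max(sum(a^2), .Machine$double.eps)
    }
    if (crit >= prev_crit) return(cur)   # criterion rose: keep previous
    cur <- new
    prev_crit <- crit
    if (crit == 0) break
  }
  cur
}
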