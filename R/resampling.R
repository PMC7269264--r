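# Bootstrap machinery for centrality stability and edge-weight accuracy.
# Both bootstraps re-run the full estimator (correlation + EBIC-glasso)
# on each resample; the estimator is injected as a function so tests can
# swap it out.

default_estimator <- function(correlation = "skeptic", gamma = 0.5,
                              n_lambda = 100, lambda_min_ratio = 0.01) {
  function(table) {
    cres <- mixed_matrix(table, mode = correlation)
    estimate_network(cres$R, n = table$n, gamma = gamma,
                     n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio,
                     labels = table$schema$name)
  }
}

centrality_indices <- function(W) {
  list(strength = strength(W), betweenness = betweenness(W),
       closeness = closeness(W))
}

#' Case-dropping bootstrap for centrality stability
#'
#' For each drop proportion in `grid` and each of `B` replicates, a random
#' subset of participants is dropped, the whole network re-estimated, and
#' each centrality index correlated (Pearson) with its full-sample value.
#' Summarize with [cs_coefficient()].
#'
#' @param table complete [response_table()].
#' @param grid drop proportions (default `seq(0.05, 0.75, by = 0.1)`).
#' @param B replicates per grid point (default 100).
#' @param seed integer seed; results are reproducible given it.
#' @param estimator function `table -> panet`; defaults to the standard
#'   pipeline with the parameters below.
#' @param correlation,gamma,n_lambda,lambda_min_ratio estimator settings.
#' @param indices which centralities to track.
#' @return object of class `panet_stability`: long data frame `samples`
#'   (`proportion`, `replicate`, `index`, `correlation`), the `grid`, `B`,
#'   `seed`, and counts of failed replicates.
#' @export
case_drop_bootstrap <- function(table, grid = seq(0.05, 0.75, by = 0.1),
                                B = 100, seed = 1, estimator = NULL,
                                correlation = "skeptic", gamma = 0.5,
                                n_lambda = 100, lambda_min_ratio = 0.01,
                                indices = c("strength", "betweenness",
                                            "closeness")) {
  if (is.null(estimator))
    estimator <- default_estimator(correlation, gamma, n_lambda,
                                   lambda_min_ratio)
  full <- estimator(table)
  cent_full <- centrality_indices(full$W)[indices]
  set.seed(seed)
  rows <- list()
  failed <- 0L
  skipped <- numeric()
  for (prop in grid) {
    keep_n <- table$n - floor(prop * table$n)
    if (keep_n < table$p + 5) {
      skipped <- c(skipped, prop)
      next
    }
    for (b in seq_len(B)) {
      idx <- sample.int(table$n, keep_n)
      sub <- table_rows(table, idx)
      fit <- tryCatch(estimator(sub), error = function(e) NULL)
      if (is.null(fit)) {
        failed <- failed + 1L
        next
      }
      cent <- centrality_indices(fit$W)[indices]
      for (ix in indices) {
        r <- suppressWarnings(stats::cor(cent_full[[ix]], cent[[ix]]))
        rows[[length(rows) + 1L]] <-
          data.frame(proportion = prop, replicate = b, index = ix,
                     correlation = r)
      }
    }
  }
  samples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(proportion = numeric(), replicate = integer(),
               index = character(), correlation = numeric())
  structure(list(samples = samples, grid = grid, B = B, seed = seed,
                 failed = failed, skipped = skipped, indices = indices,
                 full = full),
            class = "panet_stability")
}

#' @export
print.panet_stability <- function(x, ...) {
  cat(sprintf("Case-dropping bootstrap: B = %d per grid point, %d failed\n",
              x$B, x$failed))
  cs <- cs_coefficient(x)
  cat("CS-coefficients:",
      paste(sprintf("%s = %.2f", names(cs), cs), collapse = ", "), "\n")
  invisible(x)
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion in the grid such that at it *and at every
#' smaller grid value* the empirical `1 - confidence` quantile of the
#' replicate correlations stays at or above `threshold` (monotone-prefix
#' rule, no interpolation); 0 when even the smallest proportion fails.
#' Values below 0.25 indicate instability; above 0.5 is good.
#'
#' @param result a [case_drop_bootstrap()] result.
#' @param threshold correlation threshold (default 0.7).
#' @param confidence confidence level (default 0.95).
#' @return named vector of CS-coefficients, one per index.
#' @export
cs_coefficient <- function(result, threshold = 0.7, confidence = 0.95) {
  stopifnot(inherits(result, "panet_stability"))
  grid <- sort(unique(result$samples$proportion))
  out <- stats::setNames(numeric(length(result$indices)), result$indices)
  for (ix in result$indices) {
    cs <- 0
    for (prop in grid) {
      r <- result$samples$correlation[
        result$samples$index == ix & result$samples$proportion == prop]
      r <- r[!is.na(r)]
      if (!length(r)) break
      q <- stats::quantile(r, probs = 1 - confidence, names = FALSE,
                           type = 7)
      if (q >= threshold) cs <- prop else break
    }
    out[ix] <- cs
  }
  out
}

#' Nonparametric bootstrap confidence intervals for edge weights
#'
#' `B` resamples of the participants with replacement; the full estimator
#' is re-run on each and per-edge 2.5/97.5 empirical percentile bounds are
#' collected. Resamples producing a constant column are redrawn (counted,
#' capped at `10 * B` total draws).
#'
#' @inheritParams case_drop_bootstrap
#' @param B bootstrap replicates; fewer than 100 triggers a warning.
#' @return object of class `panet_edgeci`: data frame `edges` with point
#'   estimate, bootstrap mean, `lower`, `upper` per edge, plus `B`, `seed`,
#'   `redrawn`.
#' @export
edge_ci_bootstrap <- function(table, B = 200, seed = 1, estimator = NULL,
                              correlation = "skeptic", gamma = 0.5,
                              n_lambda = 100, lambda_min_ratio = 0.01) {
  if (B < 100) warning("B < 100 bootstrap replicates is not recommended")
  if (is.null(estimator))
    estimator <- default_estimator(correlation, gamma, n_lambda,
                                   lambda_min_ratio)
  full <- estimator(table)
  p <- full$p
  ut <- which(upper.tri(full$W), arr.ind = TRUE)
  boot <- matrix(NA_real_, B, nrow(ut))
  set.seed(seed)
  redrawn <- 0L
  b <- 1L
  draws <- 0L
  while (b <= B && draws < 10L * B) {
    draws <- draws + 1L
    idx <- sample.int(table$n, table$n, replace = TRUE)
    sub <- table_rows(table, idx)
    fit <- tryCatch(estimator(sub), error = function(e) NULL)
    if (is.null(fit)) {
      redrawn <- redrawn + 1L
      next
    }
    boot[b, ] <- fit$W[ut]
    b <- b + 1L
  }
  if (b <= B) stop("too many degenerate bootstrap resamples")
  edges <- data.frame(
    source = full$labels[ut[, 1]], target = full$labels[ut[, 2]],
    estimate = full$W[ut],
    boot_mean = colMeans(boot),
    lower = apply(boot, 2, stats::quantile, probs = 0.025, names = FALSE),
    upper = apply(boot, 2, stats::quantile, probs = 0.975, names = FALSE),
    stringsAsFactors = FALSE)
  structure(list(edges = edges, B = B, seed = seed, redrawn = redrawn,
                 full = full),
            class = "panet_edgeci")
}

#' @export
print.panet_edgeci <- function(x, ...) {
  cat(sprintf("Edge-weight bootstrap: B = %d (%d redrawn)\n", x$B,
              x$redrawn))
  nz <- x$edges[abs(x$edges$estimate) > 0, ]
  cat(sprintf("  %d nonzero edges; mean CI width %.3f\n", nrow(nz),
              mean(nz$upper - nz$lower)))
  invisible(x)
}
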