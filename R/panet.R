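#' Fit a regularized partial-correlation network to questionnaire data
#'
#' The front door of the package: takes a typed response table (or a plain
#' data frame plus schema), optionally imputes missing cells, estimates a
#' positive-definite correlation matrix (nonparanormal SKEPTIC by default,
#' or automatic Pearson/polychoric/polyserial dispatch), and fits a sparse
#' Gaussian graphical model by graphical lasso with EBIC selection
#' (`gamma = 0.5`). Edge weights are partial correlations.
#'
#' @param data a [response_table()], or a numeric data frame/matrix.
#' @param schema a [var_schema()]; required when `data` is not already a
#'   response table. Columns without a declaration are classified with
#'   [auto_kind()].
#' @param correlation `"skeptic"` or `"auto_mixed"` (see [mixed_matrix()]).
#' @param gamma EBIC hyperparameter.
#' @param n_lambda,lambda_min_ratio penalty-path parameters.
#' @param impute_method `"forest"`, `"knn"`, `"mode_median"` or `"none"`
#'   (error on missing cells).
#' @param seed seed for the (stochastic) forest imputer.
#' @return An object of class `panet`; see [estimate_network()] for the
#'   fields. Methods: `print`, `summary`, `coef` (the weight matrix),
#'   `plot`, `simulate` (draws from the fitted Gaussian model).
#' @examples
#' tab <- sample_responses(synthetic_spec(n = 200, seed = 7))
#' fit <- panet(tab)
#' fit
#' head(coef(fit)[, 1:4])
#' @export
panet <- function(data, schema = NULL,
                  correlation = c("skeptic", "auto_mixed"),
                  gamma = 0.5, n_lambda = 100, lambda_min_ratio = 0.01,
                  impute_method = c("forest", "knn", "mode_median", "none"),
                  seed = 1) {
  correlation <- match.arg(correlation)
  impute_method <- match.arg(impute_method)
  table <- as_response_table(data, schema)
  if (any(table$missing)) {
    if (impute_method == "none")
      stop("table has missing cells and impute_method = \"none\"")
    table <- impute(table, method = impute_method, seed = seed)
  }
  cres <- mixed_matrix(table, mode = correlation)
  fit <- estimate_network(cres$R, n = table$n, gamma = gamma,
                          n_lambda = n_lambda,
                          lambda_min_ratio = lambda_min_ratio,
                          labels = table$schema$name)
  fit$correlation <- correlation
  fit$cor_result <- cres
  fit$schema <- table$schema
  fit
}

as_response_table <- function(data, schema = NULL) {
  if (inherits(data, "response_table")) return(data)
  X <- as.matrix(data)
  if (is.null(schema)) {
    kinds <- apply(X, 2, auto_kind)
    levels <- ifelse(kinds == "ordinal",
                     apply(X, 2, function(c) max(c, na.rm = TRUE) + 1),
                     NA_integer_)
    schema <- var_schema(colnames(X), kinds, levels = levels)
  }
  response_table(X, schema)
}

#' @export
print.panet <- function(x, ...) {
  cat(sprintf(
    "EBIC-glasso partial-correlation network (%s correlations)\n",
    x$correlation %||% "given"))
  cat(sprintf("  nodes: %d   edges: %d   n: %d\n", x$p, x$edge_count, x$n))
  cat(sprintf("  lambda = %.4g (gamma = %g, EBIC = %.2f)\n",
              x$lambda_selected, x$gamma, x$ebic_value))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.panet <- function(object, ...) {
  W <- object$W
  ed <- W[upper.tri(W)]
  nz <- ed[abs(ed) > 0]
  met <- node_metrics(object)
  out <- list(fit = object, metrics = met,
              global_strength = global_strength(W),
              density = length(nz) / length(ed),
              positive = sum(nz > 0), negative = sum(nz < 0),
              max_abs_edge = if (length(nz)) max(abs(nz)) else 0)
  class(out) <- "summary.panet"
  out
}

#' @export
print.summary.panet <- function(x, digits = 3, ...) {
  print(x$fit)
  cat(sprintf(
    "  density: %.2f   +edges: %d   -edges: %d   max|w|: %.3f\n",
    x$density, x$positive, x$negative, x$max_abs_edge))
  cat(sprintf("  global strength: %.3f   global clustering (min): %.3f\n",
              x$global_strength, attr(x$metrics, "global_clustering_min")))
  cat("\nCentrality (z-scores):\n")
  print.data.frame(format(x$metrics[, c("node", "strength_z",
                                        "betweenness_z", "closeness_z")],
                          digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.panet <- function(object, ...) object$W

#' Draw new latent data from a fitted network model
#'
#' Samples from the multivariate normal with precision `K`; useful for
#' parametric checks. Discretization is not reapplied.
#'
#' @param object fitted `panet`.
#' @param nsim number of rows.
#' @param seed integer seed.
#' @param ... unused.
#' @return numeric matrix `nsim x p`.
#' @export
simulate.panet <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- spec_sigma(object$K)
  Z <- matrix(stats::rnorm(nsim * object$p), nsim) %*% chol(sigma)
  colnames(Z) <- object$labels
  Z
}

#' Convert a fitted network to its serialisable graph view
#'
#' @param fit fitted `panet`.
#' @param display_min,display_max display conventions (see
#'   [network_graph()]).
#' @param layout_seed seed for the Fruchterman-Reingold layout; `NULL`
#'   omits the layout.
#' @return a [network_graph()].
#' @export
as_network_graph <- function(fit, display_min = 0.04, display_max = 0.76,
                             layout_seed = NULL) {
  layout <- if (!is.null(layout_seed))
    fruchterman_reingold(fit$W, seed = layout_seed)
  network_graph(fit$W, labels = fit$labels, display_min = display_min,
                display_max = display_max, layout = layout)
}

#' Plot a fitted network
#'
#' Base-graphics rendering with the usual conventions: Fruchterman-Reingold
#' layout, green solid edges for positive partial correlations, red dashed
#' for negative, thickness proportional to `|w| / display_max`, edges with
#' `|w| < display_min` omitted.
#'
#' @param x fitted `panet` (or [network_graph()]).
#' @param display_min,display_max display thresholds.
#' @param layout optional `p x 2` coordinates; computed if missing.
#' @param seed layout seed.
#' @param ... passed to [graphics::plot()].
#' @export
plot.panet <- function(x, display_min = 0.04, display_max = 0.76,
                       layout = NULL, seed = 1, ...) {
  W <- x$W
  if (is.null(layout)) layout <- fruchterman_reingold(W, seed = seed)
  plot_weighted_graph(W, x$labels, layout, display_min, display_max, ...)
}

#' @export
plot.network_graph <- function(x, seed = 1, ...) {
  layout <- x$layout
  if (is.null(layout)) layout <- fruchterman_reingold(x$W, seed = seed)
  plot_weighted_graph(x$W, x$labels, layout, x$display_min, x$display_max,
                      ...)
}

plot_weighted_graph <- function(W, labels, layout, display_min, display_max,
                                ...) {
  graphics::plot(layout, type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = 1, ...)
  p <- nrow(W)
  for (j in seq_len(p)) for (i in seq_len(p)) if (i < j) {
    w <- W[i, j]
    if (abs(w) < display_min) next
    graphics::segments(layout[i, 1], layout[i, 2],
                       layout[j, 1], layout[j, 2],
                       col = if (w > 0) "darkgreen" else "red",
                       lty = if (w > 0) 1 else 2,
                       lwd = 0.5 + 4 * min(abs(w) / display_max, 1))
  }
  graphics::points(layout, pch = 21, bg = "lightblue", cex = 3)
  graphics::text(layout, labels = labels, cex = 0.7)
  invisible(NULL)
}
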