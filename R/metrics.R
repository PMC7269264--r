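# Centrality and clustering on weighted, possibly signed networks.
# Convention throughout: absolute edge weights. Distances use edge length
# 1/|w|, so strong edges are short.

check_W <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

weight_graph <- function(W) {
  A <- abs(check_W(W))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  list(g = g, A = A)
}

#' Node strength
#'
#' Sum of absolute edge weights incident to each node.
#'
#' @param W symmetric weight matrix.
#' @param node optional node index/label; default all nodes.
#' @return numeric vector (or scalar).
#' @export
strength <- function(W, node = NULL) {
  A <- abs(check_W(W))
  s <- rowSums(A)
  names(s) <- colnames(W)
  if (is.null(node)) s else s[node]
}

#' All-pairs shortest-path distances
#'
#' Edge length is the reciprocal absolute weight; unreachable pairs are
#' `Inf`.
#'
#' @param W symmetric weight matrix.
#' @return `p x p` distance matrix.
#' @export
shortest_distances <- function(W) {
  wg <- weight_graph(W)
  ew <- igraph::E(wg$g)$weight
  D <- igraph::distances(wg$g, weights = if (length(ew)) 1 / ew else NULL,
                         algorithm = "dijkstra")
  dimnames(D) <- dimnames(W)
  D
}

#' Betweenness centrality
#'
#' Brandes' algorithm on reciprocal-weight distances, with fractional
#' credit for tied shortest paths; each unordered pair is counted once.
#'
#' @param W symmetric weight matrix.
#' @return numeric vector per node.
#' @export
betweenness <- function(W) {
  wg <- weight_graph(W)
  ew <- igraph::E(wg$g)$weight
  b <- igraph::betweenness(wg$g,
                           weights = if (length(ew)) 1 / ew else NULL,
                           directed = FALSE)
  names(b) <- colnames(W)
  b
}

#' Closeness centrality
#'
#' Reciprocal of the summed shortest-path distances to all *reachable*
#' nodes; a fully isolated node gets 0.
#'
#' @param W symmetric weight matrix.
#' @return numeric vector per node.
#' @export
closeness <- function(W) {
  D <- shortest_distances(W)
  diag(D) <- NA
  apply(D, 1, function(d) {
    d <- d[is.finite(d) & !is.na(d)]
    if (!length(d)) 0 else 1 / sum(d)
  })
}

#' Z-standardise a metric vector
#'
#' `(x - mean) / sd` with the sample standard deviation. A constant input
#' returns all zeros with attribute `"degenerate" = TRUE`.
#'
#' @param values numeric vector, length >= 2.
#' @return z-scores.
#' @export
z_standardise <- function(values) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (s == 0 || !is.finite(s))
    return(structure(rep(0, length(values)), degenerate = TRUE,
                     names = names(values)))
  (values - mean(values)) / s
}

#' Local weighted clustering coefficients
#'
#' Four standard weighted generalizations of the local clustering
#' coefficient, all computed on absolute weights; nodes with fewer than two
#' neighbours get 0:
#'
#' * `"ws"` (Watts-Strogatz): triangle density of the binarized
#'   neighbourhood, `2 t_i / (k_i (k_i - 1))`.
#' * `"barrat"`: triangle weights as the mean of the two edges at the
#'   centre node, normalized by strength, `1/(s_i (k_i - 1)) *
#'   sum_(jh) (w_ij + w_ih)/2 * a_ij a_ih a_jh`.
#' * `"onnela"`: geometric mean of the three triangle edges after scaling
#'   by the maximum weight, `1/(k_i (k_i - 1)) * sum (w'_ij w'_ih
#'   w'_jh)^(1/3)`.
#' * `"zhang"`: weighted triple ratio, `sum w'_ij w'_jh w'_hi /
#'   ((sum_j w'_ij)^2 - sum_j w'_ij^2)`.
#'
#' With 0/1 weights all four coincide.
#'
#' @param W symmetric weight matrix.
#' @param method one of `"ws"`, `"barrat"`, `"zhang"`, `"onnela"`.
#' @return numeric vector per node, values in `[0, 1]`.
#' @export
clustering_local <- function(W, method = c("ws", "barrat", "zhang",
                                           "onnela")) {
  method <- match.arg(method)
  Wa <- abs(check_W(W))
  p <- nrow(Wa)
  A <- (Wa > 0) * 1
  k <- rowSums(A)
  out <- numeric(p)
  names(out) <- colnames(W)
  deg_ok <- k >= 2
  if (!any(deg_ok)) return(out)
  if (method == "ws") {
    tri <- diag(A %*% A %*% A)
    out[deg_ok] <- tri[deg_ok] / (k[deg_ok] * (k[deg_ok] - 1))
  } else if (method == "onnela") {
    Wh <- (Wa / max(Wa))^(1 / 3)
    tri <- diag(Wh %*% Wh %*% Wh)
    out[deg_ok] <- tri[deg_ok] / (k[deg_ok] * (k[deg_ok] - 1))
  } else if (method == "zhang") {
    Wh <- Wa / max(Wa)
    tri <- diag(Wh %*% Wh %*% Wh)
    den <- rowSums(Wh)^2 - rowSums(Wh^2)
    ok <- deg_ok & den > 0
    out[ok] <- tri[ok] / den[ok]
  } else { # barrat
    s <- rowSums(Wa)
    A2 <- A %*% A
    term <- rowSums(Wa * A2)  # sum_j w_ij * #(common neighbours of i, j)
    ok <- deg_ok & s > 0
    out[ok] <- term[ok] / (s[ok] * (k[ok] - 1))
  }
  out
}

#' Global clustering coefficient, minimum method
#'
#' Each triplet centred at `i` with spokes `(i,j)` and `(i,k)` contributes
#' `min(|w_ij|, |w_ik|)`; the coefficient is the minimum-weight mass over
#' closed triplets divided by the mass over all triplets. A graph without
#' triplets returns 0 (attribute `"degenerate" = TRUE`).
#'
#' @param W symmetric weight matrix.
#' @return scalar in `[0, 1]`.
#' @export
clustering_global_min <- function(W) {
  Wa <- abs(check_W(W))
  p <- nrow(Wa)
  A <- Wa > 0
  tot <- 0
  closed <- 0
  for (i in seq_len(p)) {
    nb <- which(A[i, ])
    if (length(nb) < 2) next
    for (a in seq_along(nb)) for (b in seq_along(nb)) if (a < b) {
      j <- nb[a]; k <- nb[b]
      v <- min(Wa[i, j], Wa[i, k])
      tot <- tot + v
      if (A[j, k]) closed <- closed + v
    }
  }
  if (tot == 0)
    return(structure(0, degenerate = TRUE))
  closed / tot
}

#' Per-node metrics table
#'
#' Strength, betweenness and closeness centrality (raw and z-standardised),
#' the four local clustering coefficients, and the global minimum-method
#' clustering coefficient as an attribute.
#'
#' @param x a fitted [panet()] model, a [network_graph()], or a weight
#'   matrix.
#' @param ... unused.
#' @return data frame of class `node_metrics` with one row per node;
#'   attribute `"global_clustering_min"` carries the global coefficient.
#' @export
node_metrics <- function(x, ...) UseMethod("node_metrics")

#' @export
node_metrics.panet <- function(x, ...) node_metrics(x$W, ...)

#' @export
node_metrics.network_graph <- function(x, ...) node_metrics(x$W, ...)

#' @export
node_metrics.default <- function(x, ...) {
  W <- check_W(x)
  labels <- colnames(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(W)))
  st <- strength(W)
  bt <- betweenness(W)
  cl <- closeness(W)
  out <- data.frame(
    node = labels,
    strength = as.numeric(st),
    betweenness = as.numeric(bt),
    closeness = as.numeric(cl),
    strength_z = as.numeric(z_standardise(st)),
    betweenness_z = as.numeric(z_standardise(bt)),
    closeness_z = as.numeric(z_standardise(cl)),
    clustering_ws = as.numeric(clustering_local(W, "ws")),
    clustering_barrat = as.numeric(clustering_local(W, "barrat")),
    clustering_zhang = as.numeric(clustering_local(W, "zhang")),
    clustering_onnela = as.numeric(clustering_local(W, "onnela")),
    stringsAsFactors = FALSE)
  attr(out, "global_clustering_min") <- as.numeric(clustering_global_min(W))
  class(out) <- c("node_metrics", "data.frame")
  out
}

#' @export
print.node_metrics <- function(x, digits = 3, ...) {
  cat("Node metrics (global min-method clustering:",
      format(attr(x, "global_clustering_min"), digits = digits), ")\n")
  print.data.frame(format(x, digits = digits), row.names = FALSE, ...)
  invisible(x)
}
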