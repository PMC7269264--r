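#' Serialisable weighted network view
#'
#' A plain container for a symmetric partial-correlation weight matrix plus
#' the display conventions used for plotting: edges below `display_min` in
#' absolute weight are not drawn, and `display_max` is the weight mapped to
#' maximum line thickness (so equally thick edges are comparable across
#' networks sharing the same `display_max`).
#'
#' @param W symmetric `p x p` weight matrix, zero diagonal, entries in
#'   `[-1, 1]`.
#' @param labels node labels; defaults to `colnames(W)`.
#' @param display_min minimum absolute weight drawn (default 0.04).
#' @param display_max weight mapped to maximum thickness (default 0.76).
#' @param layout optional `p x 2` coordinate matrix.
#' @return An object of class `network_graph`.
#' @export
network_graph <- function(W, labels = colnames(W), display_min = 0.04,
                          display_max = 0.76, layout = NULL) {
  W <- as.matrix(W)
  p <- nrow(W)
  if (ncol(W) != p) stop("W must be square")
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  W <- (W + t(W)) / 2
  if (any(abs(diag(W)) > 1e-12)) stop("W must have a zero diagonal")
  diag(W) <- 0
  if (max(abs(W)) > 1 + 1e-10) stop("weights must lie in [-1, 1]")
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  dimnames(W) <- list(labels, labels)
  if (!is.null(layout)) {
    layout <- as.matrix(layout)
    stopifnot(nrow(layout) == p, ncol(layout) == 2)
  }
  structure(list(W = W, labels = labels, display_min = display_min,
                 display_max = display_max, layout = layout),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  E <- sum(abs(x$W[upper.tri(x$W)]) > 0)
  cat(sprintf("Weighted network: %d nodes, %d edges (display cutoff %.2f)\n",
              length(x$labels), E, x$display_min))
  invisible(x)
}

graph_edges <- function(g) {
  W <- g$W
  ut <- which(upper.tri(W) & abs(W) > 0, arr.ind = TRUE)
  data.frame(source = g$labels[ut[, 1]], target = g$labels[ut[, 2]],
             weight = W[ut], stringsAsFactors = FALSE)
}

#' Write / read a network graph
#'
#' Three plain-text formats are supported. `edge_list_csv` holds one row per
#' nonzero edge (`source,target,weight`, upper triangle only). `graphml` is
#' standard GraphML with a `weight` edge attribute. `json` is a single JSON
#' document carrying labels, the full weight matrix, display thresholds and
#' the layout. All formats round-trip weights to better than 1e-12.
#'
#' @param graph a [network_graph()].
#' @param path output file path.
#' @param format one of `"edge_list_csv"`, `"graphml"`, `"json"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a [network_graph()]. Note the edge-list format does not carry
#'   isolated nodes, display thresholds or layout; reading it back requires
#'   `labels`.
#' @export
write_network <- function(graph, path,
                          format = c("edge_list_csv", "graphml", "json")) {
  format <- match.arg(format)
  switch(format,
    edge_list_csv = {
      ed <- graph_edges(graph)
      ed$weight <- sprintf("%.17g", ed$weight)
      utils::write.csv(ed, path, row.names = FALSE, quote = FALSE)
    },
    graphml = write_graphml(graph, path),
    json = jsonlite::write_json(
      list(labels = graph$labels, weights = graph$W,
           display_min = graph$display_min, display_max = graph$display_max,
           layout = graph$layout),
      path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor",
      na = "null"))
  invisible(path)
}

#' @param labels node labels (edge-list format only, to restore isolated
#'   nodes).
#' @rdname write_network
#' @export
read_network <- function(path, format = c("edge_list_csv", "graphml", "json"),
                         labels = NULL) {
  format <- match.arg(format)
  switch(format,
    edge_list_csv = {
      ed <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "numeric"))
      if (is.null(labels)) labels <- sort(unique(c(ed$source, ed$target)))
      W <- matrix(0, length(labels), length(labels),
                  dimnames = list(labels, labels))
      if (nrow(ed)) {
        W[cbind(ed$source, ed$target)] <- ed$weight
        W[cbind(ed$target, ed$source)] <- ed$weight
      }
      network_graph(W, labels)
    },
    graphml = read_graphml(path),
    json = {
      doc <- jsonlite::fromJSON(path)
      network_graph(as.matrix(doc$weights), doc$labels,
                    display_min = doc$display_min,
                    display_max = doc$display_max,
                    layout = if (!is.null(doc$layout))
                      as.matrix(doc$layout))
    })
}

write_graphml <- function(graph, path) {
  ed <- graph_edges(graph)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%s"/>', graph$labels),
    if (nrow(ed)) sprintf(
      '    <edge source="%s" target="%s"><data key="w">%.17g</data></edge>',
      ed$source, ed$target, ed$weight),
    "  </graph>", "</graphml>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:node", ns), "id")
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in edges) {
    s <- xml2::xml_attr(e, "source")
    t <- xml2::xml_attr(e, "target")
    w <- as.numeric(xml2::xml_text(xml2::xml_find_first(e, ".//g:data", ns)))
    W[s, t] <- w
    W[t, s] <- w
  }
  network_graph(W, nodes)
}
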