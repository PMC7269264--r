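#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(var_i) / var(total))` with sample variances,
#' computed on complete rows of an item block.
#'
#' @param items numeric matrix or data frame of item scores (k >= 2
#'   columns), or a [response_table()] (its `role == "item"` columns are
#'   used).
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  if (inherits(items, "response_table")) {
    items <- items$values[, items$schema$role == "item", drop = FALSE]
  }
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2) stop("need at least 2 items")
  vt <- stats::var(rowSums(items))
  if (vt == 0) stop("total score has zero variance")
  (k / (k - 1)) * (1 - sum(apply(items, 2, stats::var)) / vt)
}

#' Fruchterman-Reingold layout for a weighted network
#'
#' Force-directed coordinates using absolute edge weights as attraction
#' strengths, deterministic given `seed`, centred at the origin.
#'
#' @param W symmetric weight matrix.
#' @param iterations iterations for the solver (default 500).
#' @param seed integer seed.
#' @return `p x 2` coordinate matrix.
#' @export
fruchterman_reingold <- function(W, iterations = 500, seed = 1) {
  W <- check_W(W)
  p <- nrow(W)
  if (p == 1) return(matrix(0, 1, 2))
  wg <- weight_graph(W)
  set.seed(seed)
  ew <- igraph::E(wg$g)$weight
  xy <- igraph::layout_with_fr(wg$g, niter = iterations,
                               weights = if (length(ew)) ew else NULL)
  xy <- sweep(xy, 2, colMeans(xy))
  stopifnot(all(is.finite(xy)))
  rownames(xy) <- colnames(W)
  xy
}

#' Run the four-network questionnaire analysis end-to-end
#'
#' Reproduces the standard analysis sequence on one dataset: (1) an
#' items-only network; (2) a network of items plus covariates; a median
#' split of the item total score into low/high groups with (3) and (4)
#' their group networks; a permutation comparison test between (3) and
#' (4); per-network metric and clustering tables, graph exports with a
#' Fruchterman-Reingold layout, and (optionally) stability and
#' edge-accuracy bootstraps. Missing cells are imputed once up front. One
#' structured log line is emitted per stage.
#'
#' @param table a [response_table()]; item columns are those with
#'   `role == "item"`.
#' @param output_dir directory for exported files; `NULL` skips writing.
#' @param correlation,gamma,n_lambda,lambda_min_ratio estimator settings.
#' @param impute_method see [impute()].
#' @param nct_tests,P network-comparison settings.
#' @param stability,edge_accuracy logical: run the bootstraps?
#' @param B bootstrap replicates; `grid` the case-dropping grid.
#' @param display_min,display_max display conventions for exports.
#' @param seed master seed; stage seeds are derived from it.
#' @param verbose emit log lines?
#' @return list with the four fits (`items`, `full`, `low`, `high`), their
#'   `metrics` tables, the `nct` result, `alpha` (items Cronbach alpha),
#'   `split` (group labels), optional `stability` and `edge_ci`, and the
#'   output `manifest`.
#' @export
run_four_networks <- function(table, output_dir = NULL,
                              correlation = "skeptic", gamma = 0.5,
                              n_lambda = 100, lambda_min_ratio = 0.01,
                              impute_method = "forest",
                              nct_tests = c("structure", "strength"),
                              P = 1000, stability = FALSE,
                              edge_accuracy = FALSE, B = 100,
                              grid = seq(0.05, 0.75, by = 0.1),
                              display_min = 0.04, display_max = 0.76,
                              seed = 1, verbose = TRUE) {
  t0 <- proc.time()[3]
  log_stage <- function(stage, ...) {
    if (verbose)
      message(sprintf("[%s] %s (%.1fs, seed %d)", stage,
                      sprintf(...), proc.time()[3] - t0, seed))
  }
  item_cols <- which(table$schema$role == "item")
  if (length(item_cols) < 2) stop("need at least 2 item columns")

  if (any(table$missing)) {
    table <- impute(table, method = impute_method, seed = seed)
    log_stage("impute", "method %s, %d x %d", impute_method, table$n,
              table$p)
  }
  alpha <- cronbach_alpha(table$values[, item_cols, drop = FALSE])
  log_stage("descriptives", "Cronbach alpha = %.3f over %d items", alpha,
            length(item_cols))

  est <- function(tab) {
    cres <- mixed_matrix(tab, mode = correlation)
    fit <- estimate_network(cres$R, n = tab$n, gamma = gamma,
                            n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio,
                            labels = tab$schema$name)
    fit$correlation <- correlation
    fit
  }

  items_tab <- table_cols(table, item_cols)
  fit_items <- est(items_tab)
  log_stage("network_items", "%d nodes, %d edges", fit_items$p,
            fit_items$edge_count)
  fit_full <- est(table)
  log_stage("network_full", "%d nodes, %d edges", fit_full$p,
            fit_full$edge_count)

  totals <- rowSums(table$values[, item_cols, drop = FALSE])
  split <- median_split(totals)
  tab_low <- table_rows(table, which(split == "low"))
  tab_high <- table_rows(table, which(split == "high"))
  fit_low <- est(table_cols(tab_low, item_cols))
  fit_high <- est(table_cols(tab_high, item_cols))
  log_stage("median_split", "low n = %d, high n = %d", tab_low$n,
            tab_high$n)

  nct_res <- nct(table_cols(tab_low, item_cols),
                 table_cols(tab_high, item_cols), P = P, seed = seed + 1L,
                 tests = nct_tests, estimator = est)
  log_stage("nct", "M = %.3f (p = %.3f), S = %.3f (p = %.3f)",
            nct_res$observed_M, nct_res$p_M, nct_res$observed_S,
            nct_res$p_S)

  fits <- list(items = fit_items, full = fit_full, low = fit_low,
               high = fit_high)
  metrics <- lapply(fits, node_metrics)

  stab <- NULL
  if (stability) {
    stab <- case_drop_bootstrap(table, grid = grid, B = B,
                                seed = seed + 2L, estimator = est)
    log_stage("stability", "CS: %s",
              paste(sprintf("%.2f", cs_coefficient(stab)), collapse = "/"))
  }
  eci <- NULL
  if (edge_accuracy) {
    eci <- edge_ci_bootstrap(table, B = max(B, 100), seed = seed + 3L,
                             estimator = est)
    log_stage("edge_accuracy", "B = %d", eci$B)
  }

  manifest <- character()
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(fits)) {
      g <- as_network_graph(fits[[nm]], display_min, display_max,
                            layout_seed = seed)
      fj <- file.path(output_dir, paste0("network_", nm, ".json"))
      fe <- file.path(output_dir, paste0("network_", nm, "_edges.csv"))
      fm <- file.path(output_dir, paste0("metrics_", nm, ".csv"))
      write_network(g, fj, "json")
      write_network(g, fe, "edge_list_csv")
      utils::write.csv(cbind(metrics[[nm]],
                             global_clustering_min =
                               attr(metrics[[nm]], "global_clustering_min")),
                       fm, row.names = FALSE)
      manifest <- c(manifest, fj, fe, fm)
    }
    fn <- file.path(output_dir, "nct.json")
    jsonlite::write_json(
      list(observed_M = nct_res$observed_M, p_M = nct_res$p_M,
           observed_S = nct_res$observed_S, p_S = nct_res$p_S,
           global_strength_low = nct_res$global_strength_1,
           global_strength_high = nct_res$global_strength_2,
           P = nct_res$P, seed = nct_res$seed),
      fn, auto_unbox = TRUE, digits = NA)
    manifest <- c(manifest, fn)
    fman <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(list(files = basename(manifest), seed = seed,
                              alpha = alpha),
                         fman, auto_unbox = TRUE, digits = NA)
    manifest <- c(manifest, fman)
    log_stage("export", "%d files in %s", length(manifest), output_dir)
  }

  list(items = fit_items, full = fit_full, low = fit_low, high = fit_high,
       metrics = metrics, nct = nct_res, alpha = alpha, split = split,
       stability = stab, edge_ci = eci, manifest = manifest, seed = seed)
}
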