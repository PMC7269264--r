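#' Median split of participant totals
#'
#' Scores at or below the sample median go to the low group, the rest to
#' the high group (deterministic tie rule).
#'
#' @param scores numeric vector of per-participant totals.
#' @return factor with levels `"low"`, `"high"`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 participants")
  if (length(unique(scores)) == 1)
    stop("all scores identical: degenerate split")
  m <- stats::median(scores)
  factor(ifelse(scores <= m, "low", "high"), levels = c("low", "high"))
}

#' Global strength of a network
#'
#' Sum of absolute edge weights over the upper triangle (equivalently,
#' half the summed node strengths).
#'
#' @param W symmetric weight matrix.
#' @return scalar.
#' @export
global_strength <- function(W) {
  W <- check_W(W)
  sum(abs(W[upper.tri(W)]))
}

#' Permutation-based network comparison test (NCT)
#'
#' Estimates a network independently in each group and tests three
#' invariances by permuting group labels over the pooled participants
#' (group sizes preserved): network structure (`M`, the maximum absolute
#' edge difference), global strength (`S`, the absolute difference of
#' global strengths), and optionally individual edges (restricted to edges
#' nonzero in either observed network, Holm-adjusted). P-values use the
#' add-one convention `p = (1 + #(perm >= obs)) / (1 + P)`.
#'
#' @param table_a,table_b complete [response_table()]s sharing a schema.
#' @param P permutation count (default 1000; below 100 triggers a warning).
#' @param seed integer seed.
#' @param tests subset of `c("structure", "strength", "edges")`.
#' @param estimator optional function `table -> panet`.
#' @param correlation,gamma,n_lambda,lambda_min_ratio estimator settings.
#' @return object of class `panet_nct` with observed statistics, null
#'   distributions, p-values, and (if requested) the per-edge table.
#' @export
nct <- function(table_a, table_b, P = 1000, seed = 1,
                tests = c("structure", "strength"), estimator = NULL,
                correlation = "skeptic", gamma = 0.5, n_lambda = 100,
                lambda_min_ratio = 0.01) {
  tests <- match.arg(tests, c("structure", "strength", "edges"),
                     several.ok = TRUE)
  if (!identical(table_a$schema$name, table_b$schema$name))
    stop("both groups must share one schema")
  if (P < 100) warning("P < 100 permutations is not recommended")
  if (is.null(estimator))
    estimator <- default_estimator(correlation, gamma, n_lambda,
                                   lambda_min_ratio)
  fit_a <- estimator(table_a)
  fit_b <- estimator(table_b)
  diff_mat <- abs(fit_a$W - fit_b$W)
  observed_M <- max(diff_mat[upper.tri(diff_mat)])
  gs_a <- global_strength(fit_a$W)
  gs_b <- global_strength(fit_b$W)
  observed_S <- abs(gs_a - gs_b)
  ut <- which(upper.tri(fit_a$W), arr.ind = TRUE)
  edge_sel <- which(abs(fit_a$W[ut]) > 0 | abs(fit_b$W[ut]) > 0)
  pooled <- rbind(table_a$values, table_b$values)
  na <- table_a$n
  ntot <- nrow(pooled)
  set.seed(seed)
  perm_M <- perm_S <- rep(NA_real_, P)
  perm_edges <- if ("edges" %in% tests)
    matrix(NA_real_, P, length(edge_sel)) else NULL
  dropped <- 0L
  for (s in seq_len(P)) {
    idx_a <- sample.int(ntot, na)
    ta <- table_a; ta$values <- pooled[idx_a, , drop = FALSE]
    ta$missing <- is.na(ta$values); ta$n <- na
    tb <- table_b; tb$values <- pooled[-idx_a, , drop = FALSE]
    tb$missing <- is.na(tb$values); tb$n <- ntot - na
    fa <- tryCatch(estimator(ta), error = function(e) NULL)
    fb <- tryCatch(estimator(tb), error = function(e) NULL)
    if (is.null(fa) || is.null(fb)) {
      dropped <- dropped + 1L
      next
    }
    dm <- abs(fa$W - fb$W)
    perm_M[s] <- max(dm[upper.tri(dm)])
    perm_S[s] <- abs(global_strength(fa$W) - global_strength(fb$W))
    if (!is.null(perm_edges)) perm_edges[s, ] <- dm[ut][edge_sel]
  }
  if (dropped > 0.1 * P)
    warning(sprintf("%d of %d permutations dropped as degenerate", dropped,
                    P))
  ok <- !is.na(perm_M)
  Pe <- sum(ok)
  p_M <- (1 + sum(perm_M[ok] >= observed_M)) / (1 + Pe)
  p_S <- (1 + sum(perm_S[ok] >= observed_S)) / (1 + Pe)
  edge_table <- NULL
  if (!is.null(perm_edges) && length(edge_sel)) {
    obs_e <- diff_mat[ut][edge_sel]
    p_e <- vapply(seq_along(edge_sel), function(t)
      (1 + sum(perm_edges[ok, t] >= obs_e[t])) / (1 + Pe), numeric(1))
    edge_table <- data.frame(
      source = fit_a$labels[ut[edge_sel, 1]],
      target = fit_a$labels[ut[edge_sel, 2]],
      weight_a = fit_a$W[ut][edge_sel], weight_b = fit_b$W[ut][edge_sel],
      difference = obs_e, p = p_e,
      p_holm = stats::p.adjust(p_e, method = "holm"),
      stringsAsFactors = FALSE)
  }
  structure(list(observed_M = observed_M, observed_S = observed_S,
                 global_strength_1 = gs_a, global_strength_2 = gs_b,
                 p_M = p_M, p_S = p_S, perm_M = perm_M[ok],
                 perm_S = perm_S[ok], edge_tests = edge_table,
                 P = Pe, dropped = dropped, seed = seed,
                 fit_a = fit_a, fit_b = fit_b),
            class = "panet_nct")
}

#' @export
print.panet_nct <- function(x, ...) {
  cat("Network comparison test (permutation)\n")
  cat(sprintf("  structure: max |edge difference| M = %.3f, p = %.3f\n",
              x$observed_M, x$p_M))
  cat(sprintf(
    "  global strength: %.2f vs %.2f (|S| = %.3f), p = %.3f\n",
    x$global_strength_1, x$global_strength_2, x$observed_S, x$p_S))
  if (!is.null(x$edge_tests))
    cat(sprintf("  edge tests: %d edges, %d with Holm-adjusted p < 0.05\n",
                nrow(x$edge_tests), sum(x$edge_tests$p_holm < 0.05)))
  cat(sprintf("  permutations: %d (%d dropped), seed %d\n", x$P, x$dropped,
              x$seed))
  invisible(x)
}
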