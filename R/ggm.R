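#' Penalty path for the graphical lasso
#'
#' Log-spaced descending sequence from `lambda_max` (the largest absolute
#' off-diagonal correlation, at which the selected network is empty) down to
#' `lambda_max * min_ratio`.
#'
#' @param R correlation matrix.
#' @param n_lambda number of path points (default 100).
#' @param min_ratio smallest penalty as a fraction of `lambda_max`
#'   (default 0.01).
#' @return descending numeric vector.
#' @export
lambda_path <- function(R, n_lambda = 100, min_ratio = 0.01) {
  off <- abs(R[upper.tri(R)])
  lmax <- max(off)
  if (lmax == 0) {
    warning("all off-diagonal correlations are zero; degenerate path")
    return(0)
  }
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Graphical lasso at a fixed penalty
#'
#' Maximizes `log det K - tr(RK) - lambda * sum_{i != j} |K_ij|` (diagonal
#' unpenalized) by blockwise coordinate descent. The fit is verified against
#' the KKT system; a residual above `1e-4` raises an error naming the
#' penalty.
#'
#' @param R PD correlation matrix.
#' @param lambda penalty, `>= 0`.
#' @return precision matrix `K` with attribute `"kkt"` (max KKT residual).
#' @export
glasso_fit <- function(R, lambda) {
  stopifnot(lambda >= 0)
  R <- unclass((R + t(R)) / 2)
  if (lambda == 0) {
    K <- solve(R)
    K <- (K + t(K)) / 2
    attr(K, "kkt") <- 0
    dimnames(K) <- dimnames(R)
    return(K)
  }
  fit <- .glasso_cpp(R, lambda)
  if (fit$kkt > 1e-4)
    stop(sprintf("glasso did not converge at lambda = %g (KKT residual %g)",
                 lambda, fit$kkt))
  K <- fit$K
  dimnames(K) <- dimnames(R)
  attr(K, "kkt") <- fit$kkt
  K
}

#' Extended Bayesian Information Criterion of a fitted precision matrix
#'
#' `EBIC = -n [log det K - tr(RK)] + E log n + 4 E gamma log p`, where `E`
#' is the number of nonzero upper-triangle entries of `K`. At `gamma = 0`
#' this is the ordinary BIC for the Gaussian graphical model.
#'
#' @param K PD precision matrix.
#' @param R correlation matrix the model was fitted to.
#' @param n sample size.
#' @param gamma EBIC hyperparameter (0.5 in the reference pipeline).
#' @return scalar EBIC value.
#' @export
ebic_score <- function(K, R, n, gamma = 0.5) {
  ch <- tryCatch(chol(K), error = function(e)
    stop("K must be positive definite"))
  E <- sum(abs(K[upper.tri(K)]) > 1e-10)
  ll <- 2 * sum(log(diag(ch))) - sum(R * K)
  -n * ll + E * log(n) + 4 * E * gamma * log(nrow(K))
}

#' Partial correlations from a precision matrix
#'
#' `W_ij = -K_ij / sqrt(K_ii K_jj)` off the diagonal, 0 on it: the edge
#' weights of the Gaussian graphical model.
#'
#' @param K PD precision matrix.
#' @return weight matrix `W`.
#' @export
precision_to_partials <- function(K) {
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("K must be positive definite")
  d <- 1 / sqrt(diag(K))
  W <- -(d * K * rep(d, each = nrow(K)))
  diag(W) <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(K)
  W
}

#' Estimate a sparse partial-correlation network (EBIC-glasso)
#'
#' Fits the whole penalty path with warm starts, scores every fit by EBIC,
#' keeps the minimizer and converts it to partial correlations; entries
#' below `1e-10` in magnitude are exact zeros from the L1 penalty. This is
#' the estimation core behind [panet()].
#'
#' @param R PD correlation matrix.
#' @param n sample size the correlations were computed from.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio path parameters (see [lambda_path()]).
#' @param labels node labels.
#' @return An object of class `panet` (see [panet()] for the interactive
#'   front door): list with `W`, `K`, `lambda_selected`, `gamma`,
#'   `ebic_value`, `edge_count`, `n`, `p`, `labels`, `R`, and the full
#'   `path` (lambdas, EBIC values, edge counts).
#' @export
estimate_network <- function(R, n, gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, labels = colnames(R)) {
  p <- nrow(R)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  lambdas <- lambda_path(R, n_lambda, lambda_min_ratio)
  Ru <- unclass((R + t(R)) / 2)
  dimnames(Ru) <- NULL
  if (length(lambdas) == 1 && lambdas == 0) {
    K <- solve(Ru)
    sel <- 1
    path <- list(lambdas = 0, ebic = ebic_score(K, Ru, n, gamma),
                 edges = 0L, kkt = 0)
  } else {
    fit <- .glasso_path_cpp(Ru, lambdas, n, gamma)
    bad <- which(fit$kkt > 1e-4)
    if (length(bad))
      stop(sprintf("glasso did not converge at lambda = %g (KKT %g)",
                   lambdas[bad[1]], fit$kkt[bad[1]]))
    K <- fit$K
    sel <- fit$best_index
    path <- list(lambdas = lambdas, ebic = fit$ebic, edges = fit$edges,
                 kkt = fit$kkt)
  }
  W <- precision_to_partials(K)
  W[abs(W) < 1e-10] <- 0
  dimnames(W) <- dimnames(K) <- list(labels, labels)
  structure(list(W = W, K = K, lambda_selected = path$lambdas[sel],
                 gamma = gamma, ebic_value = path$ebic[sel],
                 edge_count = sum(abs(W[upper.tri(W)]) > 0),
                 n = n, p = p, labels = labels, R = R, path = path),
            class = "panet")
}
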