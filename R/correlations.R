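#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall correlation, the input to the nonparanormal
#' SKEPTIC transform. Thin wrapper over [stats::cor()] with argument checks
#' matching the rest of the pipeline.
#'
#' @param x,y numeric vectors of equal length, both non-constant.
#' @return tau-b in `[-1, 1]`.
#' @examples
#' kendall_tau_b(1:4, c(1, 3, 2, 4))  # 4/6
#' @export
kendall_tau_b <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Kendall correlation undefined")
  .kendall_matrix_cpp(cbind(x, y))[1, 2]
}

#' Nonparanormal SKEPTIC transform
#'
#' Maps Kendall's tau to the latent Gaussian correlation,
#' `rho = sin(pi * tau / 2)`, elementwise. For a matrix the diagonal is
#' forced to exactly 1. The transform is odd and strictly increasing on
#' `[-1, 1]`.
#'
#' @param tau scalar, vector or matrix of Kendall correlations.
#' @return object of the same shape.
#' @examples
#' skeptic_transform(1 / 3)  # 0.5
#' @export
skeptic_transform <- function(tau) {
  if (any(abs(tau) > 1 + 1e-12, na.rm = TRUE))
    stop("|tau| must not exceed 1")
  rho <- sin(pi * pmin(pmax(tau, -1), 1) / 2)
  if (is.matrix(rho)) diag(rho) <- 1
  rho
}

# thresholds from marginal cumulative proportions (drops the +/- Inf ends)
ordinal_thresholds <- function(x) {
  tab <- table(factor(x))
  cum <- cumsum(tab) / sum(tab)
  stats::qnorm(cum[-length(cum)])
}

# cell probabilities of a discretized bivariate normal
bvn_cell_probs <- function(rho, a, b) {
  # a, b: interior thresholds; cells are the (length(a)+1) x (length(b)+1)
  # rectangles. Uses the rectangle identity on the bivariate CDF.
  aa <- c(-Inf, a, Inf)
  bb <- c(-Inf, b, Inf)
  na <- length(aa); nb <- length(bb)
  Phi2 <- matrix(0, na, nb)
  corr <- matrix(c(1, rho, rho, 1), 2)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    Phi2[i, j] <-
      if (aa[i] == -Inf || bb[j] == -Inf) 0
      else if (aa[i] == Inf && bb[j] == Inf) 1
      else if (aa[i] == Inf) stats::pnorm(bb[j])
      else if (bb[j] == Inf) stats::pnorm(aa[i])
      else mvtnorm::pmvnorm(upper = c(aa[i], bb[j]), corr = corr)[1]
  }
  P <- Phi2[-1, -1, drop = FALSE] - Phi2[-na, -1, drop = FALSE] -
    Phi2[-1, -nb, drop = FALSE] + Phi2[-na, -nb, drop = FALSE]
  pmax(P, 0)
}

polychoric_loglik <- function(rho, counts, a, b) {
  P <- bvn_cell_probs(rho, a, b)
  keep <- counts > 0
  sum(counts[keep] * log(pmax(P[keep], 1e-300)))
}

#' Polychoric correlation (two-step estimator)
#'
#' Thresholds are fixed from the marginal cumulative proportions via the
#' inverse normal CDF; the latent correlation then maximizes the
#' bivariate-normal contingency-table likelihood over `(-0.999, 0.999)`.
#' Binary variables are handled as 2-level ordinal (tetrachoric) cases.
#'
#' @param x,y integer-coded ordinal vectors with at least 2 observed
#'   categories each.
#' @return latent correlation estimate.
#' @export
polychoric <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("polychoric needs >= 2 observed categories in each variable")
  counts <- table(factor(x), factor(y))
  a <- ordinal_thresholds(x)
  b <- ordinal_thresholds(y)
  opt <- stats::optimize(function(r) -polychoric_loglik(r, counts, a, b),
                         interval = c(-0.999, 0.999), tol = 1e-6)
  opt$minimum
}

#' Polyserial correlation
#'
#' Maximum-likelihood estimate of the latent correlation between a
#' continuous variable and an ordinal one, with the ordinal thresholds fixed
#' from its margins. If the likelihood optimization fails, falls back to the
#' two-step moment estimator (flagged via attribute `"fallback"`).
#'
#' @param x continuous vector (non-constant).
#' @param y integer-coded ordinal vector (>= 2 observed categories).
#' @return latent correlation estimate.
#' @export
polyserial <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0) stop("continuous variable is constant")
  if (length(unique(y)) < 2) stop("ordinal variable has one category")
  z <- (x - mean(x)) / stats::sd(x)
  tau <- ordinal_thresholds(y)
  cuts <- c(-Inf, tau, Inf)
  yi <- as.integer(factor(y))
  negll <- function(r) {
    s <- sqrt(1 - r^2)
    upper <- stats::pnorm((cuts[yi + 1L] - r * z) / s)
    lower <- stats::pnorm((cuts[yi] - r * z) / s)
    -sum(log(pmax(upper - lower, 1e-300)))
  }
  est <- tryCatch(
    stats::optimize(negll, interval = c(-0.999, 0.999), tol = 1e-6)$minimum,
    error = function(e) NA_real_)
  if (is.na(est) || !is.finite(est)) {
    # two-step moment estimator: r_xy * sd(y) / sum(dnorm(thresholds))
    est <- stats::cor(x, y) * stats::sd(y) *
      sqrt((length(y) - 1) / length(y)) / sum(stats::dnorm(tau))
    est <- max(min(est, 0.999), -0.999)
    attr(est, "fallback") <- TRUE
  }
  est
}

#' Nearest positive-definite correlation repair
#'
#' Pairwise polychoric/polyserial matrices need not be positive definite.
#' Eigenvalues are clipped at `1e-8` and the matrix rescaled back to unit
#' diagonal; an already-PD input is returned unchanged.
#'
#' @param R symmetric matrix with unit diagonal.
#' @return PD correlation matrix with attribute `"pd_adjusted"`.
#' @export
nearest_pd <- function(R) {
  if (max(abs(R - t(R))) > 1e-8) stop("input must be symmetric")
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 1e-8) {
    attr(R, "pd_adjusted") <- FALSE
    return(R)
  }
  # clip-and-rescale can nudge the smallest eigenvalue back below the
  # floor; raise the clip level geometrically until it holds
  floor0 <- 1e-8
  R2 <- R
  for (k in 0:40) {
    e <- eigen(R2, symmetric = TRUE)
    if (min(e$values) >= floor0) break
    v <- pmax(e$values, floor0 * 2^k)
    R2 <- e$vectors %*% (v * t(e$vectors))
    d <- 1 / sqrt(diag(R2))
    R2 <- d * R2 * rep(d, each = nrow(R2))
    R2 <- (R2 + t(R2)) / 2
    diag(R2) <- 1
  }
  dimnames(R2) <- dimnames(R)
  attr(R2, "pd_adjusted") <- TRUE
  R2
}

#' Mixed-type correlation matrix
#'
#' Two estimation modes feed the graphical lasso. `"skeptic"` (default in
#' the pipeline) computes the Kendall tau-b matrix and applies the
#' nonparanormal sine transform to every pair. `"auto_mixed"` dispatches by
#' declared kind: Pearson for continuous-continuous, polychoric for
#' ordinal/binary pairs, polyserial for mixed pairs. Either way the result
#' is passed through [nearest_pd()].
#'
#' @param table a complete (imputed) [response_table()].
#' @param mode `"skeptic"` or `"auto_mixed"`.
#' @return An object of class `cor_result`: list with `R` (PD correlation
#'   matrix), `method_map` (per-pair character matrix), `pd_adjusted`,
#'   `n_effective`.
#' @export
mixed_matrix <- function(table, mode = c("skeptic", "auto_mixed")) {
  mode <- match.arg(mode)
  X <- table$values
  if (anyNA(X))
    stop("correlation estimation requires a complete table; impute first")
  p <- ncol(X)
  nm <- table$schema$name
  method_map <- matrix("", p, p, dimnames = list(nm, nm))
  if (mode == "skeptic") {
    const <- apply(X, 2, function(c) stats::sd(c) == 0)
    if (any(const))
      stop("constant column(s): ", paste(nm[const], collapse = ", "))
    tau <- .kendall_matrix_cpp(X)
    R <- skeptic_transform(tau)
    method_map[] <- "skeptic"
  } else {
    ordinal <- schema_is_ordinal(table$schema)
    R <- diag(p)
    for (j in seq_len(p)) for (i in seq_len(p)) if (i < j) {
      est <- tryCatch({
        if (ordinal[i] && ordinal[j]) {
          method_map[i, j] <- method_map[j, i] <- "polychoric"
          polychoric(X[, i], X[, j])
        } else if (!ordinal[i] && !ordinal[j]) {
          method_map[i, j] <- method_map[j, i] <- "pearson"
          stats::cor(X[, i], X[, j])
        } else {
          method_map[i, j] <- method_map[j, i] <- "polyserial"
          if (ordinal[j]) polyserial(X[, i], X[, j])
          else polyserial(X[, j], X[, i])
        }
      }, error = function(e)
        stop(sprintf("pair (%s, %s): %s", nm[i], nm[j], conditionMessage(e)),
             call. = FALSE))
      R[i, j] <- R[j, i] <- as.numeric(est)
    }
  }
  dimnames(R) <- list(nm, nm)
  R <- nearest_pd(R)
  structure(list(R = R, method_map = method_map,
                 pd_adjusted = attr(R, "pd_adjusted"),
                 n_effective = nrow(X)),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Correlation matrix: %d variables (%s)%s\n", nrow(x$R),
              paste(unique(x$method_map[upper.tri(x$method_map)]),
                    collapse = "/"),
              if (isTRUE(x$pd_adjusted)) ", PD-repaired" else ""))
  invisible(x)
}
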