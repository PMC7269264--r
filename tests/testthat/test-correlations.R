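test_that("kendall tau-b matches direct pair enumeration", {
  expect_equal(kendall_tau_b(1:3, 1:3), 1)
  expect_equal(kendall_tau_b(1:3, 3:1), -1)
  # 6 pairs, 5 concordant 1 discordant
  expect_equal(kendall_tau_b(1:4, c(1, 3, 2, 4)), 4 / 6)
  expect_error(kendall_tau_b(c(1, 1, 1), 1:3), "constant")
  # the fast matrix path agrees with stats::cor under heavy ties
  set.seed(7)
  X <- cbind(sample(0:3, 60, TRUE), sample(0:1, 60, TRUE), rnorm(60),
             round(rnorm(60)))
  expect_lt(max(abs(panet:::.kendall_matrix_cpp(X) -
                      cor(X, method = "kendall"))), 1e-12)
})

test_that("skeptic transform identities and shape properties hold", {
  expect_equal(skeptic_transform(0), 0)
  expect_equal(skeptic_transform(1), 1)
  expect_equal(skeptic_transform(1 / 3), 0.5)
  expect_error(skeptic_transform(1.2), "exceed")
  tau <- seq(-1, 1, by = 0.05)
  rho <- skeptic_transform(tau)
  expect_equal(rho, -rev(rho))          # odd
  expect_true(all(diff(rho) > 0))       # strictly increasing
  M <- matrix(c(0.9, 0.4, 0.4, 0.9), 2)
  expect_equal(diag(skeptic_transform(M)), c(1, 1))
})

test_that("SKEPTIC recovers a bivariate normal correlation", {
  set.seed(2)
  for (rho in c(0.3, 0.6, 0.9)) {
    n <- 20000
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    est <- skeptic_transform(kendall_tau_b(z1, z2))
    expect_lt(abs(est - rho), 0.02)
  }
})

test_that("polychoric recovers latent correlations and matches the grid oracle", {
  set.seed(3)
  n <- 5000
  z1 <- rnorm(n)
  z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  x <- as.integer(z1 > 0)
  y <- as.integer(z2 > 0)
  est <- polychoric(x, y)
  expect_gt(est, 0.45)
  expect_lt(est, 0.55)
  expect_lt(abs(est - oracle_polychoric_grid(x, y)), 0.011)

  # independence: product-of-margins table
  x0 <- rep(0:2, each = 200)
  y0 <- rep(rep(0:1, c(2, 1)), 200)
  expect_lt(abs(polychoric(x0, y0)), 0.02)

  # multi-level case against the oracle
  x3 <- cut(z1, c(-Inf, -0.5, 0.5, Inf), labels = FALSE) - 1
  y3 <- cut(z2, c(-Inf, -0.8, 0, 0.8, Inf), labels = FALSE) - 1
  expect_lt(abs(polychoric(x3, y3) - oracle_polychoric_grid(x3, y3)), 0.011)
  expect_error(polychoric(rep(1, 10), rep(0:1, 5)), "categories")
})

test_that("polyserial behaves on strong, null and oracle cases", {
  set.seed(4)
  n <- 5000
  x <- rnorm(n)
  y <- as.integer(x > median(x))     # latent rho = 1
  expect_gte(polyserial(x, y), 0.95)
  y0 <- sample(0:2, n, TRUE)
  expect_lte(abs(polyserial(x, y0)), 0.05)

  # grid oracle on the same likelihood
  z2 <- 0.6 * x + 0.8 * rnorm(n)
  y2 <- cut(z2, c(-Inf, -0.5, 0.5, Inf), labels = FALSE) - 1
  grid <- seq(-0.99, 0.99, by = 0.01)
  tau <- qnorm(cumsum(table(y2)) / n)[1:2]
  zst <- (x - mean(x)) / sd(x)
  cuts <- c(-Inf, tau, Inf)
  ll <- vapply(grid, function(r) {
    s <- sqrt(1 - r^2)
    sum(log(pmax(pnorm((cuts[y2 + 2] - r * zst) / s) -
                   pnorm((cuts[y2 + 1] - r * zst) / s), 1e-300)))
  }, numeric(1))
  expect_lt(abs(polyserial(x, y2) - grid[which.max(ll)]), 0.011)
})

test_that("nearest_pd repairs indefinite matrices and preserves PD input", {
  expect_equal(nearest_pd(diag(3)), diag(3), ignore_attr = TRUE)
  expect_false(attr(nearest_pd(diag(3)), "pd_adjusted"))
  R <- matrix(0.9, 3, 3)
  R[1, 2] <- R[2, 1] <- -0.9
  diag(R) <- 1
  out <- nearest_pd(R)
  expect_true(attr(out, "pd_adjusted"))
  expect_gte(min(eigen(out, TRUE, TRUE)$values), 1e-8 - 1e-12)
  expect_equal(unname(diag(out)), rep(1, 3))
  good <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_lt(max(abs(nearest_pd(good) - good)), 1e-12)
  expect_error(nearest_pd(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("mixed_matrix dispatches by kind and returns PD matrices", {
  set.seed(5)
  n <- 120
  z <- matrix(rnorm(n * 4), n)
  X <- cbind(c1 = z[, 1], c2 = z[, 2],
             o1 = as.numeric(cut(z[, 3], c(-Inf, -0.5, 0.5, Inf))) - 1,
             b1 = as.numeric(z[, 4] > 0))
  sch <- var_schema(colnames(X), c("continuous", "continuous", "ordinal",
                                   "binary"), levels = c(NA, NA, 3, 2))
  tab <- response_table(X, sch)
  res <- mixed_matrix(tab, "auto_mixed")
  mm <- res$method_map
  expect_identical(mm["c1", "c2"], "pearson")
  expect_identical(mm["o1", "b1"], "polychoric")
  expect_identical(mm["c1", "o1"], "polyserial")
  expect_gte(min(eigen(res$R, TRUE, TRUE)$values), 1e-9)

  allc <- response_table(z, var_schema(paste0("v", 1:4), "continuous"))
  expect_true(all(mixed_matrix(allc, "auto_mixed")$method_map[
    upper.tri(diag(4))] == "pearson"))

  res2 <- mixed_matrix(tab, "skeptic")
  expect_true(all(res2$method_map == "skeptic"))
  expect_equal(unname(diag(res2$R)), rep(1, 4))
  expect_error(mixed_matrix(response_table(
    cbind(a = c(NA, 1, 2), b = c(0, 1, 2)),
    var_schema(c("a", "b"), "ordinal", levels = 3))), "impute")
})

test_that("skeptic matrices are accurate on multivariate normal data", {
  set.seed(6)
  p <- 5
  A <- matrix(rnorm(p * p), p)
  R <- cov2cor(crossprod(A) + p * diag(p))
  Z <- matrix(rnorm(5000 * p), ncol = p) %*% chol(R)
  tab <- response_table(Z, var_schema(paste0("v", 1:p), "continuous"))
  expect_lt(max(abs(mixed_matrix(tab, "skeptic")$R - R)), 0.05)
})
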