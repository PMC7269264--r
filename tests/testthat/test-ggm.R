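test_that("lambda_path spans max off-diagonal down to the min ratio", {
  R <- matrix(c(1, 0.8, 0.8, 1), 2)
  lp <- lambda_path(R, n_lambda = 100)
  expect_equal(lp[1], 0.8)
  expect_equal(lp[100], 0.008)
  lp3 <- lambda_path(R, n_lambda = 3)
  expect_length(lp3, 3)
  expect_equal(diff(log(lp3)), rep(diff(log(lp3))[1], 2))
  expect_warning(lambda_path(diag(3)), "degenerate")
})

test_that("glasso closed forms hold", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(unclass(glasso_fit(R, 0)),
               matrix(c(4, -2, -2, 4) / 3, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # lambda above the largest off-diagonal screens everything out
  K <- glasso_fit(R, 0.5)
  expect_equal(unclass(K), diag(2), tolerance = 1e-6, ignore_attr = TRUE)
  set.seed(10)
  A <- matrix(rnorm(36), 6)
  R6 <- cov2cor(crossprod(A) + 6 * diag(6))
  K6 <- glasso_fit(R6, max(abs(R6[upper.tri(R6)])) + 1e-6)
  expect_lt(max(abs(K6[upper.tri(K6)])), 1e-10)
})

test_that("glasso solution matches an independent ADMM oracle", {
  set.seed(11)
  for (rep in 1:3) {
    A <- matrix(rnorm(25), 5)
    R <- cov2cor(crossprod(A) + 5 * diag(5))
    lam <- c(0.05, 0.1, 0.3)[rep]
    K <- glasso_fit(R, lam)
    K_admm <- oracle_glasso_admm(R, lam)
    expect_lt(abs(glasso_objective(K, R, lam) -
                    glasso_objective(K_admm, R, lam)), 1e-5)
    expect_lte(attr(K, "kkt"), 1e-4)
  }
})

test_that("EBIC formula evaluates exactly", {
  expect_equal(ebic_score(diag(2), diag(2), n = 100, gamma = 0.5), 200)
  # gamma = 0 reduces to BIC exactly
  K <- matrix(c(1.2, -0.3, -0.3, 1.1), 2)
  R <- matrix(c(1, 0.4, 0.4, 1), 2)
  ll <- determinant(K, TRUE)$modulus[1] - sum(R * K)
  expect_equal(ebic_score(K, R, 50, 0), -50 * ll + 1 * log(50))
  # hand evaluation at gamma = 0.5
  expect_equal(ebic_score(K, R, 50, 0.5),
               -50 * ll + log(50) + 4 * 0.5 * log(2), tolerance = 1e-10)
  expect_error(ebic_score(matrix(c(1, 2, 2, 1), 2), R, 50, 0.5),
               "positive definite")
})

test_that("precision_to_partials equals conditional-covariance oracle", {
  expect_equal(precision_to_partials(diag(3)), matrix(0, 3, 3))
  K2 <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_partials(K2)[1, 2], 0.5)
  set.seed(12)
  A <- matrix(rnorm(49), 7)
  K <- crossprod(A) + 7 * diag(7)
  W <- precision_to_partials(K)
  S <- solve(K)
  for (pair in list(c(1, 2), c(3, 6), c(4, 7))) {
    i <- pair[1]; j <- pair[2]
    rest <- setdiff(1:7, pair)
    Sc <- S[pair, pair] - S[pair, rest] %*% solve(S[rest, rest],
                                                  S[rest, pair])
    expect_equal(W[i, j], Sc[1, 2] / sqrt(Sc[1, 1] * Sc[2, 2]),
                 tolerance = 1e-8)
  }
  expect_error(precision_to_partials(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("EBIC selection picks the path minimum and is monotone in gamma", {
  tab <- sample_responses(small_spec(n = 400, seed = 14))
  R <- mixed_matrix(tab, "skeptic")$R
  fit <- estimate_network(R, n = 400)
  expect_equal(fit$ebic_value, min(fit$path$ebic))
  fit0 <- estimate_network(R, n = 400, gamma = 0)
  fit1 <- estimate_network(R, n = 400, gamma = 1)
  expect_lte(fit1$edge_count, fit0$edge_count)
  # edge count non-increasing in gamma along the whole path by construction
  expect_true(all(fit$path$kkt <= 1e-4))
})

test_that("lambda -> 0 limit reproduces unregularized partials", {
  set.seed(15)
  A <- matrix(rnorm(36), 6)
  R <- cov2cor(crossprod(A) + 8 * diag(6))
  fit <- estimate_network(R, n = 10000, n_lambda = 60,
                          lambda_min_ratio = 1e-6)
  W0 <- precision_to_partials(solve(R))
  lastK <- glasso_fit(R, lambda_path(R, 60, 1e-6)[60])
  expect_lt(max(abs(precision_to_partials(lastK) - W0)), 1e-3)
})

test_that("true edges are recovered and empty networks stay empty", {
  # strong within-domain signal at study scale
  tab <- sample_responses(synthetic_spec(n = 2000, seed = 16,
                                         missing_rate = 0))
  truth <- attr(tab, "truth")
  fit <- panet(tab)
  strong <- which(truth >= 0.5 & upper.tri(truth), arr.ind = TRUE)
  expect_true(all(abs(fit$W[strong]) > 0))

  # independent data: expect (nearly) no edges
  set.seed(17)
  emp <- 0L
  for (s in 1:10) {
    Z <- matrix(rnorm(1000 * 10), ncol = 10)
    R <- cor(Z)
    f <- estimate_network(R, n = 1000)
    emp <- emp + (f$edge_count <= 1)
  }
  expect_gte(emp, 9)
})
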