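test_that("build_precision reproduces requested partials exactly", {
  # closed form: 2 variables, partial 0.5
  sp2 <- synthetic_spec(n = 10, p_items = 2, domains = list(1:2),
                        within_domain_partial = 0.5,
                        cross_links = data.frame(i = integer(),
                                                 j = integer(),
                                                 partial = numeric()),
                        item_levels = 2, thresholds = 0, missing_rate = 0)
  K <- build_precision(sp2)
  expect_equal(unclass(K)[1:2, 1:2], matrix(c(1, -0.5, -0.5, 1), 2),
               ignore_attr = TRUE)

  # no links -> identity
  sp0 <- synthetic_spec(n = 10, p_items = 3, domains = list(1, 2, 3),
                        within_domain_partial = numeric(3),
                        cross_links = data.frame(i = integer(),
                                                 j = integer(),
                                                 partial = numeric()),
                        missing_rate = 0, item_levels = 2, thresholds = 0)
  expect_equal(unclass(build_precision(sp0)), diag(3), ignore_attr = TRUE)

  # default 14-item design: PD, and realized partials match to 1e-8
  K14 <- build_precision(synthetic_spec())
  expect_gt(min(eigen(K14, TRUE, TRUE)$values), 0)
  P <- attr(K14, "partials")
  d <- 1 / sqrt(diag(K14))
  realized <- -(d * unclass(K14) * rep(d, each = nrow(K14)))
  diag(realized) <- 0
  expect_lt(max(abs(realized - P)), 1e-8)
  # unrequested pairs have partial exactly 0
  expect_true(all(realized[P == 0] == 0))
})

test_that("incompatible partials are rejected with advice", {
  sp <- synthetic_spec(n = 10, p_items = 3, domains = list(1:3),
                       within_domain_partial = 0.9, missing_rate = 0,
                       cross_links = data.frame(i = integer(),
                                                j = integer(),
                                                partial = numeric()))
  expect_error(build_precision(sp), "weaker")
})

test_that("sampling is deterministic and respects the missing rate", {
  sp <- small_spec(n = 100, seed = 11, missing_rate = 0.05)
  t1 <- sample_responses(sp)
  t2 <- sample_responses(sp)
  expect_identical(t1$values, t2$values)
  expect_identical(t1$missing, t2$missing)
  expect_gt(sum(t1$missing), 0)

  t3 <- sample_responses(small_spec(n = 100, seed = 11, missing_rate = 0))
  expect_false(any(t3$missing))
})

test_that("discretization matches normal-CDF category frequencies", {
  cuts <- c(-1.5, -0.5, 0.5, 1.5)
  sp <- synthetic_spec(n = 50000, p_items = 2, domains = list(1:2),
                       within_domain_partial = 0.3, thresholds = cuts,
                       cross_links = data.frame(i = integer(),
                                                j = integer(),
                                                partial = numeric()),
                       missing_rate = 0, seed = 5)
  tab <- sample_responses(sp)
  expected <- diff(c(0, pnorm(cuts), 1))
  for (j in 1:2) {
    freq <- tabulate(tab$values[, j] + 1, 5) / sp$n
    expect_lt(max(abs(freq - expected)), 0.01)
  }
})

test_that("latent partial correlations are recoverable at large n", {
  # continuous (latent) view: covariates only, no discretization of items
  sp <- synthetic_spec(n = 10000, p_items = 6,
                       domains = list(1:2, 3:4, 5:6),
                       within_domain_partial = c(0.6, 0.5, 0.4),
                       cross_links = data.frame(i = 2, j = 5,
                                                partial = -0.2),
                       missing_rate = 0, seed = 21)
  K <- build_precision(sp)
  set.seed(21)
  Z <- matrix(rnorm(sp$n * 6), ncol = 6) %*% chol(panet:::spec_sigma(K))
  Khat <- solve(cor(Z))
  d <- 1 / sqrt(diag(Khat))
  Phat <- -(d * Khat * rep(d, each = 6))
  diag(Phat) <- 0
  expect_lt(max(abs(Phat - attr(K, "partials"))), 0.05)
})

test_that("SKEPTIC on ordinal codes approaches the generating correlations", {
  sp <- small_spec(n = 4000, seed = 31)
  tab <- sample_responses(sp)
  truthK <- build_precision(sp)
  sigma <- panet:::spec_sigma(truthK)
  R <- mixed_matrix(tab, "skeptic")$R
  expect_lt(max(abs(R - sigma)), 0.06)
})

test_that("two-group designs honour their deltas", {
  sp <- small_spec(n = 200, seed = 3)
  sp$group_deltas <- data.frame(i = 1, j = 2, delta = -0.5)
  gr <- make_groups(sp)
  expect_equal(attr(gr$B, "truth")[1, 2], 0)   # 0.5 - 0.5
  expect_equal(attr(gr$A, "truth")[1, 2], 0.5)
  expect_identical(gr$A$n, gr$B$n)

  # empty deltas: identical distributions (same truth)
  sp$group_deltas <- data.frame(i = integer(), j = integer(),
                                delta = numeric())
  gr0 <- make_groups(sp)
  expect_identical(attr(gr0$A, "truth"), attr(gr0$B, "truth"))

  sp$group_deltas <- NULL
  expect_error(make_groups(sp), "group_deltas")
})

test_that("a delta on a null pair shifts sample partials in its direction", {
  sp <- small_spec(n = 5000, seed = 13)
  sp$group_deltas <- data.frame(i = 1, j = 6, delta = 0.3)
  gr <- make_groups(sp)
  pcor_hat <- function(tab) {
    Kh <- solve(mixed_matrix(tab, "skeptic")$R)
    d <- 1 / sqrt(diag(Kh))
    -(d * Kh * rep(d, each = 6))
  }
  pa <- pcor_hat(gr$A)[1, 6]
  pb <- pcor_hat(gr$B)[1, 6]
  expect_gt(pb - pa, 0.15)
})
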