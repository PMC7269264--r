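test_that("strength, distances, closeness, betweenness on hand cases", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- -0.2
  expect_equal(unname(strength(W, 1)), 0.5)
  expect_equal(unname(strength(W)[2]), 0.3)

  # chain A-B (0.5), B-C (0.5): d(A, C) = 4
  Wc <- matrix(0, 3, 3)
  Wc[1, 2] <- Wc[2, 1] <- 0.5
  Wc[2, 3] <- Wc[3, 2] <- 0.5
  D <- shortest_distances(Wc)
  expect_equal(D[1, 3], 4)
  expect_equal(unname(betweenness(Wc)), c(0, 1, 0))

  # direct edge 0.9 beats the two-hop detour
  Wd <- Wc
  Wd[1, 3] <- Wd[3, 1] <- 0.9
  expect_equal(shortest_distances(Wd)[1, 3], 1 / 0.9)

  # equal-weight triangle: no intermediates
  Wt <- matrix(0.4, 3, 3); diag(Wt) <- 0
  expect_equal(unname(betweenness(Wt)), c(0, 0, 0))

  # 3-leaf star with weights 0.5: center 1/6, leaves 1/10
  Ws <- matrix(0, 4, 4)
  Ws[1, 2:4] <- Ws[2:4, 1] <- 0.5
  cl <- closeness(Ws)
  expect_equal(unname(cl[1]), 1 / 6)
  expect_equal(unname(cl[2]), 1 / 10)

  # isolated node
  Wi <- matrix(0, 3, 3)
  Wi[1, 2] <- Wi[2, 1] <- 0.5
  expect_equal(unname(closeness(Wi)[3]), 0)
  expect_equal(unname(strength(Wi)[3]), 0)
})

test_that("z-standardisation is exact and flags degeneracy", {
  expect_equal(unname(z_standardise(1:3)), c(-1, 0, 1))
  z <- z_standardise(rep(2, 5))
  expect_true(all(z == 0))
  expect_true(attr(z, "degenerate"))
  set.seed(20)
  zz <- z_standardise(rnorm(50))
  expect_equal(mean(zz), 0)
  expect_equal(sd(zz), 1)
})

test_that("clustering coefficients: complete-graph and binary reductions", {
  Wt <- matrix(0.37, 3, 3); diag(Wt) <- 0
  for (m in c("ws", "barrat", "zhang", "onnela"))
    expect_equal(unname(clustering_local(Wt, m)), rep(1, 3), info = m)
  expect_equal(as.numeric(clustering_global_min(Wt)), 1)

  # with 0/1 weights all weighted variants reduce to Watts-Strogatz
  set.seed(21)
  for (rep in 1:10) {
    W01 <- random_graph(6, 0.5, signed = FALSE)
    W01[W01 > 0] <- 1
    ws <- clustering_local(W01, "ws")
    for (m in c("barrat", "zhang", "onnela"))
      expect_equal(clustering_local(W01, m), ws, tolerance = 1e-12)
  }

  # 3-node path: only open triplets
  Wp <- matrix(0, 3, 3)
  Wp[1, 2] <- Wp[2, 1] <- 0.5
  Wp[2, 3] <- Wp[3, 2] <- 0.4
  expect_equal(as.numeric(clustering_global_min(Wp)), 0)
})

test_that("global min-method matches hand enumeration on the pendant case", {
  # triangle A,B,C (0.6, 0.4, 0.2) plus pendant D-A (0.8)
  W <- matrix(0, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2))
  W["A", "B"] <- W["B", "A"] <- 0.6
  W["B", "C"] <- W["C", "B"] <- 0.4
  W["A", "C"] <- W["C", "A"] <- 0.2
  W["A", "D"] <- W["D", "A"] <- 0.8
  # closed triplets: center A (.2), B (.4), C (.2); open: A pairs with D
  closed <- 0.2 + 0.4 + 0.2
  open_extra <- min(0.6, 0.8) + min(0.2, 0.8)
  expect_equal(as.numeric(clustering_global_min(W)),
               closed / (closed + open_extra))
  expect_equal(as.numeric(clustering_global_min(W)), oracle_global_min(W))
})

test_that("all metrics agree with brute-force oracles on random graphs", {
  set.seed(22)
  for (rep in 1:25) {
    W <- random_graph(sample(4:8, 1), runif(1, 0.25, 0.6))
    o <- oracle_paths(W)
    expect_lt(max(abs(shortest_distances(W) - o$D), na.rm = TRUE), 1e-10)
    expect_lt(max(abs(betweenness(W) - o$betweenness)), 1e-10)
    expect_lt(max(abs(closeness(W) - oracle_closeness(W))), 1e-10)
    expect_lt(max(abs(strength(W) - oracle_strength(W))), 1e-10)
    for (m in c("ws", "barrat", "zhang", "onnela"))
      expect_lt(max(abs(clustering_local(W, m) -
                          oracle_clustering(W, m))), 1e-12)
    expect_lt(abs(as.numeric(clustering_global_min(W)) -
                    oracle_global_min(W)), 1e-12)
  }
})

test_that("metrics are permutation-equivariant and scale as documented", {
  set.seed(23)
  W <- random_graph(7, 0.45)
  perm <- sample(7)
  Wp <- W[perm, perm]
  expect_equal(unname(strength(Wp)), unname(strength(W)[perm]))
  expect_equal(unname(betweenness(Wp)), unname(betweenness(W)[perm]))
  expect_equal(unname(closeness(Wp)), unname(closeness(W)[perm]))
  for (m in c("ws", "barrat", "zhang", "onnela"))
    expect_equal(unname(clustering_local(Wp, m)),
                 unname(clustering_local(W, m)[perm]), tolerance = 1e-12)

  c_scale <- 0.37
  Ws <- W * c_scale
  expect_equal(strength(Ws), strength(W) * c_scale)
  expect_equal(betweenness(Ws), betweenness(W))
  for (m in c("ws", "zhang", "onnela"))
    expect_equal(clustering_local(Ws, m), clustering_local(W, m),
                 tolerance = 1e-12)
  expect_equal(as.numeric(clustering_global_min(Ws)),
               as.numeric(clustering_global_min(W)), tolerance = 1e-12)
})

test_that("node_metrics assembles a coherent table", {
  set.seed(24)
  W <- random_graph(6, 0.5)
  mt <- node_metrics(W)
  expect_equal(nrow(mt), 6)
  expect_equal(mean(mt$strength_z), 0, tolerance = 1e-12)
  expect_equal(sd(mt$strength_z), 1, tolerance = 1e-12)
  expect_true(all(mt[, grep("clustering", names(mt))] >= 0 &
                    mt[, grep("clustering", names(mt))] <= 1))
  expect_true(is.numeric(attr(mt, "global_clustering_min")))
})
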