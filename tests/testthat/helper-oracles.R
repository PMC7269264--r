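# Brute-force oracles, deliberately naive and independent of the package's
# algorithmic choices.

# random symmetric weighted graph with signed weights
random_graph <- function(p, edge_prob = 0.35, signed = TRUE) {
  W <- matrix(0, p, p)
  for (j in seq_len(p)) for (i in seq_len(p)) if (i < j) {
    if (runif(1) < edge_prob) {
      w <- runif(1, 0.05, 0.95) * (if (signed && runif(1) < 0.3) -1 else 1)
      W[i, j] <- W[j, i] <- w
    }
  }
  colnames(W) <- rownames(W) <- paste0("n", seq_len(p))
  W
}

# exhaustive simple-path enumeration: distances, shortest-path counts and
# betweenness credit
oracle_paths <- function(W) {
  p <- nrow(W)
  A <- abs(W)
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  betw <- numeric(p)
  for (s in seq_len(p - 1)) for (t in seq((s + 1), p)) {
    paths <- list()
    dfs <- function(v, visited, len, nodes) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(len = len, nodes = nodes)
        return(invisible())
      }
      for (u in which(A[v, ] > 0)) if (!visited[u]) {
        visited[u] <- TRUE
        dfs(u, visited, len + 1 / A[v, u], c(nodes, u))
        visited[u] <- FALSE
      }
    }
    visited <- rep(FALSE, p)
    visited[s] <- TRUE
    dfs(s, visited, 0, s)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    dmin <- min(lens)
    D[s, t] <- D[t, s] <- dmin
    short <- paths[lens <= dmin + 1e-12]
    for (v in seq_len(p)) {
      if (v == s || v == t) next
      through <- sum(vapply(short, function(pt) v %in% pt$nodes,
                            logical(1)))
      betw[v] <- betw[v] + through / length(short)
    }
  }
  list(D = D, betweenness = betw)
}

oracle_closeness <- function(W) {
  D <- oracle_paths(W)$D
  diag(D) <- NA
  apply(D, 1, function(d) {
    d <- d[is.finite(d) & !is.na(d)]
    if (!length(d)) 0 else 1 / sum(d)
  })
}

oracle_strength <- function(W) {
  p <- nrow(W)
  out <- numeric(p)
  for (i in seq_len(p)) for (j in seq_len(p)) if (j != i)
    out[i] <- out[i] + abs(W[i, j])
  out
}

# direct triple-loop local clustering, straight from the formulas
oracle_clustering <- function(W, method) {
  Wa <- abs(W)
  A <- (Wa > 0) * 1
  p <- nrow(W)
  k <- rowSums(A)
  s <- rowSums(Wa)
  mx <- max(Wa)
  Wh <- if (mx > 0) Wa / mx else Wa
  out <- numeric(p)
  for (i in seq_len(p)) {
    if (k[i] < 2) next
    num <- 0
    for (j in seq_len(p)) for (h in seq_len(p)) {
      if (j == i || h == i || j == h) next
      num <- num + switch(method,
        ws = A[i, j] * A[i, h] * A[j, h],
        barrat = ((Wa[i, j] + Wa[i, h]) / 2) * A[i, j] * A[i, h] * A[j, h],
        onnela = (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3),
        zhang = Wh[i, j] * Wh[j, h] * Wh[h, i])
    }
    den <- switch(method,
      ws = k[i] * (k[i] - 1),
      barrat = s[i] * (k[i] - 1),
      onnela = k[i] * (k[i] - 1),
      zhang = sum(Wh[i, ])^2 - sum(Wh[i, ]^2))
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

oracle_global_min <- function(W) {
  Wa <- abs(W)
  A <- Wa > 0
  p <- nrow(W)
  tot <- 0
  clo <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) for (h in seq_len(p)) {
    if (j >= h || j == i || h == i) next
    if (A[i, j] && A[i, h]) {
      v <- min(Wa[i, j], Wa[i, h])
      tot <- tot + v
      if (A[j, h]) clo <- clo + v
    }
  }
  if (tot == 0) 0 else clo / tot
}

# ADMM solver for the graphical lasso (independent of coordinate descent)
oracle_glasso_admm <- function(S, lambda, rho = 1, iters = 5000) {
  p <- nrow(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (it in seq_len(iters)) {
    e <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    xi <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    X <- e$vectors %*% (xi * t(e$vectors))
    Znew <- X + U
    Zs <- soft(Znew, lambda / rho)
    diag(Zs) <- diag(Znew)           # diagonal unpenalized
    done <- max(abs(X - Zs)) < 1e-9 && max(abs(Zs - Z)) < 1e-9
    Z <- Zs
    U <- U + X - Z
    if (done) break
  }
  Z
}

glasso_objective <- function(K, S, lambda) {
  determinant(K, logarithm = TRUE)$modulus[1] - sum(S * K) -
    lambda * sum(abs(K[upper.tri(K) | lower.tri(K)]))
}

# polychoric grid-search oracle: cell probabilities straight from
# rectangle integrals of the bivariate normal
oracle_polychoric_grid <- function(x, y, step = 0.01) {
  counts <- table(factor(x), factor(y))
  qa <- qnorm(cumsum(rowSums(counts)) / sum(counts))
  qb <- qnorm(cumsum(colSums(counts)) / sum(counts))
  a <- c(-Inf, head(qa, -1), Inf)
  b <- c(-Inf, head(qb, -1), Inf)
  grid <- seq(-0.99, 0.99, by = step)
  ll <- vapply(grid, function(r) {
    corr <- matrix(c(1, r, r, 1), 2)
    tot <- 0
    for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
      if (counts[i, j] == 0) next
      pr <- mvtnorm::pmvnorm(lower = c(a[i], b[j]),
                             upper = c(a[i + 1], b[j + 1]), corr = corr)[1]
      tot <- tot + counts[i, j] * log(max(pr, 1e-300))
    }
    tot
  }, numeric(1))
  grid[which.max(ll)]
}

# small complete synthetic design shared across tests
small_spec <- function(n = 300, seed = 1, missing_rate = 0, ...) {
  synthetic_spec(n = n, p_items = 6, domains = list(1:2, 3:4, 5:6),
                 within_domain_partial = c(0.5, 0.45, 0.4),
                 cross_links = data.frame(i = 2, j = 3, partial = 0.2),
                 missing_rate = missing_rate, seed = seed, ...)
}
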