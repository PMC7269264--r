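#' Specify a synthetic questionnaire design with known network structure
#'
#' The generator works in partial-correlation space: you request the partial
#' correlations you want (within-domain item pairs, cross-links, covariate
#' links), the corresponding unit-diagonal precision matrix is formed, and
#' latent data are drawn from the implied Gaussian. Ordinal and binary
#' columns are then discretized at fixed thresholds and an MCAR mask is
#' applied. Because the ground truth is stated in the same space every
#' downstream estimand lives in, recovery checks are direct.
#'
#' The defaults emulate a 14-item oral-health-literacy questionnaire: 7
#' two-item domains with strong within-domain partials spanning 0.54-0.89,
#' a few weaker cross-domain links (including two negative ones), 5-level
#' items discretized at thresholds giving no category under 5%, and 1.1%
#' item-level MCAR missingness.
#'
#' @param n sample size.
#' @param p_items number of questionnaire items.
#' @param domains list of item-index vectors; default 7 consecutive pairs.
#' @param within_domain_partial per-domain target partial correlation;
#'   default spans `[0.54, 0.89]`.
#' @param cross_links data frame `(i, j, partial)` of extra item links.
#' @param covariates list of covariate descriptors, each a list with
#'   elements `name`, `kind` (`"continuous"`, `"ordinal"`, `"binary"`),
#'   `levels` (ordinal only), `links` (node indices into the full variable
#'   vector) and `partial` (matching values).
#' @param item_levels ordered category count for items (default 5).
#' @param thresholds latent cut points for ordinal items (length
#'   `item_levels - 1`).
#' @param missing_rate MCAR cell probability in `[0, 1)`.
#' @param seed integer seed governing latent draws then the MCAR mask.
#' @param group_deltas optional data frame `(i, j, delta)` added to the
#'   requested partials to define a second population for two-group designs.
#' @return An object of class `synthetic_spec`.
#' @seealso [build_precision()], [sample_responses()], [make_groups()],
#'   [study_spec()]
#' @export
synthetic_spec <- function(n = 400,
                           p_items = 14,
                           domains = NULL,
                           within_domain_partial = NULL,
                           cross_links = NULL,
                           covariates = list(),
                           item_levels = 5,
                           thresholds = c(-1.2, -0.4, 0.4, 1.2),
                           missing_rate = 0.011,
                           seed = 1,
                           group_deltas = NULL) {
  if (is.null(domains))
    domains <- split(seq_len(p_items),
                     rep(seq_len(ceiling(p_items / 2)), each = 2,
                         length.out = p_items))
  if (is.null(within_domain_partial))
    within_domain_partial <- seq(0.54, 0.89, length.out = length(domains))
  within_domain_partial <- rep_len(within_domain_partial, length(domains))
  if (is.null(cross_links))
    cross_links <- default_cross_links(p_items)
  stopifnot(missing_rate >= 0, missing_rate < 1, n >= 2,
            length(thresholds) == item_levels - 1,
            all(diff(thresholds) > 0))
  if (any(abs(within_domain_partial) >= 1))
    stop("partial-correlation targets must lie in (-1, 1)")
  out <- list(n = as.integer(n), p_items = as.integer(p_items),
              domains = domains,
              within_domain_partial = within_domain_partial,
              cross_links = cross_links, covariates = covariates,
              item_levels = as.integer(item_levels),
              thresholds = thresholds, missing_rate = missing_rate,
              seed = as.integer(seed), group_deltas = group_deltas)
  class(out) <- "synthetic_spec"
  out
}

default_cross_links <- function(p_items) {
  if (p_items < 8) return(data.frame(i = integer(), j = integer(),
                                     partial = numeric()))
  data.frame(i = c(2, 4, 6, 1, 2),
             j = c(3, 5, 9, 7, 8),
             partial = c(0.12, 0.10, 0.10, -0.15, -0.12))
}

#' Default study-scale design: 14 items plus 10 mixed covariates
#'
#' Adds to the item block 4 continuous psychosocial totals, 4 five-level
#' ordinal covariates and 2 binary covariates, each with one or two partial
#' links into the network, and a two-group contrast (`group_deltas`) that
#' weakens one within-domain edge and adds one new cross link.
#'
#' @inheritParams synthetic_spec
#' @param ... passed through to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
study_spec <- function(n = 400, seed = 1, ...) {
  covs <- list(
    list(name = "impact_total",  kind = "continuous",
         links = c(1, 5),  partial = c(-0.18, -0.12)),
    list(name = "stress",        kind = "continuous",
         links = c(15),    partial = c(0.25)),
    list(name = "personal_control", kind = "continuous",
         links = c(3, 16), partial = c(0.12, -0.15)),
    list(name = "self_efficacy", kind = "continuous",
         links = c(9, 17), partial = c(0.15, 0.12)),
    list(name = "self_rated_oh", kind = "ordinal", levels = 5,
         links = c(15),    partial = c(-0.18)),
    list(name = "education",     kind = "ordinal", levels = 5,
         links = c(7),     partial = c(0.15)),
    list(name = "income",        kind = "ordinal", levels = 5,
         links = c(13, 20), partial = c(0.15, 0.12)),
    list(name = "age_group",     kind = "ordinal", levels = 5,
         links = c(11),    partial = c(0.10)),
    list(name = "sex",           kind = "binary",
         links = c(2),     partial = c(0.10)),
    list(name = "insurance",     kind = "binary",
         links = c(13, 21), partial = c(0.12, 0.10)))
  synthetic_spec(n = n, seed = seed, covariates = covs,
                 group_deltas = data.frame(i = c(1, 3),
                                           j = c(2, 5),
                                           delta = c(-0.30, 0.25)),
                 ...)
}

spec_p <- function(spec) spec$p_items + length(spec$covariates)

spec_schema <- function(spec) {
  nm_items <- sprintf("q%02d", seq_len(spec$p_items))
  kinds <- rep("ordinal", spec$p_items)
  levels <- rep(spec$item_levels, spec$p_items)
  roles <- rep("item", spec$p_items)
  for (cv in spec$covariates) {
    nm_items <- c(nm_items, cv$name)
    kinds <- c(kinds, cv$kind)
    levels <- c(levels, if (identical(cv$kind, "ordinal")) cv$levels
                        else NA_integer_)
    roles <- c(roles, "covariate")
  }
  var_schema(nm_items, kinds, levels = levels, role = roles)
}

# requested partial-correlation matrix (zero where unrequested)
spec_partials <- function(spec, deltas = NULL) {
  p <- spec_p(spec)
  P <- matrix(0, p, p)
  for (d in seq_along(spec$domains)) {
    blk <- spec$domains[[d]]
    for (a in seq_along(blk)) for (b in seq_along(blk)) if (a < b) {
      P[blk[a], blk[b]] <- P[blk[b], blk[a]] <-
        spec$within_domain_partial[d]
    }
  }
  cl <- spec$cross_links
  if (!is.null(cl) && nrow(cl))
    for (r in seq_len(nrow(cl))) {
      P[cl$i[r], cl$j[r]] <- P[cl$j[r], cl$i[r]] <- cl$partial[r]
    }
  for (k in seq_along(spec$covariates)) {
    cv <- spec$covariates[[k]]
    idx <- spec$p_items + k
    for (t in seq_along(cv$links)) {
      P[idx, cv$links[t]] <- P[cv$links[t], idx] <- cv$partial[t]
    }
  }
  if (!is.null(deltas) && nrow(deltas))
    for (r in seq_len(nrow(deltas))) {
      P[deltas$i[r], deltas$j[r]] <- P[deltas$j[r], deltas$i[r]] <-
        P[deltas$i[r], deltas$j[r]] + deltas$delta[r]
    }
  if (any(abs(P) >= 1)) stop("partial-correlation targets must lie in (-1, 1)")
  P
}

#' Ground-truth precision matrix of a synthetic design
#'
#' Builds the unit-diagonal precision matrix whose implied partial
#' correlations `-K_ij / sqrt(K_ii K_jj)` equal the requested values exactly
#' and are zero everywhere else. If the requested partials are incompatible
#' with positive definiteness the construction fails with advice to weaken
#' them (no silent repair, which would distort the requested values).
#'
#' @param spec a [synthetic_spec()].
#' @param deltas optional `(i, j, delta)` data frame of partial changes
#'   (used for the second group of a two-group design).
#' @return `p x p` precision matrix with attribute `"partials"` holding the
#'   implied partial-correlation matrix.
#' @export
build_precision <- function(spec, deltas = NULL) {
  P <- spec_partials(spec, deltas)
  K <- -P
  diag(K) <- 1
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stop("requested partial correlations are incompatible with a positive ",
         "definite precision matrix (min eigenvalue ",
         format(min(ev), digits = 3), "); use weaker values")
  attr(K, "partials") <- P
  K
}

# latent correlation matrix implied by the precision (partials invariant
# under the diagonal standardisation)
spec_sigma <- function(K) {
  S <- solve(K)
  d <- 1 / sqrt(diag(S))
  S <- d * S * rep(d, each = nrow(S))
  (S + t(S)) / 2
}

# draw one table from an already-seeded RNG stream
draw_table <- function(spec, K) {
  sigma <- spec_sigma(K)
  schema <- spec_schema(spec)
  p <- spec_p(spec)
  Z <- matrix(stats::rnorm(spec$n * p), spec$n, p) %*% chol(sigma)
  X <- Z
  lv <- schema_levels(schema)
  for (j in seq_len(p)) {
    if (schema$kind[j] == "ordinal") {
      cuts <- if (j <= spec$p_items) spec$thresholds else
        stats::qnorm(seq_len(lv[j] - 1) / lv[j])
      X[, j] <- findInterval(Z[, j], cuts)
    } else if (schema$kind[j] == "binary") {
      X[, j] <- as.numeric(Z[, j] > 0)
    }
  }
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(spec$n * p) < spec$missing_rate, spec$n, p)
    # keep at least two observed values per column so nothing degenerates
    full <- which(colSums(!mask) < 2)
    mask[, full] <- FALSE
    X[mask] <- NA
  }
  colnames(X) <- schema$name
  response_table(X, schema)
}

#' Draw a synthetic response table
#'
#' Latent scores are multivariate normal with the correlation structure
#' implied by [build_precision()]; ordinal and binary columns are
#' discretized at the design thresholds, continuous columns keep their
#' latent values, and an MCAR mask is applied. The RNG stream consumes the
#' latent draws first, then the mask, so a fixed `spec$seed` reproduces the
#' table exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return A [response_table()] with attribute `"truth"`, the ground-truth
#'   partial-correlation matrix.
#' @export
sample_responses <- function(spec) {
  K <- build_precision(spec)
  set.seed(spec$seed)
  tab <- draw_table(spec, K)
  attr(tab, "truth") <- attr(K, "partials")
  tab
}

#' Draw paired tables for a two-group design
#'
#' Group A uses the design's partials as-is; group B rebuilds the precision
#' with `group_deltas` applied. Both share thresholds and sample size, and
#' both are drawn from one seeded stream (A first, then B).
#'
#' @param spec a [synthetic_spec()] with non-`NULL` `group_deltas`.
#' @return list with elements `A` and `B` ([response_table()]s, each with a
#'   `"truth"` attribute).
#' @export
make_groups <- function(spec) {
  if (is.null(spec$group_deltas))
    stop("spec$group_deltas must be set for a two-group design")
  KA <- build_precision(spec)
  KB <- build_precision(spec, deltas = spec$group_deltas)
  set.seed(spec$seed)
  A <- draw_table(spec, KA)
  B <- draw_table(spec, KB)
  attr(A, "truth") <- attr(KA, "partials")
  attr(B, "truth") <- attr(KB, "partials")
  list(A = A, B = B)
}
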