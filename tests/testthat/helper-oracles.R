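# Brute-force reference implementations used as independent oracles.
# These deliberately use plain double loops and explicit formulas so they
# share no code path with the package internals they check.

oracle_neighbor_sets <- function(coords, d, include_center = FALSE) {
  m <- nrow(coords)
  lapply(seq_len(m), function(i) {
    out <- integer(0)
    for (l in seq_len(m)) {
      if (!include_center && l == i) next
      if (sqrt(sum((coords[i, ] - coords[l, ])^2)) < d) out <- c(out, l)
    }
    out
  })
}

oracle_local_means <- function(expr, sets) {
  m <- nrow(expr)
  lm <- matrix(NA_real_, m, ncol(expr))
  for (i in seq_len(m)) {
    s <- sets[[i]]
    for (j in seq_len(ncol(expr))) {
      lm[i, j] <- if (length(s) == 0) expr[i, j] else mean(expr[s, j])
    }
  }
  lm
}

oracle_pop_var <- function(x) sum((x - mean(x))^2) / length(x)

# end-to-end naive BSP scores on already-normalized data (ball-query
# patches, the package default)
oracle_bsp_scores <- function(expr, coords, d1, d2) {
  s1 <- oracle_local_means(expr, oracle_neighbor_sets(coords, d1, TRUE))
  s2 <- oracle_local_means(expr, oracle_neighbor_sets(coords, d2, TRUE))
  v1 <- apply(s1, 2, oracle_pop_var)
  v2 <- apply(s2, 2, oracle_pop_var)
  vraw <- apply(expr, 2, oracle_pop_var)
  w <- vraw / max(vraw)
  ifelse(v1 > 0, w * v2 / v1, 0)
}

# random dataset on uniform coordinates with a mix of smooth and iid genes
random_dataset <- function(m, n, d = 2, seed = 1) {
  withr::with_seed(seed, {
    coords <- matrix(runif(m * d, 0, 5), m, d)
    expr <- matrix(rlnorm(m * n), m, n)
    # a few genes get coordinate-driven structure so scores vary
    for (j in seq_len(min(n, 3))) {
      expr[, j] <- expr[, j] + 2 * sin(coords[, 1]) + coords[, 2]
    }
    list(coords = coords, expr = expr)
  })
}

minmax <- function(x) {
  r <- max(x) - min(x)
  if (r == 0) rep(0, length(x)) else (x - min(x)) / r
}
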