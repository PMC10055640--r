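test_that("radius neighborhoods match hand-computed sets on a line", {
  coords <- cbind(x = c(0, 1, 2), y = c(0, 0, 0))
  # strict neighbor-only variant: hand-derived sets exclude the center
  idx <- build_patch_index(coords, d = 1.5, include_center = FALSE)
  adj <- as.matrix(idx$adj)
  expect_equal(which(adj[1, ] > 0), 2L)
  expect_equal(which(adj[2, ] > 0), c(1L, 3L))
  expect_equal(which(adj[3, ] > 0), 2L)
  expect_equal(unname(idx$patch_sizes), c(1, 2, 1))

  # ball-query default adds the center to each patch
  expect_equal(
    unname(build_patch_index(coords, d = 1.5)$patch_sizes), c(2, 3, 2)
  )

  # D below the minimum pairwise distance: neighbor-only patches empty
  tiny <- build_patch_index(coords, d = 0.5, include_center = FALSE)
  expect_equal(sum(tiny$patch_sizes), 0)
  expect_equal(unname(build_patch_index(coords, d = 0.5)$patch_sizes), c(1, 1, 1))

  # D above the diameter: every neighbor-only patch holds M - 1 spots
  full <- build_patch_index(coords, d = 10, include_center = FALSE)
  expect_equal(unname(full$patch_sizes), c(2, 2, 2))
  expect_equal(unname(build_patch_index(coords, d = 10)$patch_sizes), c(3, 3, 3))

  # strict inequality: a pair exactly at distance D is excluded
  at_d <- build_patch_index(coords, d = 1, include_center = FALSE)
  expect_equal(sum(at_d$patch_sizes), 0)
})

test_that("local means follow the patch-average definition", {
  coords <- cbind(x = c(0, 1, 2), y = c(0, 0, 0))
  expr <- cbind(g = c(0, 1, 0))
  # neighbor-only patches on the line: hand evaluation gives (1, 0, 1)
  idx_nc <- build_patch_index(coords, d = 1.5, include_center = FALSE)
  expect_equal(unname(local_means(expr, idx_nc)[, 1]), c(1, 0, 1))

  # ball-query default: patches {1,2}, {1,2,3}, {2,3}
  idx <- build_patch_index(coords, d = 1.5)
  lm <- local_means(expr, idx)
  expect_equal(unname(lm[, 1]), c(1 / 2, 1 / 3, 1 / 2))
  expect_equal(local_mean_variance(lm)[[1]], oracle_pop_var(c(1 / 2, 1 / 3, 1 / 2)))

  # constant gene: local means all equal the constant
  expect_equal(unname(local_means(cbind(c(3, 3, 3)), idx)[, 1]), c(3, 3, 3))

  # empty neighbor-only patches fall back to the spot's own expression
  empty <- build_patch_index(coords, d = 0.5, include_center = FALSE)
  expect_equal(unname(local_means(expr, empty)[, 1]), c(0, 1, 0))
})

test_that("hand-derived variance of local means", {
  expect_equal(oracle_pop_var(c(1, 0, 1)), 2 / 9)
  lm <- matrix(c(1, 0, 1), 3, 1)
  expect_equal(local_mean_variance(lm)[[1]], 2 / 9)
})

test_that("a radius covering the sample zeroes every local-mean variance", {
  for (seed in 1:5) {
    dat <- random_dataset(30, 8, d = sample(2:3, 1), seed = seed)
    diam <- max(dist(dat$coords))
    idx <- build_patch_index(dat$coords, d = diam * 1.01)
    v <- local_mean_variance(local_means(dat$expr, idx))
    expect_equal(unname(v), rep(0, 8))
  }
})

test_that("patch index and local means agree with the brute-force oracle", {
  for (seed in 1:8) {
    m <- sample(20:150, 1)
    inc <- seed %% 2 == 0
    dat <- random_dataset(m, 5, d = sample(2:3, 1), seed = seed + 100)
    d_rad <- runif(1, 0.3, 3)
    idx <- build_patch_index(dat$coords, d_rad, include_center = inc)
    sets <- oracle_neighbor_sets(dat$coords, d_rad, include_center = inc)
    for (i in seq_len(m)) {
      expect_equal(which(as.matrix(idx$adj)[i, ] > 0), sets[[i]],
        ignore_attr = TRUE
      )
    }
    lm <- local_means(dat$expr, idx)
    expect_equal(unname(lm), oracle_local_means(dat$expr, sets),
      tolerance = 1e-12
    )
    expect_equal(
      unname(local_mean_variance(lm)),
      apply(oracle_local_means(dat$expr, sets), 2, oracle_pop_var),
      tolerance = 1e-12
    )
  }
})

test_that("patch structure is symmetric and monotone in the radius", {
  dat <- random_dataset(80, 1, seed = 5)
  i1 <- build_patch_index(dat$coords, 1, include_center = FALSE)
  i2 <- build_patch_index(dat$coords, 3, include_center = FALSE)
  expect_equal(i1$adj, Matrix::t(i1$adj))
  expect_true(all(Matrix::diag(i1$adj) == 0))
  expect_true(all(Matrix::diag(build_patch_index(dat$coords, 1)$adj) == 1))
  # every neighbor at D1 remains a neighbor at D2 > D1
  expect_true(all((i2$adj - i1$adj) >= 0))
})

test_that("rigid motions of the coordinates leave patches unchanged", {
  dat <- random_dataset(60, 4, seed = 9)
  idx <- build_patch_index(dat$coords, 1.2)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- dat$coords %*% rot + matrix(c(5, -3), 60, 2, byrow = TRUE)
  idx_m <- build_patch_index(moved, 1.2)
  expect_equal(
    as.matrix(idx$adj) > 0, as.matrix(idx_m$adj) > 0,
    ignore_attr = TRUE
  )
})

test_that("big patches smooth more than small patches on pattern-free genes", {
  # on permuted genes the coarse local means average more spots, so their
  # variance is smaller on average across genes
  withr::with_seed(31, {
    coords <- matrix(runif(400, 0, 10), 200, 2) * sqrt(200 / 100)
    expr <- matrix(rlnorm(200 * 120), 200, 120)
  })
  expr <- apply(expr, 2, minmax)
  i1 <- build_patch_index(coords, 1)
  i2 <- build_patch_index(coords, 3)
  v1 <- local_mean_variance(local_means(expr, i1))
  v2 <- local_mean_variance(local_means(expr, i2))
  expect_lt(mean(v2), mean(v1))
})
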