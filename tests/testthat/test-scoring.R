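test_that("gene weights normalize per-gene variance to the panel maximum", {
  expect_equal(gene_weights(cbind(c(0, 1, 0))), 1)
  # variances 1 and 4 -> weights 0.25 and 1
  x <- cbind(a = c(-1, 1), b = c(-2, 2))
  expect_equal(unname(gene_weights(x)), c(0.25, 1))
  y <- cbind(a = c(0, 1, 0), b = c(2, 2, 2))
  expect_equal(unname(gene_weights(y))[2], 0)
  expect_warning(w0 <- gene_weights(cbind(c(1, 1), c(2, 2))), "constant")
  expect_equal(unname(w0), c(0, 0))
})

test_that("BSP scores follow the weighted variance ratio on hand cases", {
  coords <- cbind(x = c(0, 1, 2), y = c(0, 0, 0))
  expr <- cbind(g = c(0, 1, 0))
  ds <- spatial_dataset(expr, coords)
  ds$expr_normalized <- TRUE # already in [0,1]
  ds$coords_normalized <- TRUE # keep the hand geometry
  tab <- bsp_scores(ds, bsp_config(d1 = 1.5, d2 = 2.5))
  # small patches {1,2}, {1,2,3}, {2,3}: local means (1/2, 1/3, 1/2)
  expect_equal(tab$sigma_d1, oracle_pop_var(c(1 / 2, 1 / 3, 1 / 2)))
  expect_equal(tab$sigma_d1, 1 / 162)
  expect_equal(tab$sigma_d2, 0) # big patch holds all spots
  expect_equal(tab$weight, 1)
  expect_equal(tab$score, 0)

  # constant gene: zero weight, zero variances, score 0
  ds2 <- spatial_dataset(cbind(c(5, 5, 5), c(0, 1, 0)), coords)
  ds2$expr_normalized <- TRUE
  ds2$coords_normalized <- TRUE
  tab2 <- bsp_scores(ds2, bsp_config(d1 = 1.5, d2 = 2.5))
  expect_equal(tab2$score[1], 0)
})

test_that("a big radius covering the sample zeroes every score", {
  dat <- random_dataset(40, 6, seed = 21)
  ds <- spatial_dataset(dat$expr, dat$coords)
  nds <- normalize_coords(normalize_expression(ds))
  diam <- max(dist(nds$coords))
  tab <- bsp_scores(nds, bsp_config(d1 = 1, d2 = diam + 1))
  expect_equal(tab$sigma_d2, rep(0, 6))
  expect_equal(tab$score, rep(0, 6))
})

test_that("scores match the brute-force oracle on random instances", {
  for (seed in 1:6) {
    m <- sample(30:200, 1)
    n <- sample(5:50, 1)
    dat <- random_dataset(m, n, d = sample(2:3, 1), seed = seed + 50)
    ds <- normalize_coords(normalize_expression(
      spatial_dataset(dat$expr, dat$coords)
    ))
    tab <- bsp_scores(ds, bsp_config())
    oracle <- oracle_bsp_scores(ds$expr, ds$coords, 1, 3)
    expect_equal(tab$score, unname(oracle), tolerance = 1e-10)
  }
})

test_that("scores and p-values are invariant to spot storage order", {
  dat <- random_dataset(60, 30, seed = 77)
  ds <- spatial_dataset(dat$expr, dat$coords)
  res <- run_bsp(ds, bsp_config(null_augmentation_threshold = 10))
  perm <- withr::with_seed(3, sample(60))
  dsp <- spatial_dataset(dat$expr[perm, ], dat$coords[perm, ])
  resp <- run_bsp(dsp, bsp_config(null_augmentation_threshold = 10))
  expect_equal(resp$score, res$score, tolerance = 1e-12)
  expect_equal(resp$p_value, res$p_value, tolerance = 1e-12)
})

test_that("permuted null genes preserve value multisets and reproduce", {
  expr <- matrix(rlnorm(50 * 3), 50, 3)
  nulls <- augment_null_genes(expr, 10, seed = 4)
  expect_equal(dim(nulls), c(50, 10))
  for (k in 1:10) {
    src <- ((k - 1) %% 3) + 1
    expect_equal(sort(nulls[, k]), sort(expr[, src]))
  }
  expect_identical(nulls, augment_null_genes(expr, 10, seed = 4))
  expect_false(identical(nulls, augment_null_genes(expr, 10, seed = 5)))
  expect_equal(ncol(augment_null_genes(expr, 0)), 0)
})

test_that("beta null fitting recovers known parameters and its support bounds", {
  x <- withr::with_seed(11, rbeta(10000, 2, 5))
  fit <- fit_beta_null(x, scale = 1)
  expect_lt(abs(fit$shape1 - 2) / 2, 0.1)
  expect_lt(abs(fit$shape2 - 5) / 5, 0.1)

  # default scaling keeps the top score strictly inside the support
  scores <- withr::with_seed(12, rgamma(500, 2, 10))
  fit2 <- fit_beta_null(scores)
  expect_gte(fit2$scale, max(scores))
  p_top <- score_pvalues(max(scores), fit2)
  expect_gt(p_top, 0)
  expect_equal(fit2$fitted_on, "observed")
  fit3 <- fit_beta_null(scores, fitted_on = "null_pool")
  expect_equal(fit3$fitted_on, "null_pool")

  expect_error(fit_beta_null(rep(1, 30)), "identical")
  expect_error(fit_beta_null(rbeta(5, 2, 2)), "at least 20")
})

test_that("p-values are a non-increasing function of scores", {
  scores <- withr::with_seed(13, rgamma(300, 2, 5))
  fit <- fit_beta_null(scores)
  p <- score_pvalues(scores, fit)
  ord <- order(scores)
  expect_true(all(diff(p[ord]) <= 1e-15))
  expect_equal(score_pvalues(0, fit), 1)
  expect_equal(which.min(score_pvalues(scores, fit)), which.max(scores))
})

test_that("small gene panels trigger permuted-null augmentation", {
  dat <- random_dataset(80, 28, seed = 15)
  ds <- spatial_dataset(dat$expr, dat$coords)
  res <- run_bsp(ds, bsp_config(null_pool_size = 2000, seed = 2))
  fit <- attr(res, "fit")
  expect_equal(fit$fitted_on, "null_pool")
  expect_equal(nrow(res), 28)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # the large panel path fits on the observed scores instead
  dat2 <- random_dataset(40, 60, seed = 16)
  res2 <- run_bsp(
    spatial_dataset(dat2$expr, dat2$coords),
    bsp_config(null_augmentation_threshold = 50)
  )
  expect_equal(attr(res2, "fit")$fitted_on, "observed")
})

test_that("an obvious spatial pattern is ranked first among permuted genes", {
  coords <- as.matrix(expand.grid(x = 1:20, y = 1:20))
  hot <- coords[, 1] <= 8 & coords[, 2] <= 8
  withr::with_seed(44, {
    patterned <- rpois(400, ifelse(hot, 25, 5))
    base <- matrix(rpois(400 * 99, 5), 400, 99)
  })
  nulls <- augment_null_genes(cbind(patterned, base), 499, seed = 6)
  expr <- cbind(patterned, nulls)
  res <- run_bsp(
    spatial_dataset(expr, coords),
    bsp_config(null_augmentation_threshold = 10)
  )
  expect_equal(which.max(res$score), 1L)
  expect_lt(res$p_value[1], 0.05)
  expect_true(res$is_svg[1])
})

test_that("an all-constant panel yields no SVG calls", {
  coords <- cbind(runif(10), runif(10))
  expr <- matrix(2, 10, 5)
  # both the weight step and the pipeline warn about the degenerate panel
  expect_warning(
    expect_warning(res <- run_bsp(spatial_dataset(expr, coords)), "constant"),
    "constant"
  )
  expect_equal(res$p_value, rep(1, 5))
  expect_false(any(res$is_svg))
})
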