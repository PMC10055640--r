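#' Per-gene variance weights
#'
#' Weight w_j = sigma_j^2 / max(sigma_j^2), where sigma_j^2 is the
#' (population) variance of gene j's normalized expression across spots.
#' The weight normalizes intrinsic expression variance so the variance
#' ratio compares spatial structure, not overall variability. If every
#' gene is constant all weights are zero and a warning is emitted.
#'
#' @param expr M x N normalized expression matrix.
#' @return Numeric vector of N weights in [0, 1].
#' @export
gene_weights <- function(expr) {
  expr <- as.matrix(expr)
  v <- col_var_pop(expr)
  top <- max(v)
  if (top == 0) {
    warning("every gene is constant; all weights are zero")
    return(v)
  }
  v / top
}

#' BSP variance-ratio scores
#'
#' The big-small patch score of gene j is
#' r(j) = w_j * sigma_D2(j) / sigma_D1(j):
#' the ratio of the variance of big-patch local means to the variance of
#' small-patch local means, weighted by the gene's overall expression
#' variance. Genes whose expression is spatially stable keep a high
#' local-mean variance only at fine granularity, so the ratio collapses;
#' genes with coherent spatial patterns keep it at coarse granularity too,
#' giving large scores. Genes with sigma_D1 = 0 cannot be spatially
#' variable and are scored 0.
#'
#' @param dataset a [spatial_dataset()] with both normalizations applied
#'   (applied on the fly, with a message, if not).
#' @param config a [bsp_config()].
#' @return A data.frame with columns `gene_id`, `sigma_d1`, `sigma_d2`,
#'   `weight`, `score`.
#' @export
bsp_scores <- function(dataset, config = bsp_config()) {
  stopifnot(inherits(dataset, "spatial_dataset"), inherits(config, "bsp_config"))
  if (nrow(dataset$expr) < 2) stop("need at least 2 spots to score genes")
  if (!dataset$expr_normalized) dataset <- normalize_expression(dataset)
  if (!dataset$coords_normalized) dataset <- normalize_coords(dataset)
  idx1 <- build_patch_index(dataset$coords, config$d1,
    include_center = config$include_center
  )
  idx2 <- build_patch_index(dataset$coords, config$d2,
    include_center = config$include_center
  )
  score_with_indexes(dataset$expr, idx1, idx2, dataset$gene_ids)
}

# scores given prebuilt patch indexes; reused for null augmentation
score_with_indexes <- function(expr, idx1, idx2, gene_ids) {
  s1 <- local_mean_variance(local_means(expr, idx1))
  s2 <- local_mean_variance(local_means(expr, idx2))
  w <- gene_weights(expr)
  score <- ifelse(s1 > 0, w * s2 / s1, 0)
  data.frame(
    gene_id = gene_ids, sigma_d1 = s1, sigma_d2 = s2,
    weight = w, score = score,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Generate permuted null genes
#'
#' Each null gene is one observed gene's values randomly permuted across
#' spots (sampling without replacement), so it keeps the gene's value
#' multiset but carries no spatial structure. Used to build an empirical
#' null score pool when the gene panel is too small to fit the null on
#' observed scores.
#'
#' @param expr M x N expression matrix.
#' @param pool_size number of null genes to generate.
#' @param seed integer seed; a fixed seed reproduces the pool exactly.
#' @return M x `pool_size` matrix of permuted genes (source genes cycle
#'   through columns of `expr`).
#' @export
augment_null_genes <- function(expr, pool_size, seed = 1L) {
  expr <- as.matrix(expr)
  pool_size <- as.integer(pool_size)
  stopifnot(pool_size >= 0, ncol(expr) >= 1)
  m <- nrow(expr)
  if (pool_size == 0) {
    return(matrix(numeric(0), nrow = m, ncol = 0))
  }
  src <- rep_len(seq_len(ncol(expr)), pool_size)
  withr::with_seed(seed, {
    out <- vapply(src, function(j) expr[sample.int(m), j], numeric(m))
  })
  colnames(out) <- paste0("null", seq_len(pool_size))
  out
}

#' Fit a beta null distribution to BSP scores
#'
#' Raw variance-ratio scores are nonnegative but unbounded, so they are
#' mapped into (0, 1) by dividing by `scale` (default: the maximum score
#' inflated by 1e-9, which keeps the top score strictly inside the
#' support) and a two-parameter beta is then fitted by maximum
#' likelihood. Zero scores (constant genes) are excluded from the fit;
#' they get p = 1 regardless.
#'
#' @param scores numeric vector of at least 20 finite scores with at
#'   least 2 distinct positive values.
#' @param scale positive scalar mapping scores into (0, 1); must be at
#'   least the maximum score. `NULL` (default) uses max(scores) * (1 + 1e-9).
#' @param fitted_on label recording which population the fit used
#'   ("observed" or "null_pool").
#' @return An object of class `beta_null_fit`: list with `shape1`,
#'   `shape2`, `scale`, `n`, `fitted_on`.
#' @export
fit_beta_null <- function(scores, scale = NULL, fitted_on = "observed") {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 20) stop("need at least 20 finite scores to fit the null")
  if (length(unique(scores)) < 2) {
    stop("all scores identical: beta likelihood is degenerate")
  }
  if (is.null(scale)) scale <- max(scores) * (1 + 1e-9)
  if (scale < max(scores)) stop("scale must be >= max(scores)")
  x <- scores[scores > 0] / scale
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  if (length(unique(x)) < 2) stop("positive scores are degenerate")
  # method-of-moments start keeps the optimizer on its feet
  mu <- mean(x)
  v <- stats::var(x)
  v <- min(v, mu * (1 - mu) * 0.999)
  k <- mu * (1 - mu) / v - 1
  start <- list(shape1 = max(mu * k, 1e-3), shape2 = max((1 - mu) * k, 1e-3))
  fit <- fitdistrplus::fitdist(x, "beta", method = "mle", start = start)
  est <- fit$estimate
  structure(
    list(
      shape1 = unname(est["shape1"]), shape2 = unname(est["shape2"]),
      scale = scale, n = length(x), fitted_on = fitted_on
    ),
    class = "beta_null_fit"
  )
}

#' @export
print.beta_null_fit <- function(x, ...) {
  cat(sprintf(
    "beta_null_fit: shape1 = %.4g, shape2 = %.4g, scale = %.4g (n = %d, fitted on %s)\n",
    x$shape1, x$shape2, x$scale, x$n, x$fitted_on
  ))
  invisible(x)
}

#' Upper-tail p-values from a fitted beta null
#'
#' p_j is the upper-tail probability of the fitted beta at gene j's
#' rescaled score, so p is non-increasing in the score. A score of 0 has
#' the full upper tail, p = 1; scores beyond the fit's scale (possible
#' when the null was fitted on a permuted pool) are clamped to the top of
#' the support and get p = 0.
#'
#' @param scores numeric score vector.
#' @param fit a [fit_beta_null()] result.
#' @return p-value vector in [0, 1].
#' @export
score_pvalues <- function(scores, fit) {
  stopifnot(inherits(fit, "beta_null_fit"))
  x <- pmin(pmax(scores / fit$scale, 0), 1)
  stats::pbeta(x, fit$shape1, fit$shape2, lower.tail = FALSE)
}

#' Run the full BSP pipeline
#'
#' Normalizes expression (min-max per gene) and coordinates (spot
#' density), builds the small- and big-patch indexes, computes the
#' variance-ratio score for every gene, fits the beta null, and attaches
#' p-values, Benjamini-Hochberg adjusted p-values and SVG calls at level
#' alpha.
#'
#' When the panel holds at least `null_augmentation_threshold` genes the
#' beta null is fitted on the observed score distribution itself;
#' otherwise (small targeted panels) permuted null genes are generated
#' with [augment_null_genes()] until `null_pool_size` null scores are
#' available, and the null is fitted on those.
#'
#' @param dataset a raw [spatial_dataset()].
#' @param config a [bsp_config()].
#' @param verbose print per-stage counts.
#' @return A `gene_score_table`: data.frame with columns `gene_id`,
#'   `sigma_d1`, `sigma_d2`, `weight`, `score`, `p_value`, `p_adjusted`,
#'   `is_svg`, plus attributes `fit` (the [fit_beta_null()] object) and
#'   `config`.
#' @examples
#' rep2d <- simulate_replicate_2d(sim2d_config(n_svg = 20, n_null = 80, seed = 1))
#' res <- run_bsp(rep2d$dataset)
#' head(res[order(res$p_value), ])
#' @export
run_bsp <- function(dataset, config = bsp_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "spatial_dataset"), inherits(config, "bsp_config"))
  if (nrow(dataset$expr) < 2) stop("need at least 2 spots")
  n_genes <- ncol(dataset$expr)
  dataset <- normalize_expression(dataset)
  dataset <- normalize_coords(dataset)
  idx1 <- build_patch_index(dataset$coords, config$d1,
    include_center = config$include_center
  )
  idx2 <- build_patch_index(dataset$coords, config$d2,
    include_center = config$include_center
  )
  if (verbose) {
    message(
      "BSP: ", nrow(dataset$expr), " spots, ", n_genes, " genes; mean patch sizes ",
      round(mean(idx1$patch_sizes), 1), " (D1=", config$d1, ") / ",
      round(mean(idx2$patch_sizes), 1), " (D2=", config$d2, ")"
    )
  }
  tab <- score_with_indexes(dataset$expr, idx1, idx2, dataset$gene_ids)

  if (all(tab$weight == 0)) {
    warning("all genes constant; no SVG can be called")
    tab$p_value <- rep(1, n_genes)
    tab$p_adjusted <- rep(1, n_genes)
    tab$is_svg <- rep(FALSE, n_genes)
    class(tab) <- c("gene_score_table", class(tab))
    return(tab)
  }

  if (n_genes >= config$null_augmentation_threshold) {
    fit <- fit_beta_null(tab$score, fitted_on = "observed")
  } else {
    if (verbose) {
      message(
        "BSP: only ", n_genes, " genes; fitting null on ",
        config$null_pool_size, " permuted null genes"
      )
    }
    nulls <- augment_null_genes(dataset$expr, config$null_pool_size,
      seed = config$seed
    )
    ntab <- score_with_indexes(
      nulls, idx1, idx2, colnames(nulls)
    )
    # observed scores may exceed the null pool's range: scale on the pool
    fit <- fit_beta_null(ntab$score, fitted_on = "null_pool")
  }
  tab$p_value <- score_pvalues(tab$score, fit)
  tab$p_value[tab$score == 0] <- 1
  tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "BH")
  p_call <- if (config$use_adjusted) tab$p_adjusted else tab$p_value
  tab$is_svg <- p_call < config$alpha
  if (verbose) {
    message(
      "BSP: ", sum(tab$is_svg), "/", n_genes, " genes called SVG at alpha = ",
      config$alpha, if (config$use_adjusted) " (BH adjusted)" else " (raw p)"
    )
  }
  attr(tab, "fit") <- fit
  attr(tab, "config") <- config
  class(tab) <- c("gene_score_table", class(tab))
  tab
}
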