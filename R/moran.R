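#' Build a spatial weight matrix
#'
#' Baseline plumbing for Moran's I. Three schemes are offered: binary
#' radius weights (w = 1 for pairs strictly closer than `parameter`),
#' k-nearest neighbors (w = 1 from each spot to its `parameter` nearest
#' spots; symmetrized by the union), and inverse distance (w = 1/d to all
#' other spots). The diagonal is always zero.
#'
#' @param coords M x d (normalized) coordinate matrix.
#' @param scheme one of "radius", "knn", "invdist".
#' @param parameter radius for "radius" (defaults to the BSP small-patch
#'   radius, 1), k for "knn"; ignored for "invdist".
#' @param row_standardize divide each row by its sum.
#' @return An object of class `spatial_weights`: list with the sparse
#'   M x M matrix `w`, the `scheme` tag and the standardization flag.
#' @export
build_spatial_weights <- function(coords, scheme = c("radius", "knn", "invdist"),
                                  parameter = 1, row_standardize = FALSE) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  m <- nrow(coords)
  stopifnot(m >= 3)
  if (scheme == "radius") {
    w <- build_patch_index(coords, parameter, include_center = FALSE)$adj
  } else {
    dm <- as.matrix(stats::dist(coords))
    if (scheme == "knn") {
      k <- as.integer(parameter)
      stopifnot(k >= 1, k <= m - 1)
      idx <- apply(dm, 1, function(row) order(row)[2:(k + 1)])
      w <- Matrix::sparseMatrix(
        i = rep(seq_len(m), each = k), j = as.integer(idx),
        x = 1, dims = c(m, m)
      )
      w <- Matrix::drop0(w + Matrix::t(w)) # union symmetrization
      w@x[] <- 1
    } else {
      inv <- 1 / dm
      diag(inv) <- 0
      w <- methods::as(inv, "CsparseMatrix")
    }
  }
  if (any(Matrix::rowSums(w) == 0)) {
    stop("isolated spot(s) under scheme '", scheme, "'; increase the parameter")
  }
  if (row_standardize) w <- w / Matrix::rowSums(w)
  structure(
    list(w = w, scheme = scheme, row_standardized = row_standardize),
    class = "spatial_weights"
  )
}

#' Moran's I per gene with permutation p-values
#'
#' Classical spatial autocorrelation:
#' I = (M / S0) * sum_il w_il (x_i - xbar)(x_l - xbar) / sum_i (x_i - xbar)^2,
#' with S0 the total weight. Under random assignment of values to spots
#' the expectation is -1/(M - 1). One-sided (positive autocorrelation)
#' p-values come from random permutations of the values over spots, the
#' same permutations being applied to every gene; an analytic normal
#' approximation under the randomization assumption is available instead.
#'
#' @param expr M x N expression matrix (spots x genes).
#' @param weights a [build_spatial_weights()] result.
#' @param n_perm number of permutations.
#' @param method "permutation" or "normal".
#' @param seed integer seed for the permutations.
#' @return data.frame with columns `gene_id`, `score` (Moran's I) and
#'   `p_value`. Constant genes get NaN with a warning.
#' @export
morans_i <- function(expr, weights, n_perm = 999, method = c("permutation", "normal"),
                     seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(weights, "spatial_weights"))
  expr <- as.matrix(expr)
  w <- weights$w
  m <- nrow(expr)
  if (m < 3) stop("Moran's I needs at least 3 spots")
  if (nrow(w) != m) stop("weights and expression cover different spot sets")
  gene_ids <- colnames(expr)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(expr)))

  s0 <- sum(w)
  z <- sweep(expr, 2, colMeans(expr), "-")
  ss <- colSums(z^2)
  const <- ss == 0
  if (any(const)) warning(sum(const), " constant gene(s): Moran's I is NaN")
  num <- colSums(z * as.matrix(w %*% z))
  i_obs <- (m / s0) * num / ss

  if (method == "normal") {
    e_i <- -1 / (m - 1)
    wt <- Matrix::t(w)
    s1 <- sum((w + wt)^2) / 2
    s2 <- sum((Matrix::rowSums(w) + Matrix::colSums(w))^2)
    b2 <- m * colSums(z^4) / (ss^2)
    v1 <- m * ((m^2 - 3 * m + 3) * s1 - m * s2 + 3 * s0^2)
    v2 <- b2 * ((m^2 - m) * s1 - 2 * m * s2 + 6 * s0^2)
    var_i <- (v1 - v2) / ((m - 1) * (m - 2) * (m - 3) * s0^2) - e_i^2
    p <- stats::pnorm((i_obs - e_i) / sqrt(var_i), lower.tail = FALSE)
  } else {
    stopifnot(n_perm >= 1)
    ge <- integer(ncol(expr))
    withr::with_seed(seed, {
      for (b in seq_len(n_perm)) {
        zp <- z[sample.int(m), , drop = FALSE]
        i_perm <- (m / s0) * colSums(zp * as.matrix(w %*% zp)) / ss
        ge <- ge + (i_perm >= i_obs)
      }
    })
    p <- (1 + ge) / (n_perm + 1)
  }
  p[const] <- NaN
  i_obs[const] <- NaN
  data.frame(
    gene_id = gene_ids, score = i_obs, p_value = p,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
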