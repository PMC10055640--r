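#' Radius-neighborhood index over spots
#'
#' For every spot i, finds the patch S_i of spots strictly within
#' Euclidean distance `d`. By default the center spot belongs to its own
#' patch (a spatial ball query): this makes every patch identical once
#' the radius covers the whole sample, so the local-mean variance is then
#' exactly zero — the analytic property the variance-ratio statistic
#' relies on. Set `include_center = FALSE` for the strict neighbor-only
#' variant, under which a spot with no neighbor has an empty patch.
#' The index is stored as a sparse binary adjacency matrix; results are
#' identical to an all-pairs scan.
#'
#' @param coords M x d matrix of (normalized) spot coordinates.
#' @param d patch radius, in the same units as `coords`.
#' @param include_center if `FALSE`, each spot is excluded from its own
#'   patch.
#' @param block number of spots per distance-computation block; controls
#'   peak memory only, not results.
#' @return An object of class `patch_index`: list with the radius `d`, the
#'   M x M sparse adjacency `adj` (`adj[i, l]` = 1 iff l is in S_i) and
#'   `patch_sizes` = num(S_i).
#' @examples
#' coords <- cbind(x = c(0, 1, 2), y = c(0, 0, 0))
#' idx <- build_patch_index(coords, d = 1.5)
#' idx$patch_sizes # 2 3 2
#' @export
build_patch_index <- function(coords, d, include_center = TRUE, block = 512L) {
  coords <- as.matrix(coords)
  stopifnot(d > 0, nrow(coords) >= 1)
  m <- nrow(coords)
  sq <- rowSums(coords^2)
  starts <- seq.int(1L, m, by = block)
  ii <- vector("list", length(starts))
  jj <- vector("list", length(starts))
  d2 <- d * d
  for (k in seq_along(starts)) {
    rows <- starts[k]:min(starts[k] + block - 1L, m)
    # squared distances, clamped against negative rounding
    dd <- outer(sq[rows], sq, "+") - 2 * tcrossprod(coords[rows, , drop = FALSE], coords)
    hit <- which(dd < d2, arr.ind = TRUE)
    keep <- include_center | (rows[hit[, 1L]] != hit[, 2L])
    ii[[k]] <- rows[hit[keep, 1L]]
    jj[[k]] <- hit[keep, 2L]
  }
  adj <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = 1, dims = c(m, m)
  )
  structure(
    list(d = d, adj = adj, patch_sizes = Matrix::rowSums(adj)),
    class = "patch_index"
  )
}

#' @export
print.patch_index <- function(x, ...) {
  cat(
    "patch_index: radius", x$d, "over", length(x$patch_sizes),
    "spots; mean patch size", round(mean(x$patch_sizes), 2), "\n"
  )
  invisible(x)
}

#' Local mean expression per patch
#'
#' Averages each gene over every spot's patch. A spot whose patch is
#' empty (possible only under `include_center = FALSE` when the spot has
#' no neighbor within the radius) falls back to its own expression
#' value, the limit of a patch shrinking onto its center.
#'
#' @param expr M x N expression matrix (spots x genes).
#' @param index a [build_patch_index()] result on the same spots.
#' @return M x N matrix of local means.
#' @export
local_means <- function(expr, index) {
  stopifnot(inherits(index, "patch_index"))
  expr <- as.matrix(expr)
  if (nrow(expr) != nrow(index$adj)) {
    stop("expression and patch index cover different spot sets")
  }
  n <- index$patch_sizes
  lm <- as.matrix(index$adj %*% expr) / pmax(n, 1)
  empty <- n == 0
  if (any(empty)) lm[empty, ] <- expr[empty, , drop = FALSE]
  dimnames(lm) <- dimnames(expr)
  lm
}

#' Per-gene variance of local means
#'
#' Population variance (divide by M) of the M local means of each gene.
#' Zero for a spatially constant gene, and exactly zero for every gene
#' once the radius covers the whole sample, since then all patches hold
#' all spots and share one mean.
#'
#' @param lm M x N local-mean matrix from [local_means()].
#' @return Numeric vector of N nonnegative variances.
#' @export
local_mean_variance <- function(lm) {
  lm <- as.matrix(lm)
  col_var_pop(lm)
}

# population column variance: sum((x - mean)^2) / M
col_var_pop <- function(x) {
  mu <- colMeans(x)
  v <- colMeans(sweep(x, 2, mu, "-")^2)
  pmax(v, 0)
}
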