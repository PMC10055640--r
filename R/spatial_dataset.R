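#' Construct a spatial expression dataset
#'
#' Bundles a spot-level expression matrix with 2D or 3D spot coordinates.
#' This is the container every other function in the package operates on.
#'
#' @param expr numeric matrix of expression values, spots in rows and genes
#'   in columns (M x N).
#' @param coords numeric matrix of spot positions, M x d with d = 2 or 3.
#'   Column order is interpreted as x, y (, z).
#' @param gene_ids character vector of N gene identifiers; defaults to the
#'   column names of `expr` or `gene1..geneN`.
#' @param spot_ids character vector of M spot identifiers; defaults to the
#'   row names of `coords` or `spot1..spotM`.
#'
#' @return An object of class `spatial_dataset`: a list with elements
#'   `expr`, `coords`, `gene_ids`, `spot_ids`, and the logical flags
#'   `expr_normalized` and `coords_normalized`.
#' @examples
#' coords <- cbind(x = runif(30), y = runif(30))
#' expr <- matrix(rpois(30 * 4, 5), nrow = 30)
#' ds <- spatial_dataset(expr, coords)
#' @export
spatial_dataset <- function(expr, coords, gene_ids = NULL, spot_ids = NULL) {
  expr <- as.matrix(expr)
  coords <- as.matrix(coords)
  storage.mode(expr) <- "double"
  storage.mode(coords) <- "double"
  if (nrow(expr) != nrow(coords)) {
    stop("expr has ", nrow(expr), " spots but coords has ", nrow(coords))
  }
  if (nrow(coords) < 2) stop("a spatial dataset needs at least 2 spots")
  if (ncol(expr) < 1) stop("a spatial dataset needs at least 1 gene")
  d <- ncol(coords)
  if (!d %in% c(2L, 3L)) stop("coords must have 2 or 3 columns, got ", d)
  if (anyNA(coords)) stop("coords contain missing values")
  if (is.null(gene_ids)) {
    gene_ids <- colnames(expr)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(expr)))
  }
  if (is.null(spot_ids)) {
    spot_ids <- rownames(coords)
    if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(coords)))
  }
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (length(gene_ids) != ncol(expr)) stop("gene_ids length mismatch")
  if (length(spot_ids) != nrow(expr)) stop("spot_ids length mismatch")
  dimnames(expr) <- list(spot_ids, gene_ids)
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y", "z")[seq_len(d)]
  structure(
    list(
      expr = expr, coords = coords,
      gene_ids = gene_ids, spot_ids = spot_ids,
      expr_normalized = FALSE, coords_normalized = FALSE
    ),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(
    "spatial_dataset:", nrow(x$expr), "spots x", ncol(x$expr), "genes,",
    ncol(x$coords), "D coordinates\n"
  )
  cat(
    "  expression normalized:", x$expr_normalized,
    "| coordinates normalized:", x$coords_normalized, "\n"
  )
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$expr)

#' Axis-aligned bounding box of spot coordinates
#'
#' Per-dimension range (max minus min) of the coordinate matrix. The 2D box
#' is a rectangle and the 3D box a cuboid; its area/volume feeds the spot
#' density used by [normalize_coords()].
#'
#' @param coords M x d coordinate matrix.
#' @return Named numeric vector of d ranges.
#' @export
bounding_box <- function(coords) {
  coords <- as.matrix(coords)
  rng <- apply(coords, 2, function(v) max(v) - min(v))
  if (any(rng < 0) || anyNA(rng)) stop("invalid coordinate ranges")
  if (all(rng == 0)) stop("all spots coincide: bounding box has zero extent")
  rng
}

#' BSP run configuration
#'
#' @param d1 small-patch radius in normalized coordinate units. The default
#'   of 1 captures roughly the nearest neighbors once coordinates are
#'   density-normalized.
#' @param d2 big-patch radius in normalized units; must exceed `d1`.
#' @param alpha significance level for SVG calls.
#' @param null_augmentation_threshold when fewer genes than this are
#'   present, the beta null is fitted on generated permuted-null genes
#'   rather than on the observed scores.
#' @param null_pool_size number of permuted null gene scores used when
#'   augmentation kicks in.
#' @param use_adjusted if `TRUE`, SVG calls use Benjamini-Hochberg adjusted
#'   p-values instead of raw p-values.
#' @param include_center include the center spot in its own patch
#'   (default). See [build_patch_index()] for why the ball-query
#'   convention is the default; `FALSE` gives the strict neighbor-only
#'   patch.
#' @param seed integer seed driving null-gene permutation.
#' @return A list of class `bsp_config`.
#' @export
bsp_config <- function(d1 = 1, d2 = 3, alpha = 0.05,
                       null_augmentation_threshold = 1000,
                       null_pool_size = 10000,
                       use_adjusted = FALSE,
                       include_center = TRUE,
                       seed = 1L) {
  stopifnot(d1 > 0, d2 > d1, alpha > 0, alpha < 1, null_pool_size >= 0)
  structure(
    list(
      d1 = d1, d2 = d2, alpha = alpha,
      null_augmentation_threshold = null_augmentation_threshold,
      null_pool_size = null_pool_size,
      use_adjusted = use_adjusted,
      include_center = include_center,
      seed = as.integer(seed)
    ),
    class = "bsp_config"
  )
}

#' Min-max normalize expression to [0, 1]
#'
#' Rescales each gene independently by (x - min) / (max - min) across all
#' spots. Genes with zero range carry no spatial signal and are mapped to
#' all zeros; they receive score 0 and p = 1 downstream.
#'
#' @param dataset a [spatial_dataset()].
#' @return The dataset with rescaled expression and `expr_normalized = TRUE`.
#'   Applying the function twice is a no-op.
#' @export
normalize_expression <- function(dataset) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  expr <- dataset$expr
  mins <- apply(expr, 2, min)
  rng <- apply(expr, 2, max) - mins
  scale <- ifelse(rng > 0, rng, 1) # constant genes -> all zeros
  expr <- sweep(sweep(expr, 2, mins, "-"), 2, scale, "/")
  dataset$expr <- expr
  dataset$expr_normalized <- TRUE
  dataset
}

#' Density-normalize spot coordinates
#'
#' Multiplies all coordinates by the scalar (M / area)^(1/2) in 2D or
#' (M / volume)^(1/3) in 3D, where area/volume comes from the axis-aligned
#' bounding box. After rescaling the mean spot-to-spot spacing is close to
#' one unit, so the default patch radii (1 and 3) capture comparable
#' neighborhoods on any input scale. Pairwise distance ratios are
#' preserved.
#'
#' A dimension with zero range (e.g. a single z-plane passed as 3D) would
#' zero the volume; such dimensions are dropped from the density estimate
#' with a warning and the scale is computed in the remaining d - 1
#' dimensions.
#'
#' @param dataset a [spatial_dataset()].
#' @return The dataset with rescaled coordinates and
#'   `coords_normalized = TRUE`.
#' @export
normalize_coords <- function(dataset) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  coords <- dataset$coords
  rng <- bounding_box(coords)
  live <- rng > 0
  if (!all(live)) {
    warning(
      "dropping ", sum(!live), " zero-range dimension(s) (",
      paste(names(rng)[!live], collapse = ", "),
      ") from the spot-density estimate"
    )
  }
  d_eff <- sum(live)
  s <- (nrow(coords) / prod(rng[live]))^(1 / d_eff)
  dataset$coords <- coords * s
  dataset$coords_normalized <- TRUE
  dataset
}
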