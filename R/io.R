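#' Read a spatial dataset from delimited files
#'
#' Reads an expression table plus a coordinate table and aligns them by
#' spot identifier into a [spatial_dataset()]. Supported expression
#' layouts: wide with genes in rows (`genes_by_spots`, the common
#' convention of published spot-level tables), wide with spots in rows
#' (`spots_by_genes`), long triplets (`long`: columns gene, spot, value;
#' absent pairs are zero), and MatrixMarket sparse triplets (`mtx`:
#' genes in rows; requires `gene_ids_path` with one gene id per line and
#' spot ids taken from the coordinate table order).
#'
#' The coordinate table must have a spot id column (first column or
#' `spot`/`spot_id`) and columns x, y and optionally z
#' (case-insensitive); presence of z makes the dataset 3D. Spots present
#' in only one of the two files are dropped with a message stating the
#' count.
#'
#' @param expr_path path to the expression table (TSV/CSV by extension,
#'   or MTX).
#' @param coords_path path to the coordinate table.
#' @param layout one of "genes_by_spots", "spots_by_genes", "long", "mtx".
#' @param gene_ids_path gene id file for `layout = "mtx"`.
#' @return a [spatial_dataset()].
#' @export
read_spatial_dataset <- function(expr_path, coords_path,
                                 layout = c(
                                   "genes_by_spots", "spots_by_genes",
                                   "long", "mtx"
                                 ),
                                 gene_ids_path = NULL) {
  layout <- match.arg(layout)
  stopifnot(file.exists(expr_path), file.exists(coords_path))
  coords_df <- read_delim_auto(coords_path)
  names(coords_df) <- tolower(names(coords_df))
  id_col <- intersect(c("spot", "spot_id", "cell", "cell_id"), names(coords_df))
  if (length(id_col) == 0) id_col <- names(coords_df)[1]
  spot_ids <- as.character(coords_df[[id_col[1]]])
  dims <- intersect(c("x", "y", "z"), names(coords_df))
  if (!all(c("x", "y") %in% dims)) stop("coordinate table needs x and y columns")
  coords <- as.matrix(coords_df[, dims, drop = FALSE])
  if (!is.numeric(coords) || anyNA(coords)) stop("non-numeric coordinates")
  rownames(coords) <- spot_ids

  if (layout == "mtx") {
    if (is.null(gene_ids_path)) stop("layout 'mtx' requires gene_ids_path")
    mm <- as.matrix(Matrix::readMM(expr_path)) # genes x spots
    gene_ids <- readLines(gene_ids_path)
    if (length(gene_ids) != nrow(mm)) stop("gene id count does not match MTX rows")
    if (ncol(mm) != length(spot_ids)) {
      stop("MTX has ", ncol(mm), " spots but coords table has ", length(spot_ids))
    }
    expr <- t(mm)
    rownames(expr) <- spot_ids
    colnames(expr) <- gene_ids
  } else if (layout == "long") {
    long <- read_delim_auto(expr_path)
    if (ncol(long) < 3) stop("long layout needs columns gene, spot, value")
    names(long)[1:3] <- c("gene", "spot", "value")
    genes <- unique(as.character(long$gene))
    spots <- unique(as.character(long$spot))
    expr <- matrix(0, length(spots), length(genes),
      dimnames = list(spots, genes)
    )
    expr[cbind(
      match(as.character(long$spot), spots),
      match(as.character(long$gene), genes)
    )] <- as.numeric(long$value)
  } else {
    wide <- read_delim_auto(expr_path)
    ids <- as.character(wide[[1]])
    mat <- as.matrix(wide[, -1, drop = FALSE])
    if (!is.numeric(mat)) stop("non-numeric expression values")
    rownames(mat) <- ids
    expr <- if (layout == "genes_by_spots") t(mat) else mat
  }

  common <- intersect(rownames(expr), rownames(coords))
  dropped <- length(union(rownames(expr), rownames(coords))) - length(common)
  if (length(common) == 0) stop("no spot ids shared between expression and coordinates")
  if (dropped > 0) {
    message("read_spatial_dataset: dropped ", dropped, " unmatched spot(s)")
  }
  spatial_dataset(
    expr[common, , drop = FALSE], coords[common, , drop = FALSE]
  )
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path,
    header = TRUE, sep = sep, check.names = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Write a spatial dataset to a coords + expression TSV pair
#'
#' Inverse of [read_spatial_dataset()] for the wide genes-by-spots
#' layout; values round-trip to full double precision.
#'
#' @param dataset a [spatial_dataset()].
#' @param expr_path,coords_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_spatial_dataset <- function(dataset, expr_path, coords_path) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  cdf <- data.frame(
    spot = dataset$spot_ids,
    dataset$coords,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(cdf, coords_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  edf <- data.frame(
    gene = dataset$gene_ids,
    t(dataset$expr),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(edf, expr_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(expr_path, coords_path))
}

#' Write a simulated replicate as a coords/expression/truth TSV trio
#'
#' @param replicate a `simulated_replicate`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the three paths.
#' @export
write_replicate <- function(replicate, dir, prefix = "replicate") {
  stopifnot(inherits(replicate, "simulated_replicate"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_path <- file.path(dir, paste0(prefix, "_expression.tsv"))
  coords_path <- file.path(dir, paste0(prefix, "_coords.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_spatial_dataset(replicate$dataset, expr_path, coords_path)
  utils::write.table(replicate$truth, truth_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(expr_path, coords_path, truth_path))
}

#' Write a gene results table as TSV
#'
#' Columns: gene_id, sigma_D1, sigma_D2, weight, score, p_value,
#' p_adjusted, is_svg (for Moran's I results only gene_id, score,
#' p_value are present).
#'
#' @param results a results data.frame ([run_bsp()] or [morans_i()]).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a power curve as TSV
#'
#' @param curve a [power_at_fdr()] or [average_power_curves()] result.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_power_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a run manifest
#'
#' Plain-text key: value record of a CLI run — input paths, configuration
#' echo, package version, stage counts and timings.
#'
#' @param entries named list of values.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(entries, path) {
  lines <- c(
    paste0("bspsvg_version: ", as.character(utils::packageVersion("bspsvg"))),
    paste0("written_at: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    vapply(
      names(entries),
      function(k) paste0(k, ": ", paste(format(entries[[k]]), collapse = " ")),
      character(1)
    )
  )
  writeLines(lines, path)
  invisible(path)
}
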