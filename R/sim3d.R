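#' 3D simulation configuration
#'
#' Parameters of the stacked-section 3D benchmark: cells are scattered by
#' a Poisson point process in a fixed square window per section, sections
#' are stacked along z, and a spatial pattern is carved out as the union
#' of spheres whose centers follow a constrained random walk. Defaults
#' match the study conditions the benchmark emulates: 10 sections of 225
#' cells, walk step length 2, sphere radius 2, quantile signal 0.80,
#' noise multiplier 1, 1000 SVGs each spawning 9 permutation nulls.
#'
#' The signal can be given either as the quantile threshold `q` (marked
#' cells sample from pool values above the q-quantile) or as a target
#' fold change `fc`, which is converted to q by solving the
#' truncated-mean equation for the configured expression pool.
#'
#' @param n_sections number of z-sections (>= 2).
#' @param cells_per_section cells per section.
#' @param window x-y extent of each section's square window. The default
#'   of 15 gives 225 cells unit density, so raw simulation units already
#'   sit close to normalized units and the sphere radii are expressed in
#'   cell spacings.
#' @param step_length random-walk step length.
#' @param n_steps number of walk steps (n_steps + 1 sphere centers).
#' @param r sphere radius.
#' @param pattern "I" (curved stick: walk monotonic in x and z), "II"
#'   (thin plate: monotonic in z only), "III" (irregular lump: no
#'   monotonicity constraint).
#' @param q quantile threshold in (0, 1) for marked-cell sampling.
#' @param fc optional target marked/unmarked mean fold change; overrides
#'   `q` via [quantile_for_fc()].
#' @param sigma_mult Gaussian noise standard deviation, as a multiple of
#'   the mean per-gene standard deviation.
#' @param n_svg number of patterned genes.
#' @param perm_per_svg permutation nulls generated per SVG.
#' @param pool expression value pool: numeric vector of reference values,
#'   or `NULL` for the default log-normal(meanlog 0, sdlog 1) pool of
#'   10000 draws.
#' @param shared_pattern all SVGs share one walk (a single tissue
#'   structure driving many genes); `FALSE` gives each SVG its own walk.
#' @param seed integer seed.
#' @return list of class `sim3d_config`.
#' @export
sim3d_config <- function(n_sections = 10, cells_per_section = 225,
                         window = 15, step_length = 2, n_steps = 10,
                         r = 2.0, pattern = c("I", "II", "III"),
                         q = 0.80, fc = NULL, sigma_mult = 1,
                         n_svg = 1000, perm_per_svg = 9,
                         pool = NULL, shared_pattern = TRUE, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(
    n_sections >= 2, cells_per_section >= 1, window > 0, step_length > 0,
    n_steps >= 1, r > 0, q > 0, q < 1, sigma_mult >= 0, n_svg >= 0,
    perm_per_svg >= 0
  )
  structure(
    list(
      n_sections = as.integer(n_sections),
      cells_per_section = as.integer(cells_per_section),
      window = window, step_length = step_length, n_steps = as.integer(n_steps),
      r = r, pattern = pattern, q = q, fc = fc, sigma_mult = sigma_mult,
      n_svg = as.integer(n_svg), perm_per_svg = as.integer(perm_per_svg),
      pool = pool, shared_pattern = shared_pattern, seed = as.integer(seed)
    ),
    class = "sim3d_config"
  )
}

#' Stacked Poisson point sections
#'
#' Scatters a fixed number of cells uniformly at random (a conditioned
#' Poisson point pattern) in a square window per section, and stacks the
#' sections with the section index as the z coordinate (z = 1, 2, ...).
#'
#' @param n_sections number of sections.
#' @param cells_per_section cells in each section.
#' @param window square window side length.
#' @param seed integer seed.
#' @return (n_sections * cells_per_section) x 3 matrix with columns x, y, z.
#' @export
poisson_sections <- function(n_sections, cells_per_section, window = 15,
                             seed = 1L) {
  n_sections <- as.integer(n_sections)
  cells_per_section <- as.integer(cells_per_section)
  stopifnot(n_sections >= 1, cells_per_section >= 1, window > 0)
  n <- n_sections * cells_per_section
  coords <- withr::with_seed(seed, cbind(
    x = stats::runif(n, 0, window),
    y = stats::runif(n, 0, window),
    z = rep(seq_len(n_sections), each = cells_per_section)
  ))
  rownames(coords) <- paste0("cell", seq_len(n))
  coords
}

#' Random-walk sphere centers
#'
#' Successive centers sit at Euclidean distance exactly `step_length`
#' from each other; step directions are uniform on the sphere, with sign
#' constraints defining the pattern type: pattern I forces positive steps
#' along x and z (a curved stick), pattern II along z only (a thin
#' plate), pattern III is unconstrained (an irregular lump). On
#' unconstrained axes the walk starts at the window center and a
#' direction whose step would leave the volume is redrawn, so every step
#' keeps the exact step length; monotone axes start at their lower bound
#' and run freely upward, letting a stick or plate traverse the sample
#' (sphere centers past the far bound simply mark no cells).
#'
#' @param pattern "I", "II" or "III".
#' @param step_length step length.
#' @param n_steps number of steps.
#' @param window x-y window side; z spans 1..n_sections.
#' @param n_sections number of stacked sections.
#' @param seed integer seed.
#' @return (n_steps + 1) x 3 matrix of centers.
#' @export
walk_centers <- function(pattern = c("I", "II", "III"), step_length = 2,
                         n_steps = 10, window = 15, n_sections = 10,
                         seed = 1L) {
  pattern <- match.arg(pattern)
  lo <- c(0, 0, 1)
  hi <- c(window, window, n_sections)
  centers <- matrix(NA_real_, n_steps + 1, 3,
    dimnames = list(NULL, c("x", "y", "z"))
  )
  force_pos <- switch(pattern,
    I = c(TRUE, FALSE, TRUE),
    II = c(FALSE, FALSE, TRUE),
    III = c(FALSE, FALSE, FALSE)
  )
  centers[1, ] <- ifelse(force_pos, lo, (lo + hi) / 2)
  bounded <- !force_pos
  withr::with_seed(seed, {
    for (s in seq_len(n_steps)) {
      for (try in seq_len(1000L)) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        dir[force_pos] <- abs(dir[force_pos])
        prop <- centers[s, ] + step_length * dir
        if (all(prop[bounded] >= lo[bounded] & prop[bounded] <= hi[bounded])) break
        if (try == 1000L) stop("random walk cannot stay inside the window")
      }
      centers[s + 1, ] <- prop
    }
  })
  centers
}

#' Mark cells inside the pattern
#'
#' A cell is marked iff its minimum Euclidean distance to any sphere
#' center is strictly below `radius`.
#'
#' @param coords M x 3 cell coordinates.
#' @param centers K x 3 sphere centers.
#' @param radius sphere radius.
#' @return logical mask of length M.
#' @export
mark_cells <- function(coords, centers, radius) {
  coords <- as.matrix(coords)
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) >= 1, radius > 0)
  mind2 <- rep(Inf, nrow(coords))
  for (k in seq_len(nrow(centers))) {
    d2 <- (coords[, 1] - centers[k, 1])^2 +
      (coords[, 2] - centers[k, 2])^2 +
      (coords[, 3] - centers[k, 3])^2
    mind2 <- pmin(mind2, d2)
  }
  mind2 < radius^2
}

#' Sample one SVG's expression from a value pool
#'
#' Marked cells draw uniformly with replacement from the pool values
#' strictly above the q-quantile of the pool; unmarked cells draw from
#' the full pool. As q -> 0 the two distributions coincide and the fold
#' change tends to 1.
#'
#' @param pool numeric vector of at least 100 reference expression values.
#' @param mask logical marked-cell mask (length = number of cells).
#' @param q quantile threshold in (0, 1).
#' @param seed integer seed.
#' @return numeric vector of per-cell expression values.
#' @export
sample_svg_expression <- function(pool, mask, q, seed = 1L) {
  stopifnot(length(pool) >= 100, q > 0, q < 1)
  cut <- stats::quantile(pool, q, names = FALSE)
  upper <- pool[pool > cut]
  if (length(upper) == 0) stop("upper-quantile slice of the pool is empty")
  withr::with_seed(seed, {
    x <- sample(pool, length(mask), replace = TRUE)
    if (any(mask)) x[mask] <- sample(upper, sum(mask), replace = TRUE)
    x
  })
}

#' Solve the quantile threshold for a target fold change
#'
#' Finds q such that the expected marked/unmarked mean ratio
#' mean(pool > quantile(pool, q)) / mean(pool) equals `fc` for the given
#' pool, by monotone root finding on q.
#'
#' @param fc target fold change (> 1).
#' @param pool value pool (default: the log-normal reference pool at a
#'   fixed internal seed).
#' @return quantile threshold in (0, 1).
#' @export
quantile_for_fc <- function(fc, pool = default_expression_pool()) {
  stopifnot(fc > 1)
  ratio <- function(q) {
    cut <- stats::quantile(pool, q, names = FALSE)
    mean(pool[pool > cut]) / mean(pool) - fc
  }
  max_ratio <- mean(pool[pool > stats::quantile(pool, 0.9999, names = FALSE)]) /
    mean(pool)
  if (fc >= max_ratio) stop("fold change ", fc, " unattainable for this pool")
  stats::uniroot(ratio, c(1e-4, 0.9999), tol = 1e-6)$root
}

#' Default log-normal expression pool
#'
#' 10000 draws from log-normal(meanlog 0, sdlog 1) at a fixed internal
#' seed, standing in for an empirical single-cell expression
#' distribution. Pass any numeric vector as `pool` in [sim3d_config()]
#' to use real measurements instead.
#'
#' @param n pool size.
#' @return numeric vector of positive values.
#' @export
default_expression_pool <- function(n = 10000) {
  withr::with_seed(20260101L, stats::rlnorm(n, 0, 1))
}

#' Add Gaussian noise scaled to the data
#'
#' Adds independent Normal(0, (sigma_mult * s)^2) noise to every entry,
#' where s is the mean over genes of the per-gene standard deviation of
#' the input matrix. `sigma_mult = 0` returns the matrix unchanged.
#'
#' @param expr M x N expression matrix.
#' @param sigma_mult noise multiplier.
#' @param seed integer seed.
#' @return noisy matrix of the same shape.
#' @export
add_noise <- function(expr, sigma_mult, seed = 1L) {
  expr <- as.matrix(expr)
  stopifnot(sigma_mult >= 0)
  if (sigma_mult == 0) {
    return(expr)
  }
  s_bar <- mean(apply(expr, 2, stats::sd))
  noise <- withr::with_seed(
    seed,
    matrix(stats::rnorm(length(expr), 0, sigma_mult * s_bar), nrow(expr))
  )
  expr + noise
}

#' Simulate one labeled 3D replicate
#'
#' Builds the stacked Poisson sections, carves the random-walk sphere
#' pattern, samples `n_svg` SVGs via upper-quantile signal assignment,
#' spawns `perm_per_svg` spot-permuted null genes per SVG from the
#' noiseless SVG values, and finally adds Gaussian noise to the full
#' matrix so SVGs and nulls carry identical noise statistics.
#'
#' @param config a [sim3d_config()].
#' @return `simulated_replicate` (see [simulate_replicate_2d()]), with a
#'   3-column coordinate matrix and the sphere centers in
#'   `attr(, "centers")`.
#' @export
simulate_replicate_3d <- function(config = sim3d_config()) {
  stopifnot(inherits(config, "sim3d_config"))
  pool <- if (is.null(config$pool)) default_expression_pool() else config$pool
  q <- if (!is.null(config$fc)) quantile_for_fc(config$fc, pool) else config$q
  coords <- poisson_sections(
    config$n_sections, config$cells_per_section, config$window,
    seed = config$seed
  )
  m <- nrow(coords)
  shared_centers <- walk_centers(
    config$pattern, config$step_length, config$n_steps,
    config$window, config$n_sections,
    seed = config$seed + 1L
  )
  shared_mask <- mark_cells(coords, shared_centers, config$r)
  gene_mask <- function(j) {
    if (config$shared_pattern) {
      return(shared_mask)
    }
    centers <- walk_centers(
      config$pattern, config$step_length, config$n_steps,
      config$window, config$n_sections,
      seed = config$seed + 1L + j
    )
    mark_cells(coords, centers, config$r)
  }
  svg <- matrix(numeric(0), nrow = m, ncol = 0)
  mask <- if (config$n_svg > 0) shared_mask else rep(FALSE, m)
  if (config$n_svg > 0) {
    svg <- vapply(seq_len(config$n_svg), function(j) {
      sample_svg_expression(pool, gene_mask(j), q, seed = config$seed + 10000L + j)
    }, numeric(m))
  }
  n_null <- config$n_svg * config$perm_per_svg
  nulls <- if (n_null > 0) {
    augment_null_genes(svg, n_null, seed = config$seed + 2L)
  } else {
    matrix(numeric(0), nrow = m, ncol = 0)
  }
  expr <- cbind(svg, nulls)
  gene_ids <- c(
    if (config$n_svg > 0) paste0("svg", seq_len(config$n_svg)),
    if (n_null > 0) paste0("null", seq_len(n_null))
  )
  colnames(expr) <- gene_ids
  expr <- add_noise(expr, config$sigma_mult, seed = config$seed + 3L)
  truth <- data.frame(
    gene_id = gene_ids,
    label = rep(c("SVG", "null"), c(config$n_svg, n_null)),
    pattern = config$pattern,
    stringsAsFactors = FALSE
  )
  out <- structure(
    list(
      dataset = spatial_dataset(expr, coords, gene_ids = gene_ids),
      truth = truth, marked_mask = mask, config = config
    ),
    class = "simulated_replicate"
  )
  attr(out, "centers") <- shared_centers
  out
}
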