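#' Circular moving-window disturbance density
#'
#' For every cell, the proportion of disturbed habitat within `radius`
#' meters: the mean of the binary input over all cells whose centers lie
#' within the radius of the focal cell's center. At the raster edge the
#' mean is taken over in-extent cells only (no padding), so an all-ones
#' raster maps to 1.0 everywhere. Implemented as an FFT convolution with a
#' disc kernel; results match direct window counting to numerical
#' round-off.
#'
#' @param bin a binary `grid_raster` (fine resolution).
#' @param radius window radius (m), default 1000; must be >= the cell size.
#' @return a `grid_raster` with representation `"proportion"`, carrying
#'   `meta$radius_m`.
#' @export
moving_window_density <- function(bin, radius = 1000) {
  stopifnot(inherits(bin, "grid_raster"))
  if (!all(bin$values %in% c(0, 1)))
    stop("moving_window_density() expects a binary raster", call. = FALSE)
  g <- bin$grid
  if (radius < g$cell)
    stop("window radius (", radius, " m) must be at least the cell size (",
         g$cell, " m)", call. = FALSE)
  r_cells <- floor(radius / g$cell)
  off <- -r_cells:r_cells
  disc <- outer(off, off, function(i, j) (i^2 + j^2) * g$cell^2 <= radius^2)
  disc <- disc * 1
  num <- conv2_same(bin$values, disc)
  den <- conv2_same(matrix(1, g$nrow, g$ncol), disc)
  vals <- num / den
  vals[vals < 0] <- 0            # FFT round-off
  vals[vals > 1] <- 1
  meta <- bin$meta; meta$radius_m <- radius
  grid_raster(vals, g, "proportion", meta = meta)
}

#' Normalize a disturbance-density raster to unit mass
#'
#' Divides the proportion surface by its sum so the cell values sum to 1,
#' yielding a pseudo-UD directly comparable to the animal UDs. Scale
#' invariant: doubling all proportions gives the identical mass raster.
#'
#' @param dr a `grid_raster` with representation `"proportion"`.
#' @return a `grid_raster` with representation `"mass"`; the proportion
#'   variant is retained at `meta$proportion_total` for reporting.
#' @export
normalize_mass <- function(dr) {
  stopifnot(inherits(dr, "grid_raster"))
  if (dr$representation != "proportion")
    stop("normalize_mass() expects a 'proportion' raster", call. = FALSE)
  s <- sum(dr$values)
  if (s <= 0)
    stop("zero-disturbance landscape: no mass to normalize - use the ",
         "proportion variant only", call. = FALSE)
  meta <- dr$meta; meta$proportion_total <- s
  grid_raster(dr$values / s, dr$grid, "mass", meta = meta)
}

#' Yearly disturbance surfaces on the analysis grid
#'
#' Full disturbance workflow for one year: cumulative footprint to `year`,
#' rasterized at the fine resolution, 1-km circular moving-window
#' proportion, block-mean resampled to the coarse analysis grid, and
#' normalized to a pseudo-UD.
#'
#' @param fs a `footprint_set`.
#' @param landscape a [make_landscape()] result (supplies both grids).
#' @param year cutoff year.
#' @param radius moving-window radius (m), default 1000.
#' @return list with `proportion` (coarse `grid_raster`), `mass` (pseudo-UD,
#'   `NULL` for a zero-disturbance year), `binary_fine`, and `year`.
#' @export
disturbance_surfaces <- function(fs, landscape, year, radius = 1000) {
  cum <- cumulative_footprint(fs, year)
  b <- rasterize_footprint(cum, landscape$grid_fine)
  prop_fine <- moving_window_density(b, radius)
  prop <- resample_to_grid(prop_fine, landscape$grid_coarse)
  prop$meta$year <- year
  mass <- if (sum(prop$values) > 0) normalize_mass(prop) else NULL
  list(proportion = prop, mass = mass, binary_fine = b, year = year)
}

#' Proportion of a range within a distance of disturbance
#'
#' Fraction of the range area lying within `radius` meters of any footprint
#' feature, computed on the fine raster: a cell is "near disturbance" when
#' the circular moving window around it contains any disturbed cell.
#'
#' @param fs a `footprint_set` (buffered wells; see
#'   [cumulative_footprint()]).
#' @param range_mask a binary `grid_raster` delimiting the range, or `NULL`
#'   to use the full grid extent.
#' @param g fine [grid_spec()] (required when `range_mask` is `NULL`).
#' @param radius buffer distance (m), default 1000.
#' @return fraction in \[0, 1\].
#' @export
percent_within <- function(fs, range_mask = NULL, g = NULL, radius = 1000) {
  if (is.null(range_mask)) {
    stopifnot(inherits(g, "grid_spec"))
    range_vals <- matrix(1, g$nrow, g$ncol)
  } else {
    stopifnot(inherits(range_mask, "grid_raster"))
    g <- range_mask$grid
    range_vals <- range_mask$values
  }
  n_range <- sum(range_vals)
  if (n_range == 0) stop("zero-area range", call. = FALSE)
  b <- rasterize_footprint(fs, g)
  if (sum(b$values) == 0) return(0)
  # a truly disturbed window holds at least one cell (proportion ~1e-3 at
  # r = 1 km on a 50-m grid); 1e-6 separates that from FFT round-off
  near <- moving_window_density(b, radius)$values > 1e-6
  sum(range_vals[near]) / n_range
}
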