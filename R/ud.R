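#' Plug-in bandwidths for bivariate kernel UD estimation
#'
#' Sheather-Jones direct plug-in bandwidth (Gaussian kernel), computed
#' independently for the x and y marginals, giving a diagonal bandwidth
#' pair. This is the standard "plug-in" smoothing choice for fixed-kernel
#' home-range estimation: the pilot stages assume normality and the final
#' bandwidth is optimized from the two-dimensional variance structure of
#' the data, axis by axis.
#'
#' @param x,y point coordinates (m), or `x` a two-column matrix/data.frame.
#' @return list of class `bandwidth_pair` with elements `hx`, `hy` (m).
#' @export
plugin_bandwidth <- function(x, y = NULL) {
  if (is.null(y)) {
    pts <- as.matrix(x)
    stopifnot(ncol(pts) == 2)
    x <- pts[, 1]; y <- pts[, 2]
  }
  if (length(x) < 10)
    stop("plug-in bandwidth needs at least 10 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate point cloud: zero variance on an axis", call. = FALSE)
  structure(list(hx = KernSmooth::dpik(x), hy = KernSmooth::dpik(y)),
            class = "bandwidth_pair")
}

#' @export
print.bandwidth_pair <- function(x, ...) {
  cat(sprintf("bandwidth_pair: hx = %.1f m, hy = %.1f m\n", x$hx, x$hy))
  invisible(x)
}

#' Build a snapped analysis grid around a set of points
#'
#' Master-grid rule: the bounding box of the points, padded by `pad` (>= 3x
#' the largest bandwidth so kernel mass is captured), with the origin
#' snapped down to a multiple of `cell` — so every raster built for the same
#' herd is co-registered.
#'
#' @param x,y point coordinates, or `x` a two-column matrix.
#' @param cell cell size (m), default 250.
#' @param pad padding (m) added on every side before snapping.
#' @return a [grid_spec()].
#' @export
make_ud_grid <- function(x, y = NULL, cell = 250, pad = 3000) {
  if (is.null(y)) {
    pts <- as.matrix(x); x <- pts[, 1]; y <- pts[, 2]
  }
  xmin <- floor((min(x) - pad) / cell) * cell
  ymin <- floor((min(y) - pad) / cell) * cell
  xmax <- ceiling((max(x) + pad) / cell) * cell
  ymax <- ceiling((max(y) + pad) / cell) * cell
  grid_spec(xmin, ymin, cell,
            as.integer(round((xmax - xmin) / cell)),
            as.integer(round((ymax - ymin) / cell)))
}

#' Fixed-kernel utilization distribution on a grid
#'
#' Evaluates the product-Gaussian kernel density estimate at every cell
#' center:
#' \deqn{f(c) = \frac{1}{n h_x h_y} \sum_k
#'   \phi\!\left(\frac{x_c - x_k}{h_x}\right)
#'   \phi\!\left(\frac{y_c - y_k}{h_y}\right)}
#' The cell value is the density at the cell center (midpoint rule), so the
#' raster integrates to 1 up to discretization error. Estimation is refused
#' for fewer than `min_points` locations (default 50), the conventional
#' reliability floor for kernel home ranges, and the grid must cover the
#' points padded by 3 bandwidths on every side so that the mass lost off
#' grid is negligible.
#'
#' @param points two-column matrix/data.frame of fix coordinates (m), or a
#'   telemetry data.frame with `x`, `y` columns.
#' @param bw a [plugin_bandwidth()] result (or list with `hx`, `hy`).
#' @param grid a [grid_spec()].
#' @param min_points refusal threshold (default 50).
#' @param meta provenance list stored on the raster.
#' @return a `grid_raster` with representation `"density"` ... save for
#'   discretization the values integrate to 1.
#' @export
kde_ud <- function(points, bw, grid, min_points = 50, meta = list()) {
  if (is.data.frame(points) && all(c("x", "y") %in% names(points)))
    points <- cbind(points$x, points$y)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < min_points)
    stop("UD not estimated: ", n, " locations < the ", min_points,
         "-location minimum for a reliable kernel UD", call. = FALSE)
  hx <- bw$hx; hy <- bw$hy
  stopifnot(is.finite(hx), is.finite(hy), hx > 0, hy > 0)
  pad <- 3 * max(hx, hy)
  gx0 <- grid$xmin; gx1 <- grid$xmin + grid$ncol * grid$cell
  gy0 <- grid$ymin; gy1 <- grid$ymin + grid$nrow * grid$cell
  if (min(points[, 1]) - pad < gx0 || max(points[, 1]) + pad > gx1 ||
      min(points[, 2]) - pad < gy0 || max(points[, 2]) + pad > gy1)
    stop("grid does not cover the point extent padded by 3 bandwidths; ",
         "enlarge the grid (see make_ud_grid)", call. = FALSE)
  Ax <- stats::dnorm(outer(grid_xcenters(grid), points[, 1], "-") / hx)
  Ay <- stats::dnorm(outer(grid_ycenters(grid), points[, 2], "-") / hy)
  vals <- tcrossprod(Ay, Ax) / (n * hx * hy)
  # padding adequacy: the midpoint-rule mass on the grid must be 1 +- 1e-3;
  # raw densities are kept (no renormalization) so grid values equal the
  # kernel sum at each cell center exactly
  s <- sum(vals) * cell_area_m2(grid)
  if (abs(s - 1) > 1e-3)
    stop("KDE mass on the grid is ", format(s),
         "; padding or resolution inadequate", call. = FALSE)
  grid_raster(vals, grid, "density", meta = meta)
}

#' Rescale a UD to the unit maximum
#'
#' Divides by the maximum cell value so the most-used cell equals 1 —
#' the individual-level standardization that removes sample-size and
#' fix-rate imbalance before individuals are averaged into a population UD.
#' Idempotent; all value ratios are preserved.
#'
#' @param ud a `grid_raster` (any nonnegative representation).
#' @return a `grid_raster` with representation `"scaled01"`.
#' @export
scale01 <- function(ud) {
  stopifnot(inherits(ud, "grid_raster"))
  m <- max(ud$values)
  if (m <= 0) stop("cannot scale an all-zero raster", call. = FALSE)
  grid_raster(ud$values / m, ud$grid, "scaled01", meta = ud$meta)
}

#' Population UD from scaled individual UDs
#'
#' Cell-wise mean of the 0-1 scaled individual UDs, then rescaled so the
#' cell values sum to 1 — areas used intensely by many individuals score
#' high, and the result is a probability mass surface comparable across
#' strata. Strata with a single UD are refused (a one-animal "population"
#' is excluded from analysis).
#'
#' @param uds list of `grid_raster`s with representation `"scaled01"` on one
#'   shared grid.
#' @param meta provenance list for the result.
#' @return a `grid_raster` with representation `"mass"`.
#' @export
population_ud <- function(uds, meta = list()) {
  if (length(uds) < 2)
    stop("stratum has ", length(uds), " UD(s); strata with a single UD are ",
         "excluded from population-level analysis", call. = FALSE)
  g <- uds[[1]]$grid
  for (u in uds) {
    stopifnot(inherits(u, "grid_raster"))
    if (u$representation != "scaled01")
      stop("population_ud() requires scaled01 inputs, got '",
           u$representation, "'", call. = FALSE)
    stop_if_grid_mismatch(g, u$grid, "individual UDs")
  }
  acc <- Reduce(`+`, lapply(uds, `[[`, "values")) / length(uds)
  grid_raster(acc / sum(acc), g, "mass", meta = meta)
}

#' Baseline-era UD
#'
#' Pools all individual UDs from the baseline era (default 1998-2005) for
#' one herd and season into a single reference surface, by the same
#' average-then-normalize construction as [population_ud()]. Later years are
#' compared against this surface to detect range shift.
#'
#' @param uds list of scaled01 `grid_raster`s whose `meta$year` is set.
#' @param era integer years defining the baseline (default `1998:2005`).
#' @param meta provenance list for the result.
#' @return a `grid_raster` with representation `"mass"`.
#' @export
baseline_ud <- function(uds, era = 1998:2005, meta = list()) {
  yrs <- vapply(uds, function(u) as.integer(u$meta$year %||% NA_integer_),
                1L)
  if (any(is.na(yrs)))
    stop("every UD needs meta$year to build a baseline", call. = FALSE)
  sel <- uds[yrs %in% era]
  if (length(sel) < 2)
    stop("baseline era contains ", length(sel),
         " UD(s); at least 2 are required", call. = FALSE)
  meta$era <- range(era)
  population_ud(sel, meta = meta)
}

#' Isopleth home range of a mass UD
#'
#' The smallest set of cells (by count, equivalently area) whose cumulative
#' mass reaches `level`: cells are ranked by value, descending, and the
#' shortest prefix reaching the level is taken. Ties at the boundary value
#' are broken deterministically by cell index under the default
#' `ties = "prefix"` (minimal home range); `ties = "all"` includes every
#' cell equal to the boundary value (conservative variant).
#'
#' @param ud a `grid_raster` with representation `"mass"`.
#' @param level isopleth level in (0, 1), default 0.95.
#' @param ties `"prefix"` (default, minimal) or `"all"`.
#' @return object of class `home_range`: list with `cells` (linear matrix
#'   indices), `mask` (logical matrix), `level`, `area_km2`, `grid`, `meta`.
#' @export
isopleth <- function(ud, level = 0.95, ties = c("prefix", "all")) {
  ties <- match.arg(ties)
  stopifnot(inherits(ud, "grid_raster"))
  if (ud$representation != "mass")
    stop("isopleth() requires a 'mass' UD (use as_mass())", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  v <- as.vector(ud$values)
  ord <- order(v, decreasing = TRUE)
  cs <- cumsum(v[ord])
  mstar <- which(cs >= level - 1e-12)[1]
  if (is.na(mstar)) mstar <- length(ord)
  members <- ord[seq_len(mstar)]
  if (ties == "all") {
    thr <- v[ord[mstar]]
    members <- which(v >= thr & v > 0)
  }
  mask <- matrix(FALSE, ud$grid$nrow, ud$grid$ncol)
  mask[members] <- TRUE
  structure(list(cells = sort(members), mask = mask, level = level,
                 area_km2 = length(members) * cell_area_m2(ud$grid) / 1e6,
                 grid = ud$grid, meta = ud$meta),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home_range: %d cells, %.2f km2 at the %.0f%% isopleth\n",
              length(x$cells), x$area_km2, 100 * x$level))
  invisible(x)
}

#' Individual seasonal UDs for a telemetry dataset
#'
#' Convenience wrapper running the individual-UD workflow for one stratum
#' list: per individual, clip to the season window, drop incomplete
#' deployments, apply the DOP filter, refuse < `min_points` locations, and
#' estimate the kernel UD on the shared grid.
#'
#' @param fixes telemetry data.frame (single herd).
#' @param window one row of [season_windows()] (list with `start`, `end`,
#'   `season`, `year`).
#' @param grid shared [grid_spec()].
#' @param max_dop DOP screening threshold (default 10, strict `<`).
#' @param min_points minimum locations per UD (default 50).
#' @param scaled return 0-1 scaled UDs (default TRUE).
#' @return named list of `grid_raster`s (individuals that pass the rules);
#'   attribute `"skipped"` records individuals dropped and why.
#' @export
individual_uds <- function(fixes, window, grid, max_dop = 10,
                           min_points = 50, scaled = TRUE) {
  fixes <- filter_by_dop(fixes, max_dop)
  out <- list()
  skipped <- character(0)
  for (tr in split_tracks(fixes)) {
    id <- tr$animal_id[1]
    cl <- clip_to_season(tr, window$start, window$end)
    if (!cl$complete) {
      skipped[id] <- "incomplete season coverage"
      next
    }
    if (nrow(cl$track) < min_points) {
      skipped[id] <- sprintf("%d locations < %d", nrow(cl$track), min_points)
      next
    }
    ud <- tryCatch({
      bw <- plugin_bandwidth(cl$track$x, cl$track$y)
      kde_ud(cl$track, bw, grid,
             min_points = min_points,
             meta = list(animal_id = id, season = window$season,
                         year = window$year))
    }, error = function(e) {
      skipped[id] <<- conditionMessage(e)
      NULL
    })
    if (is.null(ud)) next
    out[[id]] <- if (scaled) scale01(ud) else ud
  }
  attr(out, "skipped") <- skipped
  out
}
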