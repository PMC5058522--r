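#' Define a regular analysis grid
#'
#' A `grid_spec` describes a regular raster grid in projected coordinates
#' (meters): lower-left corner, square cell size, and dimensions. Every raster
#' operation in the package (UD estimation, disturbance density, overlap)
#' requires its inputs to share one `grid_spec`; combining rasters on
#' different grids is an error, never a silent resample.
#'
#' Cell centers are at `xmin + (j - 1/2) * cell` for column `j` (west to
#' east) and `ymin + (i - 1/2) * cell` for row `i` (south to north). Raster
#' values are stored as an `nrow x ncol` matrix with row 1 the southernmost
#' row.
#'
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cell cell side length (m), > 0.
#' @param ncol,nrow grid dimensions (cells).
#' @param crs free-form CRS identifier string (not interpreted).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(xmin, ymin, cell, ncol, nrow, crs = "local-metric") {
  stopifnot(is.numeric(cell), length(cell) == 1L, cell > 0,
            ncol >= 1L, nrow >= 1L,
            is.finite(xmin), is.finite(ymin))
  structure(list(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                 cell = as.numeric(cell),
                 ncol = as.integer(ncol), nrow = as.integer(nrow),
                 crs = as.character(crs)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m, origin (%g, %g), crs '%s'\n",
              x$nrow, x$ncol, x$cell, x$xmin, x$ymin, x$crs))
  invisible(x)
}

#' @rdname grid_spec
#' @param g a `grid_spec`.
#' @export
grid_xcenters <- function(g) g$xmin + (seq_len(g$ncol) - 0.5) * g$cell

#' @rdname grid_spec
#' @export
grid_ycenters <- function(g) g$ymin + (seq_len(g$nrow) - 0.5) * g$cell

#' @rdname grid_spec
#' @export
cell_area_m2 <- function(g) g$cell^2

#' @rdname grid_spec
#' @param a,b two `grid_spec` objects.
#' @export
same_grid <- function(a, b) {
  isTRUE(all.equal(a$xmin, b$xmin)) && isTRUE(all.equal(a$ymin, b$ymin)) &&
    isTRUE(all.equal(a$cell, b$cell)) && a$ncol == b$ncol && a$nrow == b$nrow
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what, " must share an identical grid_spec ",
         "(co-registration is required for all overlap arithmetic)",
         call. = FALSE)
  invisible(TRUE)
}

#' Construct a raster layer on a grid
#'
#' A `grid_raster` couples a value matrix to a [grid_spec()] together with a
#' declared value representation. The representation records what the numbers
#' mean and is checked on construction:
#' \describe{
#'   \item{`density`}{probability density (1/m^2); integrates to 1 over the
#'     grid (midpoint rule) within 1e-3 — kernel densities keep their raw
#'     midpoint values, so a small discretization remainder is expected.}
#'   \item{`mass`}{per-cell probability mass; sums to 1 within 1e-9.}
#'   \item{`scaled01`}{UD rescaled so the maximum cell value is 1.}
#'   \item{`proportion`}{values in \[0, 1\] (e.g. proportion disturbed).}
#'   \item{`binary`}{values in \{0, 1\}.}
#'   \item{`value`}{unconstrained continuous layer (elevation, ...).}
#'   \item{`class`}{integer category codes with a `levels` attribute.}
#' }
#'
#' @param values numeric matrix, `g$nrow` rows (south to north) by
#'   `g$ncol` columns (west to east).
#' @param g a [grid_spec()].
#' @param representation one of the representations listed above.
#' @param meta optional named list of provenance fields (id, season, year...).
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, g,
                        representation = c("value", "density", "mass",
                                           "scaled01", "proportion",
                                           "binary", "class"),
                        meta = list()) {
  representation <- match.arg(representation)
  stopifnot(inherits(g, "grid_spec"), is.matrix(values))
  if (nrow(values) != g$nrow || ncol(values) != g$ncol)
    stop("values matrix is ", nrow(values), "x", ncol(values),
         " but grid_spec declares ", g$nrow, "x", g$ncol, call. = FALSE)
  v <- values
  if (representation %in% c("density", "mass", "scaled01", "proportion",
                            "binary")) {
    if (any(!is.finite(v)) || any(v < 0))
      stop("representation '", representation,
           "' requires finite nonnegative values", call. = FALSE)
  }
  tol_chk <- switch(representation,
    density = abs(sum(v) * cell_area_m2(g) - 1) <= 1e-3,
    mass = abs(sum(v) - 1) <= 1e-9,
    scaled01 = abs(max(v) - 1) <= 1e-9,
    proportion = max(v) <= 1 + 1e-12,
    binary = all(v %in% c(0, 1)),
    TRUE)
  if (!isTRUE(tol_chk))
    stop("values violate the '", representation, "' representation invariant",
         call. = FALSE)
  structure(list(values = v, grid = g, representation = representation,
                 meta = meta),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster [%s]: %d x %d @ %g m; range [%g, %g]\n",
              x$representation, x$grid$nrow, x$grid$ncol, x$grid$cell,
              min(x$values), max(x$values)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Locate points on a grid
#'
#' Returns the row/column (and linear matrix index) of the cell containing
#' each point; points outside the grid get `NA`.
#'
#' @param g a [grid_spec()].
#' @param x,y point coordinates (m).
#' @return data.frame with columns `row`, `col`, `idx`.
#' @export
cell_of <- function(g, x, y) {
  col <- floor((x - g$xmin) / g$cell) + 1L
  row <- floor((y - g$ymin) / g$cell) + 1L
  bad <- col < 1L | col > g$ncol | row < 1L | row > g$nrow |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col, idx = (col - 1L) * g$nrow + row)
}

#' Convert a mass UD to density, or density to mass
#'
#' Representation algebra: `mass = density * cell_area`, renormalized so the
#' mass sums to one exactly (a raw midpoint-rule density may carry a
#' discretization remainder up to 1e-3); conversions round-trip up to that
#' global scalar.
#'
#' @param r a `grid_raster` with representation `mass` or `density`.
#' @return the converted `grid_raster`.
#' @export
as_density <- function(r) {
  stopifnot(inherits(r, "grid_raster"))
  if (r$representation == "density") return(r)
  if (r$representation != "mass")
    stop("as_density() requires a 'mass' raster, got '", r$representation,
         "'", call. = FALSE)
  grid_raster(r$values / cell_area_m2(r$grid), r$grid, "density",
              meta = r$meta)
}

#' @rdname as_density
#' @export
as_mass <- function(r) {
  stopifnot(inherits(r, "grid_raster"))
  if (r$representation == "mass") return(r)
  if (r$representation != "density")
    stop("as_mass() requires a 'density' raster, got '", r$representation,
         "'", call. = FALSE)
  v <- r$values * cell_area_m2(r$grid)
  grid_raster(v / sum(v), r$grid, "mass", meta = r$meta)
}

#' Block-mean resampling to a coarser co-registered grid
#'
#' Aggregates a fine raster to a coarser grid whose cell size is an integer
#' multiple of the source cell size and whose origin coincides with the
#' source origin. Each target cell takes the mean of the source cells it
#' contains, so the global mean (and hence the sum scaled by the area ratio)
#' is conserved exactly.
#'
#' @param r a `grid_raster` on the fine grid.
#' @param target a [grid_spec()] with `cell` an integer multiple of
#'   `r$grid$cell` and matching origin/extent.
#' @param representation representation tag for the result (defaults to the
#'   source's, except `binary` which aggregates to `proportion`).
#' @return a `grid_raster` on `target`.
#' @export
resample_to_grid <- function(r, target, representation = NULL) {
  stopifnot(inherits(r, "grid_raster"), inherits(target, "grid_spec"))
  src <- r$grid
  ratio <- target$cell / src$cell
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("target cell size (", target$cell,
         ") must be an integer multiple of source cell size (", src$cell, ")",
         call. = FALSE)
  ratio <- as.integer(round(ratio))
  if (abs(target$xmin - src$xmin) > 1e-6 || abs(target$ymin - src$ymin) > 1e-6)
    stop("grids are not co-registered: origins differ", call. = FALSE)
  if (src$ncol != target$ncol * ratio || src$nrow != target$nrow * ratio)
    stop("target extent does not tile the source extent (",
         src$nrow, "x", src$ncol, " cells vs ", target$nrow, "x", target$ncol,
         " blocks of ", ratio, ")", call. = FALSE)
  v <- r$values
  dim(v) <- c(ratio, target$nrow, ratio, target$ncol)
  out <- colMeans(aperm(v, c(1, 3, 2, 4)), dims = 2)
  if (is.null(representation))
    representation <- if (r$representation == "binary") "proportion"
      else r$representation
  grid_raster(out, target, representation, meta = r$meta)
}

#' Embed a raster into a larger co-registered grid
#'
#' Places a raster's values inside a target grid with the same cell size
#' and origins offset by whole cells, filling uncovered cells with `fill`.
#' Used to carry habitat masks and disturbance surfaces onto a master
#' analysis grid that extends beyond the landscape extent.
#'
#' @param r a `grid_raster`.
#' @param target a [grid_spec()] with the same cell size, offset by an
#'   integer number of cells.
#' @param fill value for target cells not covered by `r` (default 0).
#' @param representation representation tag for the result (default: keep
#'   the source's).
#' @return a `grid_raster` on `target`.
#' @export
embed_raster <- function(r, target, fill = 0, representation = NULL) {
  stopifnot(inherits(r, "grid_raster"), inherits(target, "grid_spec"))
  g <- r$grid
  if (abs(g$cell - target$cell) > 1e-9)
    stop("embed_raster() needs identical cell sizes", call. = FALSE)
  dx <- (g$xmin - target$xmin) / g$cell
  dy <- (g$ymin - target$ymin) / g$cell
  if (abs(dx - round(dx)) > 1e-6 || abs(dy - round(dy)) > 1e-6)
    stop("grids are not co-registered: origin offset is not a whole ",
         "number of cells", call. = FALSE)
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  out <- matrix(fill, target$nrow, target$ncol)
  src_r <- seq_len(g$nrow); src_c <- seq_len(g$ncol)
  tgt_r <- src_r + dy; tgt_c <- src_c + dx
  keep_r <- tgt_r >= 1L & tgt_r <= target$nrow
  keep_c <- tgt_c >= 1L & tgt_c <= target$ncol
  out[tgt_r[keep_r], tgt_c[keep_c]] <- r$values[src_r[keep_r],
                                                src_c[keep_c]]
  grid_raster(out, target, representation %||% r$representation,
              meta = r$meta)
}

#' Read and write rasters as ESRI ASCII grid files
#'
#' Plain-text single-band raster interchange (`.asc`): a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of values from the northernmost row down. The declared
#' representation is preserved in a comment-free sidecar convention: it is
#' stored in the (nonstandard but widely ignored) trailing header line
#' `representation`.
#'
#' @param r a `grid_raster`.
#' @param path file path to write to / read from.
#' @param nodata value used for NA cells (default -9999).
#' @return `write_asc` returns `path` invisibly; `read_asc` returns a
#'   `grid_raster`.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "grid_raster"))
  g <- r$grid
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$ncol),
               sprintf("nrows %d", g$nrow),
               sprintf("xllcorner %.10g", g$xmin),
               sprintf("yllcorner %.10g", g$ymin),
               sprintf("cellsize %.10g", g$cell),
               sprintf("NODATA_value %g", nodata),
               sprintf("representation %s", r$representation)), con)
  # rows written north -> south
  write.table(format(v[rev(seq_len(g$nrow)), , drop = FALSE], digits = 15,
                     trim = TRUE, scientific = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- kv[2]
    i <- i + 1L
  }
  g <- grid_spec(as.numeric(hdr$xllcorner), as.numeric(hdr$yllcorner),
                 as.numeric(hdr$cellsize),
                 as.integer(hdr$ncols), as.integer(hdr$nrows))
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = g$nrow, ncol = g$ncol, byrow = TRUE)
  m[m == as.numeric(hdr$nodata_value %||% "-9999")] <- NA
  rep <- hdr$representation %||% "value"
  grid_raster(m[rev(seq_len(g$nrow)), , drop = FALSE], g, rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 2-D "same"-size convolution of matrix x with kernel k (odd dimensions),
# zero padding outside; FFT-based. Used by the moving-window focal mean and
# landscape noise smoothing.
conv2_same <- function(x, k) {
  nrk <- nrow(k); nck <- ncol(k)
  stopifnot(nrk %% 2L == 1L, nck %% 2L == 1L)
  nr <- nrow(x) + nrk - 1L
  nc <- ncol(x) + nck - 1L
  nr2 <- stats::nextn(nr, c(2, 3, 5))
  nc2 <- stats::nextn(nc, c(2, 3, 5))
  X <- matrix(0, nr2, nc2); X[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  K <- matrix(0, nr2, nc2); K[seq_len(nrk), seq_len(nck)] <- k
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) /
    (nr2 * nc2)
  ro <- (nrk - 1L) %/% 2L
  co <- (nck - 1L) %/% 2L
  full[ro + seq_len(nrow(x)), co + seq_len(ncol(x))]
}
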