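#' Configure a synthetic mountain-foothills landscape
#'
#' The synthetic landscape emulates the physical template the analysis runs
#' on: a monotone elevation gradient from low-elevation foothills to a high
#' alpine zone, an alpine mask defined by an elevation threshold, and a
#' coarse land-cover map with conifer forest at low elevation and
#' herb/barren ("nonforest") habitat above treeline.
#'
#' @param width,height landscape extent (m); must be positive multiples of
#'   `coarse_cell`.
#' @param xmin,ymin lower-left corner (m).
#' @param fine_cell fine working resolution (m, default 50) used for
#'   rasterizing footprints and the moving-window density.
#' @param coarse_cell analysis resolution (m, default 250); must be an
#'   integer multiple of `fine_cell`.
#' @param elev_range elevation range (m a.s.l.) spanned linearly along the
#'   gradient axis, low end first.
#' @param gradient direction of increasing elevation: `"east"` (default,
#'   uphill to the east) or `"north"`.
#' @param alpine_threshold elevation (m) above which cells are alpine; must
#'   lie inside `elev_range`.
#' @param noise_sd standard deviation (m) of the smooth seeded terrain noise
#'   added to the ramp (default 20).
#' @param treeline_offset elevation (m) below `alpine_threshold` at which
#'   conifer gives way to mixed "other" cover (default 150).
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(width = 40000, height = 40000,
                             xmin = 0, ymin = 0,
                             fine_cell = 50, coarse_cell = 250,
                             elev_range = c(800, 2400),
                             gradient = c("east", "north"),
                             alpine_threshold = 1950,
                             noise_sd = 20,
                             treeline_offset = 150) {
  gradient <- match.arg(gradient)
  if (width <= 0 || height <= 0)
    stop("degenerate extent: width and height must be positive", call. = FALSE)
  if (coarse_cell %% fine_cell != 0)
    stop("coarse_cell must be an integer multiple of fine_cell", call. = FALSE)
  if (width %% coarse_cell != 0 || height %% coarse_cell != 0)
    stop("extent sides must be multiples of coarse_cell", call. = FALSE)
  if (alpine_threshold <= elev_range[1] || alpine_threshold >= elev_range[2])
    stop("alpine_threshold must lie strictly inside elev_range", call. = FALSE)
  structure(list(width = width, height = height, xmin = xmin, ymin = ymin,
                 fine_cell = fine_cell, coarse_cell = coarse_cell,
                 elev_range = elev_range, gradient = gradient,
                 alpine_threshold = alpine_threshold, noise_sd = noise_sd,
                 treeline_offset = treeline_offset),
            class = "landscape_config")
}

#' Generate a synthetic landscape
#'
#' Builds co-registered fine-resolution rasters: elevation (linear ramp along
#' the gradient axis plus smooth seeded noise), the alpine mask
#' (`elevation > alpine_threshold`), and a three-class land cover
#' (1 = conifer, 2 = nonforest, 3 = other). Land cover follows elevation
#' bands — conifer below the treeline band, nonforest above the alpine
#' threshold, a mixed band between — with seeded patch noise so class
#' boundaries are not straight lines.
#'
#' @param cfg a [landscape_config()].
#' @param seed integer RNG seed; the same seed and config give bit-identical
#'   rasters.
#' @return a list of class `landscape` with elements `elevation`, `alpine`
#'   (binary `grid_raster`s), `landcover` (class raster,
#'   levels conifer/nonforest/other), `grid_fine`, `grid_coarse`, and `cfg`.
#' @export
make_landscape <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "landscape_config"))
  nc <- as.integer(cfg$width / cfg$fine_cell)
  nr <- as.integer(cfg$height / cfg$fine_cell)
  gf <- grid_spec(cfg$xmin, cfg$ymin, cfg$fine_cell, nc, nr)
  gc_ <- grid_spec(cfg$xmin, cfg$ymin, cfg$coarse_cell,
                   as.integer(cfg$width / cfg$coarse_cell),
                   as.integer(cfg$height / cfg$coarse_cell))
  xs <- grid_xcenters(gf); ys <- grid_ycenters(gf)
  frac <- if (cfg$gradient == "east") {
    matrix((xs - cfg$xmin) / cfg$width, nr, nc, byrow = TRUE)
  } else {
    matrix((ys - cfg$ymin) / cfg$height, nr, nc)
  }
  elev <- cfg$elev_range[1] + frac * diff(cfg$elev_range)
  if (cfg$noise_sd > 0) {
    withr_seed(seed, {
      raw <- matrix(stats::rnorm(nr * nc), nr, nc)
    })
    # smooth white noise with a Gaussian kernel (~6 fine cells) to get
    # correlated terrain texture, then rescale to the requested sd
    ks <- 6
    half <- 3L * ks
    kern <- outer(stats::dnorm(-half:half, sd = ks),
                  stats::dnorm(-half:half, sd = ks))
    sm <- conv2_same(raw, kern / sum(kern))
    elev <- elev + sm * (cfg$noise_sd / stats::sd(as.vector(sm)))
  }
  alpine <- (elev > cfg$alpine_threshold) * 1
  # land cover bands with seeded patchiness
  withr_seed(seed + 1L, {
    jitter_band <- matrix(stats::rnorm(nr * nc, sd = 1), nr, nc)
  })
  jb <- conv2_same(jitter_band, {
    k <- outer(stats::dnorm(-9:9, sd = 3), stats::dnorm(-9:9, sd = 3))
    k / sum(k)
  })
  jb <- jb * (60 / stats::sd(as.vector(jb)))  # ~60 m of band jitter
  ej <- elev + jb
  lc <- matrix(1L, nr, nc)                                   # conifer
  lc[ej > cfg$alpine_threshold - cfg$treeline_offset] <- 3L  # other (mixed)
  lc[ej > cfg$alpine_threshold] <- 2L                        # nonforest
  lc_r <- grid_raster(lc + 0, gf, "class")
  attr(lc_r, "levels") <- c("conifer", "nonforest", "other")
  structure(list(elevation = grid_raster(elev, gf, "value"),
                 alpine = grid_raster(alpine, gf, "binary"),
                 landcover = lc_r,
                 grid_fine = gf, grid_coarse = gc_, cfg = cfg),
            class = "landscape")
}

#' Aggregate the alpine mask to the analysis grid
#'
#' Majority rule: a coarse cell is alpine if more than half of its fine cells
#' are alpine.
#'
#' @param ls a `landscape`.
#' @return a binary `grid_raster` on the coarse grid.
#' @export
alpine_mask_coarse <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  p <- resample_to_grid(ls$alpine, ls$grid_coarse)
  grid_raster((p$values > 0.5) * 1, ls$grid_coarse, "binary")
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
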