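#' Configure a growing disturbance-footprint scenario
#'
#' Describes how the anthropogenic footprint (forestry cutblocks, roads, oil
#' and gas well sites) accumulates on the synthetic landscape: a fixed area
#' of new features is added every year, biased toward low elevation where
#' industrial activity concentrates, and features never expire (cumulative
#' semantics — no reclamation).
#'
#' @param start_year,end_year inclusive year span of footprint growth.
#' @param annual_new_area_km2 nominal area (km2) of new features added per
#'   year.
#' @param initial_area_km2 area of features already present before
#'   `start_year` (assigned `year_created = start_year - 1`).
#' @param mix named numeric vector of area shares for `cutblock`, `road`,
#'   `well`; normalized to sum to 1.
#' @param well_buffer_km2 footprint area (km2) of one well site; wells
#'   supplied as points are buffered to squares of this area (default
#'   0.0158, the average well-pad footprint).
#' @param road_width_m width (m) used when turning road centerlines into
#'   polygons (default 20).
#' @param low_elev_quantile placement bias: feature centers are drawn from
#'   cells below this elevation quantile of the landscape (default 0.4).
#' @return a `disturbance_scenario` list.
#' @export
disturbance_scenario <- function(start_year, end_year,
                                 annual_new_area_km2 = 10,
                                 initial_area_km2 = 0,
                                 mix = c(cutblock = 0.7, road = 0.2,
                                         well = 0.1),
                                 well_buffer_km2 = 0.0158,
                                 road_width_m = 20,
                                 low_elev_quantile = 0.4) {
  stopifnot(end_year >= start_year, annual_new_area_km2 >= 0,
            initial_area_km2 >= 0, well_buffer_km2 > 0, road_width_m > 0)
  mix <- mix[c("cutblock", "road", "well")]
  mix[is.na(mix)] <- 0
  if (sum(mix) <= 0) stop("mix must have positive total", call. = FALSE)
  structure(list(start_year = start_year, end_year = end_year,
                 annual_new_area_km2 = annual_new_area_km2,
                 initial_area_km2 = initial_area_km2,
                 mix = mix / sum(mix),
                 well_buffer_km2 = well_buffer_km2,
                 road_width_m = road_width_m,
                 low_elev_quantile = low_elev_quantile),
            class = "disturbance_scenario")
}

new_footprint_set <- function(features, crs = "local-metric") {
  structure(list(features = features, crs = crs), class = "footprint_set")
}

#' @export
print.footprint_set <- function(x, ...) {
  tys <- vapply(x$features, `[[`, "", "type")
  cat("footprint_set:", length(x$features), "features (",
      paste(names(table(tys)), table(tys), sep = ":", collapse = ", "),
      ")\n")
  invisible(x)
}

#' Simulate a growing disturbance footprint
#'
#' Adds features year by year until each year's nominal new area reaches the
#' scenario target. Cutblocks are random rectangles (side 300-800 m), wells
#' are squares of `well_buffer_km2`, roads are straight centerlines
#' (1.5-3 km) carried with their width. Feature centers are sampled from the
#' low-elevation fraction of the landscape. Features persist in all later
#' years.
#'
#' @param scn a [disturbance_scenario()].
#' @param landscape a [make_landscape()] result (supplies extent and the
#'   elevation surface for placement bias).
#' @param seed integer RNG seed.
#' @return a `footprint_set`; each feature is a list with `type`
#'   (`"cutblock"|"road"|"well"`), `year_created`, `area_km2` (nominal), and
#'   geometry (`ring` 4x2 corner matrix for polygons, `xy` for well points,
#'   `line` + `width` for roads).
#' @export
simulate_footprint <- function(scn, landscape, seed = 1L) {
  stopifnot(inherits(scn, "disturbance_scenario"),
            inherits(landscape, "landscape"))
  cfg <- landscape$cfg
  ex <- c(cfg$xmin, cfg$xmin + cfg$width, cfg$ymin, cfg$ymin + cfg$height)
  elev <- landscape$elevation
  cutoff <- stats::quantile(elev$values, scn$low_elev_quantile)
  feats <- list()
  withr_seed(seed, {
    sample_center <- function(margin) {
      repeat {
        x <- stats::runif(1, ex[1] + margin, ex[2] - margin)
        y <- stats::runif(1, ex[3] + margin, ex[4] - margin)
        cc <- cell_of(elev$grid, x, y)
        if (!is.na(cc$idx) && elev$values[cc$idx] <= cutoff)
          return(c(x, y))
      }
    }
    add_year <- function(year, target_km2) {
      out <- list()
      got <- c(cutblock = 0, road = 0, well = 0)
      want <- scn$mix * target_km2
      while (sum(got) < target_km2 - 1e-9) {
        deficit <- want - got
        ty <- names(which.max(deficit))
        if (ty == "cutblock") {
          w <- stats::runif(1, 300, 800); h <- stats::runif(1, 300, 800)
          ctr <- sample_center(max(w, h) / 2)
          ring <- cbind(ctr[1] + c(-1, 1, 1, -1) * w / 2,
                        ctr[2] + c(-1, -1, 1, 1) * h / 2)
          a <- w * h / 1e6
          out[[length(out) + 1L]] <- list(type = "cutblock",
                                          year_created = year,
                                          area_km2 = a, ring = ring)
        } else if (ty == "well") {
          ctr <- sample_center(100)
          a <- scn$well_buffer_km2
          out[[length(out) + 1L]] <- list(type = "well", year_created = year,
                                          area_km2 = a,
                                          xy = ctr)
        } else {
          len <- stats::runif(1, 1500, 3000)
          ang <- stats::runif(1, 0, pi)
          ctr <- sample_center(len / 2 + scn$road_width_m)
          dxy <- c(cos(ang), sin(ang)) * len / 2
          line <- rbind(ctr - dxy, ctr + dxy)
          a <- len * scn$road_width_m / 1e6
          out[[length(out) + 1L]] <- list(type = "road", year_created = year,
                                          area_km2 = a, line = line,
                                          width = scn$road_width_m)
        }
        got[ty] <- got[ty] + a
      }
      out
    }
    if (scn$initial_area_km2 > 0)
      feats <- c(feats, add_year(scn$start_year - 1L, scn$initial_area_km2))
    if (scn$annual_new_area_km2 > 0)
      for (yr in scn$start_year:scn$end_year)
        feats <- c(feats, add_year(yr, scn$annual_new_area_km2))
  })
  new_footprint_set(feats)
}

#' Cumulative footprint up to a year
#'
#' Selects every feature created in or before `year` (features on the
#' landscape before the study span are included via their earlier
#' `year_created`) and converts well points to square polygons of
#' `well_buffer_km2`.
#'
#' @param fs a `footprint_set`.
#' @param year cutoff year (inclusive).
#' @param well_buffer_km2 area (km2) of the square buffer applied to well
#'   points (default 0.0158).
#' @return a `footprint_set` whose wells carry a `ring` polygon.
#' @export
cumulative_footprint <- function(fs, year, well_buffer_km2 = 0.0158) {
  stopifnot(inherits(fs, "footprint_set"))
  miss <- which(vapply(fs$features,
                       function(f) is.null(f$year_created) ||
                         is.na(f$year_created), TRUE))
  if (length(miss))
    stop("features without year_created: indices ",
         paste(miss, collapse = ", "), call. = FALSE)
  keep <- Filter(function(f) f$year_created <= year, fs$features)
  side <- sqrt(well_buffer_km2 * 1e6)
  keep <- lapply(keep, function(f) {
    if (f$type == "well" && is.null(f$ring)) {
      f$ring <- cbind(f$xy[1] + c(-1, 1, 1, -1) * side / 2,
                      f$xy[2] + c(-1, -1, 1, 1) * side / 2)
    }
    f
  })
  new_footprint_set(keep, fs$crs)
}

#' Rasterize a footprint to a binary grid
#'
#' Cell-center rule: a cell is disturbed (1) if its center falls inside a
#' polygon feature or within half the road width of a road centerline.
#'
#' @param fs a `footprint_set` (wells must already be buffered — see
#'   [cumulative_footprint()]).
#' @param g a [grid_spec()] at the fine working resolution.
#' @return a binary `grid_raster`.
#' @export
rasterize_footprint <- function(fs, g) {
  stopifnot(inherits(fs, "footprint_set"), inherits(g, "grid_spec"))
  m <- matrix(0, g$nrow, g$ncol)
  xs <- grid_xcenters(g); ys <- grid_ycenters(g)
  for (f in fs$features) {
    if (!is.null(f$ring)) {
      m <- mark_polygon(m, f$ring, g, xs, ys)
    } else if (f$type == "road") {
      m <- mark_line(m, f$line, f$width, g, xs, ys)
    } else if (f$type == "well") {
      stop("unbuffered well point in rasterize_footprint(); ",
           "run cumulative_footprint() first", call. = FALSE)
    }
  }
  grid_raster(m, g, "binary")
}

# mark cells whose center lies inside the polygon ring (even-odd rule)
mark_polygon <- function(m, ring, g, xs, ys) {
  cr <- range(ring[, 1]); rr <- range(ring[, 2])
  jj <- which(xs >= cr[1] & xs <= cr[2])
  ii <- which(ys >= rr[1] & ys <= rr[2])
  if (!length(jj) || !length(ii)) return(m)
  px <- ring[, 1]; py <- ring[, 2]
  nv <- length(px)
  gx <- rep(xs[jj], each = length(ii))
  gy <- rep(ys[ii], times = length(jj))
  inside <- logical(length(gx))
  j2 <- nv
  for (v in seq_len(nv)) {
    crosses <- ((py[v] > gy) != (py[j2] > gy)) &
      (gx < (px[j2] - px[v]) * (gy - py[v]) / (py[j2] - py[v]) + px[v])
    inside <- xor(inside, crosses)
    j2 <- v
  }
  idx <- cbind(rep(ii, times = length(jj)), rep(jj, each = length(ii)))
  m[idx[inside, , drop = FALSE]] <- 1
  m
}

# mark cells whose center is within width/2 of any segment of the polyline
mark_line <- function(m, line, width, g, xs, ys) {
  hw <- width / 2
  for (s in seq_len(nrow(line) - 1L)) {
    p1 <- line[s, ]; p2 <- line[s + 1L, ]
    jj <- which(xs >= min(p1[1], p2[1]) - hw & xs <= max(p1[1], p2[1]) + hw)
    ii <- which(ys >= min(p1[2], p2[2]) - hw & ys <= max(p1[2], p2[2]) + hw)
    if (!length(jj) || !length(ii)) next
    gx <- rep(xs[jj], each = length(ii))
    gy <- rep(ys[ii], times = length(jj))
    d <- p2 - p1
    len2 <- sum(d^2)
    t <- if (len2 == 0) rep(0, length(gx)) else
      pmin(1, pmax(0, ((gx - p1[1]) * d[1] + (gy - p1[2]) * d[2]) / len2))
    dist2 <- (gx - (p1[1] + t * d[1]))^2 + (gy - (p1[2] + t * d[2]))^2
    hit <- dist2 <= hw^2
    idx <- cbind(rep(ii, times = length(jj)), rep(jj, each = length(ii)))
    m[idx[hit, , drop = FALSE]] <- 1
  }
  m
}

#' Union area of a footprint (km2)
#'
#' Area of the union of all features, computed by rasterizing at a fine
#' resolution and counting disturbed cells (overlapping features are counted
#' once).
#'
#' @param fs a `footprint_set` with buffered wells.
#' @param g a fine [grid_spec()] covering the features.
#' @return area in km2.
#' @export
footprint_union_area_km2 <- function(fs, g) {
  b <- rasterize_footprint(fs, g)
  sum(b$values) * cell_area_m2(g) / 1e6
}

#' Read and write footprints as GeoJSON
#'
#' FeatureCollections with `properties = {type, year_created}` (roads also
#' carry `width_m`). Wells are Points, cutblocks (and buffered wells)
#' Polygons, roads LineStrings.
#'
#' @param fs a `footprint_set`.
#' @param path output / input file path.
#' @return `write_footprint_geojson` returns `path` invisibly;
#'   `read_footprint_geojson` returns a `footprint_set`.
#' @export
write_footprint_geojson <- function(fs, path) {
  stopifnot(inherits(fs, "footprint_set"))
  feat_json <- lapply(fs$features, function(f) {
    props <- list(type = f$type, year_created = f$year_created)
    if (!is.null(f$width)) props$width_m <- f$width
    geom <- if (!is.null(f$ring)) {
      ring <- rbind(f$ring, f$ring[1, , drop = FALSE])
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(i) unname(ring[i, ]))))
    } else if (!is.null(f$line)) {
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(f$line)),
                                function(i) unname(f$line[i, ])))
    } else {
      list(type = "Point", coordinates = unname(f$xy))
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat_json),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_footprint_geojson
#' @export
read_footprint_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  feats <- lapply(j$features, function(ft) {
    p <- ft$properties
    g <- ft$geometry
    out <- list(type = p$type, year_created = p$year_created)
    if (identical(g$type, "Point")) {
      out$xy <- as.numeric(unlist(g$coordinates))
    } else if (identical(g$type, "LineString")) {
      out$line <- do.call(rbind, lapply(g$coordinates, as.numeric))
      out$width <- p$width_m %||% 20
    } else if (identical(g$type, "Polygon")) {
      ring <- do.call(rbind, lapply(g$coordinates[[1]], as.numeric))
      if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
        ring <- ring[-nrow(ring), , drop = FALSE]
      out$ring <- ring
    } else stop("unsupported GeoJSON geometry: ", g$type, call. = FALSE)
    out
  })
  new_footprint_set(feats)
}
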