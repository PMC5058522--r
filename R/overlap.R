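#' PHR: probability mass of a UD inside a region
#'
#' The volume of UD `i` integrated over a two-dimensional region (another
#' UD's home range, the disturbance footprint zone, a habitat mask): the sum
#' of the UD's cell masses over the masked cells. Directional, in \[0, 1\],
#' and monotone in the mask.
#'
#' @param ud a `grid_raster` with representation `"mass"`.
#' @param region logical/binary mask: a logical matrix, a binary
#'   `grid_raster`, or a `home_range`.
#' @return fraction in \[0, 1\].
#' @export
phr <- function(ud, region) {
  stopifnot(inherits(ud, "grid_raster"))
  if (ud$representation != "mass")
    stop("phr() requires a 'mass' UD", call. = FALSE)
  mask <- region_mask(region, ud$grid)
  sum(ud$values[mask])
}

# coerce the region argument to a logical matrix on grid g
region_mask <- function(region, g) {
  if (inherits(region, "home_range")) {
    stop_if_grid_mismatch(region$grid, g, "home range and UD")
    return(region$mask)
  }
  if (inherits(region, "grid_raster")) {
    stop_if_grid_mismatch(region$grid, g, "mask and UD")
    return(region$values > 0)
  }
  if (is.matrix(region)) {
    if (nrow(region) != g$nrow || ncol(region) != g$ncol)
      stop("mask dimensions do not match the grid", call. = FALSE)
    return(region > 0)
  }
  stop("unsupported region type: ", paste(class(region), collapse = "/"),
       call. = FALSE)
}

#' Derive a comparison region from a UD or density surface
#'
#' Standard region rules for overlap comparisons: the 95% isopleth of a
#' baseline UD, the any-disturbance zone of a disturbance proportion raster
#' (cells with proportion > 0, i.e. within the window radius of a feature),
#' or a habitat mask passed through unchanged.
#'
#' @param x a `grid_raster` (mass UD, proportion raster, or binary mask).
#' @param rule `"isopleth"`, `"nonzero"`, or `"mask"`.
#' @param level isopleth level (default 0.95) for `rule = "isopleth"`.
#' @param zero_tol support guard: values at or below this are treated as
#'   zero (default 1e-12 for mass surfaces; use 1e-6 for FFT-derived
#'   proportion surfaces).
#' @return logical matrix mask.
#' @export
region_from_ud <- function(x, rule = c("isopleth", "nonzero", "mask"),
                           level = 0.95, zero_tol = 1e-12) {
  rule <- match.arg(rule)
  stopifnot(inherits(x, "grid_raster"))
  switch(rule,
         isopleth = isopleth(x, level)$mask,
         nonzero = x$values > zero_tol,
         mask = x$values > 0)
}

#' UDOI: utilization distribution overlap index
#'
#' Nondirectional overlap between two UDs: the area of the region where
#' both occur times the integral of the product of their densities,
#' \deqn{UDOI = A_{ij} \sum_c f_i(c) f_j(c) a,}
#' with `a` the cell area and `A_ij` the intersection area of the two
#' supports (or of the two 95% isopleth home ranges with
#' `region = "isopleth"`). Equals 1 for two uniform UDs over the same
#' region, 0 for disjoint UDs, and exceeds 1 for coincident strongly
#' nonuniform UDs. Exactly symmetric in its arguments.
#'
#' @param ud_i,ud_j `grid_raster`s with representation `"mass"` on one grid.
#' @param region `"support"` (default) or `"isopleth"` — the rule defining
#'   the overlap area `A_ij`.
#' @param level isopleth level when `region = "isopleth"`.
#' @param zero_tol masses at or below this count as unoccupied when
#'   determining supports (default 1e-12).
#' @return nonnegative number.
#' @export
udoi <- function(ud_i, ud_j, region = c("support", "isopleth"),
                 level = 0.95, zero_tol = 1e-12) {
  region <- match.arg(region)
  stopifnot(inherits(ud_i, "grid_raster"), inherits(ud_j, "grid_raster"))
  if (ud_i$representation != "mass" || ud_j$representation != "mass")
    stop("udoi() requires 'mass' UDs", call. = FALSE)
  stop_if_grid_mismatch(ud_i$grid, ud_j$grid, "the two UDs")
  a <- cell_area_m2(ud_i$grid)
  inter <- if (region == "support") {
    (ud_i$values > zero_tol) & (ud_j$values > zero_tol)
  } else {
    isopleth(ud_i, level)$mask & isopleth(ud_j, level)$mask
  }
  A_ij <- sum(inter) * a
  if (A_ij == 0) return(0)
  fi <- ud_i$values / a
  fj <- ud_j$values / a
  A_ij * sum(fi * fj) * a
}

#' Overlap records for all strata
#'
#' Builds the long-format table of overlap indices between population UDs
#' and (a) the yearly disturbance pseudo-UD, (b) the baseline-era UD, and
#' (c) the alpine habitat mask: PHR against all three targets, UDOI against
#' disturbance and baseline. Baseline comparisons are restricted to the
#' contemporary era (default 2006-2013); years with no disturbance surface
#' are skipped with a warning.
#'
#' @param pop_uds list of population `grid_raster`s (mass) whose `meta`
#'   carries `herd`, `season`, `year`.
#' @param disturbance named list (by year, as character) of disturbance
#'   lists from [disturbance_surfaces()] (or of mass rasters).
#' @param baselines named list of baseline mass UDs, keyed
#'   `"<herd>.<season>"`.
#' @param alpine binary `grid_raster` on the same grid (or `NULL` to skip).
#' @param contemporary_era years eligible for baseline comparison (default
#'   `2006:2013`).
#' @param isopleth_level level defining the baseline home-range region.
#' @return data.frame: `herd`, `season`, `year`, `index` (`PHR`/`UDOI`),
#'   `target` (`disturbance`/`baseline`/`alpine`), `value`.
#' @export
overlap_table <- function(pop_uds, disturbance = list(), baselines = list(),
                          alpine = NULL, contemporary_era = 2006:2013,
                          isopleth_level = 0.95) {
  rec <- list()
  add <- function(herd, season, year, index, target, value)
    rec[[length(rec) + 1L]] <<- data.frame(
      herd = herd, season = season, year = year, index = index,
      target = target, value = value, stringsAsFactors = FALSE)
  # cache baseline isopleth masks
  bl_mask <- lapply(baselines, function(b)
    region_from_ud(b, "isopleth", isopleth_level))
  alpine_mask <- if (!is.null(alpine)) region_mask(alpine, alpine$grid)
  for (ud in pop_uds) {
    herd <- ud$meta$herd %||% "all"
    season <- ud$meta$season %||% "all"
    year <- ud$meta$year
    if (is.null(year)) stop("population UD lacks meta$year", call. = FALSE)
    # disturbance
    d <- disturbance[[as.character(year)]]
    if (is.null(d)) {
      if (length(disturbance))
        warning("no disturbance surface for year ", year,
                "; records skipped")
    } else {
      dprop <- if (is.list(d) && !inherits(d, "grid_raster")) d$proportion
        else d
      dmass <- if (is.list(d) && !inherits(d, "grid_raster")) d$mass else d
      dmask <- region_from_ud(dprop, "nonzero", zero_tol = 1e-6)
      add(herd, season, year, "PHR", "disturbance", phr(ud, dmask))
      if (!is.null(dmass))
        add(herd, season, year, "UDOI", "disturbance", udoi(ud, dmass))
    }
    # alpine
    if (!is.null(alpine_mask))
      add(herd, season, year, "PHR", "alpine", phr(ud, alpine_mask))
    # baseline (contemporary years only)
    bl <- baselines[[paste(herd, season, sep = ".")]]
    if (!is.null(bl) && year %in% contemporary_era) {
      add(herd, season, year, "PHR", "baseline",
          phr(ud, bl_mask[[paste(herd, season, sep = ".")]]))
      add(herd, season, year, "UDOI", "baseline", udoi(ud, bl))
    }
  }
  if (!length(rec))
    return(data.frame(herd = character(), season = character(),
                      year = integer(), index = character(),
                      target = character(), value = numeric()))
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}
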