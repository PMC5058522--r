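#' End-to-end distribution-shift experiment on synthetic data
#'
#' One replicate of the full inference chain on a simulated study system:
#' simulate multi-year migratory telemetry with a known winter-range shift
#' rate, filter by DOP, build individual and population UDs for one focal
#' season on the shared analysis grid, pool the baseline era, compute the
#' overlap table (PHR against alpine and baseline, UDOI against baseline,
#' optionally the disturbance indices), and regress each series on year and
#' the climate index. With `shift_rate = 0` the year terms are null; with a
#' strong shift the PHR(alpine) slope is positive and the UDOI(baseline)
#' slope negative — the ground truth used to calibrate detection power and
#' type-I error.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param shift_rate winter-range displacement toward alpine (m/yr).
#' @param n_individuals collared individuals per herd per year.
#' @param years study years (default 1998:2013).
#' @param herds herd names (default two herds).
#' @param landscape optional prebuilt [make_landscape()] (rebuilt from
#'   `landscape_seed` when `NULL`); replicates can share one landscape.
#' @param season focal season label from [default_season_schedule()].
#' @param baseline_era,contemporary_era year ranges for the baseline UD and
#'   for baseline comparisons.
#' @param scenario optional [disturbance_scenario()]; when supplied the
#'   disturbance overlap indices are computed as well.
#' @param r_npi sample correlation of the climate index with year.
#' @param fix_interval_h hours between fixes (default 8).
#' @param landscape_seed seed for the default landscape.
#' @return list: `overlap` (records), `climate`, `trends` (per-series OLS
#'   table), `n_uds`, `strata_skipped`.
#' @export
shift_experiment <- function(seed, shift_rate = 0, n_individuals = 20,
                             years = 1998:2013, herds = c("NAR", "RPC"),
                             landscape = NULL, season = "late_winter",
                             baseline_era = 1998:2005,
                             contemporary_era = 2006:2013,
                             scenario = NULL, r_npi = 0.56,
                             fix_interval_h = 8, landscape_seed = 99L) {
  if (is.null(landscape))
    landscape <- make_landscape(landscape_config(), seed = landscape_seed)
  move <- movement_config(n_individuals = n_individuals, years = years,
                          herds = herds, shift_rate = shift_rate,
                          fix_interval_h = fix_interval_h,
                          deployment_years = 1)
  fixes <- simulate_tracks(move, landscape, seed = seed)
  fixes <- filter_by_dop(fixes, 10)
  climate <- simulate_climate(years, r_with_year = r_npi, seed = seed + 1L)
  schedule <- move$season_schedule
  part <- list(onsets = schedule$onset, labels = schedule$season)
  # master grid: fixes padded well beyond 3x any plausible bandwidth,
  # snapped to the cell size so it stays co-registered with the landscape
  grid <- make_ud_grid(fixes$x, fixes$y,
                       cell = landscape$cfg$coarse_cell, pad = 6000)
  alp <- embed_raster(alpine_mask_coarse(landscape), grid)
  disturbance <- list()
  if (!is.null(scenario)) {
    fp <- simulate_footprint(scenario, landscape, seed = seed + 2L)
    for (yr in years) {
      d <- disturbance_surfaces(fp, landscape, yr)
      prop <- embed_raster(d$proportion, grid)
      disturbance[[as.character(yr)]] <-
        list(proportion = prop,
             mass = if (sum(prop$values) > 0) normalize_mass(prop),
             year = yr)
    }
  }
  pop_uds <- list()
  baselines <- list()
  n_uds <- 0L
  skipped <- character(0)
  for (h in herds) {
    hf <- fixes[fixes$herd == h, , drop = FALSE]
    herd_ind_uds <- list()
    for (yr in years) {
      win <- season_windows(part, yr)
      win <- win[win$season == season, ]
      sel <- hf$timestamp >= win$start - 86400 & hf$timestamp < win$end + 86400
      iuds <- individual_uds(hf[sel, , drop = FALSE], as.list(win), grid)
      n_uds <- n_uds + length(iuds)
      if (length(iuds) < 2) {
        skipped <- c(skipped, sprintf("%s/%s/%d: %d UD(s)", h, season, yr,
                                      length(iuds)))
        next
      }
      pop_uds[[sprintf("%s.%s.%d", h, season, yr)]] <-
        population_ud(iuds, meta = list(herd = h, season = season,
                                        year = yr))
      herd_ind_uds <- c(herd_ind_uds, iuds)
    }
    yrs <- vapply(herd_ind_uds, function(u) u$meta$year, 0L)
    if (sum(yrs %in% baseline_era) >= 2)
      baselines[[paste(h, season, sep = ".")]] <-
        baseline_ud(herd_ind_uds, era = baseline_era,
                    meta = list(herd = h, season = season))
  }
  ov <- overlap_table(pop_uds, disturbance = disturbance,
                      baselines = baselines, alpine = alp,
                      contemporary_era = contemporary_era)
  tr <- overlap_trends(ov, climate)
  list(overlap = ov, climate = climate, trends = tr, n_uds = n_uds,
       strata_skipped = skipped)
}

#' Extract one slope row from an experiment's trend table
#'
#' @param trends the `trends` element of [shift_experiment()].
#' @param herd,index,target series selectors.
#' @param term coefficient of interest (default `"year"`).
#' @return one-row data.frame (beta, se, ci, supported) or `NULL`.
#' @export
trend_slope <- function(trends, herd, index, target, term = "year") {
  if (is.null(trends)) return(NULL)
  r <- trends[trends$herd == herd & trends$index == index &
                trends$target == target & trends$term == term, ,
              drop = FALSE]
  if (!nrow(r)) NULL else r
}
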