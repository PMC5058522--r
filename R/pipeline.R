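#' Build a run configuration
#'
#' Assembles (and defaults) the configuration for [run_pipeline()]. An
#' empty call yields a complete small synthetic run. All defaults mirror
#' the analysis conventions used throughout the package: 250-m analysis
#' cells, 1-km moving window, 95% isopleths, strict DOP < 10, 50-location
#' minimum, disjoint baseline and contemporary eras.
#'
#' @param ... named overrides of the defaults (nested lists are merged
#'   shallowly per block: `landscape`, `movement`, `disturbance`,
#'   `climate`).
#' @return a `run_config` list (not yet validated).
#' @export
run_config <- function(...) {
  base <- list(
    seed = 1L,
    out_dir = "udshift_run",
    telemetry_csv = NULL,        # load fixes instead of simulating
    footprint_geojson = NULL,    # load footprint instead of simulating
    landscape = list(width = 20000, height = 20000, fine_cell = 50,
                     coarse_cell = 250, alpine_threshold = 1950),
    movement = list(n_individuals = 6, years = c(2000L, 2007L),
                    herds = "A", shift_rate = 0, deployment_years = 2,
                    fix_interval_h = 8),
    disturbance = list(annual_new_area_km2 = 3, initial_area_km2 = 5),
    climate = list(r_with_year = 0.56),
    season_source = "segment",   # or "schedule"
    season_k = 6,
    baseline_era = NULL,         # default: first half of the study years
    contemporary_era = NULL,     # default: second half
    max_dop = 10,
    min_points = 50,
    isopleth_level = 0.95,
    window_radius_m = 1000,
    write_rasters = FALSE)
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(base[[nm]]) && is.list(ov[[nm]]) &&
        !is.null(names(ov[[nm]]))) {
      for (k in names(ov[[nm]])) base[[nm]][[k]] <- ov[[nm]][[k]]
    } else base[[nm]] <- ov[[nm]]
  }
  structure(base, class = "run_config")
}

#' Validate and normalize a run configuration
#'
#' Checks units, paths, and era consistency, fills derived defaults
#' (baseline = first half of the study years, contemporary = second half),
#' and returns every problem found at once rather than failing on the
#' first.
#'
#' @param cfg a [run_config()] (or plain list, e.g. parsed from YAML).
#' @return list with `config` (normalized) and `errors` (character vector,
#'   empty when valid).
#' @export
validate_config <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, cfg)
  errs <- character(0)
  yrs <- cfg$movement$years
  if (length(yrs) == 2) yrs <- yrs[1]:yrs[2]
  cfg$movement$years <- yrs
  if (!is.null(cfg$telemetry_csv) && !file.exists(cfg$telemetry_csv))
    errs <- c(errs, paste0("telemetry_csv not found: ", cfg$telemetry_csv))
  if (!is.null(cfg$footprint_geojson) &&
      !file.exists(cfg$footprint_geojson))
    errs <- c(errs, paste0("footprint_geojson not found: ",
                           cfg$footprint_geojson))
  if (is.null(cfg$baseline_era)) {
    half <- floor(length(yrs) / 2)
    cfg$baseline_era <- yrs[seq_len(half)]
  } else if (length(cfg$baseline_era) == 2) {
    cfg$baseline_era <- cfg$baseline_era[1]:cfg$baseline_era[2]
  }
  if (is.null(cfg$contemporary_era)) {
    cfg$contemporary_era <- setdiff(yrs, cfg$baseline_era)
  } else if (length(cfg$contemporary_era) == 2) {
    cfg$contemporary_era <- cfg$contemporary_era[1]:cfg$contemporary_era[2]
  }
  if (length(intersect(cfg$baseline_era, cfg$contemporary_era)))
    errs <- c(errs, "baseline and contemporary eras overlap")
  if (length(cfg$baseline_era) && length(cfg$contemporary_era) &&
      max(cfg$baseline_era) > min(cfg$contemporary_era))
    errs <- c(errs, "baseline era must precede the contemporary era")
  if (!cfg$season_source %in% c("segment", "schedule"))
    errs <- c(errs, "season_source must be 'segment' or 'schedule'")
  if (cfg$max_dop <= 0) errs <- c(errs, "max_dop must be positive")
  if (cfg$isopleth_level <= 0 || cfg$isopleth_level >= 1)
    errs <- c(errs, "isopleth_level must be in (0, 1)")
  if (cfg$window_radius_m < cfg$landscape$fine_cell)
    errs <- c(errs, "window_radius_m must be at least the fine cell size")
  list(config = cfg, errors = errs)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end workflow from one configuration:
#' simulate-or-load inputs, DOP filtering, season delineation, individual /
#' population / baseline UDs, yearly disturbance surfaces, the overlap
#' table, individual metrics, and trend models. Writes CSV/YAML/GeoJSON
#' outputs plus a reproducibility manifest (config digest, seeds, package
#' version, per-stage record counts) to `cfg$out_dir`. Any stage failure
#' aborts with the stage name; outputs of completed stages are retained.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the in-memory products (`fixes`,
#'   `seasons`, `pop_uds`, `baselines`, `overlap`, `metrics`,
#'   `trends_overlap`, `trends_metrics`, `manifest`).
#' @export
run_pipeline <- function(cfg = run_config()) {
  val <- validate_config(cfg)
  if (length(val$errors))
    stop("invalid configuration:\n  - ",
         paste(val$errors, collapse = "\n  - "), call. = FALSE)
  cfg <- val$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("udshift")),
                   seed = cfg$seed, stages = list())
  stage <- function(name, code) {
    res <- tryCatch(force(code), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }
  note <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config.yaml"))
  manifest$config_md5 <-
    unname(tools::md5sum(file.path(cfg$out_dir, "config.yaml")))

  ## stage 1: inputs (simulate or load)
  inputs <- stage("inputs", {
    ls_cfg <- do.call(landscape_config, cfg$landscape)
    landscape <- make_landscape(ls_cfg, seed = cfg$seed)
    if (is.null(cfg$telemetry_csv)) {
      mv <- cfg$movement
      move <- movement_config(
        n_individuals = mv$n_individuals, years = mv$years,
        herds = mv$herds, shift_rate = mv$shift_rate,
        deployment_years = mv$deployment_years,
        fix_interval_h = mv$fix_interval_h)
      fixes <- simulate_tracks(move, landscape, seed = cfg$seed + 1L)
      write_telemetry(fixes, file.path(cfg$out_dir, "telemetry.csv"))
    } else {
      fixes <- read_telemetry(cfg$telemetry_csv)
      if (!"herd" %in% names(fixes)) fixes$herd <- "all"
    }
    if (is.null(cfg$footprint_geojson)) {
      scn <- disturbance_scenario(
        start_year = min(cfg$movement$years),
        end_year = max(cfg$movement$years),
        annual_new_area_km2 = cfg$disturbance$annual_new_area_km2,
        initial_area_km2 = cfg$disturbance$initial_area_km2)
      fp <- simulate_footprint(scn, landscape, seed = cfg$seed + 2L)
      write_footprint_geojson(fp, file.path(cfg$out_dir,
                                            "footprint.geojson"))
    } else {
      fp <- read_footprint_geojson(cfg$footprint_geojson)
    }
    climate <- simulate_climate(cfg$movement$years,
                                r_with_year = cfg$climate$r_with_year,
                                seed = cfg$seed + 3L)
    utils::write.csv(climate, file.path(cfg$out_dir, "climate.csv"),
                     row.names = FALSE)
    list(landscape = landscape, fixes = fixes, footprint = fp,
         climate = climate)
  })
  note("inputs", fixes_read = nrow(inputs$fixes),
       individuals = length(unique(inputs$fixes$animal_id)),
       footprint_features = length(inputs$footprint$features))

  ## stage 2: DOP filter
  fixes <- stage("dop_filter",
                 filter_by_dop(inputs$fixes, cfg$max_dop))
  note("dop_filter", fixes_in = nrow(inputs$fixes),
       fixes_kept = nrow(fixes))
  # master analysis grid: all fixes padded generously beyond 3x any
  # plausible bandwidth, snapped so landscape rasters embed exactly
  master_grid <- make_ud_grid(fixes$x, fixes$y,
                              cell = cfg$landscape$coarse_cell, pad = 6000)

  ## stage 3: season delineation
  seasons <- stage("seasons", {
    if (cfg$season_source == "segment") {
      delineate_seasons(fixes, k = cfg$season_k)
    } else {
      sched <- default_season_schedule()
      parts <- lapply(unique(fixes$herd), function(h)
        structure(list(onsets = sched$onset, labels = sched$season,
                       k = nrow(sched), method = "schedule",
                       per_individual = list()),
                  class = "season_partition"))
      names(parts) <- unique(fixes$herd)
      parts
    }
  })
  yaml::write_yaml(
    lapply(seasons, function(p)
      list(onset_doy = as.numeric(round(p$onsets, 1)),
           season = as.character(p$labels))),
    file.path(cfg$out_dir, "seasons.yaml"))
  note("seasons", herds = length(seasons),
       k = unique(vapply(seasons, function(p) length(p$onsets), 0L)))

  ## stage 4: UDs (individual, population, baseline)
  uds <- stage("uds", {
    pop_uds <- list(); baselines <- list()
    n_ind_uds <- 0L; skipped <- character(0)
    years <- sort(unique(as.POSIXlt(fixes$timestamp)$year + 1900L))
    for (h in names(seasons)) {
      hf <- fixes[fixes$herd == h, , drop = FALSE]
      # master grid: all fixes padded generously, snapped to the cell size
      # so habitat and disturbance rasters embed exactly
      grid <- master_grid
      herd_ind <- list()
      for (yr in years) {
        wins <- season_windows(seasons[[h]], yr)
        for (w in seq_len(nrow(wins))) {
          win <- as.list(wins[w, ])
          sel <- hf$timestamp >= win$start - 86400 &
            hf$timestamp < win$end + 86400
          iuds <- individual_uds(hf[sel, , drop = FALSE], win, grid,
                                 max_dop = Inf,
                                 min_points = cfg$min_points)
          n_ind_uds <- n_ind_uds + length(iuds)
          if (length(iuds) < 2) {
            skipped <- c(skipped,
                         sprintf("%s/%s/%d: %d UD(s)", h, win$season, yr,
                                 length(iuds)))
            next
          }
          key <- sprintf("%s.%s.%d", h, win$season, yr)
          pop_uds[[key]] <- population_ud(
            iuds, meta = list(herd = h, season = win$season, year = yr))
          herd_ind[[win$season]] <- c(herd_ind[[win$season]], iuds)
        }
      }
      for (sn in names(herd_ind)) {
        yrs_i <- vapply(herd_ind[[sn]], function(u) u$meta$year, 0L)
        if (sum(yrs_i %in% cfg$baseline_era) >= 2)
          baselines[[paste(h, sn, sep = ".")]] <-
            baseline_ud(herd_ind[[sn]], era = cfg$baseline_era,
                        meta = list(herd = h, season = sn))
      }
    }
    list(pop_uds = pop_uds, baselines = baselines, n_ind_uds = n_ind_uds,
         skipped = skipped, individual = NULL)
  })
  note("uds", individual_uds = uds$n_ind_uds,
       population_uds = length(uds$pop_uds),
       baselines = length(uds$baselines),
       strata_skipped = length(uds$skipped))

  ## stage 5: disturbance surfaces (every year the telemetry touches)
  disturbance <- stage("disturbance", {
    yrs <- sort(unique(as.POSIXlt(fixes$timestamp)$year + 1900L))
    out <- list()
    for (yr in yrs)
      out[[as.character(yr)]] <-
        disturbance_surfaces(inputs$footprint, inputs$landscape, yr,
                             radius = cfg$window_radius_m)
    out
  })
  note("disturbance", years = length(disturbance))
  disturbance_m <- lapply(disturbance, function(d) {
    prop <- embed_raster(d$proportion, master_grid)
    list(proportion = prop,
         mass = if (sum(prop$values) > 0) normalize_mass(prop),
         year = d$year)
  })

  ## stage 6: overlap table
  overlap <- stage("overlap", {
    alp <- embed_raster(alpine_mask_coarse(inputs$landscape), master_grid)
    overlap_table(uds$pop_uds, disturbance = disturbance_m,
                  baselines = uds$baselines, alpine = alp,
                  contemporary_era = cfg$contemporary_era,
                  isopleth_level = cfg$isopleth_level)
  })
  utils::write.csv(overlap, file.path(cfg$out_dir, "overlap.csv"),
                   row.names = FALSE)
  note("overlap", records = nrow(overlap))

  ## stage 7: metrics and trends
  results <- stage("trends", {
    metrics <- metrics_table(fixes, seasons, inputs$landscape,
                             disturbance_m, inputs$climate, cfg,
                             grid = master_grid)
    utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
    t_ov <- overlap_trends(overlap, inputs$climate)
    if (!is.null(t_ov))
      utils::write.csv(t_ov, file.path(cfg$out_dir, "trends_overlap.csv"),
                       row.names = FALSE)
    t_mx <- metric_trends(metrics)
    if (!is.null(t_mx))
      utils::write.csv(t_mx, file.path(cfg$out_dir, "trends_metrics.csv"),
                       row.names = FALSE)
    list(metrics = metrics, trends_overlap = t_ov, trends_metrics = t_mx)
  })
  note("trends",
       metric_records = nrow(results$metrics),
       overlap_trend_rows = if (is.null(results$trends_overlap)) 0L
         else nrow(results$trends_overlap),
       metric_trend_rows = if (is.null(results$trends_metrics)) 0L
         else nrow(results$trends_metrics))

  if (isTRUE(cfg$write_rasters)) {
    rdir <- file.path(cfg$out_dir, "rasters")
    dir.create(rdir, showWarnings = FALSE)
    for (key in names(uds$pop_uds))
      write_asc(uds$pop_uds[[key]],
                file.path(rdir, paste0("ud_", key, ".asc")))
    for (yr in names(disturbance))
      if (!is.null(disturbance[[yr]]$mass))
        write_asc(disturbance[[yr]]$mass,
                  file.path(rdir, paste0("disturbance_", yr, ".asc")))
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fixes = fixes, seasons = seasons, pop_uds = uds$pop_uds,
                 baselines = uds$baselines, overlap = overlap,
                 metrics = results$metrics,
                 trends_overlap = results$trends_overlap,
                 trends_metrics = results$trends_metrics,
                 manifest = manifest))
}

#' Individual metric records for mixed-model trend analysis
#'
#' One record per individual x season x year that passes the completeness
#' and sample-size rules: season-mean daily movement rate, 95% isopleth
#' home-range size, mean elevation and land-cover proportions at the fixes,
#' proportion of the home range disturbed, and the year's climate index.
#' The extreme home-range-size outlier rule is applied per herd x season.
#'
#' @param fixes DOP-filtered telemetry.
#' @param seasons named list of `season_partition`s by herd.
#' @param landscape a [make_landscape()] result.
#' @param disturbance named list of [disturbance_surfaces()] by year.
#' @param climate data.frame `year`, `npi`.
#' @param cfg a validated [run_config()].
#' @param grid analysis [grid_spec()] for the individual UDs (default: the
#'   landscape's coarse grid); disturbance surfaces must share it.
#' @return data.frame of metric records.
#' @export
metrics_table <- function(fixes, seasons, landscape, disturbance, climate,
                          cfg = run_config(), grid = NULL) {
  rec <- list()
  if (is.null(grid)) grid <- landscape$grid_coarse
  years <- sort(unique(as.POSIXlt(fixes$timestamp)$year + 1900L))
  for (h in names(seasons)) {
    hf <- fixes[fixes$herd == h, , drop = FALSE]
    for (yr in years) {
      wins <- season_windows(seasons[[h]], yr)
      d <- disturbance[[as.character(yr)]]
      for (w in seq_len(nrow(wins))) {
        win <- as.list(wins[w, ])
        sel <- hf$timestamp >= win$start - 86400 &
          hf$timestamp < win$end + 86400
        iuds <- individual_uds(hf[sel, , drop = FALSE], win, grid,
                               max_dop = Inf, min_points = cfg$min_points,
                               scaled = FALSE)
        for (id in names(iuds)) {
          tr <- clip_to_season(hf[hf$animal_id == id & sel, , drop = FALSE],
                               win$start, win$end)$track
          hr <- isopleth(as_mass(iuds[[id]]), cfg$isopleth_level)
          um <- extract_use_metrics(tr, landscape$elevation,
                                    landscape$landcover)
          dfrac <- if (!is.null(d))
            home_range_disturbed_fraction(hr, d$proportion) else NA_real_
          rec[[length(rec) + 1L]] <- data.frame(
            animal_id = id, herd = h, season = win$season, year = yr,
            movement_rate_kmd = um$movement_rate_kmd,
            hr_km2 = hr$area_km2,
            mean_elevation_m = um$mean_elevation_m,
            prop_conifer = um$prop_conifer,
            prop_nonforest = um$prop_nonforest,
            dist_frac = dfrac,
            npi = climate$npi[match(yr, climate$year)],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rec)) return(NULL)
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  # extreme home-range outliers screened within herd x season
  keys <- unique(out[, c("herd", "season")])
  kept <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- out[out$herd == keys$herd[i] & out$season == keys$season[i], ,
               drop = FALSE]
    if (nrow(sub) >= 3) sub <- remove_hr_outlier(sub, "hr_km2")
    kept[[i]] <- sub
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

#' Mixed-model trends for every herd x season x response
#'
#' Fits [lmm_trend()] (year + climate + home-range disturbance, random
#' intercept per individual) for each individual-level response, skipping
#' strata without enough repeated measures.
#'
#' @param metrics data.frame from [metrics_table()].
#' @param responses response columns to model.
#' @param terms fixed-effect terms.
#' @return data.frame of tidy coefficients or `NULL`.
#' @export
metric_trends <- function(metrics,
                          responses = c("movement_rate_kmd", "hr_km2",
                                        "mean_elevation_m", "prop_conifer",
                                        "prop_nonforest"),
                          terms = c("year", "npi", "dist_frac")) {
  if (is.null(metrics)) return(NULL)
  out <- list()
  keys <- unique(metrics[, c("herd", "season")])
  for (i in seq_len(nrow(keys))) {
    sub <- metrics[metrics$herd == keys$herd[i] &
                     metrics$season == keys$season[i], , drop = FALSE]
    tt <- terms[vapply(terms, function(t) !all(is.na(sub[[t]])), TRUE)]
    tab <- table(sub$animal_id)
    if (length(tab) < 2 || sum(tab >= 2) < 2 ||
        nrow(sub) < length(tt) + 3) next
    for (resp in responses) {
      # small strata can emit optimizer chatter; singular fits are still
      # reported via the flag column
      tr <- tryCatch(suppressWarnings(suppressMessages(
        lmm_trend(sub, resp, tt))), error = function(e) NULL)
      if (is.null(tr)) next
      cf <- tr$coef
      cf$herd <- keys$herd[i]; cf$season <- keys$season[i]
      cf$response <- resp
      cf$singular <- isTRUE(tr$flags$singular)
      out[[length(out) + 1L]] <- cf
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
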