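#' Default six-season schedule
#'
#' Season calendar used by the movement simulator, patterned on a migratory
#' mountain ungulate: late winter (low-elevation range), spring migration,
#' calving and summer (high-elevation range), fall migration, early winter.
#' Onsets are day-of-year; `center` names the seasonal range-center rule
#' (`"winter"` = low-elevation side, `"summer"` = high side, `"mid"` =
#' migration midpoint); `rate_mult` scales the per-step dispersion so daily
#' movement rates differ between seasons (migration seasons are fast), which
#' is the ground truth the season-segmentation module must recover.
#'
#' @return data.frame with columns `season`, `onset`, `center`, `rate_mult`.
#' @export
default_season_schedule <- function() {
  data.frame(
    season = c("late_winter", "spring", "calving", "summer", "fall",
               "early_winter"),
    onset = c(36L, 125L, 152L, 171L, 281L, 333L),
    center = c("winter", "mid", "summer", "summer", "mid", "winter"),
    rate_mult = c(0.6, 1.8, 0.5, 1.0, 1.8, 0.8),
    stringsAsFactors = FALSE)
}

#' Configure the telemetry simulator
#'
#' Individuals perform a discrete-time mean-reverting (Ornstein-Uhlenbeck
#' style) random walk toward their current season's range center. Winter
#' range centers translate toward the alpine zone by `shift_rate` meters per
#' year, which is the ground-truth distribution shift downstream stages must
#' detect; `shift_rate = 0` gives a stationary population.
#'
#' @param n_individuals collared individuals per herd per deployment cohort.
#' @param years inclusive integer year range of the study.
#' @param herds character vector of herd names.
#' @param season_schedule data.frame as [default_season_schedule()]; onsets
#'   must be strictly increasing within the year.
#' @param attraction per-step mean-reversion fraction in (0, 1]. Together
#'   with `step_sd` this sets the stationary spread
#'   `step_sd / sqrt(2 * attraction - attraction^2)` of an individual's
#'   seasonal range; the defaults give a spread of about 2 km, i.e.
#'   individual seasonal ranges of order 10^1-10^2 km2, typical of mountain
#'   caribou.
#' @param step_sd per-step dispersion (m) at `rate_mult = 1`.
#' @param fix_interval_h hours between GPS fixes; must divide 24.
#' @param dop_sampler function(n) drawing per-fix dilution-of-precision
#'   values; the default lognormal puts ~90% of draws below 10 so the DOP
#'   filter is exercised but not dominant.
#' @param shift_rate per-year displacement (m/yr, >= 0) of winter range
#'   centers toward the alpine (uphill) direction.
#' @param center_jitter_sd between-individual scatter (m) of seasonal range
#'   centers.
#' @param deployment_years collar deployment length (years) per individual;
#'   cohorts start every year.
#' @param truncate_prob probability a collar fails mid-deployment (exercises
#'   the incomplete-season exclusion rule; default 0, off).
#' @return a `movement_config` list.
#' @export
movement_config <- function(n_individuals = 20,
                            years = 1998:2013,
                            herds = "A",
                            season_schedule = default_season_schedule(),
                            attraction = 0.05,
                            step_sd = 600,
                            fix_interval_h = 8,
                            dop_sampler = function(n)
                              stats::rlnorm(n, log(4), 0.7),
                            shift_rate = 0,
                            center_jitter_sd = 4000,
                            deployment_years = 1,
                            truncate_prob = 0) {
  stopifnot(n_individuals >= 1, length(years) >= 1,
            attraction > 0, attraction <= 1, step_sd >= 0,
            24 %% fix_interval_h == 0, shift_rate >= 0,
            deployment_years >= 1)
  ss <- season_schedule
  if (is.unsorted(ss$onset, strictly = TRUE))
    stop("season onsets must be strictly increasing within the year",
         call. = FALSE)
  if (any(ss$onset < 1) || any(ss$onset > 365))
    stop("season onsets must be days-of-year in 1..365", call. = FALSE)
  structure(list(n_individuals = n_individuals, years = years, herds = herds,
                 season_schedule = ss, attraction = attraction,
                 step_sd = step_sd, fix_interval_h = fix_interval_h,
                 dop_sampler = dop_sampler, shift_rate = shift_rate,
                 center_jitter_sd = center_jitter_sd,
                 deployment_years = deployment_years,
                 truncate_prob = truncate_prob),
            class = "movement_config")
}

# seasonal range centers for one herd on a landscape; winter low on the
# gradient axis, summer high, herds offset along the cross axis
herd_centers <- function(landscape, herd_index, n_herds) {
  cfg <- landscape$cfg
  along_lo <- 0.45; along_hi <- 0.70
  crossfrac <- if (n_herds == 1) 0.5 else
    0.25 + 0.5 * (herd_index - 1) / (n_herds - 1)
  pt <- function(alongfrac) {
    if (cfg$gradient == "east")
      c(cfg$xmin + alongfrac * cfg$width, cfg$ymin + crossfrac * cfg$height)
    else
      c(cfg$xmin + crossfrac * cfg$width, cfg$ymin + alongfrac * cfg$height)
  }
  list(winter = pt(along_lo), summer = pt(along_hi),
       uphill = if (cfg$gradient == "east") c(1, 0) else c(0, 1))
}

#' Simulate multi-year migratory GPS telemetry
#'
#' Each individual's position follows a mean-reverting random walk toward its
#' current season's range center; winter centers translate uphill by
#' `shift_rate * (year - first year)`. Fixes are strictly time-ordered,
#' clamped to the landscape extent, and carry DOP values from the configured
#' sampler. Identical seed and configs give identical output.
#'
#' @param move a [movement_config()].
#' @param landscape a [make_landscape()] result; must contain all range
#'   centers.
#' @param seed integer RNG seed.
#' @return data.frame (one row per fix): `animal_id`, `herd`, `timestamp`
#'   (POSIXct UTC), `x`, `y`, `dop`.
#' @export
simulate_tracks <- function(move, landscape, seed = 1L) {
  stopifnot(inherits(move, "movement_config"), inherits(landscape, "landscape"))
  cfg <- landscape$cfg
  ex <- c(cfg$xmin, cfg$xmin + cfg$width, cfg$ymin, cfg$ymin + cfg$height)
  ss <- move$season_schedule
  n_herds <- length(move$herds)
  y0 <- min(move$years)
  spd <- 24L %/% move$fix_interval_h  # fixes per day
  acc_id <- list(); acc_herd <- list(); acc_t <- list()
  acc_x <- list(); acc_y <- list(); acc_dop <- list()
  k <- 0L
  ctrs <- lapply(seq_len(n_herds), function(hi)
    herd_centers(landscape, hi, n_herds))
  for (ctr in ctrs)
    if (any(ctr$winter < ex[c(1, 3)]) || any(ctr$winter > ex[c(2, 4)]) ||
        any(ctr$summer < ex[c(1, 3)]) || any(ctr$summer > ex[c(2, 4)]))
      stop("range centers fall outside the landscape extent", call. = FALSE)
  withr_seed(seed, {
    for (cohort_year in move$years) {
      t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", cohort_year), tz = "UTC")
      t1 <- as.POSIXct(sprintf("%d-01-01 00:00:00",
                               cohort_year + move$deployment_years),
                       tz = "UTC")
      times <- seq(t0, t1 - 1, by = move$fix_interval_h * 3600)
      tnum <- as.numeric(times)
      n <- length(times)
      lt <- as.POSIXlt(times)
      doy <- lt$yday + 1L
      yr <- lt$year + 1900L
      si <- season_index_of(doy, ss$onset)
      for (hi in seq_len(n_herds)) {
        ctr <- ctrs[[hi]]
        for (ind in seq_len(move$n_individuals)) {
          id <- sprintf("%s_%d_%02d", move$herds[hi], cohort_year, ind)
          jit <- stats::rnorm(2, 0, move$center_jitter_sd)
          shift_vec <- outer(move$shift_rate * (yr - y0), ctr$uphill)
          mux <- numeric(n); muy <- numeric(n)
          winter_like <- ss$center == "winter"
          for (s in seq_len(nrow(ss))) {
            sel <- si == s
            base <- switch(ss$center[s],
                           winter = ctr$winter,
                           summer = ctr$summer,
                           mid = (ctr$winter + ctr$summer) / 2)
            mux[sel] <- base[1] + jit[1]
            muy[sel] <- base[2] + jit[2]
            if (winter_like[s]) {
              mux[sel] <- mux[sel] + shift_vec[sel, 1]
              muy[sel] <- muy[sel] + shift_vec[sel, 2]
            }
          }
          # individual centers stay well inside the landscape so ranges
          # are not flattened against the boundary
          margin <- 2000
          mux <- pmin(pmax(mux, ex[1] + margin), ex[2] - margin)
          muy <- pmin(pmax(muy, ex[3] + margin), ex[4] - margin)
          sdv <- move$step_sd * ss$rate_mult[si]
          a <- move$attraction
          ex_ <- a * mux + stats::rnorm(n, 0, sdv)
          ey <- a * muy + stats::rnorm(n, 0, sdv)
          x <- stats::filter(ex_, 1 - a, method = "recursive",
                             init = mux[1])
          y <- stats::filter(ey, 1 - a, method = "recursive",
                             init = muy[1])
          x <- pmin(pmax(as.numeric(x), ex[1] + 1), ex[2] - 1)
          y <- pmin(pmax(as.numeric(y), ex[3] + 1), ex[4] - 1)
          nk <- n
          if (move$truncate_prob > 0 &&
              stats::runif(1) < move$truncate_prob)
            nk <- sample.int(n, 1)
          k <- k + 1L
          acc_id[[k]] <- rep.int(id, nk)
          acc_herd[[k]] <- rep.int(move$herds[hi], nk)
          acc_t[[k]] <- tnum[seq_len(nk)]
          acc_x[[k]] <- x[seq_len(nk)]
          acc_y[[k]] <- y[seq_len(nk)]
          acc_dop[[k]] <- move$dop_sampler(nk)
        }
      }
    }
  })
  data.frame(animal_id = unlist(acc_id, use.names = FALSE),
             herd = unlist(acc_herd, use.names = FALSE),
             timestamp = .POSIXct(unlist(acc_t, use.names = FALSE),
                                  tz = "UTC"),
             x = unlist(acc_x, use.names = FALSE),
             y = unlist(acc_y, use.names = FALSE),
             dop = unlist(acc_dop, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# which schedule row governs each day-of-year (onsets wrap around the year)
season_index_of <- function(doy, onsets) {
  idx <- findInterval(doy, onsets)
  idx[idx == 0L] <- length(onsets)  # before first onset -> wrapped last season
  idx
}

#' Simulate an interannual climate index
#'
#' Generates a unitless NPI-like annual index with a specified sample
#' correlation with year (achieved exactly by orthogonalization), emulating
#' the secular trend in winter-severity climate indices.
#'
#' @param years integer years.
#' @param r_with_year target sample correlation between index and year
#'   (default 0.56).
#' @param mean,sd location and scale of the returned index.
#' @param seed integer RNG seed.
#' @return data.frame with columns `year`, `npi`.
#' @export
simulate_climate <- function(years, r_with_year = 0.56, mean = 0, sd = 1,
                             seed = 1L) {
  n <- length(years)
  stopifnot(n >= 3, abs(r_with_year) <= 1)
  withr_seed(seed, {
    e <- stats::rnorm(n)
  })
  z <- as.numeric(scale(years))
  e <- stats::residuals(stats::lm(e ~ z))
  e <- e / stats::sd(e)
  x <- r_with_year * z + sqrt(1 - r_with_year^2) * e
  data.frame(year = years, npi = mean + sd * x)
}
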