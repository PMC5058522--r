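# shared in-code fixtures for the test suite

# tiny flat landscape for fast geometry tests
tiny_landscape <- function(width = 10000, height = 10000, seed = 7) {
  make_landscape(landscape_config(width = width, height = height,
                                  noise_sd = 0), seed = seed)
}

# fixes data.frame from raw vectors
make_fixes <- function(t, x, y, dop = 1, id = "a1", herd = "A") {
  data.frame(animal_id = id, herd = herd,
             timestamp = as.POSIXct(t, tz = "UTC"),
             x = x, y = y, dop = dop, stringsAsFactors = FALSE)
}

# hourly-ish timestamp sequence starting at a date
ts_seq <- function(start, n, by_h = 1) {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * by_h * 3600
}

# mass raster on a k x k toy grid from a weight matrix
toy_mass <- function(w, cell = 100) {
  g <- grid_spec(0, 0, cell, ncol(w), nrow(w))
  grid_raster(w / sum(w), g, "mass")
}

# direct double-loop KDE oracle at one probe location
kde_oracle_at <- function(px, py, pts, hx, hy) {
  s <- 0
  for (k in seq_len(nrow(pts)))
    s <- s + stats::dnorm((px - pts[k, 1]) / hx) *
      stats::dnorm((py - pts[k, 2]) / hy)
  s / (nrow(pts) * hx * hy)
}

# piecewise-constant six-season daily rate series with noise, on the
# day-of-year circle; onsets and levels follow the generator's calendar
six_season_series <- function(onsets = c(36, 125, 152, 171, 281, 333),
                              levels = c(1, 5, 0.5, 2.5, 5, 1.5),
                              noise_sd = 0.1, jitter = 0) {
  on <- sort(onsets + if (jitter > 0) round(stats::rnorm(6, 0, jitter))
             else 0)
  si <- findInterval(1:365, on)
  si[si == 0] <- 6  # days before the first onset belong to the wrap season
  pmax(levels[si] + stats::rnorm(365, 0, noise_sd), 0)
}
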