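test_that("landscape generation respects thresholds and determinism", {
  cfg <- landscape_config(width = 10000, height = 10000, noise_sd = 0)
  ls1 <- make_landscape(cfg, seed = 5)
  ls2 <- make_landscape(cfg, seed = 5)
  expect_identical(ls1$elevation$values, ls2$elevation$values)
  expect_identical(ls1$landcover$values, ls2$landcover$values)
  # threshold above the maximum elevation: alpine mask all false
  cfg_hi <- landscape_config(width = 10000, height = 10000,
                             elev_range = c(800, 2400),
                             alpine_threshold = 2399.9, noise_sd = 0)
  ls_hi <- make_landscape(cfg_hi, seed = 5)
  expect_lt(mean(ls_hi$alpine$values), 0.01)
  # monotone gradient with threshold at the midpoint: alpine fraction ~ 0.5
  cfg_mid <- landscape_config(width = 20000, height = 20000,
                              elev_range = c(1000, 2000),
                              alpine_threshold = 1500)
  ls_mid <- make_landscape(cfg_mid, seed = 11)
  expect_equal(mean(ls_mid$alpine$values), 0.5, tolerance = 0.04)
  expect_error(landscape_config(width = 0, height = 1000), "degenerate")
  expect_error(landscape_config(alpine_threshold = 100), "inside")
})

test_that("simulated tracks are time-ordered, in-extent, deterministic", {
  ls <- tiny_landscape()
  mv <- movement_config(n_individuals = 2, years = 2000:2001,
                        herds = c("A", "B"))
  fx1 <- simulate_tracks(mv, ls, seed = 3)
  fx2 <- simulate_tracks(mv, ls, seed = 3)
  expect_identical(fx1, fx2)
  expect_setequal(unique(fx1$herd), c("A", "B"))
  expect_true(all(fx1$x > 0 & fx1$x < 10000))
  expect_true(all(fx1$y > 0 & fx1$y < 10000))
  for (tr in split_tracks(fx1))
    expect_false(is.unsorted(tr$timestamp, strictly = TRUE))
})

test_that("degenerate walk collapses to the seasonal center", {
  ls <- tiny_landscape()
  mv <- movement_config(n_individuals = 1, years = 2000,
                        attraction = 1, step_sd = 0, center_jitter_sd = 0)
  fx <- simulate_tracks(mv, ls, seed = 1)
  # during mid-summer every fix sits exactly at the summer center
  doy <- as.POSIXlt(fx$timestamp)$yday + 1
  summer <- doy > 180 & doy < 280
  expect_lt(sd(fx$x[summer]), 1e-9)
  expect_lt(sd(fx$y[summer]), 1e-9)
})

test_that("winter-range shift moves era-wise mean winter position", {
  ls <- make_landscape(landscape_config(width = 40000, height = 40000),
                       seed = 42)
  doy_winter <- function(fx) {
    doy <- as.POSIXlt(fx$timestamp)$yday + 1
    fx[doy >= 40 & doy < 120, ]  # well inside late winter
  }
  era_means <- function(fx) {
    w <- doy_winter(fx)
    yr <- as.POSIXlt(w$timestamp)$year + 1900
    c(mean(w$x[yr <= 2005]), mean(w$x[yr >= 2006]))
  }
  mv0 <- movement_config(n_individuals = 20, years = 1998:2013,
                         shift_rate = 0)
  m0 <- era_means(simulate_tracks(mv0, ls, seed = 8))
  expect_lt(abs(m0[2] - m0[1]), mv0$step_sd)
  mv5 <- movement_config(n_individuals = 20, years = 1998:2013,
                         shift_rate = 500)
  m5 <- era_means(simulate_tracks(mv5, ls, seed = 8))
  # eras 1998-2005 vs 2006-2013: mean shift-year gap is 8 years -> ~4 km
  expect_equal(m5[2] - m5[1], 4000, tolerance = 0.25)
})

test_that("winter centroid drift recovers the configured shift rate", {
  ls <- make_landscape(landscape_config(width = 40000, height = 40000),
                       seed = 42)
  mv <- movement_config(n_individuals = 20, years = 1998:2013,
                        shift_rate = 500)
  # bias check: the per-seed OLS slope is noisy (between-individual range
  # scatter), so average the estimate over seeds
  slopes <- vapply(15:18, function(s) {
    fx <- simulate_tracks(mv, ls, seed = s)
    doy <- as.POSIXlt(fx$timestamp)$yday + 1
    w <- fx[doy >= 40 & doy < 120, ]
    yr <- as.POSIXlt(w$timestamp)$year + 1900
    cent <- tapply(w$x, yr, mean)
    unname(coef(lm(cent ~ as.numeric(names(cent))))[2])
  }, 0)
  expect_equal(mean(slopes), 500, tolerance = 0.10)
})

test_that("footprint grows cumulatively and hits the area target", {
  # a roomy landscape so random placement rarely overlaps
  ls <- tiny_landscape(width = 30000, height = 30000)
  scn <- disturbance_scenario(2000, 2004, annual_new_area_km2 = 2)
  fp <- simulate_footprint(scn, ls, seed = 4)
  yrs <- vapply(fp$features, `[[`, 0, "year_created")
  expect_true(all(yrs %in% 2000:2004))
  areas <- vapply(2000:2004, function(y)
    footprint_union_area_km2(cumulative_footprint(fp, y), ls$grid_fine), 0)
  expect_true(all(diff(areas) >= 0))
  expect_equal(areas[5], 10, tolerance = 0.10)
  # zero growth: identical polygon set every year
  fp0 <- simulate_footprint(
    disturbance_scenario(2000, 2004, annual_new_area_km2 = 0,
                         initial_area_km2 = 1), ls, seed = 4)
  expect_identical(cumulative_footprint(fp0, 2000)$features,
                   cumulative_footprint(fp0, 2004)$features)
})

test_that("well points are buffered to squares of the configured area", {
  fs <- new_fs <- udshift:::new_footprint_set(
    list(list(type = "well", year_created = 2000, xy = c(5000, 5000))))
  cum <- cumulative_footprint(fs, 2000)
  ring <- cum$features[[1]]$ring
  side <- diff(range(ring[, 1]))
  expect_equal(side, sqrt(0.0158e6), tolerance = 1e-9)
  expect_equal(diff(range(ring[, 2])), side)
  expect_equal(side^2 / 1e6, 0.0158)
  # missing year errors with the offending index
  fs_bad <- udshift:::new_footprint_set(
    list(list(type = "well", year_created = NA, xy = c(1, 1))))
  expect_error(cumulative_footprint(fs_bad, 2010), "year_created")
  # features created later are excluded
  expect_length(cumulative_footprint(fs, 1999)$features, 0)
})

test_that("footprint GeoJSON round-trips all geometry types", {
  ls <- tiny_landscape()
  scn <- disturbance_scenario(2000, 2001, annual_new_area_km2 = 1)
  fp <- simulate_footprint(scn, ls, seed = 9)
  path <- tempfile(fileext = ".geojson")
  write_footprint_geojson(fp, path)
  fp2 <- read_footprint_geojson(path)
  expect_length(fp2$features, length(fp$features))
  for (i in seq_along(fp$features)) {
    expect_identical(fp2$features[[i]]$type, fp$features[[i]]$type)
    expect_identical(fp2$features[[i]]$year_created,
                     fp$features[[i]]$year_created)
  }
  g1 <- rasterize_footprint(cumulative_footprint(fp, 2001), ls$grid_fine)
  g2 <- rasterize_footprint(cumulative_footprint(fp2, 2001), ls$grid_fine)
  expect_equal(g1$values, g2$values)
})

test_that("climate series hits the target correlation with year", {
  cl <- simulate_climate(1998:2013, r_with_year = 0.56, seed = 2)
  expect_equal(cor(cl$year, cl$npi), 0.56, tolerance = 1e-10)
  expect_identical(cl, simulate_climate(1998:2013, r_with_year = 0.56,
                                        seed = 2))
  expect_equal(nrow(cl), 16)
})
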