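test_that("plug-in bandwidth is near the normal reference for Gaussian data", {
  set.seed(1)
  pts <- cbind(rnorm(1000, 0, 1000), rnorm(1000, 0, 1000))
  bw <- plugin_bandwidth(pts)
  href <- 1.06 * 1000 * 1000^(-1 / 5)  # ~ 265 m normal-reference
  expect_equal(bw$hx, href, tolerance = 0.15)
  expect_equal(bw$hy, href, tolerance = 0.15)
  # axis swap swaps the pair
  bw_sw <- plugin_bandwidth(pts[, 2], pts[, 1])
  expect_equal(bw_sw$hx, bw$hy)
  expect_equal(bw_sw$hy, bw$hx)
  # duplicating every point shrinks h by ~ 2^(-1/5); the plug-in pilot
  # stages also rescale, so agreement is loose
  bw2 <- plugin_bandwidth(rbind(pts, pts))
  expect_equal(bw2$hx / bw$hx, 2^(-1 / 5), tolerance = 0.10)
  expect_error(plugin_bandwidth(cbind(1:20, rep(3, 20))), "zero variance")
  expect_error(plugin_bandwidth(cbind(1:5, 1:5)), "at least 10")
})

test_that("KDE matches the direct double-loop oracle to 1e-12", {
  set.seed(2)
  pts <- cbind(runif(200, 0, 10000), runif(200, 0, 10000))
  bw <- list(hx = 600, hy = 450)
  g <- grid_spec(-3000, -3000, 250, 64, 64)
  ud <- kde_ud(pts, bw, g)
  expect_identical(ud$representation, "density")
  xs <- grid_xcenters(g); ys <- grid_ycenters(g)
  probe <- cbind(sample(64, 100, TRUE), sample(64, 100, TRUE))
  for (p in seq_len(nrow(probe))) {
    i <- probe[p, 1]; j <- probe[p, 2]
    f <- kde_oracle_at(xs[j], ys[i], pts, bw$hx, bw$hy)
    expect_lt(abs(ud$values[i, j] - f) / max(f, 1e-300), 1e-12)
  }
  expect_equal(sum(ud$values) * cell_area_m2(g), 1, tolerance = 1e-3)
})

test_that("KDE closed form at the mode of a point mass", {
  set.seed(3)
  pts <- cbind(5000 + runif(50, -1, 1), 5000 + runif(50, -1, 1))
  bw <- list(hx = 400, hy = 400)
  g <- grid_spec(0, 0, 250, 40, 40)
  ud <- kde_ud(pts, bw, g)
  cc <- cell_of(g, 5000, 5000)
  # the 250-m cell center sits up to ~125 m from the mass point; compare
  # to the oracle there rather than the exact mode value
  f_mode <- 1 / (2 * pi * bw$hx * bw$hy)
  expect_equal(ud$values[cc$row, cc$col],
               kde_oracle_at(grid_xcenters(g)[cc$col],
                             grid_ycenters(g)[cc$row], pts, 400, 400),
               tolerance = 1e-12)
  expect_lt(abs(max(ud$values) - f_mode) / f_mode, 0.1)
})

test_that("KDE refuses < 50 locations and inadequate grids", {
  set.seed(4)
  pts <- cbind(rnorm(49, 0, 500), rnorm(49, 0, 500))
  g <- grid_spec(-5000, -5000, 250, 40, 40)
  expect_error(kde_ud(pts, list(hx = 300, hy = 300), g), "50-location")
  pts2 <- cbind(rnorm(60, 0, 500), rnorm(60, 0, 500))
  g_small <- grid_spec(-600, -600, 250, 5, 5)
  expect_error(kde_ud(pts2, list(hx = 300, hy = 300), g_small),
               "3 bandwidths")
})

test_that("scale01 is idempotent and preserves ratios", {
  g <- grid_spec(0, 0, 100, 2, 2)
  r <- grid_raster(matrix(c(1, 2, 3, 4), 2, 2), g, "value")
  s <- scale01(r)
  expect_equal(max(s$values), 1)
  expect_equal(s$values[2, 1] / s$values[2, 2], 0.5)
  expect_equal(scale01(s)$values, s$values)
  # constant raster becomes all ones
  expect_true(all(scale01(grid_raster(matrix(3, 2, 2), g,
                                      "value"))$values == 1))
  expect_error(scale01(grid_raster(matrix(0, 2, 2), g, "value")),
               "all-zero")
})

test_that("population UD averages scaled inputs and normalizes to mass", {
  g <- grid_spec(0, 0, 100, 4, 4)
  set.seed(5)
  mk <- function() scale01(grid_raster(matrix(runif(16), 4, 4), g, "value"))
  uds <- list(mk(), mk(), mk())
  p <- population_ud(uds)
  expect_equal(sum(p$values), 1, tolerance = 1e-12)
  # cellwise-mean oracle
  acc <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    s <- 0
    for (u in uds) s <- s + u$values[i, j]
    acc[i, j] <- s / 3
  }
  expect_equal(p$values, acc / sum(acc), tolerance = 1e-14)
  # permutation invariance and the single-UD exclusion rule
  expect_equal(population_ud(uds[c(3, 1, 2)])$values, p$values)
  expect_error(population_ud(uds[1]), "single UD")
  # two identical UDs: population equals either input renormalized
  p2 <- population_ud(list(uds[[1]], uds[[1]]))
  expect_equal(p2$values, uds[[1]]$values / sum(uds[[1]]$values))
})

test_that("two disjoint uniform UDs split the population mass 50/50", {
  g <- grid_spec(0, 0, 100, 4, 4)
  a <- matrix(0, 4, 4); a[, 1:2] <- 1
  b <- matrix(0, 4, 4); b[, 3:4] <- 1
  p <- population_ud(list(grid_raster(a, g, "scaled01"),
                          grid_raster(b, g, "scaled01")))
  expect_equal(sum(p$values[, 1:2]), 0.5)
  expect_equal(sum(p$values[, 3:4]), 0.5)
})

test_that("baseline UD pools era years only", {
  g <- grid_spec(0, 0, 100, 3, 3)
  mk <- function(yr, v) {
    r <- scale01(grid_raster(matrix(v, 3, 3), g, "value"))
    r$meta$year <- yr
    r
  }
  set.seed(6)
  uds <- list(mk(1999, runif(9)), mk(2003, runif(9)), mk(2010, runif(9)))
  bl <- baseline_ud(uds, era = 1998:2005)
  expect_equal(bl$values,
               population_ud(uds[1:2])$values)
  expect_equal(sum(bl$values), 1, tolerance = 1e-12)
  expect_error(baseline_ud(uds[3], era = 1998:2005), "at least 2")
})

test_that("isopleth selects the minimal prefix", {
  # constructed example: masses {0.5, 0.3, 0.15, 0.05} -> 3 cells
  m <- toy_mass(matrix(c(0.5, 0.3, 0.15, 0.05), 2, 2))
  hr <- isopleth(m, 0.95)
  expect_length(hr$cells, 3)
  expect_gte(sum(m$values[hr$cells]), 0.95)
  # exhaustive check: no smaller subset reaches 0.95
  v <- as.vector(m$values)
  combos2 <- utils::combn(4, 2)
  expect_true(all(colSums(matrix(v[combos2], 2)) < 0.95))
  # uniform mass over 100 cells at level 0.95 -> 95 cells
  u <- toy_mass(matrix(1, 10, 10))
  expect_length(isopleth(u, 0.95)$cells, 95)
  # level -> 1 captures all nonzero cells
  w <- matrix(c(rep(1, 50), rep(0, 50)), 10, 10)
  expect_length(isopleth(toy_mass(w), 0.999)$cells, 50)
})

test_that("isopleth area is nonincreasing in level and matches count", {
  set.seed(7)
  m <- toy_mass(matrix(runif(100), 10, 10), cell = 250)
  areas <- vapply(c(0.5, 0.75, 0.9, 0.95, 0.99),
                  function(l) isopleth(m, l)$area_km2, 0)
  expect_true(all(diff(areas) >= 0))
  hr <- isopleth(m, 0.95)
  expect_equal(hr$area_km2, length(hr$cells) * 0.0625)
  # removing the smallest member drops below the level (minimality)
  smallest <- hr$cells[which.min(m$values[hr$cells])]
  expect_lt(sum(m$values[setdiff(hr$cells, smallest)]), 0.95)
})

test_that("isopleth equals the exhaustive smallest-prefix solution", {
  set.seed(8)
  for (rep in 1:3) {
    m <- toy_mass(matrix(rexp(100), 10, 10))
    hr <- isopleth(m, 0.95)
    v <- as.vector(m$values)
    ord <- order(v, decreasing = TRUE)
    k <- which(cumsum(v[ord]) >= 0.95 - 1e-12)[1]
    expect_setequal(hr$cells, ord[seq_len(k)])
  }
})

test_that("individual_uds applies completeness, DOP and n rules", {
  ls <- tiny_landscape()
  mv <- movement_config(n_individuals = 3, years = 2002, herds = "A",
                        step_sd = 300, center_jitter_sd = 500)
  fx <- simulate_tracks(mv, ls, seed = 10)
  win <- list(season = "late_winter", year = 2002,
              start = as.POSIXct("2002-02-05", tz = "UTC"),
              end = as.POSIXct("2002-05-05", tz = "UTC"))
  g <- make_ud_grid(fx$x, fx$y, cell = 250, pad = 4000)
  uds <- individual_uds(fx, win, g)
  expect_length(uds, 3)
  for (u in uds) {
    expect_identical(u$representation, "scaled01")
    expect_identical(u$meta$season, "late_winter")
  }
  # truncate one collar mid-season: that animal is excluded
  id1 <- unique(fx$animal_id)[1]
  cut <- as.POSIXct("2002-03-15", tz = "UTC")
  fx_cut <- fx[!(fx$animal_id == id1 & fx$timestamp > cut), ]
  uds2 <- individual_uds(fx_cut, win, g)
  expect_length(uds2, 2)
  expect_match(attr(uds2, "skipped")[[id1]], "incomplete")
})
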