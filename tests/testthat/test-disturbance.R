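test_that("moving window handles constant rasters and rejects bad radii", {
  g <- grid_spec(0, 0, 50, 30, 30)
  ones <- grid_raster(matrix(1, 30, 30), g, "binary")
  zeros <- grid_raster(matrix(0, 30, 30), g, "binary")
  expect_equal(moving_window_density(ones, 500)$values,
               matrix(1, 30, 30), tolerance = 1e-9)
  expect_equal(moving_window_density(zeros, 500)$values,
               matrix(0, 30, 30), tolerance = 1e-12)
  expect_error(moving_window_density(ones, 20), "at least the cell")
  expect_error(moving_window_density(
    grid_raster(matrix(0.5, 2, 2), grid_spec(0, 0, 50, 2, 2),
                "proportion"), 500), "binary")
})

test_that("single-cell impulse matches brute-force window counting", {
  g <- grid_spec(0, 0, 50, 41, 41)
  v <- matrix(0, 41, 41); v[21, 21] <- 1
  d <- moving_window_density(grid_raster(v, g, "binary"), 1000)
  xs <- grid_xcenters(g); ys <- grid_ycenters(g)
  # brute-force oracle at several probes, including the impulse center
  probes <- rbind(c(21, 21), c(21, 1), c(1, 21), c(15, 28), c(41, 41))
  for (p in seq_len(nrow(probes))) {
    i <- probes[p, 1]; j <- probes[p, 2]
    inwin <- outer(ys, xs, function(yy, xx)
      (xx - xs[j])^2 + (yy - ys[i])^2 <= 1000^2)
    expect_equal(d$values[i, j], sum(v[inwin]) / sum(inwin),
                 tolerance = 1e-9)
  }
  # impulse response: 1/N with N the cell centers inside the circle
  N <- sum(outer(ys - ys[21], xs - xs[21],
                 function(a, b) a^2 + b^2 <= 1000^2))
  expect_equal(d$values[21, 21], 1 / N, tolerance = 1e-9)
})

test_that("moving window commutes with horizontal mirroring", {
  set.seed(1)
  g <- grid_spec(0, 0, 50, 24, 24)
  v <- matrix(rbinom(576, 1, 0.2), 24, 24)
  d <- moving_window_density(grid_raster(v, g, "binary"), 300)
  dm <- moving_window_density(
    grid_raster(v[, 24:1], g, "binary"), 300)
  expect_equal(dm$values, d$values[, 24:1], tolerance = 1e-9)
})

test_that("normalize_mass is scale-invariant and guards zero input", {
  g <- grid_spec(0, 0, 50, 5, 5)
  set.seed(2)
  v <- matrix(runif(25, 0, 0.5), 5, 5)
  p <- grid_raster(v, g, "proportion")
  m <- normalize_mass(p)
  expect_equal(sum(m$values), 1, tolerance = 1e-12)
  m2 <- normalize_mass(grid_raster(v * 2, g, "proportion"))
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  # uniform proportion raster -> uniform mass 1/n
  u <- normalize_mass(grid_raster(matrix(0.3, 5, 5), g, "proportion"))
  expect_true(all(abs(u$values - 1 / 25) < 1e-12))
  expect_error(normalize_mass(grid_raster(matrix(0, 5, 5), g,
                                          "proportion")), "proportion")
})

test_that("disturbance surfaces are monotone in year", {
  ls <- tiny_landscape(width = 15000, height = 15000)
  scn <- disturbance_scenario(2000, 2004, annual_new_area_km2 = 3,
                              initial_area_km2 = 2)
  fp <- simulate_footprint(scn, ls, seed = 3)
  res <- lapply(c(2000, 2002, 2004), function(y)
    disturbance_surfaces(fp, ls, y))
  # total disturbed proportion mass grows with the footprint
  totals <- vapply(res, function(r) sum(r$proportion$values), 0)
  expect_true(all(diff(totals) > 0))
  for (r in res) {
    expect_true(all(r$proportion$values >= 0 &
                      r$proportion$values <= 1))
    expect_equal(sum(r$mass$values), 1, tolerance = 1e-9)
    expect_true(same_grid(r$proportion$grid, ls$grid_coarse))
  }
  # percent_within grows too
  pw <- vapply(c(2000, 2002, 2004), function(y)
    percent_within(cumulative_footprint(fp, y), g = ls$grid_fine), 0)
  expect_true(all(diff(pw) > 0))
  expect_true(all(pw >= 0 & pw <= 1))
})

test_that("percent_within matches the buffered-square closed form", {
  # one 1x1 km cutblock centered in a 10x10 km range, r = 1 km:
  # buffered area = 1 + 4*1 + pi = 8.1416 km2 -> fraction 0.0814
  fs <- udshift:::new_footprint_set(list(list(
    type = "cutblock", year_created = 2000,
    ring = cbind(c(4500, 5500, 5500, 4500), c(4500, 4500, 5500, 5500)))))
  g10 <- grid_spec(0, 0, 10, 1000, 1000)
  pw <- percent_within(fs, g = g10, radius = 1000)
  expect_equal(pw, (1 + 4 + pi) / 100, tolerance = 0.005)
  g <- grid_spec(0, 0, 50, 200, 200)
  # empty footprint -> 0; blanket footprint -> 1
  fs0 <- udshift:::new_footprint_set(list())
  expect_equal(percent_within(fs0, g = g), 0)
  fs_all <- udshift:::new_footprint_set(list(list(
    type = "cutblock", year_created = 2000,
    ring = cbind(c(-100, 10100, 10100, -100), c(-100, -100, 10100, 10100)))))
  expect_equal(percent_within(fs_all, g = g), 1)
})

test_that("rasterization uses the cell-center rule", {
  g <- grid_spec(0, 0, 50, 10, 10)
  # square covering centers of cells (2,2)-(3,3) only
  fs <- udshift:::new_footprint_set(list(list(
    type = "cutblock", year_created = 2000,
    ring = cbind(c(60, 160, 160, 60), c(60, 60, 160, 160)))))
  b <- rasterize_footprint(fs, g)
  expect_equal(sum(b$values), 4)
  expect_equal(b$values[2:3, 2:3], matrix(1, 2, 2))
  # a road marks cells within width/2 of its centerline
  road <- udshift:::new_footprint_set(list(list(
    type = "road", year_created = 2000,
    line = rbind(c(0, 125), c(500, 125)), width = 60)))
  br <- rasterize_footprint(road, g)
  expect_true(all(br$values[3, 1:10] == c(rep(1, 10))))
  expect_equal(sum(br$values[-3, ]), 0)
})
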