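test_that("PHR analytic cases hold exactly", {
  set.seed(1)
  m <- toy_mass(matrix(rexp(100), 10, 10))
  full <- matrix(TRUE, 10, 10)
  expect_identical(phr(m, full), sum(m$values))
  expect_equal(phr(m, full), 1, tolerance = 1e-12)
  expect_equal(phr(m, matrix(FALSE, 10, 10)), 0)
  # uniform mass over 100 cells, mask of 30 -> 0.30
  u <- toy_mass(matrix(1, 10, 10))
  mask30 <- matrix(FALSE, 10, 10); mask30[1:3, ] <- TRUE
  expect_equal(phr(u, mask30), 0.30, tolerance = 1e-12)
  expect_error(phr(as_density(m), full), "mass")
})

test_that("PHR matches a cell loop oracle and is monotone in the mask", {
  set.seed(2)
  m <- toy_mass(matrix(runif(400), 20, 20))
  maskA <- matrix(runif(400) < 0.3, 20, 20)
  maskB <- maskA | matrix(runif(400) < 0.3, 20, 20)
  # loop oracle
  s <- 0
  for (i in 1:20) for (j in 1:20) if (maskA[i, j]) s <- s + m$values[i, j]
  expect_lt(abs(phr(m, maskA) - s) / s, 1e-12)
  expect_lte(phr(m, maskA), phr(m, maskB))
})

test_that("UDOI analytic cases: disjoint 0, identical uniform 1", {
  a <- matrix(0, 10, 10); a[1:5, ] <- 1
  b <- matrix(0, 10, 10); b[6:10, ] <- 1
  ua <- toy_mass(a); ub <- toy_mass(b)
  expect_identical(udoi(ua, ub), 0)
  expect_equal(udoi(ua, ua), 1, tolerance = 1e-12)
  # uniform over the same region of any area: exactly 1
  expect_equal(udoi(ub, ub), 1, tolerance = 1e-12)
})

test_that("UDOI matches a cell loop oracle and is symmetric", {
  set.seed(3)
  g <- grid_spec(0, 0, 100, 20, 20)
  xs <- grid_xcenters(g); ys <- grid_ycenters(g)
  gauss <- function(cx, cy, s) {
    v <- outer(ys, xs, function(y, x)
      exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)))
    grid_raster(v / sum(v), g, "mass")
  }
  ui <- gauss(700, 800, 300)
  uj <- gauss(1200, 1100, 400)
  a <- cell_area_m2(g)
  # brute-force loop oracle
  inter <- 0; prodsum <- 0
  for (i in 1:20) for (j in 1:20) {
    if (ui$values[i, j] > 1e-12 && uj$values[i, j] > 1e-12)
      inter <- inter + a
    prodsum <- prodsum + (ui$values[i, j] / a) * (uj$values[i, j] / a) * a
  }
  expect_lt(abs(udoi(ui, uj) - inter * prodsum) /
              (inter * prodsum), 1e-12)
  expect_identical(udoi(ui, uj), udoi(uj, ui))
})

test_that("UDOI exceeds 1 for coincident strongly nonuniform UDs", {
  # two identical sharply peaked UDs: product integral beats uniform
  w <- matrix(1e-6, 10, 10); w[5, 5] <- 1; w[5, 6] <- 1
  u <- toy_mass(w)
  expect_gt(udoi(u, u), 1)
})

test_that("region_from_ud applies the documented rules", {
  set.seed(4)
  m <- toy_mass(matrix(rexp(100), 10, 10))
  expect_identical(region_from_ud(m, "isopleth", 0.95),
                   isopleth(m, 0.95)$mask)
  # all-zero disturbance raster -> empty mask
  g <- grid_spec(0, 0, 100, 10, 10)
  z <- grid_raster(matrix(0, 10, 10), g, "proportion")
  expect_false(any(region_from_ud(z, "nonzero")))
  # uniform baseline over k cells at level 0.95 -> ceiling(0.95 k) cells
  w <- matrix(0, 10, 10); w[1:4, 1:5] <- 1
  expect_equal(sum(region_from_ud(toy_mass(w), "isopleth", 0.95)),
               ceiling(0.95 * 20))
})

test_that("overlap_table emits one record per stratum/index/target", {
  set.seed(5)
  g <- grid_spec(0, 0, 100, 10, 10)
  mk <- function(yr) {
    r <- toy_mass(matrix(rexp(100), 10, 10))
    r$meta <- list(herd = "A", season = "winter", year = yr)
    r
  }
  pop <- lapply(2006:2008, mk)
  bl <- toy_mass(matrix(rexp(100), 10, 10))
  alp <- grid_raster(matrix(rbinom(100, 1, 0.3), 10, 10), g, "binary")
  dist <- lapply(2006:2008, function(yr) {
    p <- grid_raster(matrix(runif(100, 0, 0.5), 10, 10), g, "proportion")
    list(proportion = p, mass = normalize_mass(p), year = yr)
  })
  names(dist) <- 2006:2008
  ov <- overlap_table(pop, dist, baselines = list(A.winter = bl),
                      alpine = alp)
  # per year: PHR x {disturbance, alpine, baseline} + UDOI x
  # {disturbance, baseline} = 5 records
  expect_equal(nrow(ov), 15)
  expect_equal(sum(ov$index == "PHR"), 9)
  expect_true(all(ov$value[ov$index == "PHR"] >= 0 &
                    ov$value[ov$index == "PHR"] <= 1))
  # baseline-era years are excluded from baseline comparisons
  pop_bl <- lapply(2003:2004, mk)
  ov2 <- overlap_table(pop_bl, dist = list(), baselines = list(A.winter = bl),
                       alpine = NULL, contemporary_era = 2006:2013)
  expect_equal(nrow(ov2), 0)
  # missing disturbance year: skipped with a warning
  expect_warning(
    ov3 <- overlap_table(lapply(2006:2009, mk), dist,
                         baselines = list(), alpine = NULL),
    "2009")
  expect_equal(sum(ov3$year == 2009), 0)
})

test_that("grid mismatches are refused everywhere", {
  m1 <- toy_mass(matrix(1, 5, 5), cell = 100)
  m2 <- toy_mass(matrix(1, 5, 5), cell = 200)
  expect_error(udoi(m1, m2), "grid mismatch")
  expect_error(phr(m1, isopleth(m2, 0.5)), "grid mismatch")
})
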