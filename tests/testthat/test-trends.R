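test_that("OLS matches the closed-form normal equations", {
  set.seed(1)
  n <- 12
  df <- data.frame(year = 2001:2012, npi = rnorm(n))
  df$value <- 0.4 - 0.02 * df$year + 0.3 * df$npi + rnorm(n, 0, 0.05)
  tr <- ols_trend(df)
  X <- cbind(1, df$year, df$npi)
  beta_hat <- solve(t(X) %*% X, t(X) %*% df$value)
  resid <- df$value - X %*% beta_hat
  s2 <- sum(resid^2) / (n - 3)
  se_hat <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(tr$coef$beta, as.numeric(beta_hat), tolerance = 1e-10)
  expect_equal(tr$coef$se, se_hat, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tr$coef$ci_lo, tr$coef$beta - 1.96 * tr$coef$se)
})

test_that("OLS degenerate cases behave as documented", {
  df <- data.frame(year = 1:10, value = 1:10)
  # suppressWarnings: summary.lm flags the deliberately perfect fit
  tr <- suppressWarnings(ols_trend(df, terms = "year"))
  expect_equal(tr$coef$beta[2], 1, tolerance = 1e-12)
  expect_lt(tr$coef$se[2], 1e-12)
  df2 <- data.frame(year = 1:10, value = 5)
  tr2 <- suppressWarnings(ols_trend(df2, terms = "year"))
  expect_equal(tr2$coef$beta[2], 0, tolerance = 1e-12)
  expect_false(tr2$coef$supported[2])
  # collinear design is refused with the term named
  df3 <- data.frame(year = 1:10, y2 = 2 * (1:10) + 3, value = rnorm(10))
  expect_error(ols_trend(df3, terms = c("year", "y2")), "y2")
  expect_error(ols_trend(df[1:2, ], terms = "year"), "at least")
})

test_that("VIF arithmetic and screening threshold", {
  set.seed(2)
  n <- 200
  x <- rnorm(n)
  # orthogonal predictors -> VIF 1
  e <- residuals(lm(rnorm(n) ~ x))
  v0 <- vif_screen(data.frame(a = x, b = e))
  expect_equal(v0$vif$vif, 1, tolerance = 1e-12)
  expect_true(v0$pass)
  # exact r = 0.56 -> VIF = 1 / (1 - 0.3136), passes the < 3 screen
  b <- 0.56 * x + sqrt(1 - 0.56^2) * (e / sd(e)) * sd(x)
  b <- as.numeric(b)
  r <- cor(x, b)
  v1 <- vif_screen(data.frame(a = x, b = b))
  expect_equal(v1$vif$vif, 1 / (1 - r^2), tolerance = 1e-12)
  expect_equal(v1$vif$vif, 1.46, tolerance = 0.01)
  expect_true(v1$pass)
  # r = 0.9 -> VIF ~ 5.26, fails
  c_ <- 0.9 * x + sqrt(1 - 0.81) * (e / sd(e)) * sd(x)
  v2 <- vif_screen(data.frame(a = x, b = as.numeric(c_)))
  expect_equal(v2$vif$vif, 1 / (1 - cor(x, c_)^2), tolerance = 1e-12)
  expect_gt(v2$vif$vif, 3)
  expect_false(v2$pass)
  expect_error(vif_screen(data.frame(a = x, b = 1)), "constant")
})

test_that("home-range outlier rule removes iteratively", {
  mk <- function(sz) data.frame(animal_id = seq_along(sz), hr_km2 = sz)
  r1 <- remove_hr_outlier(mk(c(10, 12, 30)))
  expect_equal(sort(r1$hr_km2), c(10, 12))
  expect_equal(attr(r1, "removed")$hr_km2, 30)
  r2 <- remove_hr_outlier(mk(c(10, 12, 20)))
  expect_equal(nrow(r2), 3)
  r3 <- remove_hr_outlier(mk(c(10, 12, 30, 100)))
  expect_equal(sort(r3$hr_km2), c(10, 12))
  expect_equal(sort(attr(r3, "removed")$hr_km2), c(30, 100))
  expect_error(remove_hr_outlier(mk(c(1, 2))), "at least 3")
})

test_that("LMM with no between-individual variance reproduces OLS", {
  set.seed(3)
  n_id <- 30
  df <- expand.grid(animal_id = sprintf("a%02d", 1:n_id), year = 1:6)
  df$x <- rnorm(nrow(df))
  # residuals centered within individual: between-individual variance is
  # exactly zero, so REML sits on the boundary and the GLS fit is OLS
  eps <- rnorm(nrow(df))
  eps <- eps - ave(eps, df$animal_id)
  df$y <- 2 + 0.5 * df$year - 1.2 * df$x + eps
  lm_m <- suppressMessages(lmm_trend(df, "y", c("year", "x")))
  ols_m <- ols_trend(df, "y", c("year", "x"))
  expect_true(isTRUE(lm_m$flags$singular))
  expect_lt(lm_m$ranef_var, 1e-8)
  expect_equal(lm_m$coef$beta, ols_m$coef$beta, tolerance = 1e-6)
})

test_that("LMM recovers a known slope and intercept variance", {
  set.seed(4)
  n_id <- 50
  ids <- sprintf("a%02d", 1:n_id)
  b_i <- rnorm(n_id, 0, 1)  # intercept sd 1.0
  df <- expand.grid(animal_id = ids, year = 1:8)
  df$y <- 2 + 0.5 * df$year + b_i[match(df$animal_id, ids)] +
    rnorm(nrow(df), 0, 0.7)
  m <- lmm_trend(df, "y", "year")
  slope <- m$coef[m$coef$term == "year", ]
  expect_lt(abs(slope$beta - 0.5), 2 * slope$se)
  expect_equal(m$ranef_var, 1.0, tolerance = 0.5)
  expect_false(m$flags$singular)
  # a single individual is refused
  expect_error(lmm_trend(df[df$animal_id == "a01", ], "y", "year"),
               ">= 2 individuals")
})

test_that("use metrics match hand counts on a toy landscape", {
  g <- grid_spec(0, 0, 100, 10, 10)
  elev <- grid_raster(matrix(1500, 10, 10), g, "value")
  lcv <- matrix(1, 10, 10)  # conifer everywhere...
  lcv[, 6:10] <- 2          # ...except nonforest in the east half
  lc <- grid_raster(lcv, g, "class")
  attr(lc, "levels") <- c("conifer", "nonforest", "other")
  # 10 hand-placed fixes: 7 conifer (x < 500), 3 nonforest
  tr <- make_fixes(ts_seq("2000-06-01", 10, by_h = 12),
                   x = c(50, 150, 250, 350, 450, 150, 250, 650, 750, 850),
                   y = 450)
  um <- extract_use_metrics(tr, elev, lc)
  expect_equal(um$mean_elevation_m, 1500)
  expect_equal(um$prop_conifer, 0.7)
  expect_equal(um$prop_nonforest, 0.3)
  expect_equal(um$n_off_raster, 0)
  # off-raster fixes beyond 5% error out
  tr_bad <- tr; tr_bad$x[1:2] <- -1000
  expect_error(extract_use_metrics(tr_bad, elev, lc), "off the raster")
})

test_that("home_range_disturbed_fraction averages member cells", {
  m <- toy_mass(matrix(c(rep(1, 50), rep(1e-9, 50)), 10, 10))
  hr <- isopleth(m, 0.95)
  g <- m$grid
  # half the members disturbed at 1, half at 0
  v <- matrix(0, 10, 10)
  v[hr$cells[seq(1, length(hr$cells), 2)]] <- 1
  frac <- home_range_disturbed_fraction(
    hr, grid_raster(v, g, "proportion"))
  expect_equal(frac, mean(v[hr$cells]))
  expect_equal(home_range_disturbed_fraction(
    hr, grid_raster(matrix(1, 10, 10), g, "proportion")), 1)
  expect_equal(home_range_disturbed_fraction(
    hr, grid_raster(matrix(0, 10, 10), g, "proportion")), 0)
})
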