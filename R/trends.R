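#' Proportion of a home range that is disturbed
#'
#' Mean disturbance proportion over the home-range member cells.
#'
#' @param hr a `home_range` (from [isopleth()]).
#' @param dist_prop a `grid_raster` with representation `"proportion"` on
#'   the same grid.
#' @return fraction in \[0, 1\].
#' @export
home_range_disturbed_fraction <- function(hr, dist_prop) {
  stopifnot(inherits(hr, "home_range"), inherits(dist_prop, "grid_raster"))
  stop_if_grid_mismatch(hr$grid, dist_prop$grid, "home range and disturbance")
  if (!length(hr$cells)) stop("empty home range", call. = FALSE)
  mean(dist_prop$values[hr$cells])
}

#' Habitat-use metrics for one individual-season
#'
#' Point data stand in for the UD when extracting habitat attributes: mean
#' elevation over the fixes, the proportion of fixes in conifer and
#' nonforest land cover, and the season-average daily movement rate.
#' Fixes falling off the rasters are counted and tolerated up to 5% of the
#' track, beyond which extraction errors out.
#'
#' @param track data.frame of fixes for one individual (already clipped to
#'   the season).
#' @param elevation `grid_raster` of elevation (m).
#' @param landcover class `grid_raster` with levels containing `conifer`
#'   and `nonforest`.
#' @return list: `mean_elevation_m`, `prop_conifer`, `prop_nonforest`,
#'   `movement_rate_kmd`, `n_fixes`, `n_off_raster`.
#' @export
extract_use_metrics <- function(track, elevation, landcover) {
  stopifnot(inherits(elevation, "grid_raster"),
            inherits(landcover, "grid_raster"))
  stop_if_grid_mismatch(elevation$grid, landcover$grid,
                        "elevation and landcover")
  cc <- cell_of(elevation$grid, track$x, track$y)
  off <- is.na(cc$idx)
  if (sum(off) > 0.05 * nrow(track))
    stop(sum(off), " of ", nrow(track),
         " fixes fall off the raster extent (> 5%)", call. = FALSE)
  idx <- cc$idx[!off]
  lv <- attr(landcover, "levels") %||% c("conifer", "nonforest", "other")
  cls <- lv[landcover$values[idx]]
  rates <- daily_movement_rate(track)
  list(mean_elevation_m = mean(elevation$values[idx]),
       prop_conifer = mean(cls == "conifer"),
       prop_nonforest = mean(cls == "nonforest"),
       movement_rate_kmd = mean(rates$rate[rates$covered], na.rm = TRUE),
       n_fixes = nrow(track), n_off_raster = sum(off))
}

#' Remove extreme home-range-size outliers
#'
#' Drops any record whose home-range size is more than double the largest of
#' all the other records, reapplied until no record qualifies. With sizes
#' \{10, 12, 30\} the 30 is removed (30 > 2 x 12); with \{10, 12, 20\}
#' nothing is.
#'
#' @param records data.frame with a home-range-size column.
#' @param size_col its name (default `"hr_km2"`).
#' @return `records` without the outliers; attribute `"removed"` holds the
#'   dropped rows.
#' @export
remove_hr_outlier <- function(records, size_col = "hr_km2") {
  stopifnot(size_col %in% names(records))
  if (nrow(records) < 3)
    stop("need at least 3 records to screen outliers", call. = FALSE)
  removed <- records[0, , drop = FALSE]
  repeat {
    sz <- records[[size_col]]
    i <- which.max(sz)
    if (length(sz) >= 2 && sz[i] > 2 * max(sz[-i])) {
      removed <- rbind(removed, records[i, , drop = FALSE])
      records <- records[-i, , drop = FALSE]
    } else break
  }
  attr(records, "removed") <- removed
  records
}

#' Pairwise variance-inflation screen
#'
#' For every pair of candidate predictors, VIF = 1 / (1 - r^2) from their
#' Pearson correlation; the screen passes when all pairwise VIFs are below
#' the threshold (3, the conventional cut for including collinear
#' covariates such as year and a climate index together).
#'
#' @param design data.frame or matrix of numeric predictor columns.
#' @param threshold pass cut (default 3).
#' @return list: `vif` (data.frame `var1`, `var2`, `r`, `vif`), `pass`.
#' @export
vif_screen <- function(design, threshold = 3) {
  X <- as.data.frame(design)
  if (nrow(X) < 3) stop("need at least 3 observations", call. = FALSE)
  sds <- vapply(X, stats::sd, 0)
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(names(X)[sds == 0], collapse = ", "), call. = FALSE)
  nm <- names(X)
  pairs <- utils::combn(nm, 2)
  out <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ],
                    r = NA_real_, vif = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    r <- stats::cor(X[[pairs[1, i]]], X[[pairs[2, i]]])
    out$r[i] <- r
    out$vif[i] <- 1 / (1 - r^2)
  }
  list(vif = out, pass = all(out$vif < threshold))
}

tidy_terms <- function(beta, se, n, model_id = NULL) {
  data.frame(term = names(beta), beta = unname(beta), se = unname(se),
             ci_lo = unname(beta - 1.96 * se),
             ci_hi = unname(beta + 1.96 * se),
             supported = unname(abs(beta) - 1.96 * se > 0),
             n = n, stringsAsFactors = FALSE)
}

#' OLS trend of an overlap index on year and climate
#'
#' Multiple linear regression of an overlap series (or any numeric
#' response) on the given terms. Reports Wald 95% confidence intervals
#' (beta +- 1.96 se); a term is `supported` when its interval excludes
#' zero.
#'
#' @param data data.frame holding the response and term columns.
#' @param response response column name (default `"value"`).
#' @param terms predictor column names (default `c("year", "npi")`).
#' @return object of class `trend_result`: list with `coef` (tidy term
#'   table), `n`, `sigma`, `model_id`, `fit`.
#' @export
ols_trend <- function(data, response = "value", terms = c("year", "npi")) {
  stopifnot(all(c(response, terms) %in% names(data)))
  n <- nrow(data)
  if (n < length(terms) + 2)
    stop("need at least ", length(terms) + 2, " observations for ",
         length(terms), " terms", call. = FALSE)
  f <- stats::reformulate(terms, response)
  fit <- stats::lm(f, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  structure(list(coef = tidy_terms(stats::coef(fit),
                                   sm$coefficients[, "Std. Error"], n),
                 n = n, sigma = sm$sigma, fit = fit,
                 flags = list()),
            class = "trend_result")
}

#' Mixed-model trend of an individual metric
#'
#' Linear mixed model (REML) of an individual-level response on the fixed
#' terms with a random intercept per individual, absorbing consistent
#' between-individual differences in behavior and home-range composition.
#' Singular fits (random-intercept variance estimated at zero) are reported
#' in `flags`, not hidden.
#'
#' @param data data.frame with the response, fixed-term and grouping
#'   columns.
#' @param response response column name.
#' @param terms fixed-effect column names.
#' @param group grouping column for the random intercept (default
#'   `"animal_id"`).
#' @return a `trend_result` with `ranef_var` (random-intercept variance)
#'   and `flags$singular`.
#' @export
lmm_trend <- function(data, response, terms, group = "animal_id") {
  stopifnot(all(c(response, terms, group) %in% names(data)))
  tab <- table(data[[group]])
  if (length(tab) < 2 || sum(tab >= 2) < 2)
    stop("mixed model needs >= 2 individuals with >= 2 records each",
         call. = FALSE)
  f <- stats::as.formula(paste(response, "~",
                               paste(terms, collapse = " + "),
                               "+ (1 |", group, ")"))
  fit <- lme4::lmer(f, data = data, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- vc$vcov[vc$grp == group][1]
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(coef = tidy_terms(beta, se, nrow(data)),
                 n = nrow(data), ranef_var = rv, fit = fit,
                 flags = list(singular = lme4::isSingular(fit))),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat("trend_result (n =", x$n, ")\n")
  tab <- x$coef
  tab$beta <- signif(tab$beta, 4); tab$se <- signif(tab$se, 4)
  tab$ci_lo <- signif(tab$ci_lo, 4); tab$ci_hi <- signif(tab$ci_hi, 4)
  print(tab, row.names = FALSE)
  if (isTRUE(x$flags$singular)) cat("  [singular fit]\n")
  invisible(x)
}

#' Trend tables for every herd x season x (index, target) series
#'
#' Runs [ols_trend()] on each overlap series in a long-format table joined
#' to a climate series, mirroring the herd-by-season coefficient-table
#' layout of distribution-shift analyses.
#'
#' @param overlap data.frame from [overlap_table()].
#' @param climate data.frame with `year`, `npi`.
#' @param terms regression terms (default `c("year", "npi")`).
#' @param min_n skip series with fewer points (default `length(terms) + 2`).
#' @return data.frame: `herd`, `season`, `index`, `target`, plus the tidy
#'   coefficient columns.
#' @export
overlap_trends <- function(overlap, climate, terms = c("year", "npi"),
                           min_n = length(terms) + 2) {
  df <- merge(overlap, climate, by = "year")
  keys <- unique(df[, c("herd", "season", "index", "target")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- df[df$herd == k$herd & df$season == k$season &
                df$index == k$index & df$target == k$target, ]
    if (nrow(sub) < min_n) next
    tr <- ols_trend(sub, "value", terms)
    cf <- tr$coef
    out[[length(out) + 1L]] <- cbind(k, cf, row.names = NULL)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
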