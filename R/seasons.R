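#' Average a daily-rate series onto the day-of-year axis
#'
#' Collapses a (possibly multi-year) [daily_movement_rate()] series to one
#' mean rate per day-of-year 1..365 (day 366 of leap years is folded into
#' 365). Days never covered are `NA`.
#'
#' @param rate_series data.frame from [daily_movement_rate()].
#' @return numeric vector of length 365 (NA where uncovered).
#' @export
rate_by_doy <- function(rate_series) {
  doy <- as.POSIXlt(rate_series$date)$yday + 1L
  doy[doy == 366L] <- 365L
  out <- rep(NA_real_, 365)
  ok <- rate_series$covered & !is.na(rate_series$rate)
  if (any(ok)) {
    m <- tapply(rate_series$rate[ok], doy[ok], mean)
    out[as.integer(names(m))] <- as.numeric(m)
  }
  out
}

# prefix-sum segment SSE machinery (NA-tolerant).
# sse_fun(i, j) = within-segment sum of squared deviations of v[i..j].
make_sse <- function(v) {
  ok <- !is.na(v)
  vv <- ifelse(ok, v, 0)
  S1 <- c(0, cumsum(vv)); S2 <- c(0, cumsum(vv^2)); N <- c(0, cumsum(ok))
  function(i, j) {
    n <- N[j + 1] - N[i]
    s1 <- S1[j + 1] - S1[i]
    s2 <- S2[j + 1] - S2[i]
    ifelse(n <= 1, 0, pmax(0, s2 - s1^2 / n))
  }
}

# best single split of v[lo..hi] into [lo..b-1], [b..hi]; returns
# list(b, reduction) or NULL if no admissible split
best_linear_split <- function(sse, lo, hi, min_days) {
  bs <- seq.int(lo + min_days, hi - min_days + 1L)
  if (lo + min_days > hi - min_days + 1L) return(NULL)
  red <- sse(lo, hi) - sse(lo, bs - 1L) - sse(bs, hi)
  k <- which.max(red)
  list(b = bs[k], reduction = red[k])
}

#' Segment a daily movement-rate series into seasons
#'
#' Recursive partitioning of the day-of-year axis into piecewise-constant
#' mean-rate segments. Each split is the one that maximally reduces the
#' total within-segment sum of squared errors (SSE); splitting stops when
#' `max_segments` is reached or the best available split fails the
#' cost-complexity pruning test (SSE reduction below `prune_frac` of the
#' current total SSE). Segment boundaries are returned as season onset
#' days.
#'
#' With `circular = TRUE` (default) the day-of-year axis is treated as a
#' circle, so a winter season spanning December-February forms a single
#' segment: the first step is an exhaustive search over all admissible pairs
#' of cuts (a single cut cannot partition a circle), after which each arc is
#' split greedily like a linear series.
#'
#' @param rates numeric vector of daily rates indexed by day (day-of-year
#'   1..365 when `circular = TRUE`); `NA` allowed for uncovered days.
#' @param max_segments maximum number of segments (default 8).
#' @param min_segment_days minimum calendar length of a segment (default 14).
#' @param prune_frac accept a split only if it reduces total SSE by at least
#'   this fraction (default 0.05). Scale-invariant: multiplying all rates by
#'   a constant changes no decision.
#' @param circular treat the axis as a circle (default TRUE).
#' @return sorted numeric vector of onset days (possibly empty: a constant
#'   series yields a single segment).
#' @export
partition_rate_series <- function(rates, max_segments = 8,
                                  min_segment_days = 14,
                                  prune_frac = 0.05, circular = TRUE) {
  stopifnot(is.numeric(rates), max_segments >= 1, min_segment_days >= 1)
  n_ok <- sum(!is.na(rates))
  if (n_ok < 2 * min_segment_days)
    stop("rate series too short: need at least ", 2 * min_segment_days,
         " non-missing days, got ", n_ok, call. = FALSE)
  if (!circular) return(greedy_linear(rates, max_segments, min_segment_days,
                                      prune_frac))
  n <- length(rates)
  if (n != 365)
    stop("circular partitioning expects a 365-day day-of-year series",
         call. = FALSE)
  if (max_segments < 2) return(numeric(0))
  # doubled series so any arc is a contiguous linear slice
  v2 <- c(rates, rates)
  sse2 <- make_sse(v2)
  total0 <- sse2(1L, n)
  # exhaustive best pair of cuts (b1 < b2 in 1..365): arcs [b1, b2) and
  # [b2, b1 + 365)
  best <- NULL
  for (b1 in 1:n) {
    b2 <- seq.int(b1 + min_segment_days, b1 + n - min_segment_days)
    b2 <- b2[b2 <= b1 + n - 1L]
    if (!length(b2)) next
    ss <- sse2(b1, b2 - 1L) + sse2(b2, b1 + n - 1L)
    k <- which.max(-ss)
    if (is.null(best) || ss[k] < best$ss)
      best <- list(b1 = b1, b2 = b2[k], ss = ss[k])
  }
  if (is.null(best) || total0 - best$ss <= prune_frac * total0)
    return(numeric(0))
  # arcs as (start index on doubled axis, length); refine greedily
  arcs <- list(c(best$b1, best$b2 - best$b1),
               c(best$b2, best$b1 + n - best$b2))
  total <- best$ss
  while (length(arcs) < max_segments) {
    cand <- lapply(arcs, function(a)
      best_linear_split(sse2, a[1], a[1] + a[2] - 1L, min_segment_days))
    reds <- vapply(cand, function(s) if (is.null(s)) -Inf else s$reduction, 0)
    k <- which.max(reds)
    if (!is.finite(reds[k]) || reds[k] <= prune_frac * total) break
    a <- arcs[[k]]; b <- cand[[k]]$b
    arcs[[k]] <- c(a[1], b - a[1])
    arcs[[length(arcs) + 1L]] <- c(b, a[1] + a[2] - b)
    total <- total - reds[k]
  }
  sort(vapply(arcs, function(a) ((a[1] - 1L) %% n) + 1L, 0L))
}

greedy_linear <- function(v, max_segments, min_days, prune_frac) {
  sse <- make_sse(v)
  segs <- list(c(1L, length(v)))
  total <- sse(1L, length(v))
  onsets <- integer(0)
  while (length(segs) < max_segments) {
    cand <- lapply(segs, function(s)
      best_linear_split(sse, s[1], s[2], min_days))
    reds <- vapply(cand, function(s) if (is.null(s)) -Inf else s$reduction, 0)
    k <- which.max(reds)
    if (!is.finite(reds[k]) || reds[k] <= prune_frac * total) break
    s <- segs[[k]]; b <- cand[[k]]$b
    segs[[k]] <- c(s[1], b - 1L)
    segs[[length(segs) + 1L]] <- c(b, s[2])
    onsets <- c(onsets, b)
    total <- total - reds[k]
  }
  sort(onsets)
}

#' Exhaustive optimal segmentation (oracle)
#'
#' Minimum-SSE segmentation of a linear series into exactly `k` segments by
#' dynamic programming over all boundary placements. Intended as an
#' independent check of the greedy partitioner on short series; cost is
#' O(k n^2).
#'
#' @param rates numeric vector (NA allowed).
#' @param k number of segments.
#' @param min_segment_days minimum segment length.
#' @return list with `onsets` (k-1 boundaries) and `sse` (the optimum).
#' @export
optimal_segmentation <- function(rates, k, min_segment_days = 1) {
  n <- length(rates)
  sse <- make_sse(rates)
  # D[s, j] = min SSE of v[1..j] in s segments
  D <- matrix(Inf, k, n)
  B <- matrix(NA_integer_, k, n)
  for (j in seq_len(n)) if (j >= min_segment_days) D[1, j] <- sse(1L, j)
  if (k > 1) for (s in 2:k) {
    for (j in seq_len(n)) {
      lo <- (s - 1) * min_segment_days
      if (j - min_segment_days < lo) next
      bs <- seq.int(lo + 1L, j - min_segment_days + 1L)
      vals <- D[s - 1, bs - 1L] + sse(bs, j)
      m <- which.min(vals)
      D[s, j] <- vals[m]
      B[s, j] <- bs[m]
    }
  }
  onsets <- integer(0)
  j <- n
  if (k > 1) for (s in k:2) {
    b <- B[s, j]
    onsets <- c(b, onsets)
    j <- b - 1L
  }
  list(onsets = onsets, sse = D[k, n])
}

#' Total SSE of a segmentation
#'
#' @param rates numeric vector.
#' @param onsets boundary positions (first index of each segment after the
#'   first).
#' @param circular whether boundaries live on the day-of-year circle.
#' @return total within-segment SSE.
#' @export
segmentation_sse <- function(rates, onsets, circular = FALSE) {
  n <- length(rates)
  if (!length(onsets)) {
    s <- make_sse(rates)
    return(s(1L, n))
  }
  onsets <- sort(onsets)
  if (!circular) {
    b <- c(1L, onsets, n + 1L)
    s <- make_sse(rates)
    sum(vapply(seq_len(length(b) - 1L),
               function(i) s(b[i], b[i + 1L] - 1L), 0))
  } else {
    s2 <- make_sse(c(rates, rates))
    b <- c(onsets, onsets[1] + n)
    sum(vapply(seq_len(length(b) - 1L),
               function(i) s2(b[i], b[i + 1L] - 1L), 0))
  }
}

#' Aggregate per-individual onsets into a population season calendar
#'
#' Pools every individual's onset days, clusters them on the circular
#' day-of-year axis into `k` transition clusters (the k largest circular
#' gaps between sorted pooled onsets separate the clusters), and takes the
#' circular median (or mean) of each cluster as the population onset.
#'
#' @param onset_list list of numeric onset-day vectors, one per individual.
#' @param k number of seasons.
#' @param method `"circular_median"` (default, robust to stragglers) or
#'   `"circular_mean"`.
#' @param labels optional character vector of `k` season names, assigned in
#'   increasing-onset order.
#' @return object of class `season_partition`: list with `onsets` (sorted),
#'   `k`, `labels`, `method`, `per_individual`.
#' @export
aggregate_onsets <- function(onset_list, k,
                             method = c("circular_median", "circular_mean"),
                             labels = NULL) {
  method <- match.arg(method)
  pooled <- sort(unlist(onset_list))
  if (length(unique(pooled)) < k)
    stop("only ", length(unique(pooled)), " distinct onsets pooled; ",
         "cannot support k = ", k, " seasons - try a smaller k",
         call. = FALSE)
  n <- 365
  gaps <- diff(c(pooled, pooled[1] + n))  # circular gaps after each point
  cut_after <- sort(order(gaps, decreasing = TRUE)[seq_len(k)])
  # clusters are runs between cuts, wrapping past the last pooled point
  m <- length(pooled)
  starts <- c(cut_after[k], cut_after[-k]) %% m + 1L  # index after each cut
  ends <- cut_after
  onsets <- numeric(k)
  for (i in seq_len(k)) {
    idx <- if (starts[i] <= ends[i]) starts[i]:ends[i]
      else c(starts[i]:m, 1:ends[i])
    vals <- pooled[idx]
    ref <- vals[1]
    rel <- (vals - ref) %% n
    stat <- if (method == "circular_median") stats::median(rel) else mean(rel)
    onsets[i] <- ((ref + stat - 1) %% n) + 1
  }
  onsets <- sort(onsets)
  if (is.null(labels)) labels <- sprintf("season_%d", seq_len(k))
  if (length(labels) != k) stop("labels must have length k", call. = FALSE)
  structure(list(onsets = onsets, k = k, labels = labels, method = method,
                 per_individual = onset_list),
            class = "season_partition")
}

#' @export
print.season_partition <- function(x, ...) {
  cat("season_partition:", x$k, "seasons (", x$method, ")\n")
  print(data.frame(season = x$labels, onset_doy = round(x$onsets, 1)))
  invisible(x)
}

#' Season date windows for a given year
#'
#' Expands a [aggregate_onsets()] partition (or any sorted onset/label pair)
#' into concrete date windows. The season starting at the last onset of year
#' `Y` wraps into year `Y + 1`; each season is attributed to the year its
#' window starts in.
#'
#' @param partition a `season_partition`, or a list with `onsets`, `labels`.
#' @param year calendar year the windows start in.
#' @return data.frame: `season`, `year`, `start`, `end` (POSIXct UTC,
#'   half-open `[start, end)`).
#' @export
season_windows <- function(partition, year) {
  on <- round(partition$onsets)
  lab <- partition$labels
  k <- length(on)
  jan1 <- as.POSIXct(sprintf("%d-01-01", year), tz = "UTC")
  jan1n <- as.POSIXct(sprintf("%d-01-01", year + 1), tz = "UTC")
  start <- jan1 + (on - 1) * 86400
  end <- c(start[-1], jan1n + (on[1] - 1) * 86400)
  data.frame(season = lab, year = year, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Per-herd season delineation from telemetry
#'
#' Full segmentation workflow: per individual, daily movement rates are
#' averaged onto the day-of-year axis and partitioned; per herd, individual
#' onsets are aggregated into a population calendar.
#'
#' @param fixes telemetry data.frame (columns `animal_id`, `herd`,
#'   `timestamp`, `x`, `y`).
#' @param k seasons per herd (default 6).
#' @param labels optional season labels (length `k`).
#' @param min_segment_days,prune_frac passed to [partition_rate_series()].
#' @param min_days_per_individual skip individuals with fewer covered days.
#' @return named list (by herd) of `season_partition` objects.
#' @export
delineate_seasons <- function(fixes, k = 6, labels = NULL,
                              min_segment_days = 14, prune_frac = 0.05,
                              min_days_per_individual = 200) {
  if (!"herd" %in% names(fixes)) fixes$herd <- "all"
  out <- list()
  for (h in unique(fixes$herd)) {
    tracks <- split_tracks(fixes[fixes$herd == h, , drop = FALSE])
    onsets <- list()
    for (tr in tracks) {
      rb <- rate_by_doy(daily_movement_rate(tr))
      if (sum(!is.na(rb)) < min_days_per_individual) next
      on <- partition_rate_series(rb, max_segments = k,
                                  min_segment_days = min_segment_days,
                                  prune_frac = prune_frac)
      if (length(on)) onsets[[length(onsets) + 1L]] <- on
    }
    out[[h]] <- aggregate_onsets(onsets, k = k, labels = labels)
  }
  out
}
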