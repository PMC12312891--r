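#' Per-class areas of a classified scene
#'
#' Converts per-class pixel counts to square kilometres using the map's
#' pixel size; mudflat and sand are additionally reported merged, the
#' granularity of a seasonal-lake monitoring table.
#'
#' @param map A [class_map()].
#' @return One-row data frame: `date`, `water_km2`, `vegetation_km2`,
#'   `mudflat_km2`, `sand_km2`, `mudflat_sand_km2`, `total_km2`.
#' @export
class_areas <- function(map) {
  stopifnot(inherits(map, "class_map"))
  px_km2 <- (map$pixel_size / 1000)^2
  count <- function(code) sum(map$labels == code)
  w <- count(LAKE_CLASSES[["water"]]) * px_km2
  v <- count(LAKE_CLASSES[["vegetation"]]) * px_km2
  m <- count(LAKE_CLASSES[["mudflat"]]) * px_km2
  s <- count(LAKE_CLASSES[["sand"]]) * px_km2
  data.frame(date = map$date, water_km2 = w, vegetation_km2 = v,
             mudflat_km2 = m, sand_km2 = s, mudflat_sand_km2 = m + s,
             total_km2 = w + v + m + s, stringsAsFactors = FALSE)
}

#' Build an area series from classified maps
#'
#' @param maps List of [class_map()]s with distinct, parseable dates.
#' @param source Provenance tag stored on the series.
#' @return An `area_series`: data frame with one [class_areas()] row per
#'   map, ordered by date.
#' @export
area_series <- function(maps, source = "classified maps") {
  rows <- do.call(rbind, lapply(maps, class_areas))
  as_area_series(rows, source = source)
}

#' Coerce a data frame to an area series
#'
#' @param df Data frame with columns `date`, `water_km2`, `vegetation_km2`
#'   and either `mudflat_sand_km2` or both `mudflat_km2` and `sand_km2`.
#' @param source Provenance tag.
#' @return An `area_series` data frame, ordered by date.
#' @export
as_area_series <- function(df, source = "table") {
  need <- c("date", "water_km2", "vegetation_km2")
  if (!all(need %in% names(df))) {
    stopf("area series needs columns %s", paste(need, collapse = ", "))
  }
  if (!"mudflat_sand_km2" %in% names(df)) {
    if (!all(c("mudflat_km2", "sand_km2") %in% names(df))) {
      stopf("area series needs mudflat_sand_km2 or mudflat_km2 + sand_km2")
    }
    df$mudflat_sand_km2 <- df$mudflat_km2 + df$sand_km2
  }
  dates <- tryCatch(as.Date(df$date), error = function(e) NA)
  if (anyNA(dates)) stopf("unparseable dates in area series")
  if (anyDuplicated(dates)) stopf("duplicate dates in area series")
  df <- df[order(dates), , drop = FALSE]
  df$date <- as.character(sort(dates))
  rownames(df) <- NULL
  areas <- df[c("water_km2", "vegetation_km2", "mudflat_sand_km2")]
  if (any(areas < 0)) stopf("negative areas in series")
  structure(df, class = c("area_series", "data.frame"), source = source)
}

series_classes <- c("water", "vegetation", "mudflat_sand")

series_column <- function(series, class) {
  class <- match.arg(as.character(class), series_classes)
  series[[paste0(class, "_km2")]]
}

#' Descriptive statistics of one class-area series
#'
#' @param series An `area_series`.
#' @param class One of `"water"`, `"vegetation"`, `"mudflat_sand"`.
#' @return List with `mean`, `sd` (sample, divisor n-1), `min`, `max`, and
#'   the dates of the extremes (`min_date`, `max_date`), plus `n`.
#' @export
descriptive_stats <- function(series, class) {
  x <- series_column(series, class)
  if (length(x) < 2L) stopf("need at least 2 records for a standard deviation")
  i_min <- which.min(x); i_max <- which.max(x)
  list(class = class, n = length(x), mean = mean(x), sd = sd(x),
       min = x[i_min], max = x[i_max],
       min_date = series$date[i_min], max_date = series$date[i_max])
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs test: `G = max |x_i - mean| / s` with the sample
#' standard deviation, compared against the critical value
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` where `t` is the
#' upper `alpha/(2n)` Student-t quantile on `n - 2` degrees of freedom.
#' A zero-variance series is reported as degenerate with no outlier.
#'
#' @param x Numeric vector (n >= 3) or an `area_series` column.
#' @param alpha Significance level in (0, 1).
#' @return A `grubbs_result`: `statistic`, `critical`, `alpha`, `n`,
#'   `index` of the most extreme point, `outlier` (logical), `p_value`
#'   (analogue from the t mapping), `degenerate`.
#' @export
grubbs <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stopf("Grubbs test needs n >= 3")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  s <- sd(x)
  if (s == 0) {
    return(structure(list(statistic = 0, critical = grubbs_critical(n, alpha),
                          alpha = alpha, n = n, index = 1L, outlier = FALSE,
                          p_value = 1, degenerate = TRUE),
                     class = "grubbs_result"))
  }
  g_i <- abs(x - mean(x)) / s
  idx <- which.max(g_i)
  g <- g_i[idx]
  crit <- grubbs_critical(n, alpha)
  # invert the critical-value mapping to get the p-value analogue
  # 2n * P(T > t); Bonferroni-style, deliberately left uncapped (it can
  # exceed 1 for unremarkable extremes)
  g2 <- min(g^2, ((n - 1)^2 / n) * (1 - 1e-12))
  t2 <- (n - 2) * g2 / ((n - 1)^2 / n - g2)
  p <- 2 * n * pt(sqrt(t2), df = n - 2, lower.tail = FALSE)
  structure(list(statistic = g, critical = crit, alpha = alpha, n = n,
                 index = idx, outlier = g > crit, p_value = p,
                 degenerate = FALSE),
            class = "grubbs_result")
}

#' Grubbs critical value
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @return The two-sided Grubbs critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3L) stopf("Grubbs test needs n >= 3")
  t <- qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("<grubbs_result> G = %.4f vs G_crit(%d, %.2f) = %.4f -> %s\n",
              x$statistic, x$n, x$alpha, x$critical,
              if (x$outlier) "outlier" else "no outlier"))
  invisible(x)
}

#' Pearson correlation with its coefficient of determination
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with non-zero variance.
#' @return List with `r` and `r_squared`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("series lengths differ")
  if (length(x) < 3L) stopf("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance: correlation undefined")
  r <- cor(x, y)
  list(r = r, r_squared = r^2)
}

#' Pairwise class-area correlations of a series
#'
#' @param series An `area_series`.
#' @return Data frame with columns `pair`, `r`, `r_squared` for the three
#'   class pairs.
#' @export
series_correlations <- function(series) {
  pairs <- list(c("water", "vegetation"), c("water", "mudflat_sand"),
                c("vegetation", "mudflat_sand"))
  do.call(rbind, lapply(pairs, function(p) {
    res <- pearson(series_column(series, p[1]), series_column(series, p[2]))
    data.frame(pair = paste(p, collapse = "-"), r = res$r,
               r_squared = res$r_squared)
  }))
}

share_table <- function(series) {
  tot <- series$water_km2 + series$vegetation_km2 + series$mudflat_sand_km2
  if (any(tot <= 0)) stopf("record with non-positive total area")
  data.frame(date = series$date,
             year = as.integer(substr(series$date, 1, 4)),
             month = as.integer(substr(series$date, 6, 7)),
             water = 100 * series$water_km2 / tot,
             vegetation = 100 * series$vegetation_km2 / tot,
             mudflat_sand = 100 * series$mudflat_sand_km2 / tot)
}

#' Inter-annual mean class shares
#'
#' Per-record class shares (percent of the record's total area) averaged,
#' unweighted, within each calendar year.
#'
#' @param series An `area_series`.
#' @return Data frame with columns `year`, `water`, `vegetation`,
#'   `mudflat_sand` (percent).
#' @export
annual_share <- function(series) {
  sh <- share_table(series)
  agg <- aggregate(sh[c("water", "vegetation", "mudflat_sand")],
                   by = list(year = sh$year), FUN = mean)
  agg[order(agg$year), , drop = FALSE]
}

#' Intra-annual (calendar month) mean class shares
#'
#' Groups records by calendar month across all years and averages the
#' per-record shares; months never observed are absent from the output.
#'
#' @param series An `area_series`.
#' @return Data frame with columns `month`, `n_scenes`, `water`,
#'   `vegetation`, `mudflat_sand` (percent).
#' @export
monthly_share <- function(series) {
  sh <- share_table(series)
  agg <- aggregate(sh[c("water", "vegetation", "mudflat_sand")],
                   by = list(month = sh$month), FUN = mean)
  agg$n_scenes <- as.vector(table(factor(sh$month, levels = agg$month)))
  agg[order(agg$month), c("month", "n_scenes", "water", "vegetation",
                          "mudflat_sand")]
}
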