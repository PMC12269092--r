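#' Seasonal Mann-Kendall test with Sen's slope
#'
#' Nonparametric trend test for monthly series: the Mann-Kendall S
#' statistic is summed over seasons (pairs are formed only within a
#' season, so the annual cycle does not masquerade as trend), the
#' variance uses the standard tie correction per season, Z carries a
#' +/-1 continuity correction, and the two-sided p comes from the normal
#' approximation. Sen's slope is the median of all within-season pairwise
#' slopes, converted to units per year. Following the browning
#' classification protocol, slopes with p >= 0.05 are carried as zero in
#' `slope_for_clustering`.
#'
#' @param data Data frame with a date column and a value column.
#' @param date,value Column names (unquoted) of the time stamps (`Date`)
#'   and the measurements. Missing values are dropped.
#' @param period Number of seasons per year (12 for monthly data).
#' @param alpha Significance level used for the zero-replacement rule.
#' @return An object of class `smk_fit`; see [tidy.smk_fit()].
#' @examples
#' d <- tibble::tibble(date = seq(as.Date("2000-01-01"), by = "month",
#'                                length.out = 60),
#'                     value = 0.1 * (0:59))
#' tidy(seasonal_mann_kendall(d))
#' @export
seasonal_mann_kendall <- function(data, date = date, value = value,
                                  period = 12, alpha = 0.05) {
  dates <- dplyr::pull(data, {{ date }})
  values <- dplyr::pull(data, {{ value }})
  ok <- !is.na(values) & !is.na(dates)
  dates <- dates[ok]
  values <- values[ok]
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  t_mon <- month_index(dates)
  ord <- order(t_mon)
  t_mon <- t_mon[ord]
  values <- values[ord]
  season <- t_mon %% period

  tab <- table(season)
  if (sum(tab >= 2) < 2) {
    abort_insufficient("need >= 2 observations in >= 2 seasons")
  }

  s_stat <- 0
  var_s <- 0
  slopes <- numeric(0)
  for (s in unique(season)) {
    x <- values[season == s]
    t <- t_mon[season == s]
    n <- length(x)
    if (n < 2) next
    pairs <- utils::combn(n, 2)
    dx <- x[pairs[2, ]] - x[pairs[1, ]]
    dt <- t[pairs[2, ]] - t[pairs[1, ]]
    s_stat <- s_stat + sum(sign(dx))
    ties <- table(x)
    var_s <- var_s + (n * (n - 1) * (2 * n + 5) -
                        sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    slopes <- c(slopes, dx[dt != 0] / dt[dt != 0])
  }

  z <- if (s_stat > 0) (s_stat - 1) / sqrt(var_s)
       else if (s_stat < 0) (s_stat + 1) / sqrt(var_s)
       else 0
  p <- if (var_s == 0) 1 else 2 * pnorm(-abs(z))
  # pairwise slopes are per month; 12 converts to per year
  sen <- if (length(slopes)) median(slopes) * 12 else 0
  significant <- is.finite(p) && p < alpha

  structure(
    list(s_stat = s_stat, var_s = var_s, z = z, p_value = p,
         sen_slope = sen, significant = significant,
         slope_for_clustering = if (significant) sen else 0,
         n = length(values), n_seasons = sum(tab >= 2), period = period),
    class = "smk_fit"
  )
}

# Months elapsed since 1970-01-01 (calendar months; monthly resolution
# needs no leap handling).
month_index <- function(dates) {
  lt <- as.POSIXlt(dates)
  (lt$year + 1900L) * 12L + lt$mon
}

#' @export
print.smk_fit <- function(x, ...) {
  cat("Seasonal Mann-Kendall fit\n")
  cat(sprintf("  S = %d, Var(S) = %.1f, Z = %.3f, p = %.4g\n",
              x$s_stat, x$var_s, x$z, x$p_value))
  cat(sprintf("  Sen slope = %.5g per year (%ssignificant at 0.05)\n",
              x$sen_slope, if (x$significant) "" else "not "))
  invisible(x)
}

#' Tidy a seasonal Mann-Kendall fit
#'
#' @param x An `smk_fit` object.
#' @param ... Unused.
#' @return One-row tibble with the test statistic, p-value, Sen slope
#'   (per year) and the zero-replaced slope used for clustering.
#' @method tidy smk_fit
#' @export
tidy.smk_fit <- function(x, ...) {
  tibble(s_stat = x$s_stat, var_s = x$var_s, z = x$z, p_value = x$p_value,
         sen_slope = x$sen_slope, significant = x$significant,
         slope_for_clustering = x$slope_for_clustering)
}

#' @rdname tidy.smk_fit
#' @method glance smk_fit
#' @export
glance.smk_fit <- function(x, ...) {
  tibble(n = x$n, n_seasons = x$n_seasons, period = x$period)
}

#' Per-lake, per-parameter trend table
#'
#' Runs [seasonal_mann_kendall()] on every (lake, parameter) series of a
#' long-term chemistry table. Records of differing extent are honoured
#' (e.g. colour ending early, SUVA254 starting late); a parameter with
#' fewer than `min_months` observations for a lake is flagged missing
#' rather than failing the run.
#'
#' @param chem Chemistry tibble as produced by [gen_chemistry()] (rows
#'   from several lakes may be bound together).
#' @param parameters Character vector of chemistry columns to test.
#' @param min_months Minimum observations per series.
#' @param period,alpha Passed to [seasonal_mann_kendall()].
#' @return Tibble with one row per (lake, parameter): the `smk_fit`
#'   statistics plus `n` and `missing`.
#' @export
trend_table <- function(chem,
                        parameters = c("doc", "color", "suva254", "ph",
                                       "so4_no3"),
                        min_months = 24, period = 12, alpha = 0.05) {
  parameters <- intersect(parameters, names(chem))
  grid <- tidyr::expand_grid(lake_id = unique(chem$lake_id),
                             parameter = parameters)
  purrr::pmap_dfr(grid, function(lake_id, parameter) {
    d <- chem[chem$lake_id == lake_id, c("date", parameter)]
    names(d)[2] <- "value"
    d <- d[!is.na(d$value), ]
    base <- tibble(lake_id = lake_id, parameter = parameter)
    if (nrow(d) < min_months) {
      return(dplyr::bind_cols(base, tibble(
        s_stat = NA_real_, var_s = NA_real_, z = NA_real_,
        p_value = NA_real_, sen_slope = NA_real_, significant = NA,
        slope_for_clustering = NA_real_, n = nrow(d), missing = TRUE)))
    }
    fit <- seasonal_mann_kendall(d, period = period, alpha = alpha)
    dplyr::bind_cols(base, tidy(fit), tibble(n = fit$n, missing = FALSE))
  })
}

#' Classify browning status by k-means on standardized Sen slopes
#'
#' Standardizes the zero-replaced Sen slopes of DOC, colour and SUVA254
#' across lakes (z-scores per dimension) and partitions the lakes into
#' three clusters with k-means (100 restarts, fixed seed). Labels are
#' mapped deterministically to the mild/moderate/intense browning
#' ordering: cluster A has the lowest mean standardized DOC + colour
#' slope, and of the remaining two, C has the more negative mean
#' standardized SUVA254 slope.
#'
#' @param trends A [trend_table()] result containing `doc`, `color` and
#'   `suva254` rows.
#' @param seed Integer seed for the k-means restarts.
#' @return Object of class `browning_clusters`: a tibble with `lake_id`,
#'   `cluster` (factor A/B/C) and the standardized slopes, with the
#'   `stats::kmeans` fit attached as attribute `kmeans`.
#' @export
classify_browning <- function(trends, seed = 1) {
  wide <- trends %>%
    filter(.data$parameter %in% c("doc", "color", "suva254")) %>%
    select("lake_id", "parameter", "slope_for_clustering") %>%
    tidyr::pivot_wider(names_from = "parameter",
                       values_from = "slope_for_clustering") %>%
    tidyr::drop_na()
  if (nrow(wide) < 3) {
    abort_insufficient("need >= 3 lakes with DOC, colour and SUVA254 slopes")
  }
  zs <- function(x) if (sd(x) == 0) rep(0, length(x)) else
    (x - mean(x)) / sd(x)
  m <- cbind(doc = zs(wide$doc), color = zs(wide$color),
             suva254 = zs(wide$suva254))

  if (all(apply(m, 2, sd) == 0)) {
    warn("all lakes have identical slopes; degenerate clustering",
         class = "lakephoto_degenerate_clustering")
    out <- tibble(lake_id = wide$lake_id,
                  cluster = factor("A", levels = c("A", "B", "C")),
                  z_doc = m[, 1], z_color = m[, 2], z_suva254 = m[, 3])
    return(structure(out, class = c("browning_clusters", class(out)),
                     kmeans = NULL))
  }

  ord <- order(wide$lake_id)
  fit <- withr::with_seed(sub_seed(seed, 5L),
                          kmeans(m[ord, , drop = FALSE], centers = 3,
                                 nstart = 100, iter.max = 100))
  assign_ord <- fit$cluster
  assignment <- integer(nrow(m))
  assignment[ord] <- assign_ord

  centers <- fit$centers
  a <- which.min(centers[, "doc"] + centers[, "color"])
  rest <- setdiff(1:3, a)
  cc <- rest[which.min(centers[rest, "suva254"])]
  b <- setdiff(rest, cc)
  labels <- character(3)
  labels[c(a, b, cc)] <- c("A", "B", "C")

  out <- tibble(lake_id = wide$lake_id,
                cluster = factor(labels[assignment],
                                 levels = c("A", "B", "C")),
                z_doc = m[, 1], z_color = m[, 2], z_suva254 = m[, 3])
  structure(out, class = c("browning_clusters", class(out)), kmeans = fit)
}

#' @rdname classify_browning
#' @param x A `browning_clusters` object.
#' @param ... Unused.
#' @method glance browning_clusters
#' @export
glance.browning_clusters <- function(x, ...) {
  fit <- attr(x, "kmeans")
  tibble(n_lakes = nrow(x), k = length(levels(x$cluster)),
         tot_withinss = if (is.null(fit)) NA_real_ else fit$tot.withinss,
         betweenss = if (is.null(fit)) NA_real_ else fit$betweenss)
}
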