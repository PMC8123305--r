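# Count aggregation and the period-comparison statistics: Shapiro-Wilk
# normality, two-group one-way ANOVA at alpha = 0.05, polynomial display
# trends, and percent-change summaries.

#' Aggregate tweets into a day- or hour-level count series
#'
#' Every bin of the period is present, including empty ones (count 0), so
#' the series is contiguous at the stated granularity; counts sum to the
#' number of tweets falling inside the period.
#'
#' @param tweets Corpus tibble (typically the predicted-complaint subset).
#' @param granularity `"day"` or `"hour"`.
#' @param period Length-2 `c(start, end)` dates, start inclusive, end
#'   exclusive (UTC midnights).
#' @param period_tag Label attached to the series.
#' @return A `count_series` tibble: `bin_start` (POSIXct UTC), `count`.
#' @export
aggregate_counts <- function(tweets, granularity = c("day", "hour"), period,
                             period_tag = "") {
  granularity <- match.arg(granularity)
  period <- as.Date(period)
  stopifnot(length(period) == 2L, period[[2L]] > period[[1L]])
  step <- if (granularity == "day") 86400 else 3600
  start <- as.POSIXct(paste(period[[1L]], "00:00:00"), tz = "UTC")
  end <- as.POSIXct(paste(period[[2L]], "00:00:00"), tz = "UTC")
  bins <- seq(start, end - step, by = step)
  ts <- tweets$created_at
  inside <- ts >= start & ts < end
  idx <- floor(as.numeric(difftime(ts[inside], start, units = "secs")) / step) + 1L
  counts <- tabulate(idx, length(bins))
  out <- tibble::tibble(bin_start = bins, count = counts)
  class(out) <- c("count_series", class(out))
  attr(out, "granularity") <- granularity
  attr(out, "period_tag") <- period_tag
  out
}

#' Shapiro-Wilk normality test of a count series
#'
#' Significance is judged at alpha = 0.05 by convention; the pipeline
#' reports this result next to every ANOVA rather than blocking on it.
#'
#' @param series A `count_series` (or numeric vector), n >= 3,
#'   non-constant.
#' @param alpha_level Significance threshold (default 0.05).
#' @return A `normality_result`: `W`, `p_value`, `alpha_level`, `normal`
#'   (logical: not rejected at `alpha_level`).
#' @export
normality_test <- function(series, alpha_level = 0.05) {
  x <- if (is.data.frame(series)) series$count else as.numeric(series)
  if (length(x) < 3L) stop("normality test needs at least 3 observations", call. = FALSE)
  if (sd(x) == 0) {
    stop("normality test undefined for a constant series", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  structure(list(W = unname(sw$statistic), p_value = sw$p.value,
                 alpha_level = alpha_level, normal = sw$p.value >= alpha_level),
            class = "normality_result")
}

#' Two-group one-way ANOVA between count series
#'
#' Compares the two periods' mean bin counts with a one-way analysis of
#' variance (equal-variance F test; for two groups F equals the squared
#' pooled two-sample t statistic). Significance at alpha = 0.05.
#'
#' @param series_a,series_b Two `count_series` of the same granularity
#'   (or numeric vectors), each with at least 2 observations.
#' @param alpha_level Significance threshold (default 0.05).
#' @return A `group_comparison`: `F`, `p_value`, `df_between`,
#'   `df_within`, `significant`.
#' @export
compare_groups <- function(series_a, series_b, alpha_level = 0.05) {
  ga <- if (is.data.frame(series_a)) attr(series_a, "granularity") else NULL
  gb <- if (is.data.frame(series_b)) attr(series_b, "granularity") else NULL
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb)) {
    stop("series have different granularities", call. = FALSE)
  }
  a <- if (is.data.frame(series_a)) series_a$count else as.numeric(series_a)
  b <- if (is.data.frame(series_b)) series_b$count else as.numeric(series_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      stop("ANOVA undefined: zero within-group variance and equal means",
           call. = FALSE)
    }
    # zero within-group variance with distinct means: infinite F
    return(structure(list(F = Inf, p_value = 0,
                          df_between = 1L, df_within = length(y) - 2L,
                          significant = TRUE),
                     class = "group_comparison"))
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  structure(list(F = unname(fit$statistic), p_value = fit$p.value,
                 df_between = as.integer(unname(fit$parameter[1L])),
                 df_within = as.integer(unname(fit$parameter[2L])),
                 significant = fit$p.value < alpha_level),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4f, df = (%d, %d), p = %.4g (%s at 0.05)\n",
              x$F, x$df_between, x$df_within, x$p_value,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Percent ratio and percent change between two period counts
#'
#' `ratio_pct = 100 * count_cmp / count_ref` and
#' `change_pct = ratio_pct - 100`, rounded half-even to 2 decimals;
#' `change_headline` is the integer display form of the change.
#'
#' @param count_ref Reference-period count (> 0).
#' @param count_cmp Comparison-period count.
#' @return A list: `ratio_pct`, `change_pct`, `change_headline`.
#' @export
ratio_report <- function(count_ref, count_cmp) {
  if (length(count_ref) != 1L || is.na(count_ref) || count_ref <= 0) {
    stop("reference count must be positive", call. = FALSE)
  }
  ratio <- 100 * count_cmp / count_ref
  list(ratio_pct = round(ratio, 2),
       change_pct = round(ratio - 100, 2),
       change_headline = round(ratio - 100))
}

#' Least-squares polynomial trend of a count series
#'
#' Fits a polynomial of the given degree (default 6, the display-trend
#' convention) to counts over the bin index, using an orthogonal
#' (centered and scaled) polynomial basis for numerical conditioning.
#' Coefficients are reported in that orthogonal basis.
#'
#' @param series A `count_series` (or numeric vector).
#' @param degree Polynomial degree (default 6); requires n > degree.
#' @return A `trend_fit`: `degree`, `coefficients` (orthogonal basis),
#'   `fitted` (per bin), `residuals`.
#' @export
trend_fit <- function(series, degree = 6L) {
  y <- if (is.data.frame(series)) series$count else as.numeric(series)
  n <- length(y)
  degree <- as.integer(degree)
  if (n <= degree) {
    stop(sprintf("need more than degree + 1 = %d points (got %d)",
                 degree + 1L, n), call. = FALSE)
  }
  idx <- seq_len(n) - 1
  fit <- if (degree == 0L) stats::lm(y ~ 1) else stats::lm(y ~ stats::poly(idx, degree))
  structure(list(degree = degree,
                 coefficients = unname(stats::coef(fit)),
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::resid(fit))),
            class = "trend_fit")
}

#' Plot two count series with their polynomial trends
#'
#' Draws the two periods' counts over bin index with dotted degree-`degree`
#' trend curves overlaid, mirroring the usual two-period comparison figure.
#'
#' @param series_a,series_b Two `count_series` of equal granularity.
#' @param degree Trend polynomial degree (default 6).
#' @param labels Legend labels for the two series.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the two `trend_fit`s.
#' @export
plot_count_series <- function(series_a, series_b, degree = 6L,
                              labels = c("period A", "period B"), ...) {
  ya <- series_a$count; yb <- series_b$count
  ta <- trend_fit(series_a, degree); tb <- trend_fit(series_b, degree)
  xa <- seq_along(ya); xb <- seq_along(yb)
  graphics::plot(xa, ya, type = "l", col = "blue", xlab = "bin index",
                 ylab = "complaint count",
                 ylim = range(c(ya, yb)), ...)
  graphics::lines(xb, yb, col = "red")
  graphics::lines(xa, ta$fitted, col = "blue", lty = 3)
  graphics::lines(xb, tb$fitted, col = "red", lty = 3)
  graphics::legend("topleft", legend = labels, col = c("blue", "red"),
                   lty = 1, bty = "n")
  invisible(list(trend_a = ta, trend_b = tb))
}
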